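two_member_matrix <- function(p1, p2, labels = NULL, levels = c("a", "b")) {
  n <- length(p1)
  lab <- if (is.null(labels)) rep(levels[1], n) else labels
  score_matrix(list(make_scoreset("svm", p1, lab, levels = levels),
                    make_scoreset("knn", p2, lab, levels = levels)))
}

test_that("weighted sum: equal weights average, single member is identity", {
  m <- two_member_matrix(0.8, 0.6)
  f <- weighted_sum_fuse(m, c(0.5, 0.5))
  expect_equal(unname(f$scores[1, 2]), 0.7)

  single <- score_matrix(list(make_scoreset("svm", c(0.3, 0.9), c("a", "b"))))
  fs <- weighted_sum_fuse(single, 1.0)
  expect_equal(unname(fs$scores), unname(single$scores[[1]]))
  expect_equal(fs$accuracy, 1.0)
})

test_that("weighted sum on a 2-sample fixture matches the hand-computed table", {
  # member scores for class b: (0.9, 0.2); weights (1.0, 0.1)
  m <- two_member_matrix(c(0.9, 0.4), c(0.2, 0.3), labels = c("b", "a"))
  f <- weighted_sum_fuse(m, c(1.0, 0.1))
  # class-b fused: 1.0*0.9 + 0.1*0.2 = 0.92 ; class-a: 1.0*0.1 + 0.1*0.8 = 0.18
  expect_equal(unname(f$scores[1, ]), c(0.18, 0.92))
  expect_equal(as.character(f$predictions[1]), "b")
  # sample 2: class-b 1.0*0.4+0.1*0.3 = 0.43; class-a 1.0*0.6+0.1*0.7 = 0.67
  expect_equal(unname(f$scores[2, ]), c(0.67, 0.43))
  expect_equal(as.character(f$predictions[2]), "a")
  expect_equal(f$accuracy, 1.0)
})

test_that("weighted product: annihilation, identity, direct evaluation", {
  m <- two_member_matrix(c(0, 0.8), c(0.7, 0.5))
  f <- weighted_product_fuse(m, c(1.0, 0.5))
  expect_equal(unname(f$scores[1, 2]), 0)                  # zero annihilates
  expect_equal(unname(f$scores[2, 2]), 0.8 * sqrt(0.5))    # 0.5657
  single <- score_matrix(list(make_scoreset("svm", c(0.3, 0.9), c("a", "b"))))
  fp <- weighted_product_fuse(single, 1.0)
  expect_equal(unname(fp$scores), unname(single$scores[[1]]))
})

test_that("Bayes rule: indifference, direct value, saturation, singularity", {
  expect_equal(bayes_fuse(two_member_matrix(0.5, 0.5), weight = 1)$scores[1, 2],
               0.5, ignore_attr = TRUE)
  f <- bayes_fuse(two_member_matrix(0.8, 0.8), weight = 1)
  expect_equal(unname(f$scores[1, 2]), 0.64 / (0.04 + 0.64))  # 0.9412
  expect_equal(unname(bayes_fuse(two_member_matrix(1, 0.3), weight = 1)$scores[1, 2]),
               1)
  expect_warning(
    fs <- bayes_fuse(two_member_matrix(1, 0), weight = 1),
    "singular")
  expect_equal(unname(fs$scores[1, 2]), 0.5)
})

test_that("Bayes rule is symmetric in its members at weight 1", {
  set.seed(2)
  pa <- runif(20); pb <- runif(20)
  f1 <- bayes_fuse(two_member_matrix(pa, pb), weight = 1)
  f2 <- bayes_fuse(two_member_matrix(pb, pa), weight = 1)
  expect_equal(unname(f1$scores), unname(f2$scores))
})

test_that("fusion rules map [0,1] inputs into [0,1] and Bayes is monotone", {
  set.seed(3)
  for (rep in 1:200) {
    p <- runif(3); w <- sample(1:10, 3) / 10
    m3 <- score_matrix(list(make_scoreset("svm", p[1], "a"),
                            make_scoreset("knn", p[2], "a"),
                            make_scoreset("sgd", p[3], "a")))
    wsum <- weighted_sum_fuse(m3, w / sum(w))   # weights summing to 1
    expect_true(all(wsum$scores >= 0 & wsum$scores <= 1))
    wprod <- weighted_product_fuse(m3, w)
    expect_true(all(wprod$scores >= 0 & wprod$scores <= 1))
    s0 <- bayes_fuse(two_member_matrix(p[1], p[2]), weight = 1)$scores[1, 2]
    expect_gte(s0, 0); expect_lte(s0, 1)
    eps <- runif(1, 0, 1 - p[1])
    s1 <- bayes_fuse(two_member_matrix(p[1] + eps, p[2]), weight = 1)$scores[1, 2]
    expect_gte(s1, s0 - 1e-12)
  }
})

test_that("misaligned or ill-formed inputs are rejected", {
  a <- make_scoreset("svm", c(0.1, 0.9), c("a", "b"))
  b <- make_scoreset("knn", c(0.2, 0.8), c("a", "b"),
                     ids = c("other1", "other2"))
  expect_error(score_matrix(list(a, b)), "misaligned")
  m <- two_member_matrix(0.5, 0.5)
  expect_error(weighted_sum_fuse(m, c(0.5, 0.5, 0.5)), "one weight per member")
  expect_error(weighted_sum_fuse(m, c(0, 1)), "weights")
  expect_error(bayes_fuse(m, weight_on = 3), "weight_on")
  neg <- score_matrix(list(make_scoreset("svm", 0.5, "a")))
  neg$scores[[1]][1, 1] <- -0.1
  expect_error(weighted_product_fuse(neg, 1), "non-negative")
})

search_fixture <- function(seed = 10, n = 30) {
  set.seed(seed)
  labels <- rep(c("a", "b"), length.out = n)
  mk <- function(fam, noise) {
    p <- ifelse(labels == "b", 0.7, 0.3) + rnorm(n, 0, noise)
    make_scoreset(fam, pmin(pmax(p, 0.01), 0.99), labels)
  }
  list(cands = list(mk("svm", 0.15), mk("knn", 0.25), mk("sgd", 0.35)),
       labels = factor(labels, levels = c("a", "b")))
}

test_that("grid search equals the nested-loop oracle for sum and product", {
  fx <- search_fixture()
  for (rule in c("sum", "product")) {
    res <- search_weights_and_combinations(fx$cands, rule, sizes = 2:3,
                                           labels = fx$labels)
    for (size in 2:3) {
      orc <- oracle_search(fx$cands, rule, size, fx$labels)
      got <- res$per_size[[as.character(size)]]
      expect_equal(got$accuracy, orc$accuracy)
      expect_equal(got$member_index, orc$member_index)
      expect_equal(got$weights, orc$weights)
      expect_equal(got$n_evaluations, orc$n_evaluations)
    }
  }
})

test_that("Bayes pair search equals its oracle including evaluation counts", {
  fx <- search_fixture(seed = 11)
  res <- search_weights_and_combinations(fx$cands, "bayes", sizes = 5,
                                         labels = fx$labels)
  orc <- oracle_search_bayes(fx$cands, fx$labels)
  got <- res$per_size[["2"]]
  expect_equal(got$accuracy, orc$accuracy)
  expect_equal(got$member_index, orc$member_index)
  expect_equal(got$n_evaluations, orc$n_evaluations)  # pairs x 2 x 10
})

test_that("two candidates under the sum rule cost exactly 100 evaluations", {
  fx <- search_fixture()
  res <- search_weights_and_combinations(fx$cands[1:2], "sum", sizes = 2,
                                         labels = fx$labels)
  expect_equal(res$per_size[["2"]]$n_evaluations, 100L)
})

test_that("a dominant member keeps accuracy 1.0 in any subset containing it", {
  labels <- rep(c("a", "b"), 15)
  perfect <- make_scoreset("svm", ifelse(labels == "b", 0.95, 0.05), labels)
  noisy <- make_scoreset("knn", rep(0.5, 30), labels)
  res <- search_weights_and_combinations(list(perfect, noisy), "sum",
                                         sizes = 2)
  expect_equal(res$per_size[["2"]]$accuracy, 1.0)
  expect_false(res$per_size[["2"]]$improves_single)  # cannot beat 1.0 strictly
  expect_equal(res$best_single_accuracy, 1.0)
})

test_that("search accuracy bounds any manually specified configuration", {
  fx <- search_fixture(seed = 12)
  res <- search_weights_and_combinations(fx$cands, "sum", sizes = 2,
                                         labels = fx$labels)
  best <- res$per_size[["2"]]$accuracy
  set.seed(1)
  for (rep in 1:20) {
    memb <- sort(sample(3, 2))
    w <- sample(1:10, 2, replace = TRUE) / 10
    f <- weighted_sum_fuse(score_matrix(fx$cands[memb]), w, labels = fx$labels)
    expect_lte(f$accuracy, best + 1e-12)
  }
})

test_that("classifier-based fusion learns the derived 4-column score space", {
  labels <- rep(c("a", "b"), each = 30)
  sep1 <- make_scoreset("svm", ifelse(labels == "b", 0.9, 0.1), labels)
  sep2 <- make_scoreset("knn", ifelse(labels == "b", 0.8, 0.2), labels)
  res <- classifier_score_fusion(list(sep1, sep2),
                                 default_classifier_specs(
                                   c("decision_tree", "knn"), k_range = 2L),
                                 split_ratio = 0.7, seed = 5)
  expect_named(res, c("decision_tree", "knn"))
  for (ss in res) {
    expect_equal(ss$test_accuracy, 1.0)
    expect_equal(nrow(ss$scores), 18L)  # 30% of 60
  }

  flat1 <- make_scoreset("svm", rep(0.5, 60), labels)
  flat2 <- make_scoreset("knn", rep(0.5, 60), labels)
  res0 <- classifier_score_fusion(list(flat1, flat2),
                                  default_classifier_specs("knn", 2L),
                                  seed = 6)
  expect_lt(abs(res0$knn$test_accuracy - 0.5), 0.25)

  expect_error(classifier_score_fusion(list(sep1),
                                       default_classifier_specs("knn", 2L)),
               "two score sets")
})
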