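test_that("split_dataset is stratified, disjoint, exhaustive and seeded", {
  tbl <- make_feature_table(n_per_class = 50)   # 100 balanced rows
  sp <- split_dataset(tbl, 0.8, seed = 3)
  expect_length(sp$train_index, 80L)
  expect_length(sp$test_index, 20L)
  y <- feature_labels(tbl)
  expect_equal(as.integer(table(y[sp$train_index])), c(40L, 40L))
  expect_equal(as.integer(table(y[sp$test_index])), c(10L, 10L))
  expect_length(intersect(sp$train_index, sp$test_index), 0L)
  expect_setequal(c(sp$train_index, sp$test_index), seq_len(100))
  expect_identical(sp, split_dataset(tbl, 0.8, seed = 3))
  expect_error(split_dataset(tbl, 1.0), "ratio")
  expect_error(split_dataset(tbl, 0), "ratio")
})

test_that("tune_and_train reaches perfect CV accuracy on separable clusters", {
  tbl <- make_feature_table(n_per_class = 20, sep = 10)
  fused <- fuse_features(tbl, "pupil", 1:40)
  for (fam in c("decision_tree", "knn", "svm")) {
    tuned <- tune_and_train(classifier_spec(fam, k_range = 2:3),
                            fused, 1:40, seed = 1)
    expect_equal(tuned$cv_accuracy, 1.0)
  }
})

test_that("tune_and_train hovers at chance on permuted labels", {
  set.seed(8)
  tbl <- make_feature_table(n_per_class = 60, sep = 0)  # no signal at all
  fused <- fuse_features(tbl, "pupil", 1:120)
  tuned <- tune_and_train(classifier_spec("knn", list(k_neighbors = 5L),
                                          k_range = 5L),
                          fused, 1:120, seed = 2)
  se <- sqrt(0.25 / 120)
  # grid max over a single configuration: plain binomial null applies
  expect_lt(abs(tuned$cv_accuracy - 0.5), 3 * se + 0.05)
})

test_that("a single (params, k) search equals a manual fold loop", {
  tbl <- make_feature_table(n_per_class = 15, sep = 2, seed = 4)
  fused <- fuse_features(tbl, c("pupil", "blink", "fixation"), 1:30)
  spec <- classifier_spec("knn", list(k_neighbors = 3L), k_range = 3L)
  tuned <- tune_and_train(spec, fused, 1:30, seed = 6)

  # manual loop over the identical fold assignment
  x <- feature_matrix(fused)[1:30, ]
  y <- feature_labels(fused)[1:30]
  seeds <- periofuse:::derive_seeds(6, 2)
  folds <- periofuse:::make_folds(y, 3L, seeds[1] + 3L)
  accs <- vapply(1:3, function(f) {
    tr <- folds != f
    m <- train_model("knn", x[tr, ], y[tr], list(k_neighbors = 3L),
                     seed = seeds[2] + f)
    pr <- predict_proba(m, x[!tr, ])
    mean(colnames(pr)[max.col(pr, ties.method = "first")] == as.character(y[!tr]))
  }, numeric(1))
  expect_equal(tuned$cv_accuracy, mean(accs))
  expect_equal(tuned$k, 3L)
  expect_equal(tuned$params$k_neighbors, 3L)
})

test_that("score_heldout normalizes scores and counts accuracy correctly", {
  tbl <- make_feature_table(n_per_class = 25, sep = 10)
  sp <- split_dataset(tbl, 0.8, seed = 1)
  fused <- fuse_features(tbl, "pupil", sp$train_index)
  tuned <- tune_and_train(classifier_spec("decision_tree", k_range = 2L),
                          fused, sp$train_index, seed = 1)
  ss <- score_heldout(tuned, fused, sp$test_index)
  expect_equal(ss$test_accuracy, 1.0)
  expect_equal(unname(rowSums(ss$scores)), rep(1, length(sp$test_index)))
  expect_length(ss$sample_ids, length(sp$test_index))

  # 17 of 20 correct -> 0.85, via a hand-built score matrix
  y <- factor(rep(c("a", "b"), each = 10), levels = c("a", "b"))
  p_pos <- ifelse(y == "b", 0.9, 0.1)
  p_pos[1:3] <- 0.9   # three class-a samples scored as b
  fake <- periofuse:::score_set_from_scores(
    list(family = "svm", params = list(), k = 2L, cv_accuracy = NA_real_),
    cbind(1 - p_pos, p_pos, deparse.level = 0) |>
      `colnames<-`(c("a", "b")),
    y, sprintf("id%02d", 1:20))
  expect_equal(fake$test_accuracy, 0.85)
})

test_that("tied confidences resolve to the first class level", {
  y <- factor(c("a", "a", "b"), levels = c("a", "b"))
  sc <- matrix(0.5, 3, 2, dimnames = list(NULL, c("a", "b")))
  fake <- periofuse:::score_set_from_scores(
    list(family = "knn", params = list(), k = 2L, cv_accuracy = NA_real_),
    sc, y, c("i1", "i2", "i3"))
  expect_equal(fake$test_accuracy, 2 / 3)   # prevalence of level "a"
})

test_that("select_candidates filters, sorts and breaks ties by family order", {
  y <- rep(c("a", "b"), each = 5)
  mk <- function(fam, acc) make_scoreset(fam, rep(0.6, 10), y, acc = acc)
  sets <- list(mk("sgd", 0.61), mk("svm", 0.84), mk("knn", 0.80))
  sel <- select_candidates(sets, 0.75)
  expect_equal(vapply(sel, function(s) s$classifier$family, character(1)),
               c("svm", "knn"))
  sel0 <- select_candidates(sets, 0)
  expect_equal(length(sel0), 3L)
  # tie at 0.80: knn precedes svm in the family precedence list
  sets2 <- list(mk("svm", 0.80), mk("knn", 0.80))
  expect_equal(select_candidates(sets2, 0.5)[[1]]$classifier$family, "knn")
  expect_error(select_candidates(sets, 0.99), "threshold")
})

test_that("no leakage: scores exist only for test rows, disjoint from train", {
  tbl <- make_feature_table(n_per_class = 20, sep = 3)
  sp <- split_dataset(tbl, 0.8, seed = 2)
  fused <- fuse_features(tbl, c("pupil", "blink"), sp$train_index)
  zoo <- train_zoo(default_classifier_specs(c("decision_tree", "knn"), 2L),
                   fused, sp$train_index, sp$test_index, seed = 3)
  test_ids <- paste(fused$rows$subject_id[sp$test_index],
                    fused$rows$stimulus_id[sp$test_index], sep = ":")
  for (ss in zoo) {
    expect_identical(ss$sample_ids, test_ids)
    expect_equal(nrow(ss$scores), length(sp$test_index))
  }
})

test_that("the selected (params, k) pair is never dominated", {
  # exhaustive re-evaluation: every pair's CV mean must be <= the winner's
  tbl <- make_feature_table(n_per_class = 15, sep = 1.5, seed = 9)
  fused <- fuse_features(tbl, "pupil", 1:30)
  spec <- classifier_spec("knn", list(k_neighbors = c(1L, 3L, 5L)), k_range = 2:3)
  tuned <- tune_and_train(spec, fused, 1:30, seed = 4)
  x <- feature_matrix(fused)[1:30, ]
  y <- feature_labels(fused)[1:30]
  seeds <- periofuse:::derive_seeds(4, 2)
  for (kn in c(1L, 3L, 5L)) {
    for (k in 2:3) {
      folds <- periofuse:::make_folds(y, k, seeds[1] + k)
      accs <- vapply(seq_len(k), function(f) {
        tr <- folds != f
        m <- train_model("knn", x[tr, ], y[tr], list(k_neighbors = kn),
                         seed = seeds[2] + f)
        pr <- predict_proba(m, x[!tr, ])
        mean(colnames(pr)[max.col(pr, ties.method = "first")] ==
               as.character(y[!tr]))
      }, numeric(1))
      expect_lte(mean(accs), tuned$cv_accuracy + 1e-12)
    }
  }
})
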