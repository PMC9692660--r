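#' Align member score sets into a score matrix
#'
#' @param scoresets list of `score_set` objects with identical sample ids in
#'   identical order.
#' @return object of class `score_matrix`: `members` (family names),
#'   `sample_ids`, `levels`, `labels` (from the first member), and `scores`
#'   (list of n x 2 matrices).
#' @export
score_matrix <- function(scoresets) {
  if (length(scoresets) < 1L) stop("need at least one score set")
  ids <- scoresets[[1]]$sample_ids
  for (s in scoresets) {
    if (!identical(s$sample_ids, ids)) {
      stop("misaligned sample ids across score sets")
    }
  }
  structure(
    list(
      members = vapply(scoresets, function(s) s$classifier$family, character(1)),
      sample_ids = ids,
      levels = colnames(scoresets[[1]]$scores),
      labels = scoresets[[1]]$labels,
      scores = lapply(scoresets, `[[`, "scores")
    ),
    class = "score_matrix"
  )
}

check_weights <- function(matrix, weights) {
  if (length(weights) != length(matrix$scores)) {
    stop("need exactly one weight per member")
  }
  if (any(weights <= 0) || any(weights > 1)) {
    stop("weights must lie in (0, 1]")
  }
  weights
}

fused_result <- function(rule, matrix, weights, fused, labels) {
  pred <- factor(matrix$levels[max.col(fused, ties.method = "first")],
                 levels = matrix$levels)
  acc <- if (is.null(labels)) NA_real_ else mean(pred == labels)
  structure(
    list(rule = rule, members = matrix$members, weights = weights,
         scores = fused, predictions = pred, accuracy = acc),
    class = "fused_scores"
  )
}

#' Weighted-sum score fusion
#'
#' Fused class score `S = sum_i w_i s_i` per class; prediction is the argmax
#' (ties resolved toward the first class level).
#'
#' @param matrix a [score_matrix()].
#' @param weights one weight in (0, 1] per member.
#' @param labels optional true labels for accuracy; defaults to the labels
#'   carried by the matrix.
#' @return object of class `fused_scores` with `scores`, `predictions`,
#'   `accuracy`.
#' @export
weighted_sum_fuse <- function(matrix, weights, labels = matrix$labels) {
  weights <- check_weights(matrix, weights)
  fused <- Reduce(`+`, Map(function(s, w) w * s, matrix$scores, weights))
  fused_result("sum", matrix, weights, fused, labels)
}

#' Weighted-product score fusion
#'
#' Fused class score `S = prod_i s_i^{w_i}`; a member score of 0 for a class
#' annihilates that class's fused score.
#'
#' @inheritParams weighted_sum_fuse
#' @return object of class `fused_scores`.
#' @export
weighted_product_fuse <- function(matrix, weights, labels = matrix$labels) {
  weights <- check_weights(matrix, weights)
  if (any(vapply(matrix$scores, function(s) any(s < 0), logical(1)))) {
    stop("weighted product requires non-negative member scores")
  }
  fused <- Reduce(`*`, Map(function(s, w) s^w, matrix$scores, weights))
  fused_result("product", matrix, weights, fused, labels)
}

#' Pairwise Bayes score fusion
#'
#' With `t_a`, `t_b` the two members' positive-class confidences (positive
#' class = second class level; the weighted member's confidence is first
#' multiplied by `weight`), the fused score is
#' `S = t_a t_b / ((1 - t_a)(1 - t_b) + t_a t_b)`,
#' and the prediction is the positive class iff `S >= 0.5`. The singular
#' input `(1, 0)` (both numerator and complement product zero) is defined as
#' `S = 0.5` with a warning.
#'
#' @param matrix a [score_matrix()] of exactly two members.
#' @param weight_on index (1 or 2) of the member whose score is
#'   down-weighted.
#' @param weight multiplier in (0, 1] applied to that member's confidence.
#' @param labels optional true labels for accuracy.
#' @return object of class `fused_scores`.
#' @export
bayes_fuse <- function(matrix, weight_on = 1L, weight = 1,
                       labels = matrix$labels) {
  if (length(matrix$scores) != 2L) stop("Bayes fusion needs exactly two members")
  if (!weight_on %in% c(1L, 2L)) stop("weight_on must be 1 or 2")
  if (weight <= 0 || weight > 1) stop("weight must lie in (0, 1]")
  t_a <- matrix$scores[[1]][, 2]
  t_b <- matrix$scores[[2]][, 2]
  if (weight_on == 1L) t_a <- t_a * weight else t_b <- t_b * weight
  num <- t_a * t_b
  den <- (1 - t_a) * (1 - t_b) + num
  s <- ifelse(den == 0, 0.5, num / den)
  if (any(den == 0)) {
    warning("singular Bayes input (scores (1, 0)); fused score set to 0.5")
  }
  fused <- cbind(1 - s, s)
  colnames(fused) <- matrix$levels
  pred <- factor(matrix$levels[ifelse(s >= 0.5, 2L, 1L)],
                 levels = matrix$levels)
  acc <- if (is.null(labels)) NA_real_ else mean(pred == labels)
  structure(
    list(rule = "bayes", members = matrix$members,
         weights = stats::setNames(weight, matrix$members[weight_on]),
         weight_on = weight_on,
         scores = fused, predictions = pred, accuracy = acc),
    class = "fused_scores"
  )
}

# w/10 weight grid for m members, rows in lexicographic order with the first
# member's weight varying slowest.
weight_grid <- function(m, grid = (1:10) / 10) {
  g <- expand.grid(rev(rep(list(grid), m)), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_len(m)), drop = FALSE])
}

#' Brute-force search over member subsets and the w/10 weight grid
#'
#' For every subset of the requested size of the candidate score sets and
#' every weight assignment with each weight in \{0.1, ..., 1.0\}, fuses the
#' member scores with the requested rule and measures accuracy against the
#' labels; the maximum-accuracy configuration per size is returned (ties go
#' to the first configuration in enumeration order: subsets in candidate
#' order, weights ascending lexicographically). For the Bayes rule, members
#' are combined two by two and the grid is (weighted member) x (10 weights).
#' A configuration is flagged as an improvement only when it strictly
#' exceeds the best single candidate's accuracy.
#'
#' @param candidates list of `score_set` objects (typically the output of
#'   [select_candidates()], ordered by decreasing accuracy).
#' @param rule `"sum"`, `"product"` or `"bayes"`.
#' @param sizes subset sizes to search (forced to 2 for `"bayes"`).
#' @param labels true labels; default taken from the candidates.
#' @param chunk_rows weight-grid rows evaluated per block (memory knob).
#' @return list with `rule`, `best_single_accuracy`, and `per_size`, a named
#'   list keyed by size with entries `members`, `member_index`, `weights`
#'   (plus `weight_on` for Bayes), `accuracy`, `n_evaluations`,
#'   `improves_single`.
#' @export
search_weights_and_combinations <- function(candidates,
                                            rule = c("sum", "product", "bayes"),
                                            sizes = 2L,
                                            labels = NULL,
                                            chunk_rows = 20000L) {
  rule <- match.arg(rule)
  n_cand <- length(candidates)
  if (n_cand < 2L) stop("need at least two candidates")
  if (rule == "bayes") sizes <- 2L
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2L) || any(sizes > n_cand)) {
    stop("sizes must lie within 2..", n_cand)
  }
  mat_all <- score_matrix(candidates)
  if (is.null(labels)) labels <- mat_all$labels
  if (is.null(labels)) stop("labels are required to score configurations")
  lev <- mat_all$levels
  pos <- labels == lev[2]
  n <- length(mat_all$sample_ids)
  s1 <- do.call(rbind, lapply(mat_all$scores, function(s) s[, 1]))  # members x n
  s2 <- do.call(rbind, lapply(mat_all$scores, function(s) s[, 2]))
  best_single <- max(vapply(candidates, `[[`, numeric(1), "test_accuracy"))

  per_size <- list()
  for (size in sizes) {
    subsets <- combn(n_cand, size)
    best <- NULL
    n_eval <- 0L
    for (ci in seq_len(ncol(subsets))) {
      memb <- subsets[, ci]
      if (rule == "bayes") {
        for (won in 1:2) {
          for (w in (1:10) / 10) {
            pair <- score_matrix(candidates[memb])
            f <- bayes_fuse(pair, weight_on = won, weight = w, labels = labels)
            n_eval <- n_eval + 1L
            if (is.null(best) || f$accuracy > best$accuracy + 1e-12) {
              best <- list(members = mat_all$members[memb],
                           member_index = memb,
                           weights = f$weights, weight_on = won,
                           accuracy = f$accuracy)
            }
          }
        }
      } else {
        wg <- weight_grid(size)
        n_eval <- n_eval + nrow(wg)
        for (start in seq(1L, nrow(wg), by = chunk_rows)) {
          rows <- start:min(start + chunk_rows - 1L, nrow(wg))
          wchunk <- wg[rows, , drop = FALSE]
          if (rule == "sum") {
            f1 <- wchunk %*% s1[memb, , drop = FALSE]
            f2 <- wchunk %*% s2[memb, , drop = FALSE]
          } else {
            f1 <- exp(wchunk %*% log(s1[memb, , drop = FALSE]))
            f2 <- exp(wchunk %*% log(s2[memb, , drop = FALSE]))
          }
          predpos <- f2 > f1    # tie -> first class level
          acc <- rowMeans(predpos == matrix(pos, nrow(predpos), n, byrow = TRUE))
          b <- which.max(acc)
          if (is.null(best) || acc[b] > best$accuracy + 1e-12) {
            best <- list(members = mat_all$members[memb],
                         member_index = memb,
                         weights = unname(wchunk[b, ]),
                         accuracy = acc[b])
          }
        }
      }
    }
    best$n_evaluations <- n_eval
    best$improves_single <- best$accuracy > best_single + 1e-12
    per_size[[as.character(size)]] <- best
  }
  list(rule = rule, best_single_accuracy = best_single, per_size = per_size)
}

#' Classifier-based score fusion
#'
#' Builds a derived dataset whose feature vector per sample is the
#' concatenation of the two members' class-confidence vectors (2 members x
#' 2 classes = 4 columns), re-splits it 70:30 (seeded, stratified), and runs
#' the exhaustive search of [tune_and_train()] plus held-out scoring for
#' each requested family on this derived problem.
#'
#' @param scoresets exactly two `score_set` objects with aligned sample ids
#'   (conventionally the two highest-accuracy candidates).
#' @param specs named list of [classifier_spec()] objects to train on the
#'   derived dataset.
#' @param split_ratio training fraction of the re-split (default 0.7).
#' @param seed seed for the re-split and the estimators.
#' @return named list per family: `score_set` on the derived problem's
#'   held-out samples.
#' @export
classifier_score_fusion <- function(scoresets, specs,
                                    split_ratio = 0.7, seed = 1L) {
  if (length(scoresets) < 2L) stop("classifier fusion needs two score sets")
  scoresets <- scoresets[1:2]
  mat <- score_matrix(scoresets)
  x <- do.call(cbind, mat$scores)
  colnames(x) <- paste(rep(mat$members, each = 2L),
                       rep(mat$levels, 2L),
                       rep(1:2, each = 2L), sep = "_")
  y <- mat$labels
  if (is.null(y)) stop("score sets carry no labels")
  idx <- split_indices(y, split_ratio, seed)
  seeds <- derive_seeds(seed, length(specs))
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    tuned <- tune_and_train_xy(specs[[i]],
                               x[idx$train_index, , drop = FALSE],
                               y[idx$train_index], seed = seeds[i])
    pr <- predict_proba(tuned$model, x[idx$test_index, , drop = FALSE])
    out[[i]] <- score_set_from_scores(
      tuned, pr, y[idx$test_index], mat$sample_ids[idx$test_index])
  }
  stats::setNames(out, vapply(specs, `[[`, character(1), "family"))
}
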