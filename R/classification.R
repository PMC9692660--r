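#' Specification of one classifier's exhaustive search
#'
#' @param family one of [classifier_families()].
#' @param grid named list of candidate parameter values; every combination
#'   is evaluated. An empty list means the family defaults only.
#' @param k_range integer cross-validation fold counts, within 2..10.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, grid = list(), k_range = 2:10) {
  family <- match.arg(family, classifier_families())
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L || any(k_range < 2L) || any(k_range > 10L)) {
    stop_config("k_range", "must be a non-empty subset of 2..10")
  }
  structure(list(family = family, grid = grid, k_range = k_range),
            class = "classifier_spec")
}

#' Default search specifications for the whole zoo
#'
#' Small published-default grids per family; fully overridable.
#'
#' @param families subset of [classifier_families()].
#' @param k_range fold counts shared by all specs.
#' @return named list of [classifier_spec()] objects.
#' @export
default_classifier_specs <- function(families = classifier_families(),
                                     k_range = 2:10) {
  grids <- list(
    decision_tree = list(max_depth = c(2L, 4L, 6L)),
    random_forest = list(n_trees = c(25L, 50L)),
    bagging = list(n_trees = c(25L, 50L)),
    adaboost = list(n_rounds = c(20L, 40L)),
    gradient_boosting = list(n_rounds = c(30L, 60L)),
    knn = list(k_neighbors = c(3L, 5L, 9L)),
    svm = list(lambda = c(0.1, 0.01)),
    sgd = list(alpha = c(1e-2, 1e-4))
  )
  specs <- lapply(families, function(f) {
    classifier_spec(f, grids[[f]] %||% list(), k_range)
  })
  stats::setNames(specs, families)
}

#' Stratified train/test split of a feature table
#'
#' @param table a `feature_table`.
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed split seed.
#' @return list with integer `train_index` and `test_index`, disjoint and
#'   exhaustive, stratified by the task label.
#' @export
split_dataset <- function(table, ratio = 0.8, seed = 1L) {
  y <- feature_labels(table)
  if (length(y) == 0L) stop("empty feature table")
  split_indices(y, ratio, seed)
}

# Stratified index split shared by split_dataset and the score-fusion
# re-split.
split_indices <- function(y, ratio, seed) {
  if (!(ratio > 0 && ratio < 1)) stop_config("ratio", "must lie strictly in (0, 1)")
  if (any(table(y) < 2L)) stop("each class needs at least 2 rows to split")
  train <- with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      n_tr <- round(length(idx) * ratio)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      sort(sample(idx, n_tr))
    }))
  })
  train <- sort(train)
  list(train_index = train, test_index = setdiff(seq_along(y), train))
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over k folds.
make_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

param_grid_rows <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  gg <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(gg)), function(i) as.list(gg[i, , drop = FALSE]))
}

#' Exhaustive parameter and fold-count search with cross-validation
#'
#' Evaluates every (parameter combination, k) pair of the spec by stratified
#' k-fold cross-validated accuracy on the training rows, picks the best pair
#' (ties broken by grid declaration order, then smaller k) and refits it on
#' all training rows.
#'
#' @param spec a [classifier_spec()].
#' @param table a `feature_table` (typically scaled via [fuse_features()]).
#' @param train_index training row indices.
#' @param seed seed driving fold assignment and stochastic estimators.
#' @return list of class `tuned_model`: `model` (refit `perio_model`),
#'   `family`, `params`, `k`, `cv_accuracy`.
#' @export
tune_and_train <- function(spec, table, train_index, seed = 1L) {
  x <- feature_matrix(table)[train_index, , drop = FALSE]
  y <- droplevels(feature_labels(table)[train_index])
  if (nlevels(y) < 2L) stop("training rows cover a single class")
  y <- factor(as.character(y),
              levels = levels(feature_labels(table)))
  tune_and_train_xy(spec, x, y, seed)
}

# Core search on a plain (x, y); also used for classifier-based score fusion.
tune_and_train_xy <- function(spec, x, y, seed = 1L) {
  param_rows <- param_grid_rows(spec$grid)
  seeds <- derive_seeds(seed, 2L)
  best <- NULL
  for (pi in seq_along(param_rows)) {
    for (k in spec$k_range) {
      folds <- make_folds(y, k, seeds[1] + k)
      accs <- rep(NA_real_, k)
      for (f in seq_len(k)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L || !any(!tr)) {
          warning("skipping degenerate fold ", f, " (single-class)")
          next
        }
        m <- train_model(spec$family, x[tr, , drop = FALSE], y[tr],
                         param_rows[[pi]], seed = seeds[2] + f)
        pr <- predict_proba(m, x[!tr, , drop = FALSE])
        pred <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                       levels = levels(y))
        accs[f] <- mean(pred == y[!tr])
      }
      if (all(is.na(accs))) stop("all folds degenerate for k = ", k)
      cv <- mean(accs, na.rm = TRUE)
      if (is.null(best) || cv > best$cv_accuracy + 1e-12) {
        best <- list(params = param_rows[[pi]], k = k, cv_accuracy = cv)
      }
    }
  }
  model <- train_model(spec$family, x, y, best$params, seed = seeds[2])
  structure(
    list(model = model, family = spec$family, params = best$params,
         k = best$k, cv_accuracy = best$cv_accuracy),
    class = "tuned_model"
  )
}

#' Score the held-out split with a tuned model
#'
#' @param tuned a `tuned_model` from [tune_and_train()].
#' @param table the `feature_table` used for training.
#' @param test_index held-out row indices (disjoint from training).
#' @return object of class `score_set`: `classifier` (family, params, k),
#'   `sample_ids`, `scores` (n x 2 confidence matrix, rows sum to 1),
#'   `test_accuracy`, `cv_accuracy`.
#' @export
score_heldout <- function(tuned, table, test_index) {
  x <- feature_matrix(table)[test_index, , drop = FALSE]
  y <- feature_labels(table)[test_index]
  ids <- paste(table$rows$subject_id[test_index],
               table$rows$stimulus_id[test_index], sep = ":")
  score_set_from_scores(tuned, predict_proba(tuned$model, x), y, ids)
}

score_set_from_scores <- function(tuned, scores, y, ids) {
  scores <- scores / rowSums(scores)
  pred <- factor(colnames(scores)[max.col(scores, ties.method = "first")],
                 levels = levels(y))
  structure(
    list(
      classifier = list(family = tuned$family, params = tuned$params,
                        k = tuned$k),
      sample_ids = ids,
      scores = scores,
      labels = y,
      test_accuracy = mean(pred == y),
      cv_accuracy = tuned$cv_accuracy
    ),
    class = "score_set"
  )
}

#' Select fusion candidates by an accuracy threshold
#'
#' Keeps score sets whose held-out accuracy strictly exceeds the threshold,
#' ordered by decreasing accuracy; ties follow the fixed family precedence
#' of [classifier_families()].
#'
#' @param scoresets list of `score_set` objects sharing sample ids.
#' @param threshold accuracy threshold (default 0.75).
#' @return ordered sublist of `scoresets`.
#' @export
select_candidates <- function(scoresets, threshold = 0.75) {
  ids <- lapply(scoresets, `[[`, "sample_ids")
  if (length(unique(ids)) > 1L) stop("score sets do not share sample ids")
  accs <- vapply(scoresets, `[[`, numeric(1), "test_accuracy")
  fams <- vapply(scoresets, function(s) s$classifier$family, character(1))
  keep <- which(accs > threshold)
  if (length(keep) == 0L) {
    stop("no classifier exceeds accuracy threshold ", threshold,
         "; lower --select-threshold")
  }
  ord <- keep[order(-accs[keep], match(fams[keep], classifier_families()))]
  scoresets[ord]
}

#' Train the full zoo and score the held-out split
#'
#' @param specs named list of [classifier_spec()] objects.
#' @param table a scaled `feature_table`.
#' @param train_index,test_index split indices from [split_dataset()].
#' @param seed master seed; one child seed is derived per family.
#' @return named list of `score_set` objects, one per family.
#' @export
train_zoo <- function(specs, table, train_index, test_index, seed = 1L) {
  seeds <- derive_seeds(seed, length(specs))
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    tuned <- tune_and_train(specs[[i]], table, train_index, seed = seeds[i])
    out[[i]] <- score_heldout(tuned, table, test_index)
  }
  stats::setNames(out, vapply(specs, `[[`, character(1), "family"))
}

#' Write score sets to JSON
#'
#' Per classifier: family, chosen parameters and k, accuracies, and
#' per-sample `[id, p_class0, p_class1]` triplets.
#'
#' @param scoresets list of `score_set` objects.
#' @param path output path.
#' @export
write_scores_json <- function(scoresets, path) {
  payload <- lapply(scoresets, function(s) {
    list(
      family = s$classifier$family,
      params = s$classifier$params,
      k = s$classifier$k,
      cv_accuracy = s$cv_accuracy,
      test_accuracy = s$test_accuracy,
      levels = colnames(s$scores),
      samples = lapply(seq_along(s$sample_ids), function(i) {
        list(id = s$sample_ids[i],
             scores = unname(s$scores[i, ]),
             label = as.character(s$labels[i]))
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}
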