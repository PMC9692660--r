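#' Classification accuracy
#'
#' @param predictions predicted labels.
#' @param labels true labels of equal length.
#' @return fraction of matches.
#' @export
accuracy_of <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length")
  }
  if (length(labels) == 0L) stop("empty label vector")
  mean(as.character(predictions) == as.character(labels))
}

#' Mean cross-modality Spearman correlation
#'
#' Computes the Spearman rank correlation for every cross pair of one
#' feature column from each modality block and returns the arithmetic mean.
#' A constant column contributes coefficient 0 to each of its pairs (with a
#' warning), since ranks carry no information.
#'
#' @param table a `feature_table`.
#' @param modality_a,modality_b two distinct modalities.
#' @return mean Spearman coefficient over all cross pairs.
#' @export
mean_cross_modality_spearman <- function(table, modality_a, modality_b) {
  cols_a <- modality_columns(modality_a)
  cols_b <- modality_columns(modality_b)
  rows <- table$rows
  if (nrow(rows) < 3L) stop("need at least 3 rows for a rank correlation")
  const_warned <- FALSE
  vals <- numeric(0)
  for (a in cols_a) {
    xa <- rows[[a]]
    for (b in cols_b) {
      xb <- rows[[b]]
      if (pop_sd(xa) == 0 || pop_sd(xb) == 0) {
        if (!const_warned) {
          warning("constant feature column; its pairs contribute 0")
          const_warned <- TRUE
        }
        vals <- c(vals, 0)
      } else {
        vals <- c(vals, cor(xa, xb, method = "spearman"))
      }
    }
  }
  mean(vals)
}

#' Configuration of a full fusion experiment
#'
#' @param task `"gender"` or `"age"`.
#' @param with_concatenation if `TRUE`, classifiers are trained on the
#'   feature-level concatenation of all modalities; if `FALSE`, one zoo is
#'   trained per modality and the best score set per modality feeds fusion
#'   (the study's comparison condition).
#' @param cohort a [cohort_config()] describing the synthetic cohort.
#' @param modalities modalities included in the experiment.
#' @param families classifier families to train.
#' @param k_range cross-validation fold counts (within 2..10).
#' @param grids optional named list of per-family parameter grids overriding
#'   the defaults of [default_classifier_specs()].
#' @param select_threshold accuracy threshold for fusion candidates.
#' @param split_ratio base train fraction (default 0.8, i.e. an 80:20 split).
#' @param fusion_split_ratio train fraction of the classifier-fusion
#'   re-split (default 0.7, i.e. 70:30).
#' @param rules fusion rules to run.
#' @param sizes member-subset sizes for the sum/product searches.
#' @param dispersion_threshold_px,min_fix_duration_ms I-DT parameters.
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(task = c("gender", "age"),
                              with_concatenation = TRUE,
                              cohort = cohort_config(),
                              modalities = c("pupil", "blink", "fixation"),
                              families = classifier_families(),
                              k_range = 2:10,
                              grids = NULL,
                              select_threshold = 0.75,
                              split_ratio = 0.8,
                              fusion_split_ratio = 0.7,
                              rules = c("sum", "product", "bayes", "classifier"),
                              sizes = 2:4,
                              dispersion_threshold_px = 100,
                              min_fix_duration_ms = 100,
                              seed = 1L) {
  task <- match.arg(task)
  modalities <- match.arg(modalities, c("pupil", "blink", "fixation"),
                          several.ok = TRUE)
  rules <- match.arg(rules, c("sum", "product", "bayes", "classifier"),
                     several.ok = TRUE)
  for (r in c("split_ratio", "fusion_split_ratio")) {
    v <- get(r)
    if (!(v > 0 && v < 1)) stop_config(r, "must lie strictly in (0, 1)")
  }
  if (any(sizes < 2L)) stop_config("sizes", "must be >= 2")
  specs <- default_classifier_specs(families, k_range)
  if (!is.null(grids)) {
    for (f in names(grids)) {
      if (f %in% names(specs)) specs[[f]]$grid <- grids[[f]]
    }
  }
  structure(
    list(task = task, with_concatenation = with_concatenation,
         cohort = cohort, modalities = modalities, specs = specs,
         select_threshold = select_threshold, split_ratio = split_ratio,
         fusion_split_ratio = fusion_split_ratio, rules = rules,
         sizes = as.integer(sizes),
         dispersion_threshold_px = dispersion_threshold_px,
         min_fix_duration_ms = min_fix_duration_ms,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full fusion experiment
#'
#' Pipeline: simulate cohort sessions, preprocess and featurize, assemble
#' the balanced labeled dataset, split 80:20, train the classifier zoo
#' (on the concatenated features and/or per modality), select fusion
#' candidates above the accuracy threshold, run the transformation-based
#' fusion searches and classifier-based fusion, and summarize. Every stage
#' is seeded from the master seed; identical configurations yield identical
#' reports.
#'
#' @param config an [experiment_config()].
#' @param records optional pre-loaded gaze records (with a matching
#'   `metadata` roster) to analyse instead of simulating.
#' @param metadata roster for `records`.
#' @return object of class `experiment_report` (a nested list; see
#'   [report_to_json()]).
#' @export
run_experiment <- function(config, records = NULL, metadata = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, 8L)
  rate <- config$cohort$sampling_rate_hz

  if (is.null(records)) {
    sim <- run_stage("simulate", simulate_cohort_sessions(config$cohort,
                                                          seed = seeds[1]))
    records <- sim$records
    metadata <- sim$cohort
  } else if (is.null(metadata)) {
    stop("stage 'load': records supplied without metadata")
  }

  rows <- run_stage("features", featurize_sessions(
    records, rate, config$dispersion_threshold_px, config$min_fix_duration_ms))
  tbl <- run_stage("dataset", assemble_dataset(
    rows, metadata, config$task, balance_seed = seeds[2]))
  sp <- run_stage("split", split_dataset(tbl, config$split_ratio,
                                         seed = seeds[3]))

  spearman <- run_stage("spearman", {
    pairs <- combn(config$modalities, 2, simplify = FALSE)
    if (length(config$modalities) < 2L) list() else
      stats::setNames(
        lapply(pairs, function(p) {
          suppressWarnings(mean_cross_modality_spearman(tbl, p[1], p[2]))
        }),
        vapply(pairs, paste, character(1), collapse = "-")
      )
  })

  ## per-modality zoos (always reported; the fusion candidates for the
  ## no-concatenation condition)
  per_modality <- run_stage("per_modality", {
    out <- list()
    for (i in seq_along(config$modalities)) {
      m <- config$modalities[i]
      tbl_m <- fuse_features(tbl, m, sp$train_index)
      zoo <- train_zoo(config$specs, tbl_m, sp$train_index, sp$test_index,
                       seed = seeds[4] + i)
      accs <- vapply(zoo, `[[`, numeric(1), "test_accuracy")
      best <- which.max(accs)   # first max; family order is the zoo order
      out[[m]] <- list(zoo = zoo, best = zoo[[best]],
                       best_family = names(zoo)[best],
                       best_accuracy = unname(accs[best]))
    }
    out
  })

  if (config$with_concatenation) {
    fused_tbl <- run_stage("feature_fusion",
                           fuse_features(tbl, config$modalities, sp$train_index))
    zoo <- run_stage("train_zoo", train_zoo(
      config$specs, fused_tbl, sp$train_index, sp$test_index, seed = seeds[5]))
    candidates <- run_stage("select_candidates",
                            select_candidates(zoo, config$select_threshold))
  } else {
    zoo <- NULL
    ranked <- order(-vapply(per_modality, `[[`, numeric(1), "best_accuracy"))
    candidates <- lapply(per_modality[ranked], `[[`, "best")
  }

  fusion <- run_stage("score_fusion", {
    out <- list()
    if (length(candidates) >= 2L) {
      sizes <- config$sizes[config$sizes <= length(candidates)]
      for (rule in intersect(config$rules, c("sum", "product", "bayes"))) {
        if (rule == "bayes" || length(sizes) > 0L) {
          out[[rule]] <- search_weights_and_combinations(
            candidates, rule, if (rule == "bayes") 2L else sizes)
        }
      }
    }
    out
  })

  classifier_fusion <- NULL
  if ("classifier" %in% config$rules && length(candidates) >= 2L) {
    classifier_fusion <- run_stage("classifier_fusion", {
      res <- classifier_score_fusion(candidates, config$specs,
                                     config$fusion_split_ratio,
                                     seed = seeds[6])
      lapply(res, function(s) list(
        family = s$classifier$family, params = s$classifier$params,
        k = s$classifier$k, accuracy = s$test_accuracy))
    })
  }

  ## overall best across everything the report summarizes
  all_acc <- c(
    vapply(per_modality, `[[`, numeric(1), "best_accuracy"),
    if (!is.null(zoo)) vapply(zoo, `[[`, numeric(1), "test_accuracy"),
    unlist(lapply(fusion, function(r) {
      vapply(r$per_size, `[[`, numeric(1), "accuracy")
    })),
    if (!is.null(classifier_fusion)) {
      vapply(classifier_fusion, `[[`, numeric(1), "accuracy")
    }
  )

  structure(
    list(
      task = config$task,
      with_concatenation = config$with_concatenation,
      seed = config$seed,
      n_rows = nrow(tbl$rows),
      n_train = length(sp$train_index),
      n_test = length(sp$test_index),
      spearman = spearman,
      per_modality = lapply(per_modality, function(m) list(
        best_family = m$best_family,
        best_accuracy = m$best_accuracy,
        best_k = m$best$classifier$k,
        accuracies = lapply(m$zoo, `[[`, "test_accuracy")
      )),
      zoo_accuracies = if (!is.null(zoo)) {
        lapply(zoo, `[[`, "test_accuracy")
      },
      candidates = vapply(candidates, function(s) s$classifier$family,
                          character(1)),
      candidate_accuracies = vapply(candidates, `[[`, numeric(1),
                                    "test_accuracy"),
      fusion = fusion,
      classifier_fusion = classifier_fusion,
      best_accuracy = max(all_acc)
    ),
    class = "experiment_report"
  )
}

#' Serialize an experiment report
#'
#' `report_to_json` writes the full nested report; `write_report_tables`
#' writes a flat comma-separated summary (strategy, rule, size, members,
#' weights, accuracy to 4 decimal places) mirroring the layout of the
#' study's result tables.
#'
#' @param report an `experiment_report`.
#' @param path output file path.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname report_to_json
#' @export
write_report_tables <- function(report, path) {
  rows <- list()
  add <- function(strategy, rule, size, members, weights, acc) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      strategy = strategy, rule = rule, size = size,
      members = paste(members, collapse = "&"),
      weights = paste(round(weights, 2), collapse = "/"),
      accuracy = sprintf("%.4f", acc)
    )
  }
  for (m in names(report$per_modality)) {
    pm <- report$per_modality[[m]]
    add(paste0("single_", m), pm$best_family, 1L, pm$best_family, 1,
        pm$best_accuracy)
  }
  for (rule in names(report$fusion)) {
    r <- report$fusion[[rule]]
    for (sz in names(r$per_size)) {
      b <- r$per_size[[sz]]
      add("transformation", rule, as.integer(sz), b$members, b$weights,
          b$accuracy)
    }
  }
  for (f in names(report$classifier_fusion)) {
    cf <- report$classifier_fusion[[f]]
    add("classifier", f, 2L, f, 1, cf$accuracy)
  }
  data.table::fwrite(data.table::rbindlist(rows), path, quote = FALSE)
  invisible(path)
}
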