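pupil_feature_names <- c("mean", "median", "std", "min", "max", "q1", "q3")
blink_feature_names <- c("count", "n_fast", "dur_mean", "dur_std", "dur_min", "dur_max")
fixation_feature_names <- c("count", "dur_mean", "dur_std", "dur_min", "dur_max")

#' Names of the feature columns of one modality
#'
#' Columns are named `modality__feature`, e.g. `pupil__mean`.
#'
#' @param modality one of `"pupil"`, `"blink"`, `"fixation"`.
#' @return character vector of column names.
#' @export
modality_columns <- function(modality) {
  base <- switch(modality,
    pupil = pupil_feature_names,
    blink = blink_feature_names,
    fixation = fixation_feature_names,
    stop_config("modality", "must be pupil, blink or fixation")
  )
  paste0(modality, "__", base)
}

#' Summarize one session's ocular events into a feature row
#'
#' Pupil descriptors (mean, median, population std, min, max, quartiles) are
#' computed over the per-record mean of left and right diameter on (0,0)
#' records only. Blink features are the event count, the fast-blink counter
#' and duration statistics over the timed (non-fast) blinks; fixation
#' features are count and duration statistics. Sessions without blinks or
#' fixations get zero duration statistics with a presence flag
#' (`blink_present` / `fixation_present`) recorded alongside.
#'
#' @param events an `ocular_events` object from [extract_ocular_events()].
#' @return one-row `data.table` of features, or `NULL` (with a warning) when
#'   the session retains no (0,0) record.
#' @export
extract_modality_features <- function(events) {
  rec <- events$retained_records
  ok <- rec$validity_left == 0L & rec$validity_right == 0L
  pup <- (rec$pupil_left_mm[ok] + rec$pupil_right_mm[ok]) / 2
  pup <- pup[is.finite(pup)]
  if (length(pup) == 0L) {
    warning("session rejected: no valid (0,0) pupil records")
    return(NULL)
  }
  q <- unname(quantile(pup, c(0.25, 0.5, 0.75)))
  row <- data.table::data.table(
    pupil__mean = mean(pup), pupil__median = q[2], pupil__std = pop_sd(pup),
    pupil__min = min(pup), pupil__max = max(pup),
    pupil__q1 = q[1], pupil__q3 = q[3]
  )

  bl <- events$blinks
  timed <- bl$duration_ms[!bl$is_fast]
  has_bl <- length(timed) > 0L
  row[, `:=`(
    blink__count = nrow(bl),
    blink__n_fast = as.numeric(events$n_fast_blinks),
    blink__dur_mean = if (has_bl) mean(timed) else 0,
    blink__dur_std = if (has_bl) pop_sd(timed) else 0,
    blink__dur_min = if (has_bl) min(timed) else 0,
    blink__dur_max = if (has_bl) max(timed) else 0
  )]

  fx <- events$fixations
  has_fx <- nrow(fx) > 0L
  row[, `:=`(
    fixation__count = nrow(fx),
    fixation__dur_mean = if (has_fx) mean(fx$duration_ms) else 0,
    fixation__dur_std = if (has_fx) pop_sd(fx$duration_ms) else 0,
    fixation__dur_min = if (has_fx) min(fx$duration_ms) else 0,
    fixation__dur_max = if (has_fx) max(fx$duration_ms) else 0,
    blink_present = as.numeric(has_bl),
    fixation_present = as.numeric(has_fx)
  )]
  row[]
}

#' Turn a full cohort's raw records into per-session feature rows
#'
#' Groups records by (subject, stimulus), extracts ocular events and
#' summarizes each session with [extract_modality_features()]. Sessions with
#' no retained (0,0) records are dropped with a warning.
#'
#' @param records gaze records of one or more sessions.
#' @param sampling_rate_hz sampling frequency.
#' @param dispersion_threshold_px,min_duration_ms I-DT parameters.
#' @return `data.table` with `subject_id`, `stimulus_id` and all feature
#'   columns.
#' @export
featurize_sessions <- function(records, sampling_rate_hz = 50,
                               dispersion_threshold_px = 100,
                               min_duration_ms = 100) {
  records <- data.table::as.data.table(records)
  records[, {
    ev <- extract_ocular_events(.SD, sampling_rate_hz,
                                dispersion_threshold_px, min_duration_ms)
    extract_modality_features(ev)   # NULL rows (no valid records) drop out
  }, by = c("subject_id", "stimulus_id")]
}

#' Attach labels and balance classes for a classification task
#'
#' Joins subject metadata onto feature rows, derives `age_label` (`under30`
#' when age <= 30, else `over30`) and `gender_label`, and randomly
#' down-samples the majority class of the requested task to exact parity
#' with the minority class (seeded).
#'
#' @param rows feature rows from [featurize_sessions()].
#' @param metadata roster with `subject_id`, `age`, `gender`.
#' @param task `"gender"` or `"age"`.
#' @param balance_seed seed for the down-sampling draw.
#' @return a `feature_table`: list with `rows` (balanced, labeled
#'   `data.table` including a `label` column for the task),
#'   `modality_blocks` (named list of column names), `task`, and
#'   `scaling` (NULL until [fuse_features()] is applied).
#' @export
assemble_dataset <- function(rows, metadata, task = c("gender", "age"),
                             balance_seed = 1L) {
  task <- match.arg(task)
  metadata <- data.table::as.data.table(metadata)
  orphans <- setdiff(unique(rows$subject_id), metadata$subject_id)
  if (length(orphans) > 0L) {
    stop("missing metadata for subjects: ", paste(orphans, collapse = ", "))
  }
  meta <- metadata[, list(subject_id, age, gender)]
  lab <- merge(rows, meta, by = "subject_id", sort = FALSE)
  lab[, gender_label := gender]
  lab[, age_label := ifelse(age <= 30, "under30", "over30")]
  lab[, label := if (task == "gender") gender_label else age_label]
  lab[, c("age", "gender") := NULL]

  counts <- table(lab$label)
  if (length(counts) < 2L) {
    stop("task '", task, "' has a single class; cannot balance")
  }
  n_min <- min(counts)
  keep <- with_seed(balance_seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(lab$label == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  lab <- lab[sort(keep)]

  structure(
    list(
      rows = lab,
      modality_blocks = list(
        pupil = modality_columns("pupil"),
        blink = modality_columns("blink"),
        fixation = modality_columns("fixation")
      ),
      task = task,
      scaling = NULL
    ),
    class = "feature_table"
  )
}

#' Feature-level fusion by scaling and concatenation
#'
#' Selects the requested modality blocks, fits a max-absolute scale factor
#' per feature on the training rows only, and divides every row's feature by
#' it. Max-abs scaling maps training values into \[-1, 1\] while keeping zero
#' entries exactly zero (no centering); an all-zero feature gets scale
#' factor 1. With a single modality the call performs scaling only.
#'
#' @param table a `feature_table` from [assemble_dataset()].
#' @param modalities non-empty subset of `c("pupil", "blink", "fixation")`.
#' @param train_index integer row indices on which scale factors are fitted.
#' @return a new `feature_table` restricted to the selected blocks, with
#'   `scaling` recording the per-feature factors.
#' @export
fuse_features <- function(table, modalities = c("pupil", "blink", "fixation"),
                          train_index) {
  stopifnot(inherits(table, "feature_table"))
  modalities <- match.arg(modalities, c("pupil", "blink", "fixation"),
                          several.ok = TRUE)
  if (length(train_index) == 0L) stop("train_index must be non-empty")
  cols <- unlist(lapply(modalities, modality_columns), use.names = FALSE)
  rows <- data.table::copy(table$rows)
  scales <- vapply(cols, function(cl) {
    m <- max(abs(rows[[cl]][train_index]), na.rm = TRUE)
    if (!is.finite(m) || m == 0) 1 else m
  }, numeric(1))
  for (cl in cols) data.table::set(rows, j = cl, value = rows[[cl]] / scales[[cl]])
  structure(
    list(
      rows = rows,
      modality_blocks = stats::setNames(
        lapply(modalities, modality_columns), modalities),
      task = table$task,
      scaling = scales
    ),
    class = "feature_table"
  )
}

#' Feature matrix and labels of a feature table
#'
#' @param table a `feature_table`.
#' @return `feature_matrix`: numeric matrix of the active modality blocks;
#'   `feature_labels`: factor of task labels (level order fixed as
#'   male/female or under30/over30).
#' @export
feature_matrix <- function(table) {
  cols <- unlist(table$modality_blocks, use.names = FALSE)
  as.matrix(table$rows[, cols, with = FALSE])
}

#' @rdname feature_matrix
#' @export
feature_labels <- function(table) {
  levs <- if (table$task == "gender") c("male", "female") else c("under30", "over30")
  factor(table$rows$label, levels = levs)
}

#' Write a feature table as comma-separated text
#'
#' Columns: `subject_id`, `stimulus_id`, `modality__feature` blocks,
#' `gender_label`, `age_label`.
#'
#' @param table a `feature_table`.
#' @param path file path.
#' @export
write_feature_csv <- function(table, path) {
  cols <- c("subject_id", "stimulus_id",
            unlist(table$modality_blocks, use.names = FALSE),
            "gender_label", "age_label")
  data.table::fwrite(table$rows[, cols, with = FALSE], path, quote = FALSE)
  invisible(path)
}

utils::globalVariables(c(
  "subject_id", "stimulus_id", "gender", "gender_label", "age_label", "label",
  ":=", "."
))
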