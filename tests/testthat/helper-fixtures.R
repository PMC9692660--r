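# Shared fixture builders and independent oracles. Oracles deliberately use
# naive algorithms (linear scans, nested loops) distinct from the package's
# vectorized implementations.

# Build a gaze record table from a list of per-record validity pairs.
records_from_codes <- function(codes, rate_hz = 50, gaze = NULL, pupil = 4) {
  n <- length(codes)
  vl <- vapply(codes, `[`, numeric(1), 1)
  vr <- vapply(codes, `[`, numeric(1), 2)
  if (is.null(gaze)) gaze <- cbind(rep(100, n), rep(100, n))
  data.table::data.table(
    timestamp_ms = (seq_len(n) - 1) * 1000 / rate_hz,
    validity_left = vl, validity_right = vr,
    pupil_left_mm = ifelse(vl == 4 & vr == 4, NA_real_, pupil),
    pupil_right_mm = ifelse(vl == 4 & vr == 4, NA_real_, pupil),
    gaze_x = ifelse(vl == 4 & vr == 4, NA_real_, gaze[, 1]),
    gaze_y = ifelse(vl == 4 & vr == 4, NA_real_, gaze[, 2]),
    stimulus_id = "P01", subject_id = "S001"
  )
}

# Records from both-eyes codes given as a single vector (0 or 4 per record).
records_from_both_eyes <- function(v, rate_hz = 50) {
  records_from_codes(lapply(v, function(x) c(x, x)), rate_hz)
}

# Records from gaze points, all validity (0,0).
records_from_gaze <- function(x, y, rate_hz = 50) {
  records_from_codes(rep(list(c(0, 0)), length(x)), rate_hz, cbind(x, y))
}

# Independent blink-count oracle: walk the both-eyes-4 indicator with an
# explicit state machine instead of rle().
oracle_blink_counts <- function(is4) {
  n_blink <- 0L; n_fast <- 0L
  run <- 0L
  for (i in seq_along(is4)) {
    if (is4[i]) {
      run <- run + 1L
    } else {
      if (run > 0L) {
        n_blink <- n_blink + 1L
        if (run == 1L) n_fast <- n_fast + 1L
      }
      run <- 0L
    }
  }
  # a trailing run never sees the return to validity: no event
  list(n_blink = n_blink, n_fast = n_fast)
}

# Independent I-DT oracle: same greedy semantics, written as a naive scan
# that recomputes dispersion from scratch at every step.
oracle_idt <- function(t, x, y, thr, min_dur) {
  disp <- function(i, j) {
    xs <- x[i:j]; ys <- y[i:j]
    (max(xs) - min(xs)) + (max(ys) - min(ys))
  }
  out <- list()
  i <- 1L; n <- length(t)
  while (i <= n) {
    j <- i
    while (j <= n && t[j] - t[i] < min_dur) j <- j + 1L
    if (j > n) break
    if (disp(i, j) <= thr) {
      while (j < n && disp(i, j + 1L) <= thr) j <- j + 1L
      out[[length(out) + 1L]] <- c(start = t[i], end = t[j],
                                   cx = mean(x[i:j]), cy = mean(y[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Construct a score_set directly from a positive-class confidence vector.
make_scoreset <- function(family, p_pos, labels, ids = NULL, acc = NULL,
                          levels = c("a", "b")) {
  labels <- factor(labels, levels = levels)
  if (is.null(ids)) ids <- sprintf("id%03d", seq_along(p_pos))
  scores <- cbind(1 - p_pos, p_pos)
  colnames(scores) <- levels
  pred <- levels[ifelse(p_pos > 1 - p_pos, 2L, 1L)]
  structure(
    list(
      classifier = list(family = family, params = list(), k = 2L),
      sample_ids = ids, scores = scores, labels = labels,
      test_accuracy = if (is.null(acc)) mean(pred == as.character(labels)) else acc,
      cv_accuracy = NA_real_
    ),
    class = "score_set"
  )
}

# Nested-loop exhaustive fusion oracle (sum/product), subsets in combn
# order, weights in lexicographic order with the first member slowest.
oracle_search <- function(scoresets, rule, size, labels) {
  lev <- colnames(scoresets[[1]]$scores)
  subsets <- utils::combn(length(scoresets), size)
  grid <- (1:10) / 10
  best <- NULL
  n_eval <- 0L
  rec <- function(memb, ws) {
    if (length(ws) == size) {
      n_eval <<- n_eval + 1L
      s1 <- rep(0, length(labels)); s2 <- rep(0, length(labels))
      if (rule == "sum") {
        for (m in seq_len(size)) {
          s1 <- s1 + ws[m] * scoresets[[memb[m]]]$scores[, 1]
          s2 <- s2 + ws[m] * scoresets[[memb[m]]]$scores[, 2]
        }
      } else {
        s1 <- rep(1, length(labels)); s2 <- rep(1, length(labels))
        for (m in seq_len(size)) {
          s1 <- s1 * scoresets[[memb[m]]]$scores[, 1]^ws[m]
          s2 <- s2 * scoresets[[memb[m]]]$scores[, 2]^ws[m]
        }
      }
      pred <- ifelse(s2 > s1, lev[2], lev[1])
      acc <- mean(pred == as.character(labels))
      if (is.null(best) || acc > best$accuracy + 1e-12) {
        best <<- list(member_index = memb, weights = ws, accuracy = acc)
      }
      return(invisible())
    }
    for (w in grid) rec(memb, c(ws, w))
  }
  for (ci in seq_len(ncol(subsets))) rec(subsets[, ci], numeric(0))
  best$n_evaluations <- n_eval
  best
}

# Nested-loop Bayes pair oracle.
oracle_search_bayes <- function(scoresets, labels) {
  lev <- colnames(scoresets[[1]]$scores)
  subsets <- utils::combn(length(scoresets), 2)
  best <- NULL
  n_eval <- 0L
  for (ci in seq_len(ncol(subsets))) {
    memb <- subsets[, ci]
    for (won in 1:2) {
      for (w in (1:10) / 10) {
        n_eval <- n_eval + 1L
        ta <- scoresets[[memb[1]]]$scores[, 2]
        tb <- scoresets[[memb[2]]]$scores[, 2]
        if (won == 1) ta <- ta * w else tb <- tb * w
        num <- ta * tb
        den <- (1 - ta) * (1 - tb) + num
        s <- ifelse(den == 0, 0.5, num / den)
        pred <- ifelse(s >= 0.5, lev[2], lev[1])
        acc <- mean(pred == as.character(labels))
        if (is.null(best) || acc > best$accuracy + 1e-12) {
          best <- list(member_index = memb, weight_on = won, weight = w,
                       accuracy = acc)
        }
      }
    }
  }
  best$n_evaluations <- n_eval
  best
}

# Tiny separable feature table for classification tests: two Gaussian
# clusters in the pupil block, noise elsewhere.
make_feature_table <- function(n_per_class = 20, task = "gender",
                               sep = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  lev <- if (task == "gender") c("male", "female") else c("under30", "over30")
  lab <- rep(lev, each = n_per_class)
  rows <- data.table::data.table(
    subject_id = sprintf("S%03d", seq_len(n)),
    stimulus_id = "P01"
  )
  for (cl in periofuse::modality_columns("pupil")) {
    rows[[cl]] <- rnorm(n) + sep * (lab == lev[2])
  }
  for (cl in c(periofuse::modality_columns("blink"),
               periofuse::modality_columns("fixation"))) {
    rows[[cl]] <- rnorm(n)
  }
  rows$gender_label <- if (task == "gender") lab else "male"
  rows$age_label <- if (task == "age") lab else "under30"
  rows$label <- lab
  structure(
    list(rows = rows,
         modality_blocks = list(pupil = periofuse::modality_columns("pupil"),
                                blink = periofuse::modality_columns("blink"),
                                fixation = periofuse::modality_columns("fixation")),
         task = task, scaling = NULL),
    class = "feature_table"
  )
}
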