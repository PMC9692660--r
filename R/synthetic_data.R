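#' Configuration for a synthetic eye-tracking cohort
#'
#' Describes the cohort composition, acquisition geometry and demographic
#' effect structure used by [generate_cohort()] and [simulate_session()].
#' Defaults mirror a remote-tracker picture-viewing study: 112 subjects
#' (73 male / 39 female), 18 stimuli per subject, 50 Hz sampling, an
#' age-related decline of resting pupil diameter, and a slightly higher
#' spontaneous blink rate in women than in men (15.2 vs 13.3 per minute).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param gender_ratio fraction of male subjects; the male count is
#'   `round(n_subjects * gender_ratio)`.
#' @param age_distribution data.frame with columns `lo`, `hi`, `weight`
#'   giving integer age ranges and their sampling weights (must sum to 1).
#' @param n_stimuli stimuli viewed per subject (opaque ids `P01`, `P02`, ...).
#' @param sampling_rate_hz tracker sampling frequency.
#' @param session_duration_s duration of one stimulus viewing, seconds.
#' @param pupil_base_mm pupil-diameter intercept at age 0, millimetres.
#' @param pupil_age_slope decline of baseline pupil diameter per decade of
#'   age, millimetres (positive number; baseline =
#'   `pupil_base_mm - pupil_age_slope * age / 10`).
#' @param pupil_subject_sd sd of the per-subject baseline offset, mm
#'   (individual differences beyond the age trend; 0 disables).
#' @param pupil_noise_sd per-sample, per-eye Gaussian measurement noise, mm.
#' @param blink_rate_by_gender named vector `c(male=, female=)`,
#'   blinks per minute.
#' @param blink_rate_age_slope additional blinks per minute per decade of
#'   age (default 0: no age effect on blinking).
#' @param blink_duration_mean_ms,blink_duration_sd_ms mean and sd of the
#'   log-normal blink-duration distribution, milliseconds.
#' @param fast_blink_fraction fraction of blinks rendered as a single
#'   eyes-not-found sample (too short for a duration to be computed).
#' @param fixation_params list with `duration_mean_ms`, `duration_sd_ms`
#'   (log-normal fixation durations) and `saccade_duration_ms` (inter-fixation
#'   transit time; the fixation rate is the implied
#'   `1 / (duration_mean + saccade_duration)`).
#' @param fixation_age_slope_ms shift of mean fixation duration per decade
#'   of age, ms (default 0).
#' @param fixation_gender_shift_ms shift of mean fixation duration for
#'   female subjects, ms (default 0).
#' @param gaze_noise_sd per-sample gaze jitter within a fixation, pixels.
#' @param screen_px screen resolution `c(width, height)` in pixels.
#' @param corrupt_fraction fraction of non-blink records carrying uncertain
#'   validity codes 1-3 (removed by preprocessing).
#' @param seed integer seed governing cohort generation and default session
#'   seeds.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 112L,
                          gender_ratio = 73 / 112,
                          age_distribution = default_age_distribution(),
                          n_stimuli = 18L,
                          sampling_rate_hz = 50,
                          session_duration_s = 18,
                          pupil_base_mm = 5.9,
                          pupil_age_slope = 0.3,
                          pupil_subject_sd = 0.3,
                          pupil_noise_sd = 0.15,
                          blink_rate_by_gender = c(male = 13.3, female = 15.2),
                          blink_rate_age_slope = 0,
                          blink_duration_mean_ms = 150,
                          blink_duration_sd_ms = 60,
                          fast_blink_fraction = 0.1,
                          fixation_params = list(duration_mean_ms = 250,
                                                 duration_sd_ms = 100,
                                                 saccade_duration_ms = 40),
                          fixation_age_slope_ms = 0,
                          fixation_gender_shift_ms = 0,
                          gaze_noise_sd = 3,
                          screen_px = c(1280, 1024),
                          corrupt_fraction = 0.02,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), gender_ratio = gender_ratio,
    age_distribution = as.data.frame(age_distribution),
    n_stimuli = as.integer(n_stimuli), sampling_rate_hz = sampling_rate_hz,
    session_duration_s = session_duration_s,
    pupil_base_mm = pupil_base_mm, pupil_age_slope = pupil_age_slope,
    pupil_subject_sd = pupil_subject_sd, pupil_noise_sd = pupil_noise_sd,
    blink_rate_by_gender = blink_rate_by_gender,
    blink_rate_age_slope = blink_rate_age_slope,
    blink_duration_mean_ms = blink_duration_mean_ms,
    blink_duration_sd_ms = blink_duration_sd_ms,
    fast_blink_fraction = fast_blink_fraction,
    fixation_params = fixation_params,
    fixation_age_slope_ms = fixation_age_slope_ms,
    fixation_gender_shift_ms = fixation_gender_shift_ms,
    gaze_noise_sd = gaze_noise_sd, screen_px = screen_px,
    corrupt_fraction = corrupt_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Age-range weights mirroring the emulated cohort
#'
#' Seven integer age ranges with subject counts 11, 58, 9, 16, 8, 9 and 1
#' (normalized to weights), spanning ages 17 to 80.
#'
#' @return data.frame with columns `lo`, `hi`, `weight`.
#' @export
default_age_distribution <- function() {
  d <- data.frame(
    lo = c(17L, 21L, 31L, 41L, 51L, 61L, 71L),
    hi = c(18L, 30L, 40L, 50L, 60L, 70L, 80L),
    weight = c(11, 58, 9, 16, 8, 9, 1)
  )
  d$weight <- d$weight / sum(d$weight)
  d
}

validate_cohort_config <- function(cfg) {
  if (!is.finite(cfg$n_subjects) || cfg$n_subjects <= 0L) {
    stop_config("n_subjects", "must be a positive count")
  }
  if (cfg$gender_ratio < 0 || cfg$gender_ratio > 1) {
    stop_config("gender_ratio", "must lie in [0, 1]")
  }
  ad <- cfg$age_distribution
  if (!all(c("lo", "hi", "weight") %in% names(ad)) || nrow(ad) == 0L) {
    stop_config("age_distribution", "needs columns lo, hi, weight")
  }
  if (any(ad$weight < 0) || abs(sum(ad$weight) - 1) > 1e-8) {
    stop_config("age_distribution", "weights must be non-negative and sum to 1")
  }
  if (any(ad$lo < 0) || any(ad$hi < ad$lo)) {
    stop_config("age_distribution", "ranges must satisfy 0 <= lo <= hi")
  }
  if (cfg$n_stimuli <= 0L) stop_config("n_stimuli", "must be a positive count")
  if (!is.finite(cfg$sampling_rate_hz) || cfg$sampling_rate_hz <= 0) {
    stop_config("sampling_rate_hz", "must be > 0")
  }
  if (!is.finite(cfg$session_duration_s) || cfg$session_duration_s <= 0) {
    stop_config("session_duration_s", "must be > 0")
  }
  if (any(cfg$blink_rate_by_gender < 0)) {
    stop_config("blink_rate_by_gender", "rates must be >= 0")
  }
  if (!all(c("male", "female") %in% names(cfg$blink_rate_by_gender))) {
    stop_config("blink_rate_by_gender", "needs named entries male and female")
  }
  for (f in c("pupil_subject_sd", "pupil_noise_sd", "gaze_noise_sd")) {
    if (cfg[[f]] < 0) stop_config(f, "must be >= 0")
  }
  for (f in c("fast_blink_fraction", "corrupt_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_config(f, "must lie in [0, 1]")
  }
  fp <- cfg$fixation_params
  if (!all(c("duration_mean_ms", "duration_sd_ms", "saccade_duration_ms") %in%
             names(fp))) {
    stop_config("fixation_params",
                "needs duration_mean_ms, duration_sd_ms, saccade_duration_ms")
  }
  if (fp$duration_mean_ms <= 0 || fp$duration_sd_ms < 0 ||
        fp$saccade_duration_ms < 0) {
    stop_config("fixation_params", "durations must be positive")
  }
  invisible(cfg)
}

#' Generate the subject roster of a synthetic cohort
#'
#' Gender counts are deterministic (`round(n_subjects * gender_ratio)` males);
#' ages are drawn from the configured range distribution; the derived
#' `age_group` is `under30` for ages up to and including 30, `over30`
#' otherwise. A per-subject pupil baseline offset (`pupil_offset_mm`) is drawn
#' once here so a subject keeps one resting diameter across all sessions.
#'
#' @param config a [cohort_config()].
#' @return `data.table` with columns `subject_id`, `age`, `gender`,
#'   `age_group`, `pupil_offset_mm`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_subjects
  n_male <- as.integer(round(n * config$gender_ratio))
  with_seed(config$seed, {
    genders <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    ad <- config$age_distribution
    ridx <- sample.int(nrow(ad), n, replace = TRUE, prob = ad$weight)
    ages <- ad$lo[ridx] +
      floor(runif(n) * (ad$hi[ridx] - ad$lo[ridx] + 1L))
    offsets <- rnorm(n, 0, config$pupil_subject_sd)
    data.table::data.table(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = as.integer(ages),
      gender = genders,
      age_group = ifelse(ages <= 30, "under30", "over30"),
      pupil_offset_mm = offsets
    )
  })
}

lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log1p((sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

corrupt_patterns <- matrix(c(
  0, 1, 0, 2, 0, 3, 1, 0, 2, 0, 3, 0,
  1, 1, 2, 2, 3, 3, 1, 2, 2, 3
), ncol = 2, byrow = TRUE)

#' Simulate one stimulus-viewing session
#'
#' Emits a Tobii-style record sequence at the configured sampling rate:
#' a subject- and age-determined pupil baseline with Gaussian measurement
#' noise, Poisson blink events rendered as runs of both-eyes validity-4
#' samples (pupil and gaze undefined) flanked by both-eyes validity-0
#' samples, a fixation-saccade gaze alternation, and a configurable fraction
#' of records with uncertain validity codes 1-3.
#'
#' @param subject one row of [generate_cohort()] output (list or data.frame
#'   row with at least `subject_id`, `age`, `gender`).
#' @param stimulus_id opaque stimulus identifier.
#' @param config a [cohort_config()].
#' @param seed integer seed for this session.
#' @return `data.table` of gaze records with columns `timestamp_ms`,
#'   `validity_left`, `validity_right`, `pupil_left_mm`, `pupil_right_mm`,
#'   `gaze_x`, `gaze_y`, `stimulus_id`, `subject_id`. Ground-truth events are
#'   attached as `attr(, "truth")` (lists `blinks`, `fixations`,
#'   `blink_rate_per_min`).
#' @export
simulate_session <- function(subject, stimulus_id, config, seed = config$seed) {
  validate_cohort_config(config)
  subject <- as.list(subject)
  for (f in c("subject_id", "age", "gender")) {
    if (is.null(subject[[f]])) stop("unknown subject: missing field ", f)
  }
  if (!subject$gender %in% c("male", "female")) {
    stop("unknown subject: gender must be male or female")
  }
  dt_ms <- 1000 / config$sampling_rate_hz
  n <- as.integer(round(config$session_duration_s * config$sampling_rate_hz))
  if (n <= 0L) stop("non-positive session length")
  ts <- (seq_len(n) - 1L) * dt_ms

  offset <- subject$pupil_offset_mm %||% 0
  baseline <- max(
    0.5,
    config$pupil_base_mm - config$pupil_age_slope * subject$age / 10 + offset
  )

  with_seed(seed, {
    ## --- blink events (Poisson arrivals, non-overlapping placements) ---
    rate <- unname(config$blink_rate_by_gender[[subject$gender]]) +
      config$blink_rate_age_slope * subject$age / 10
    rate <- max(0, rate)
    n_blinks <- rpois(1L, rate * config$session_duration_s / 60)
    occupied <- logical(n)   # blink samples plus one flank sample each side
    blink_runs <- list()
    if (n_blinks > 0L) {
      bp <- lnorm_pars(config$blink_duration_mean_ms, config$blink_duration_sd_ms)
      fast <- runif(n_blinks) < config$fast_blink_fraction
      lens <- ifelse(fast, 1L,
                     pmax(2L, as.integer(round(
                       rlnorm(n_blinks, bp$meanlog, bp$sdlog) / dt_ms))))
      for (b in seq_len(n_blinks)) {
        len <- lens[b]
        if (n - len < 2L) next
        for (try in 1:100) {
          start <- sample(2:(n - len), 1L)
          span <- (start - 1L):(start + len)
          if (!any(occupied[span])) {
            occupied[span] <- TRUE
            blink_runs[[length(blink_runs) + 1L]] <-
              c(start = start, len = len, fast = as.integer(fast[b]))
            break
          }
        }
      }
    }
    blink_mask <- logical(n)
    for (r in blink_runs) blink_mask[r["start"]:(r["start"] + r["len"] - 1L)] <- TRUE

    ## --- gaze: fixation-saccade alternation ---
    fp <- config$fixation_params
    fix_mean <- fp$duration_mean_ms +
      config$fixation_age_slope_ms * subject$age / 10 +
      if (subject$gender == "female") config$fixation_gender_shift_ms else 0
    fix_mean <- max(dt_ms * 2, fix_mean)
    lp <- lnorm_pars(fix_mean, max(1e-6, fp$duration_sd_ms))
    sacc_len <- max(1L, as.integer(round(fp$saccade_duration_ms / dt_ms)))
    W <- config$screen_px[1]; H <- config$screen_px[2]
    draw_loc <- function() c(runif(1, 0.1, 0.9) * W, runif(1, 0.1, 0.9) * H)
    gx <- numeric(n); gy <- numeric(n)
    truth_fix <- list()
    i <- 1L
    loc <- draw_loc()
    while (i <= n) {
      len <- max(2L, as.integer(round(rlnorm(1, lp$meanlog, lp$sdlog) / dt_ms)))
      len <- min(len, n - i + 1L)
      idx <- i:(i + len - 1L)
      gx[idx] <- loc[1] + rnorm(len, 0, config$gaze_noise_sd)
      gy[idx] <- loc[2] + rnorm(len, 0, config$gaze_noise_sd)
      truth_fix[[length(truth_fix) + 1L]] <- c(
        start_ms = ts[i], end_ms = ts[i + len - 1L],
        duration_ms = (len - 1L) * dt_ms, x = loc[1], y = loc[2]
      )
      i <- i + len
      if (i > n) break
      nxt <- draw_loc()
      slen <- min(sacc_len, n - i + 1L)
      frac <- seq_len(slen) / (slen + 1L)
      idx <- i:(i + slen - 1L)
      gx[idx] <- loc[1] + (nxt[1] - loc[1]) * frac + rnorm(slen, 0, config$gaze_noise_sd)
      gy[idx] <- loc[2] + (nxt[2] - loc[2]) * frac + rnorm(slen, 0, config$gaze_noise_sd)
      i <- i + slen
      loc <- nxt
    }

    ## --- validity codes and corruption ---
    vl <- integer(n); vr <- integer(n)
    vl[blink_mask] <- 4L; vr[blink_mask] <- 4L
    free <- which(!occupied)
    if (config$corrupt_fraction > 0 && length(free) > 0L) {
      hit <- free[runif(length(free)) < config$corrupt_fraction]
      if (length(hit) > 0L) {
        pat <- corrupt_patterns[
          sample.int(nrow(corrupt_patterns), length(hit), replace = TRUE), ,
          drop = FALSE]
        vl[hit] <- pat[, 1]; vr[hit] <- pat[, 2]
      }
    }

    ## --- pupil diameters ---
    pl <- baseline + rnorm(n, 0, config$pupil_noise_sd)
    pr <- baseline + rnorm(n, 0, config$pupil_noise_sd)
    pl[blink_mask] <- NA_real_; pr[blink_mask] <- NA_real_
    gx[blink_mask] <- NA_real_; gy[blink_mask] <- NA_real_

    rec <- data.table::data.table(
      timestamp_ms = ts,
      validity_left = vl, validity_right = vr,
      pupil_left_mm = pl, pupil_right_mm = pr,
      gaze_x = gx, gaze_y = gy,
      stimulus_id = as.character(stimulus_id),
      subject_id = as.character(subject$subject_id)
    )
    truth <- list(
      blinks = if (length(blink_runs) > 0L) {
        data.table::rbindlist(lapply(blink_runs, as.list))
      } else {
        data.table::data.table(start = integer(), len = integer(), fast = integer())
      },
      fixations = if (length(truth_fix) > 0L) {
        data.table::rbindlist(lapply(truth_fix, as.list))
      } else {
        data.table::data.table()
      },
      blink_rate_per_min = rate,
      pupil_baseline_mm = baseline
    )
    data.table::setattr(rec, "truth", truth)
    rec
  })
}

#' Simulate every session of a cohort
#'
#' Runs [simulate_session()] for each subject x stimulus pair with
#' session seeds derived from `config$seed` (or `seed`).
#'
#' @param config a [cohort_config()].
#' @param cohort optional pre-generated roster; default [generate_cohort()].
#' @param seed master seed; defaults to `config$seed`.
#' @return list with `cohort` (roster) and `records` (one `data.table` of all
#'   gaze records, keyed by `subject_id`, `stimulus_id`).
#' @export
simulate_cohort_sessions <- function(config, cohort = NULL, seed = config$seed) {
  validate_cohort_config(config)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  stim_ids <- sprintf("P%02d", seq_len(config$n_stimuli))
  seeds <- derive_seeds(seed, nrow(cohort) * length(stim_ids))
  out <- vector("list", nrow(cohort) * length(stim_ids))
  k <- 0L
  for (s in seq_len(nrow(cohort))) {
    subj <- cohort[s]
    for (p in seq_along(stim_ids)) {
      k <- k + 1L
      out[[k]] <- simulate_session(subj, stim_ids[p], config, seed = seeds[k])
    }
  }
  list(cohort = cohort, records = data.table::rbindlist(out))
}

#' Read or write gaze logs as tab-separated text
#'
#' One record per line with header
#' `timestamp_ms validity_left validity_right pupil_left_mm pupil_right_mm
#' gaze_x gaze_y stimulus_id subject_id`; undefined pupil/gaze values are
#' written as empty fields.
#'
#' @param records gaze record `data.table`.
#' @param path file path.
#' @return `write_gaze_tsv` returns `path` invisibly; `read_gaze_tsv` returns
#'   a gaze record `data.table`.
#' @export
write_gaze_tsv <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path) {
  rec <- data.table::fread(
    path, sep = "\t", header = TRUE, na.strings = "",
    colClasses = list(character = c("stimulus_id", "subject_id"))
  )
  need <- c("timestamp_ms", "validity_left", "validity_right", "pupil_left_mm",
            "pupil_right_mm", "gaze_x", "gaze_y", "stimulus_id", "subject_id")
  missing <- setdiff(need, names(rec))
  if (length(missing) > 0L) {
    stop("gaze log misses columns: ", paste(missing, collapse = ", "))
  }
  rec[, need, with = FALSE]
}

#' Read or write the subject metadata table
#'
#' Comma-separated `subject_id,age,gender`; the derived `age_group`
#' (under30 when age <= 30) is reconstructed on read.
#'
#' @param cohort roster `data.table` (extra columns are dropped on write).
#' @param path file path.
#' @return `read_subject_metadata` returns a `data.table` with `subject_id`,
#'   `age`, `gender`, `age_group`.
#' @export
write_subject_metadata <- function(cohort, path) {
  data.table::fwrite(cohort[, c("subject_id", "age", "gender"), with = FALSE],
                     path, sep = ",", quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_metadata
#' @export
read_subject_metadata <- function(path) {
  meta <- data.table::fread(path, sep = ",", header = TRUE,
                            colClasses = list(character = "subject_id"))
  meta[, age := as.integer(age)]
  meta[, age_group := ifelse(age <= 30, "under30", "over30")]
  meta[]
}

utils::globalVariables(c("age", "age_group"))
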