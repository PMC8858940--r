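#' Vector-magnitude count sum over a window
#'
#' Combines the three accelerometer axes into the per-sample vector
#' magnitude `sqrt(x^2 + y^2 + z^2)` and sums it over the samples of one
#' analysis window. This is the per-window VM predictor used throughout.
#'
#' @param counts Tibble/data frame with columns `x`, `y`, `z` (one row per
#'   sample).
#' @param start_s,end_s Half-open window bounds in seconds; defaults cover
#'   the whole series.
#' @param rate Sampling rate in Hz.
#' @return The scalar VM sum (counts/window).
#' @examples
#' vector_magnitude(data.frame(x = 3, y = 4, z = 12), 0, 1, rate = 1) # 13
#' @export
vector_magnitude <- function(counts, start_s = 0,
                             end_s = nrow(counts) / rate, rate = 30) {
  if (end_s <= start_s) stop("empty window", call. = FALSE)
  idx <- window_samples(start_s, end_s, rate)
  if (max(idx) > nrow(counts) || min(idx) < 1) {
    stop("window extends beyond the count series", call. = FALSE)
  }
  sum(sqrt(counts$x[idx]^2 + counts$y[idx]^2 + counts$z[idx]^2))
}

#' Names of the model-input features
#'
#' The 14 per-window inputs of the neural-network models (and the window
#' statistics available to regression): ten statistics of the per-sample VM
#' series within the window (mean, SD, covariance with the previous
#' window's VM samples, min, max and the 10/25/50/75/90th percentiles,
#' linear-interpolation convention), the window-mean heart rate, and the
#' subject's height, weight and sex code. Matches the 14-6-1 / 14-10-1
#' network architectures.
#'
#' @return Character vector of length 14.
#' @export
bpnn_feature_names <- function() {
  c("vm_mean", "vm_sd", "vm_cov_adjacent", "vm_min", "vm_max",
    "vm_p10", "vm_p25", "vm_p50", "vm_p75", "vm_p90",
    "hr_mean", "height", "weight", "sex_code")
}

#' Per-window feature rows for one wear site
#'
#' Segments a session by its window plan and computes, for every window,
#' the VM sum, the ten VM window statistics, the window-mean heart rate,
#' and the subject's anthropometrics. The adjacent covariance of window `w`
#' is the sample covariance between the per-sample VM vectors of windows
#' `w - 1` and `w`; the first window has no predecessor and gets 0.
#'
#' @param session A `tabata_session`.
#' @param site Wear site name (one of `names(session$counts)`).
#' @return A tibble, one row per window, with identifier columns
#'   (`subject_id`, `site`, `window_index`, `stage_index`, `period`),
#'   `vm_sum`, the 14 model-input columns of [bpnn_feature_names()], and
#'   the measured `ee` (kcal/window).
#' @export
window_features <- function(session, site = "right_ankle") {
  stopifnot(inherits(session, "tabata_session"))
  if (!site %in% names(session$counts)) {
    stop("unknown wear site: ", site, call. = FALSE)
  }
  protocol <- session$protocol
  plan <- build_window_plan(protocol)
  rate <- session$sampling_rate
  counts <- session$counts[[site]]
  n_expected <- protocol$duration_s * rate
  if (nrow(counts) < n_expected) {
    stop("count series shorter than the protocol requires", call. = FALSE)
  }
  bpm <- session$hr$bpm
  if (length(bpm) < protocol$duration_s || anyNA(bpm)) {
    stop("heart-rate series has gaps or is shorter than the protocol",
         call. = FALSE)
  }
  vm <- sqrt(counts$x^2 + counts$y^2 + counts$z^2)
  n_win <- nrow(plan)
  out <- matrix(NA_real_, n_win, 12)
  colnames(out) <- c("vm_sum", "vm_mean", "vm_sd", "vm_cov_adjacent",
                     "vm_min", "vm_max", "vm_p10", "vm_p25", "vm_p50",
                     "vm_p75", "vm_p90", "hr_mean")
  prev <- NULL
  for (i in seq_len(n_win)) {
    v <- vm[window_samples(plan$start_s[i], plan$end_s[i], rate)]
    qs <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
    cov_adj <- if (is.null(prev)) 0 else cov(prev, v)
    out[i, ] <- c(sum(v), mean(v), sd(v), cov_adj, min(v), max(v), qs,
                  mean(bpm[window_seconds(plan$start_s[i], plan$end_s[i])]))
    prev <- v
  }
  dplyr::bind_cols(
    tibble(subject_id = session$subject$subject_id, site = site),
    plan[, c("window_index", "stage_index", "period")],
    as_tibble(out),
    tibble(
      height = session$subject$height,
      weight = session$subject$weight,
      sex_code = session$subject$sex_code,
      ee = session$ee$kcal
    )
  )
}

#' Feature rows for every subject in a cohort
#'
#' @param cohort A `tabata_cohort`.
#' @param sites Wear sites to extract; defaults to the right ankle (the
#'   site whose counts feed the network models).
#' @return Row-bound [window_features()] tibble across subjects and sites.
#' @export
cohort_features <- function(cohort, sites = "right_ankle") {
  stopifnot(inherits(cohort, "tabata_cohort"))
  purrr::map_dfr(cohort$sessions, function(s) {
    purrr::map_dfr(sites, function(site) window_features(s, site))
  })
}

#' Whole-stage VM sum
#'
#' Sum of the per-window VM sums over all windows of one stage (for the
#' classic protocol: the 20-s bout plus the 10-s interval, i.e. 3 windows).
#'
#' @param rows A [window_features()] tibble (one site).
#' @param stage Stage index.
#' @return Scalar counts/stage.
#' @export
stage_vm <- function(rows, stage) {
  keep <- rows$stage_index == stage
  if (!any(keep)) stop("stage ", stage, " not present", call. = FALSE)
  sum(rows$vm_sum[keep])
}

#' Exercise-intensity summary of a session
#'
#' Mean exercise-second heart rate, observed maximum heart rate, mean METs
#' over all windows (`kcal/window * 3600/window_s / weight`; 1 MET = 1
#' kcal/kg/h), and the observed maximum as a percentage of the age-predicted
#' maximum `220 - age`.
#'
#' @param session A `tabata_session`.
#' @return One-row tibble: `mean_exercise_hr`, `max_hr`, `mean_mets`,
#'   `pct_hrmax`.
#' @export
intensity_summary <- function(session) {
  stopifnot(inherits(session, "tabata_session"))
  w <- session$subject$weight
  if (w <= 0) stop("subject weight must be positive", call. = FALSE)
  plan <- build_window_plan(session$protocol)
  ex_secs <- unlist(lapply(which(plan$period == "exercise"), function(i) {
    window_seconds(plan$start_s[i], plan$end_s[i])
  }))
  mets <- session$ee$kcal * (3600 / session$protocol$window_s) / w
  max_hr <- max(session$hr$bpm)
  tibble(
    mean_exercise_hr = mean(session$hr$bpm[ex_secs]),
    max_hr = max_hr,
    mean_mets = mean(mets),
    pct_hrmax = max_hr / (220 - session$subject$age) * 100
  )
}

# fast per-window VM sums and HR means for one session/site (no statistics)
window_sums <- function(session, site) {
  protocol <- session$protocol
  plan <- build_window_plan(protocol)
  rate <- session$sampling_rate
  counts <- session$counts[[site]]
  vm <- sqrt(counts$x^2 + counts$y^2 + counts$z^2)
  win_id <- rep(plan$window_index, each = protocol$window_s * rate)
  sec_id <- rep(plan$window_index, each = protocol$window_s)
  tibble(
    window_index = plan$window_index,
    stage_index = plan$stage_index,
    period = plan$period,
    vm_sum = as.numeric(rowsum(vm, win_id)),
    hr_mean = as.numeric(rowsum(session$hr$bpm, sec_id)) / protocol$window_s
  )
}

anthropometrics_of <- function(subject) {
  tibble(
    height = subject$height, weight = subject$weight,
    sex_code = subject$sex_code, age = subject$age,
    bmi = subject$bmi, body_fat = subject$body_fat
  )
}

#' Exercise-period candidate table
#'
#' One row per exercise window per subject, holding the pre-selected
#' exercise-period regression candidates: the window VM sum at each wear
#' site, the window-mean exercise heart rate, and the anthropometrics; the
#' target column `ee` is the measured kcal for that window.
#'
#' @param cohort A `tabata_cohort`.
#' @return Tibble with identifier columns, candidate columns
#'   (`vm_<site>` per site, `hr_exercise`, `height`, `weight`, `sex_code`,
#'   `age`, `bmi`, `body_fat`) and `ee`.
#' @export
candidate_table_exercise <- function(cohort) {
  stopifnot(inherits(cohort, "tabata_cohort"))
  sites <- names(cohort$config$site_scale)
  purrr::map_dfr(cohort$sessions, function(s) {
    per_site <- lapply(sites, function(site) window_sums(s, site)$vm_sum)
    names(per_site) <- paste0("vm_", sites)
    base <- window_sums(s, sites[[1]])
    row <- dplyr::bind_cols(
      tibble(subject_id = s$subject$subject_id),
      base[, c("window_index", "stage_index", "period")],
      as_tibble(per_site),
      tibble(hr_exercise = base$hr_mean),
      anthropometrics_of(s$subject),
      tibble(ee = s$ee$kcal)
    )
    row[row$period == "exercise", ]
  })
}

#' Interval-period candidate table
#'
#' One row per interval window per subject, holding the pre-selected
#' interval-period candidates built from the right-ankle VM and heart rate
#' of the surrounding stage: VM during 0-10 s, 10-20 s and 0-20 s of the
#' bout, the whole-stage VM, HR during the same bout segments and the whole
#' stage, the interval HR itself, and the anthropometrics. Requires 10-s
#' windows and a 20-s bout (the classic protocol).
#'
#' @param cohort A `tabata_cohort`.
#' @param site Wear site for the VM aggregates.
#' @return Tibble with identifier columns, the nine VM/HR candidates,
#'   anthropometrics, and the target `ee`.
#' @export
candidate_table_interval <- function(cohort, site = "right_ankle") {
  stopifnot(inherits(cohort, "tabata_cohort"))
  protocol <- cohort$config$protocol
  if (protocol$window_s != 10 || protocol$exercise_s != 20) {
    stop("interval candidates are defined for 20-s bouts in 10-s windows",
         call. = FALSE)
  }
  purrr::map_dfr(cohort$sessions, function(s) {
    ws <- window_sums(s, site)
    purrr::map_dfr(split(ws, ws$stage_index), function(st) {
      ex <- st[st$period == "exercise", ]
      iv <- st[st$period == "interval", ]
      dplyr::bind_cols(
        tibble(
          subject_id = s$subject$subject_id,
          stage_index = iv$stage_index,
          window_index = iv$window_index,
          vm_exercise_0_10 = ex$vm_sum[1],
          vm_exercise_10_20 = ex$vm_sum[2],
          vm_exercise_0_20 = ex$vm_sum[1] + ex$vm_sum[2],
          vm_stage = sum(st$vm_sum),
          hr_exercise_0_10 = ex$hr_mean[1],
          hr_exercise_10_20 = ex$hr_mean[2],
          hr_exercise_0_20 = mean(ex$hr_mean[1:2]),
          hr_stage = mean(st$hr_mean),
          hr_interval = iv$hr_mean
        ),
        anthropometrics_of(s$subject),
        tibble(ee = s$ee$kcal[iv$window_index])
      )
    })
  })
}

#' Pre-selected candidate variable names
#'
#' The named candidate presets screened by correlation and offered to
#' stepwise regression, per period.
#'
#' @param period `"exercise"` or `"interval"`.
#' @param sites Wear-site names (exercise preset only).
#' @return Character vector of candidate column names.
#' @export
candidate_preset <- function(period = c("exercise", "interval"),
                             sites = c("dominant_hand", "nondominant_hand",
                                       "right_hip", "right_ankle")) {
  period <- match.arg(period)
  anthro <- c("height", "weight", "sex_code", "age", "bmi", "body_fat")
  if (period == "exercise") {
    c(paste0("vm_", sites), "hr_exercise", anthro)
  } else {
    c("vm_exercise_0_10", "vm_exercise_10_20", "vm_exercise_0_20",
      "vm_stage", "hr_exercise_0_10", "hr_exercise_10_20",
      "hr_exercise_0_20", "hr_stage", "hr_interval", anthro)
  }
}
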