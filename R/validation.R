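#' Subject-level train/test split
#'
#' Randomly partitions subjects (never windows) into training and testing
#' sets. The training size is `round(ratio_train * n)` (half-up), clamped
#' so both sides keep at least one subject. `n_test` overrides the ratio
#' with an explicit validation-group size.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param ratio_train Training proportion (3:1 split = 0.75, the default).
#' @param seed Integer seed.
#' @param n_test Optional explicit test-set size overriding the ratio.
#' @return List with `train` and `test` id vectors.
#' @export
split_subjects <- function(subject_ids, ratio_train = 0.75, seed = 1,
                           n_test = NULL) {
  n <- length(subject_ids)
  if (n < 2) stop("need at least 2 subjects to split", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  if (is.null(n_test)) {
    if (ratio_train <= 0 || ratio_train >= 1) {
      stop("ratio_train must lie strictly between 0 and 1", call. = FALSE)
    }
    n_train <- floor(ratio_train * n + 0.5)
  } else {
    if (n_test < 1 || n_test > n - 1) stop("invalid n_test", call. = FALSE)
    n_train <- n - n_test
  }
  n_train <- min(max(n_train, 1L), n - 1L)
  shuffled <- withr::with_seed(seed, sample(subject_ids))
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[-seq_len(n_train)]))
}

#' Mean absolute percentage error
#'
#' `100/n * sum(|measured - predicted| / denominator)`. The default
#' convention divides by the measured value; the `"as-printed"` convention
#' divides by the predicted value instead (the error formula as typeset,
#' with the measured value in the numerator roles swapped).
#'
#' @param measured,predicted Numeric vectors of equal length.
#' @param convention `"measured"` (default) or `"as-printed"`.
#' @return Percentage error.
#' @export
mape <- function(measured, predicted,
                 convention = c("measured", "as-printed")) {
  convention <- match.arg(convention)
  if (length(measured) != length(predicted)) {
    stop("measured and predicted must have equal length", call. = FALSE)
  }
  denom <- if (convention == "measured") measured else predicted
  zero <- which(denom == 0)
  if (length(zero) > 0) {
    stop("zero denominator at index ", zero[1], call. = FALSE)
  }
  100 * mean(abs(measured - predicted) / abs(denom))
}

#' Root mean square error
#'
#' @param measured,predicted Numeric vectors of equal length >= 1.
#' @return kcal (same units as the inputs).
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 1) {
    stop("measured and predicted must be nonempty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((measured - predicted)^2))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `measured - predicted`; the x-coordinate of the plot is
#' the pairwise mean. Limits of agreement are `mean +/- 1.96 * SD` with the
#' sample SD (n - 1). Points exactly on a limit count as within.
#'
#' @param measured,predicted Numeric vectors of equal length >= 2.
#' @return An object of class `ee_bland_altman`: one-row tibble with
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `pct_within`,
#'   `n_points`, plus the per-point `data` (means and differences) as an
#'   attribute for plotting.
#' @export
bland_altman <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 2) {
    stop("need equal-length vectors with at least 2 points", call. = FALSE)
  }
  d <- measured - predicted
  m <- (measured + predicted) / 2
  mean_d <- mean(d)
  sd_d <- sd(d)
  lo <- mean_d - 1.96 * sd_d
  hi <- mean_d + 1.96 * sd_d
  out <- tibble(
    mean_diff = mean_d, sd_diff = sd_d, loa_low = lo, loa_high = hi,
    pct_within = 100 * mean(d >= lo & d <= hi), n_points = length(d)
  )
  attr(out, "points") <- tibble(mean = m, diff = d)
  class(out) <- c("ee_bland_altman", class(out))
  out
}

#' Per-stage MAPE decomposition
#'
#' MAPE restricted to each stage's windows, per model, plus the count of
#' stages whose MAPE exceeds a threshold (15% by default, the conventional
#' upper bound of a reasonable EE prediction error).
#'
#' @param predictions Tibble with columns `model`, `stage_index`,
#'   `measured`, `predicted`.
#' @param threshold Exceedance threshold in percent.
#' @param convention MAPE denominator convention.
#' @return List: `by_stage` tibble (`model`, `stage_index`, `mape`) and
#'   `n_above` tibble (`model`, `n_above_threshold`).
#' @export
per_stage_mape <- function(predictions, threshold = 15,
                           convention = c("measured", "as-printed")) {
  convention <- match.arg(convention)
  by_stage <- predictions |>
    dplyr::group_by(.data$model, .data$stage_index) |>
    dplyr::summarise(
      mape = mape(.data$measured, .data$predicted, convention = convention),
      .groups = "drop"
    )
  n_above <- by_stage |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(n_above_threshold = sum(.data$mape > threshold),
                     .groups = "drop")
  list(by_stage = by_stage, n_above = n_above)
}

# long prediction table for one cohort subset and a set of fitted models
predict_windows <- function(cohort, ids, lr_exercise, lr_interval,
                            nn_exercise, nn_interval,
                            nn_site = "right_ankle") {
  sub <- cohort
  sub$sessions <- cohort$sessions[ids]
  sub$subjects <- cohort$subjects[cohort$subjects$subject_id %in% ids, ]
  cand_ex <- candidate_table_exercise(sub)
  cand_in <- candidate_table_interval(sub, site = nn_site)
  feats <- cohort_features(sub, sites = nn_site)
  f_ex <- feats[feats$period == "exercise", ]
  f_in <- feats[feats$period == "interval", ]
  key <- c("subject_id", "window_index", "stage_index")
  base_ex <- cand_ex[, c(key, "ee")]
  base_in <- cand_in[, c(key, "ee")]
  mk <- function(base, pred, model, period) {
    tibble(
      subject_id = base$subject_id, window_index = base$window_index,
      stage_index = base$stage_index, period = period, model = model,
      measured = base$ee, predicted = pred
    )
  }
  dplyr::bind_rows(
    mk(base_ex, predict(lr_exercise, cand_ex), "lr", "exercise"),
    mk(base_in, predict(lr_interval, cand_in), "lr", "interval"),
    mk(f_ex[, c(key, "ee")], predict(nn_exercise, f_ex), "bpnn", "exercise"),
    mk(f_in[, c(key, "ee")], predict(nn_interval, f_in), "bpnn", "interval")
  ) |>
    dplyr::arrange(.data$model, .data$subject_id, .data$window_index)
}

#' Evaluate fitted models on held-out subjects
#'
#' Applies the period-matched models window-by-window to the test subjects
#' (exercise models to exercise windows, interval models to interval
#' windows) and assembles the agreement report: overall and per-period
#' MAPE, MAPE standard error (SD of per-subject MAPEs over the square root
#' of the subject count), RMSE and Bland-Altman limits per model, plus the
#' per-stage MAPE decomposition.
#'
#' @param cohort A `tabata_cohort` containing the test subjects' sessions.
#' @param test_ids Subject ids to evaluate on (must be disjoint from the
#'   ids the models were trained on; the caller guarantees this).
#' @param lr_exercise,lr_interval Fitted or published `ee_lm` models.
#' @param nn_exercise,nn_interval Fitted `ee_bpnn` models.
#' @param convention MAPE denominator convention.
#' @param nn_site Wear site feeding the network features.
#' @return An object of class `ee_validation_report`: list with
#'   `predictions`, `overall`, `by_period`, `by_stage`, `n_above`,
#'   `bland_altman`, `n_test_subjects`, `convention`.
#' @export
evaluate_models <- function(cohort, test_ids, lr_exercise, lr_interval,
                            nn_exercise, nn_interval,
                            convention = c("measured", "as-printed"),
                            nn_site = "right_ankle") {
  convention <- match.arg(convention)
  stopifnot(inherits(cohort, "tabata_cohort"))
  if (!all(test_ids %in% names(cohort$sessions))) {
    stop("unknown test subject ids", call. = FALSE)
  }
  for (m in list(lr_exercise, nn_exercise)) {
    if (!is.null(m$period) && m$period != "exercise") {
      stop("exercise-period model required", call. = FALSE)
    }
  }
  for (m in list(lr_interval, nn_interval)) {
    if (!is.null(m$period) && m$period != "interval") {
      stop("interval-period model required", call. = FALSE)
    }
  }
  preds <- predict_windows(cohort, test_ids, lr_exercise, lr_interval,
                           nn_exercise, nn_interval, nn_site = nn_site)
  metrics <- function(df) {
    per_subject <- df |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        m = mape(.data$measured, .data$predicted, convention = convention),
        .groups = "drop"
      )
    tibble(
      mape = mape(df$measured, df$predicted, convention = convention),
      mape_se = sd(per_subject$m) / sqrt(nrow(per_subject)),
      rmse = rmse(df$measured, df$predicted),
      r_squared = r_squared(df$measured, df$predicted),
      n = nrow(df)
    )
  }
  overall <- preds |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(~ metrics(.x)) |>
    dplyr::ungroup()
  by_period <- preds |>
    dplyr::group_by(.data$model, .data$period) |>
    dplyr::group_modify(~ metrics(.x)) |>
    dplyr::ungroup()
  stages <- per_stage_mape(preds, convention = convention)
  ba <- preds |>
    dplyr::mutate(scope = "overall") |>
    dplyr::bind_rows(dplyr::mutate(preds, scope = .data$period)) |>
    dplyr::group_by(.data$model, .data$scope) |>
    dplyr::group_modify(~ as_tibble(bland_altman(.x$measured, .x$predicted))) |>
    dplyr::ungroup()
  structure(
    list(
      predictions = preds, overall = overall, by_period = by_period,
      by_stage = stages$by_stage, n_above = stages$n_above,
      bland_altman = ba, n_test_subjects = length(test_ids),
      convention = convention
    ),
    class = "ee_validation_report"
  )
}

#' @export
print.ee_validation_report <- function(x, ...) {
  cat(sprintf("<ee_validation_report> %d test subjects, %d predictions/model (MAPE denominator: %s)\n",
              x$n_test_subjects, sum(x$predictions$model == "lr"),
              x$convention))
  ov <- x$overall
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-4s MAPE %5.2f%% (SE %.2f), RMSE %.3f kcal, r^2 %.3f\n",
                ov$model[i], ov$mape[i], ov$mape_se[i], ov$rmse[i],
                ov$r_squared[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ee_validation_report <- function(x, ...) x$by_period

#' @exportS3Method generics::glance
glance.ee_validation_report <- function(x, ...) {
  x$overall |>
    tidyr::pivot_wider(names_from = "model",
                       values_from = c("mape", "mape_se", "rmse",
                                       "r_squared", "n"))
}
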