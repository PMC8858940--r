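#' Stepwise linear regression by entry/removal p-values
#'
#' Forward selection with backward elimination: at each step the excluded
#' candidate with the smallest partial-F p-value below `p_enter` is added,
#' then any included term whose p-value has risen above `p_remove` is
#' dropped. Iterates to a fixed point. Only terms significant at `p_enter`
#' can be present in the final model, matching the p < 0.05 retention rule.
#'
#' @param data Tibble holding the target and candidate columns.
#' @param target Target column name (kcal/window).
#' @param candidates Candidate column names; defaults to the period preset.
#' @param period Period label stored on the model.
#' @param p_enter Entry significance threshold.
#' @param p_remove Removal significance threshold.
#' @return An object of class `ee_lm`: period, intercept, a `terms` tibble
#'   (`term`, `estimate`, `p_value`), `r_squared`, the underlying `lm` fit,
#'   and `intercept_only` flag when no candidate was admissible.
#' @export
stepwise_fit <- function(data, target = "ee", candidates = NULL,
                         period = c("exercise", "interval"),
                         p_enter = 0.05, p_remove = 0.10) {
  period <- match.arg(period)
  if (is.null(candidates)) candidates <- candidate_preset(period)
  stopifnot(p_enter > 0, p_enter < 1, p_remove >= p_enter, p_remove < 1)
  missing_cols <- setdiff(c(target, candidates), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 10 * length(candidates)) {
    warning("fewer than 10 rows per candidate; stepwise selection may be unstable",
            call. = FALSE)
  }

  fit_with <- function(terms) {
    rhs <- if (length(terms) == 0) "1" else
      paste(sprintf("`%s`", terms), collapse = " + ")
    lm(as.formula(sprintf("`%s` ~ %s", target, rhs)), data = data)
  }
  term_p <- function(fit) {
    cf <- summary(fit)$coefficients
    p <- cf[, "Pr(>|t|)"]
    p[setdiff(rownames(cf), "(Intercept)")]
  }

  included <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 2L * length(candidates) + 10L) break  # cycle guard
    changed <- FALSE
    # forward: candidate with smallest partial p below p_enter
    pool <- setdiff(candidates, included)
    if (length(pool) > 0) {
      entry_p <- vapply(pool, function(v) {
        fit <- fit_with(c(included, v))
        cf <- summary(fit)$coefficients
        key <- sprintf("`%s`", v)
        rn <- rownames(cf)
        hit <- match(key, rn, nomatch = match(v, rn, nomatch = 0L))
        if (hit == 0L) NA_real_ else cf[hit, "Pr(>|t|)"]  # aliased -> NA
      }, numeric(1))
      ok <- which(!is.na(entry_p) & entry_p < p_enter)
      if (length(ok) > 0) {
        included <- c(included, pool[ok[which.min(entry_p[ok])]])
        changed <- TRUE
      }
    }
    # backward: drop worst term above p_remove
    repeat {
      if (length(included) == 0) break
      p <- term_p(fit_with(included))
      worst <- which.max(p)
      if (length(p) > 0 && max(p, na.rm = TRUE) > p_remove) {
        drop_name <- gsub("`", "", names(p)[worst])
        included <- setdiff(included, drop_name)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  fit <- fit_with(included)
  sm <- summary(fit)
  est <- coef(fit)
  terms_tbl <- if (length(included) == 0) {
    tibble(term = character(0), estimate = numeric(0), p_value = numeric(0))
  } else {
    p <- term_p(fit)
    tibble(
      term = gsub("`", "", names(p)),
      estimate = unname(est[names(p)]),
      p_value = unname(p)
    )
  }
  structure(
    list(
      period = period,
      intercept = unname(est[["(Intercept)"]]),
      terms = terms_tbl,
      r_squared = sm$r.squared,
      fit = fit,
      intercept_only = length(included) == 0,
      source = "stepwise"
    ),
    class = "ee_lm"
  )
}

#' @export
print.ee_lm <- function(x, ...) {
  cat(sprintf("<ee_lm> %s-period model (%s), r^2 = %s\n", x$period, x$source,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  if (x$intercept_only) cat("  intercept-only (no admissible candidate)\n")
  eq <- paste(sprintf("%.6g*%s", x$terms$estimate, x$terms$term),
              collapse = " + ")
  cat(sprintf("  EE = %s%s%.6g\n", eq, if (nzchar(eq)) " + " else "",
              x$intercept))
  invisible(x)
}

#' @export
predict.ee_lm <- function(object, newdata, ...) {
  miss <- setdiff(object$terms$term, names(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks model terms: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- rep(object$intercept, nrow(newdata))
  for (i in seq_len(nrow(object$terms))) {
    out <- out + object$terms$estimate[i] * newdata[[object$terms$term[i]]]
  }
  out
}

#' @exportS3Method generics::tidy
tidy.ee_lm <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept, p_value = NA_real_),
    x$terms
  )
}

#' @exportS3Method generics::glance
glance.ee_lm <- function(x, ...) {
  tibble(period = x$period, r_squared = x$r_squared,
         n_terms = nrow(x$terms), intercept_only = x$intercept_only,
         source = x$source)
}

#' Published Tabata EE regression equations
#'
#' The fixed linear predictors reported for the classic Tabata protocol:
#' exercise period `EE = 0.000044*VM + 0.193*HR + 0.23*BW - 3.05`
#' (per-window right-ankle VM sum, window-mean exercise HR, body weight);
#' interval period `EE = 0.000011*VM_stage + 0.0116*HR_0_10 + 0.030*BW -
#' 1.99` (whole-stage right-ankle VM sum, HR during the bout's first 10 s,
#' body weight). Coefficients are used exactly as printed.
#'
#' @param period `"exercise"` or `"interval"`.
#' @return An `ee_lm` object whose terms are named after the candidate-table
#'   columns, so `predict()` works on [candidate_table_exercise()] /
#'   [candidate_table_interval()] rows.
#' @export
published_lr <- function(period = c("exercise", "interval")) {
  period <- match.arg(period)
  if (period == "exercise") {
    terms_tbl <- tibble(
      term = c("vm_right_ankle", "hr_exercise", "weight"),
      estimate = c(0.000044, 0.193, 0.23),
      p_value = NA_real_
    )
    intercept <- -3.05
    r2 <- 0.71
  } else {
    terms_tbl <- tibble(
      term = c("vm_stage", "hr_exercise_0_10", "weight"),
      estimate = c(0.000011, 0.0116, 0.030),
      p_value = NA_real_
    )
    intercept <- -1.99
    r2 <- 0.73
  }
  structure(
    list(period = period, intercept = intercept, terms = terms_tbl,
         r_squared = r2, fit = NULL, intercept_only = FALSE,
         source = "published"),
    class = "ee_lm"
  )
}

#' Evaluate the published exercise-period equation
#'
#' @param vm_exercise Per-window right-ankle VM sum (counts/window).
#' @param hr_exercise Window-mean exercise heart rate (bpm).
#' @param weight Body weight (kg).
#' @return kcal/window (the printed linear combination, unmodified).
#' @examples
#' predict_published_exercise(0, 0, 0) # the intercept, -3.05
#' @export
predict_published_exercise <- function(vm_exercise, hr_exercise, weight) {
  0.000044 * vm_exercise + 0.193 * hr_exercise + 0.23 * weight - 3.05
}

#' Evaluate the published interval-period equation
#'
#' @param vm_stage Whole-stage right-ankle VM sum (counts/stage).
#' @param hr_exercise_0_10 Mean heart rate during the bout's first 10 s
#'   (bpm).
#' @param weight Body weight (kg).
#' @return kcal/window.
#' @examples
#' predict_published_interval(0, 0, 0) # the intercept, -1.99
#' @export
predict_published_interval <- function(vm_stage, hr_exercise_0_10, weight) {
  0.000011 * vm_stage + 0.0116 * hr_exercise_0_10 + 0.030 * weight - 1.99
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of fitted against measured values.
#'
#' @param measured,fitted Numeric vectors of equal length >= 2.
#' @return Proportion of variance explained.
#' @export
r_squared <- function(measured, fitted) {
  if (length(measured) != length(fitted)) {
    stop("measured and fitted must have equal length", call. = FALSE)
  }
  if (length(measured) < 2) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) stop("zero total variance", call. = FALSE)
  1 - sum((measured - fitted)^2) / ss_tot
}
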