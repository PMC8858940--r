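#' Simulation configuration for synthetic Tabata cohorts
#'
#' Bundles every tunable of the synthetic-data generator: the anthropometric
#' population, the count-signal intensity per wear site, the heart-rate
#' kinetics, and the generative energy-expenditure model. Defaults emulate a
#' young-adult cohort performing the classic Tabata protocol: exercise heart
#' rate averaging about 165 bpm with maxima near 183, roughly 8-9 METs
#' during bouts, and near-zero accelerometer counts during the standing
#' intervals.
#'
#' @param protocol A [tabata_protocol()].
#' @param sampling_rate Accelerometer sampling rate in Hz.
#' @param p_female Probability that a simulated subject is female.
#' @param age_mean,age_sd Age distribution (years), truncated positive.
#' @param height_mean,height_sd Height distribution (m), truncated positive.
#' @param weight_mean,weight_sd Body-weight distribution (kg), truncated
#'   positive.
#' @param bodyfat_mean,bodyfat_sd Body-fat percentage, truncated to
#'   \[0, 100\].
#' @param site_scale Named numeric vector: mean per-axis per-sample count
#'   during exercise for each wear site.
#' @param site_cv Coefficient of variation of per-axis counts around
#'   `site_scale` within a bout.
#' @param subject_intensity_sd SD of the subject-level multiplier shared by
#'   all wear sites (overall movement vigour varies between subjects).
#' @param site_intensity_sd SD of the additional subject-by-site multiplier
#'   component (limbs move with partly independent vigour, so per-site
#'   count scales are correlated but not collinear across subjects).
#' @param interval_level Mean (and SD) of per-axis counts during standing
#'   intervals; `0` yields exactly-zero interval counts.
#' @param hr_rest Pre-session heart rate (bpm) the trajectory starts from.
#' @param hr_ex_mean,hr_ex_sd Subject-level mean exercise heart rate (bpm).
#' @param hr_recovery Recovery asymptote the interval decay heads toward.
#' @param hr_tau_on,hr_tau_off Time constants (s) of the first-order rise
#'   during bouts and decay during intervals.
#' @param hr_drift Upward drift of the bout target per stage (bpm/stage),
#'   emulating cardiovascular drift across the session.
#' @param hr_noise_sd Per-second Gaussian heart-rate noise (bpm).
#' @param hr_max_mean,hr_max_sd Subject-level cap on heart rate (bpm).
#' @param ee_exercise,ee_interval Named numeric vectors
#'   `c(vm=, hr=, weight=, intercept=)`: per-period generative coefficients
#'   mapping (window VM sum, window-mean HR, body weight) to kcal/window.
#' @param ee_site Wear site whose VM drives the generative EE model.
#' @param ee_noise_sd SD of additive Gaussian EE noise (kcal/window).
#' @param nonlin_gain Gain of the optional nonlinearity added to
#'   exercise-window EE; `0` keeps the generative model purely linear.
#' @param nonlin_hr_center,nonlin_hr_scale,nonlin_vm_center,nonlin_vm_scale
#'   Centering/scaling used inside the nonlinearity (see Details).
#'
#' @details With `nonlin_gain > 0`, exercise windows receive the extra term
#' `gain * tanh(z_hr * z_vm + 0.5 * z_hr^2)` where `z_hr` and `z_vm` are the
#' centred/scaled window-mean HR and window VM sum: a saturating heart-rate
#' by movement interaction that an additive linear model cannot express,
#' bounded so extreme draws cannot push a window's energy expenditure to
#' the physiologically impossible zero floor.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(protocol = tabata_protocol(),
                       sampling_rate = 30,
                       p_female = 23 / 45,
                       age_mean = 21.04, age_sd = 2.39,
                       height_mean = 1.67, height_sd = 0.075,
                       weight_mean = 59.61, weight_sd = 8.27,
                       bodyfat_mean = 18.46, bodyfat_sd = 5.47,
                       site_scale = c(dominant_hand = 14, nondominant_hand = 13,
                                      right_hip = 10, right_ankle = 19),
                       site_cv = 0.35,
                       subject_intensity_sd = 0.10,
                       site_intensity_sd = 0.12,
                       interval_level = 0.5,
                       hr_rest = 95,
                       hr_ex_mean = 165.46, hr_ex_sd = 5.39,
                       hr_recovery = 130,
                       hr_tau_on = 15, hr_tau_off = 20,
                       hr_drift = 3,
                       hr_noise_sd = 2,
                       hr_max_mean = 183.43, hr_max_sd = 7.09,
                       ee_exercise = c(vm = 3e-5, hr = 0.0125,
                                       weight = 0.018, intercept = -2.0),
                       ee_interval = c(vm = 3e-5, hr = 0.010,
                                       weight = 0.012, intercept = -1.0),
                       ee_site = "right_ankle",
                       ee_noise_sd = 0.15,
                       nonlin_gain = 0,
                       nonlin_hr_center = 165, nonlin_hr_scale = 10,
                       nonlin_vm_center = 10000, nonlin_vm_scale = 2000) {
  stopifnot(inherits(protocol, "tabata_protocol"))
  sds <- c(age_sd, height_sd, weight_sd, bodyfat_sd, subject_intensity_sd,
           site_intensity_sd, hr_ex_sd, hr_noise_sd, hr_max_sd, ee_noise_sd)
  if (any(sds < 0)) stop("all SDs must be nonnegative", call. = FALSE)
  if (interval_level < 0) stop("interval_level must be nonnegative", call. = FALSE)
  if (is.null(names(site_scale)) || any(site_scale < 0)) {
    stop("site_scale must be a named nonnegative vector", call. = FALSE)
  }
  if (!ee_site %in% names(site_scale)) {
    stop("ee_site must be one of the wear sites in site_scale", call. = FALSE)
  }
  for (cf in list(ee_exercise, ee_interval)) {
    if (!all(c("vm", "hr", "weight", "intercept") %in% names(cf))) {
      stop("EE coefficient vectors need names vm, hr, weight, intercept",
           call. = FALSE)
    }
  }
  cfg <- mget(names(formals(sim_config)))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  protocol: %d x (%d + %d) s, %d Hz counts, sites: %s\n",
              x$protocol$n_stages, x$protocol$exercise_s,
              x$protocol$interval_s, x$sampling_rate,
              paste(names(x$site_scale), collapse = ", ")))
  cat(sprintf("  HR: exercise mean %.1f +/- %.1f bpm, cap %.1f +/- %.1f\n",
              x$hr_ex_mean, x$hr_ex_sd, x$hr_max_mean, x$hr_max_sd))
  cat(sprintf("  EE noise SD %.3f kcal/window, nonlinearity gain %.2f\n",
              x$ee_noise_sd, x$nonlin_gain))
  invisible(x)
}

# truncated-normal draws by rejection; lower bound inclusive.
# sd = 0 degenerates to the mean (must satisfy the bounds).
rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate truncated normal outside its bounds", call. = FALSE)
    }
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection did not terminate",
                             call. = FALSE)
  }
  x
}
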