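#' Simulate one subject's anthropometrics
#'
#' Draws sex, age, height, weight and body-fat percentage from the
#' configured truncated-normal population and recomputes BMI from the drawn
#' height and weight. With all SDs set to zero the profile equals the
#' population means exactly. Identical seeds give identical profiles.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; mandatory.
#' @param subject_id Identifier to record.
#' @return A one-row tibble: `subject_id`, `sex`, `sex_code` (female 0,
#'   male 1), `age`, `height`, `weight`, `bmi`, `body_fat`.
#' @export
simulate_subject <- function(config, seed, subject_id = "S01") {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    sex <- if (runif(1) < config$p_female) "female" else "male"
    age <- rnorm_trunc(1, config$age_mean, config$age_sd, lower = 1e-8)
    height <- rnorm_trunc(1, config$height_mean, config$height_sd, lower = 1e-8)
    weight <- rnorm_trunc(1, config$weight_mean, config$weight_sd, lower = 1e-8)
    body_fat <- rnorm_trunc(1, config$bodyfat_mean, config$bodyfat_sd,
                            lower = 0, upper = 100)
  })
  tibble(
    subject_id = subject_id,
    sex = sex,
    sex_code = as.integer(sex == "male"),
    age = age,
    height = height,
    weight = weight,
    bmi = weight / height^2,
    body_fat = body_fat
  )
}

# per-second heart-rate trajectory: first-order rise toward a per-stage bout
# target during exercise, first-order decay toward the recovery asymptote
# during intervals, then shifted so the exercise-second mean equals the
# subject's plateau, plus noise, capped at the subject's maximum.
simulate_hr <- function(protocol, config, plateau, hr_max) {
  dur <- protocol$duration_s
  plan <- build_window_plan(protocol)
  sec_period <- character(dur)
  sec_stage <- integer(dur)
  for (i in seq_len(nrow(plan))) {
    secs <- window_seconds(plan$start_s[i], plan$end_s[i])
    sec_period[secs] <- plan$period[i]
    sec_stage[secs] <- plan$stage_index[i]
  }
  k <- numeric(dur)
  h <- config$hr_rest
  a_on <- exp(-1 / config$hr_tau_on)
  a_off <- exp(-1 / config$hr_tau_off)
  mid <- (protocol$n_stages + 1) / 2
  for (t in seq_len(dur)) {
    if (sec_period[t] == "exercise") {
      target <- plateau + config$hr_drift * (sec_stage[t] - mid)
      h <- target + (h - target) * a_on
    } else {
      h <- config$hr_recovery + (h - config$hr_recovery) * a_off
    }
    k[t] <- h
  }
  ex <- sec_period == "exercise"
  k <- k + (plateau - mean(k[ex]))
  k <- k + rnorm(dur, 0, config$hr_noise_sd)
  pmin(pmax(k, 30), min(hr_max, 230))
}

# tri-axial counts for one site: truncated-normal per-axis samples at the
# exercise scale during bouts, near-zero during intervals.
simulate_counts <- function(protocol, config, site, intensity) {
  rate <- config$sampling_rate
  n <- protocol$duration_s * rate
  plan <- build_window_plan(protocol)
  ex_sample <- logical(n)
  for (i in which(plan$period == "exercise")) {
    ex_sample[window_samples(plan$start_s[i], plan$end_s[i], rate)] <- TRUE
  }
  m_ex <- config$site_scale[[site]] * intensity
  s_ex <- config$site_cv * m_ex
  lvl <- config$interval_level
  draw_axis <- function() {
    x <- numeric(n)
    x[ex_sample] <- rnorm_trunc(sum(ex_sample), m_ex, s_ex, lower = 0)
    x[!ex_sample] <- rnorm_trunc(sum(!ex_sample), lvl, lvl, lower = 0)
    x
  }
  tibble(sample_index = seq_len(n), x = draw_axis(), y = draw_axis(),
         z = draw_axis())
}

# generative EE for one window (vectorised over windows)
generative_ee <- function(vm, hr, weight, period, config) {
  cf_ex <- config$ee_exercise
  cf_in <- config$ee_interval
  ee <- ifelse(
    period == "exercise",
    cf_ex[["vm"]] * vm + cf_ex[["hr"]] * hr + cf_ex[["weight"]] * weight +
      cf_ex[["intercept"]],
    cf_in[["vm"]] * vm + cf_in[["hr"]] * hr + cf_in[["weight"]] * weight +
      cf_in[["intercept"]]
  )
  if (config$nonlin_gain != 0) {
    z_hr <- (hr - config$nonlin_hr_center) / config$nonlin_hr_scale
    z_vm <- (vm - config$nonlin_vm_center) / config$nonlin_vm_scale
    ee <- ee + ifelse(period == "exercise",
                      config$nonlin_gain * tanh(z_hr * z_vm + 0.5 * z_hr^2),
                      0)
  }
  ee
}

#' Simulate one Tabata session for a subject
#'
#' Generates 30-Hz (configurable) tri-axial counts at each wear site,
#' a per-second heart-rate trajectory with on/off kinetics, and per-window
#' measured energy expenditure from the configured generative function of
#' window VM, window-mean HR and body weight, plus additive Gaussian noise
#' floored at zero.
#'
#' @param subject A one-row subject tibble from [simulate_subject()].
#' @param config A [sim_config()].
#' @param seed Integer seed; mandatory.
#' @return An object of class `tabata_session`: list with `subject`,
#'   `protocol`, `sampling_rate`, `counts` (named list of per-site tibbles
#'   `sample_index, x, y, z`), `hr` (tibble `second, bpm`), and `ee`
#'   (tibble `window_index, kcal`).
#' @export
simulate_session <- function(subject, config, seed) {
  stopifnot(inherits(config, "sim_config"), nrow(subject) == 1)
  protocol <- config$protocol
  if (protocol$duration_s <= 0) stop("protocol duration must be positive",
                                     call. = FALSE)
  plan <- build_window_plan(protocol)
  withr::with_seed(seed, {
    shared <- rnorm(1, 0, config$subject_intensity_sd)
    intensity <- pmax(1 + shared + rnorm(length(config$site_scale), 0,
                                         config$site_intensity_sd), 0.2)
    names(intensity) <- names(config$site_scale)
    plateau <- rnorm_trunc(1, config$hr_ex_mean, config$hr_ex_sd, lower = 30)
    hr_max <- rnorm_trunc(1, config$hr_max_mean, config$hr_max_sd, lower = 30)
    counts <- lapply(names(config$site_scale), function(site) {
      simulate_counts(protocol, config, site, intensity[[site]])
    })
    names(counts) <- names(config$site_scale)
    bpm <- simulate_hr(protocol, config, plateau, hr_max)
    site_c <- counts[[config$ee_site]]
    vm_samp <- sqrt(site_c$x^2 + site_c$y^2 + site_c$z^2)
    win_id <- rep(plan$window_index, each = protocol$window_s * config$sampling_rate)
    vm_win <- as.numeric(rowsum(vm_samp, win_id))
    sec_id <- rep(plan$window_index, each = protocol$window_s)
    hr_win <- as.numeric(rowsum(bpm, sec_id)) / protocol$window_s
    kcal <- generative_ee(vm_win, hr_win, subject$weight, plan$period, config)
    kcal <- pmax(kcal + rnorm(length(kcal), 0, config$ee_noise_sd), 0)
  })
  structure(
    list(
      subject = subject,
      protocol = protocol,
      sampling_rate = config$sampling_rate,
      counts = counts,
      hr = tibble(second = seq_len(protocol$duration_s), bpm = bpm),
      ee = tibble(window_index = plan$window_index, kcal = kcal)
    ),
    class = "tabata_session"
  )
}

#' @export
print.tabata_session <- function(x, ...) {
  cat(sprintf(
    "<tabata_session> subject %s: %d s at %d Hz, %d sites, %d EE windows\n",
    x$subject$subject_id, x$protocol$duration_s, x$sampling_rate,
    length(x$counts), nrow(x$ee)
  ))
  invisible(x)
}

#' Simulate a cohort of subjects with full sessions
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; per-subject seeds are derived from it, so the
#'   whole cohort is a pure function of `(config, n_subjects, seed)`.
#' @return An object of class `tabata_cohort`: list with `subjects`
#'   (tibble), `sessions` (named list of `tabata_session`), `config`,
#'   `seed`.
#' @export
simulate_cohort <- function(config, n_subjects = 45, seed = 1) {
  stopifnot(inherits(config, "sim_config"), n_subjects >= 1)
  seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, 2L * n_subjects),
           ncol = 2L))
  ids <- sprintf("S%02d", seq_len(n_subjects))
  subjects <- vector("list", n_subjects)
  sessions <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    subjects[[i]] <- simulate_subject(config, seeds[i, 1], subject_id = ids[i])
    sessions[[i]] <- simulate_session(subjects[[i]], config, seeds[i, 2])
  }
  names(sessions) <- ids
  structure(
    list(subjects = dplyr::bind_rows(subjects), sessions = sessions,
         config = config, seed = seed),
    class = "tabata_cohort"
  )
}

#' @export
print.tabata_cohort <- function(x, ...) {
  cat(sprintf("<tabata_cohort> %d subjects, seed %s\n",
              nrow(x$subjects), format(x$seed)))
  invisible(x)
}
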