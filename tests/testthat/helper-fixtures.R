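# memoised fixtures so expensive cohorts are built once per test run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# default-condition cohort, 8 subjects
fixture_cohort <- function() {
  cached("cohort_default", simulate_cohort(sim_config(), 8, seed = 101))
}

# cohort generated from the published exercise equation, no nonlinearity
fixture_cohort_published <- function() {
  cached("cohort_published", {
    cfg <- sim_config(ee_exercise = c(vm = 0.000044, hr = 0.193,
                                      weight = 0.23, intercept = -3.05))
    simulate_cohort(cfg, 30, seed = 202)
  })
}

# hand-built 2-window session: 2 Hz, one 2-s exercise window then one 2-s
# interval window; per-sample VM equals the x axis (y = z = 0)
manual_session <- function(x = c(1, 2, 3, 4, 5, 6, 7, 8),
                           bpm = c(150, 160, 140, 130),
                           kcal = c(1.5, 1.0),
                           weight = 60, age = 20) {
  protocol <- tabata_protocol(n_stages = 1, exercise_s = 2, interval_s = 2,
                              window_s = 2)
  subject <- tibble::tibble(
    subject_id = "M01", sex = "female", sex_code = 0L, age = age,
    height = 1.67, weight = weight, bmi = weight / 1.67^2, body_fat = 20
  )
  structure(
    list(
      subject = subject,
      protocol = protocol,
      sampling_rate = 2,
      counts = list(right_ankle = tibble::tibble(
        sample_index = seq_along(x), x = x, y = 0, z = 0
      )),
      hr = tibble::tibble(second = seq_along(bpm), bpm = bpm),
      ee = tibble::tibble(window_index = 1:2, kcal = kcal)
    ),
    class = "tabata_session"
  )
}
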