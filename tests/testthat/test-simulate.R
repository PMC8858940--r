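zero_sd_config <- function(...) {
  sim_config(age_sd = 0, height_sd = 0, weight_sd = 0, bodyfat_sd = 0,
             subject_intensity_sd = 0, site_intensity_sd = 0,
             hr_ex_sd = 0, hr_noise_sd = 0, hr_max_sd = 0, ee_noise_sd = 0,
             ...)
}

test_that("degenerate population SDs reproduce the sample means exactly", {
  s <- simulate_subject(zero_sd_config(), seed = 5)
  expect_equal(s$weight, 59.61)
  expect_equal(s$age, 21.04)
  expect_equal(s$height, 1.67)
  expect_equal(s$bmi, 59.61 / 1.67^2, tolerance = 0.1 / s$bmi)
})

test_that("subjects and sessions are pure functions of their seed", {
  cfg <- sim_config()
  a <- simulate_subject(cfg, seed = 11)
  b <- simulate_subject(cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_subject(cfg, seed = 12)))

  s1 <- simulate_session(a, cfg, seed = 13)
  s2 <- simulate_session(a, cfg, seed = 13)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$hr, s2$hr)
  expect_identical(s1$ee, s2$ee)
})

test_that("anthropometric draws concentrate around the configured means", {
  cfg <- sim_config()
  draws <- withr::with_seed(1, sample.int(1e7, 1000))
  w <- vapply(draws, function(s) simulate_subject(cfg, s)$weight, numeric(1))
  se <- cfg$weight_sd / sqrt(1000)
  expect_lt(abs(mean(w) - 59.61), 3 * se)
  expect_true(all(w > 0))
})

test_that("session series respect the protocol and physiological bounds", {
  cfg <- sim_config()
  s <- simulate_session(simulate_subject(cfg, 21), cfg, 22)
  expect_equal(nrow(s$counts$right_ankle),
               cfg$protocol$duration_s * cfg$sampling_rate)
  expect_equal(nrow(s$hr), cfg$protocol$duration_s)
  expect_true(all(s$hr$bpm >= 30 & s$hr$bpm <= 230))
  expect_true(all(s$ee$kcal >= 0))
  for (site in names(s$counts)) {
    expect_true(all(s$counts[[site]]$x >= 0))
  }
})

test_that("zero interval level yields exactly-zero interval-window VM", {
  cfg <- sim_config(interval_level = 0)
  s <- simulate_session(simulate_subject(cfg, 31), cfg, 32)
  plan <- build_window_plan(cfg$protocol)
  for (i in which(plan$period == "interval")) {
    expect_identical(
      vector_magnitude(s$counts$right_ankle, plan$start_s[i], plan$end_s[i],
                       rate = cfg$sampling_rate),
      0
    )
  }
})

test_that("noiseless generation reproduces the published exercise equation exactly", {
  cfg <- zero_sd_config(
    ee_exercise = c(vm = 0.000044, hr = 0.193, weight = 0.23,
                    intercept = -3.05)
  )
  subj <- simulate_subject(cfg, 41)
  s <- simulate_session(subj, cfg, 42)
  ws <- tabataEE:::window_sums(s, "right_ankle")
  ex <- ws$period == "exercise"
  expect_equal(
    s$ee$kcal[ex],
    predict_published_exercise(ws$vm_sum[ex], ws$hr_mean[ex], subj$weight),
    tolerance = 1e-12
  )
})

test_that("exercise-second heart rate averages the configured plateau across a cohort", {
  cfg <- sim_config()
  co <- simulate_cohort(cfg, 30, seed = 7)
  plan <- build_window_plan(cfg$protocol)
  ex_secs <- unlist(lapply(which(plan$period == "exercise"), function(i) {
    seq.int(plan$start_s[i] + 1L, plan$end_s[i])
  }))
  grand <- mean(vapply(co$sessions,
                       function(s) mean(s$hr$bpm[ex_secs]), numeric(1)))
  se <- cfg$hr_ex_sd / sqrt(30)
  expect_lt(abs(grand - cfg$hr_ex_mean), 3 * se)
})

test_that("simulated intensity matches the high-intensity profile of classic Tabata", {
  co <- fixture_cohort()
  summ <- purrr::map_dfr(co$sessions, intensity_summary)
  expect_gt(mean(summ$mean_mets), 6)     # 'vigorous' by ACSM convention
  expect_lt(mean(summ$mean_mets), 12)
  expect_gt(mean(summ$pct_hrmax), 80)
  expect_true(all(summ$max_hr >= summ$mean_exercise_hr))
})
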