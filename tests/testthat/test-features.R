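test_that("vector magnitude matches hand-computed sums", {
  expect_equal(vector_magnitude(tibble::tibble(x = 3, y = 4, z = 12),
                                0, 1, rate = 1), 13)
  two <- tibble::tibble(x = c(1, 2), y = c(2, 3), z = c(2, 6))
  expect_equal(vector_magnitude(two, 0, 1, rate = 2), 10)  # 3 + 7
  zero <- tibble::tibble(x = rep(0, 30), y = 0, z = 0)
  expect_equal(vector_magnitude(zero, 0, 1, rate = 30), 0)
  expect_error(vector_magnitude(two, 0, 0, rate = 2), "empty")
  expect_error(vector_magnitude(two, 0, 2, rate = 2), "beyond")
})

test_that("vector magnitude equals a per-sample brute-force oracle and is homogeneous", {
  withr::with_seed(99, {
    for (k in 1:20) {
      n <- sample(5:50, 1)
      cts <- tibble::tibble(x = runif(n, 0, 50), y = runif(n, 0, 50),
                            z = runif(n, 0, 50))
      oracle <- 0
      for (i in seq_len(n)) {
        oracle <- oracle + sqrt(cts$x[i]^2 + cts$y[i]^2 + cts$z[i]^2)
      }
      got <- vector_magnitude(cts, 0, 1, rate = n)
      expect_equal(got, oracle, tolerance = 1e-12)
      doubled <- tibble::tibble(x = 2 * cts$x, y = 2 * cts$y, z = 2 * cts$z)
      expect_equal(vector_magnitude(doubled, 0, 1, rate = n), 2 * got,
                   tolerance = 1e-12)
    }
  })
})

test_that("window statistics follow the linear-interpolation percentile convention", {
  f <- window_features(manual_session(x = c(1, 2, 3, 4, 5, 6, 7, 8)),
                       site = "right_ankle")
  expect_equal(nrow(f), 2)
  expect_equal(f$vm_p50[1], 2.5)      # median of {1,2,3,4} by interpolation
  expect_equal(f$vm_p25[1], 1.75)
  expect_equal(f$vm_sum[1], 10)
  expect_equal(f$vm_min[1], 1)
  expect_equal(f$vm_max[1], 4)
  expect_equal(f$hr_mean, c(155, 135))
})

test_that("constant windows collapse every VM statistic to the constant", {
  f <- window_features(manual_session(x = rep(7, 8)), site = "right_ankle")
  for (col in c("vm_mean", "vm_min", "vm_max", "vm_p10", "vm_p25",
                "vm_p50", "vm_p75", "vm_p90")) {
    expect_equal(f[[col]], c(7, 7))
  }
  expect_equal(f$vm_sd, c(0, 0))
})

test_that("adjacent covariance is zero for the first window and the variance for a repeat", {
  f <- window_features(manual_session(x = c(1, 2, 3, 4, 1, 2, 3, 4)))
  expect_equal(f$vm_cov_adjacent[1], 0)
  expect_equal(f$vm_cov_adjacent[2], var(c(1, 2, 3, 4)))
})

test_that("feature rows carry exactly the 14 model inputs with ordered percentiles", {
  co <- fixture_cohort()
  f <- window_features(co$sessions[[1]], "right_ankle")
  expect_true(all(bpnn_feature_names() %in% names(f)))
  expect_length(bpnn_feature_names(), 14)
  ord <- with(f, vm_min <= vm_p10 & vm_p10 <= vm_p25 & vm_p25 <= vm_p50 &
                vm_p50 <= vm_p75 & vm_p75 <= vm_p90 & vm_p90 <= vm_max)
  expect_true(all(ord))
  expect_true(all(f$vm_sd >= 0))
  expect_true(all(f$vm_sum >= 0))
})

test_that("stage VM sums the stage's windows and scales linearly", {
  rows <- tibble::tibble(stage_index = rep(1:2, each = 3),
                         vm_sum = c(100, 200, 0, 50, 60, 70))
  expect_equal(stage_vm(rows, 1), 300)
  expect_equal(stage_vm(rows, 2), 180)
  rows$vm_sum <- 2 * rows$vm_sum
  expect_equal(stage_vm(rows, 1), 600)
  expect_error(stage_vm(rows, 3), "not present")
})

test_that("intensity summary converts kcal per window to METs and %HRmax", {
  s <- manual_session(bpm = c(150, 160, 165, 130), kcal = c(1.5, 1.5),
                      weight = 60, age = 20)
  s$protocol <- tabata_protocol(1, 2, 2, 2)
  # 2-s windows: kcal/window * 1800 / weight; here use a 10-s equivalent
  out <- intensity_summary(s)
  expect_equal(out$max_hr, 165)
  expect_equal(out$pct_hrmax, 165 / 200 * 100)  # 82.5%
  expect_equal(out$mean_exercise_hr, 155)

  s10 <- simulate_session(
    simulate_subject(sim_config(weight_sd = 0), 3),
    sim_config(weight_sd = 0), 4
  )
  s10$ee$kcal <- rep(1.5, 24)
  expect_equal(intensity_summary(s10)$mean_mets, 1.5 * 360 / 59.61)
  s10$ee$kcal <- rep(0, 24)
  expect_equal(intensity_summary(s10)$mean_mets, 0)
})

test_that("candidate tables expose the pre-selected variables per period", {
  co <- fixture_cohort()
  ce <- candidate_table_exercise(co)
  ci <- candidate_table_interval(co)
  expect_equal(nrow(ce), 8 * 16)     # 16 exercise windows per subject
  expect_equal(nrow(ci), 8 * 8)      # 8 interval windows per subject
  expect_true(all(candidate_preset("exercise") %in% names(ce)))
  expect_true(all(candidate_preset("interval") %in% names(ci)))
  # stage aggregates are consistent: 0-20 s VM is the sum of its halves
  expect_equal(ci$vm_exercise_0_20,
               ci$vm_exercise_0_10 + ci$vm_exercise_10_20)
  expect_true(all(ci$vm_stage >= ci$vm_exercise_0_20))
})
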