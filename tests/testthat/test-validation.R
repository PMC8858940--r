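test_that("subject splits honour the 3:1 ratio with round-half-up", {
  ids <- sprintf("S%02d", 1:45)
  sp <- split_subjects(ids, ratio_train = 0.75, seed = 1)
  expect_length(sp$train, 34)   # 45 * 0.75 = 33.75 rounds up
  expect_length(sp$test, 11)
  expect_setequal(c(sp$train, sp$test), ids)

  sp4 <- split_subjects(sprintf("S%d", 1:4), 0.75, seed = 2)
  expect_length(sp4$train, 3)
  expect_length(sp4$test, 1)

  expect_identical(split_subjects(ids, 0.75, seed = 9),
                   split_subjects(ids, 0.75, seed = 9))
  over <- split_subjects(ids, seed = 3, n_test = 15)
  expect_length(over$test, 15)
  expect_error(split_subjects(ids, ratio_train = 1.2, seed = 1), "strictly")
  expect_error(split_subjects("S1", seed = 1), "at least 2")
})

test_that("MAPE follows both denominator conventions", {
  expect_equal(mape(c(2, 4), c(2, 4)), 0)
  expect_equal(mape(c(2, 4), c(1, 5)), 37.5)
  expect_equal(mape(c(2, 4), c(1, 5), convention = "as-printed"), 60)
  expect_error(mape(c(0, 4), c(1, 5)), "index 1")
  expect_error(mape(c(2, 4), c(1, 0), convention = "as-printed"), "index 2")
  expect_error(mape(1:3, 1:2), "equal length")
})

test_that("MAPE and RMSE agree with one-line brute-force oracles", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(5, 3), 2)
  expect_equal(rmse(1:4, 1:4), 0)
  withr::with_seed(17, {
    for (k in 1:30) {
      n <- sample(3:60, 1)
      m <- runif(n, 1, 5); p <- runif(n, 1, 5)
      expect_equal(mape(m, p), 100 * mean(abs(m - p) / m), tolerance = 1e-12)
      expect_equal(rmse(m, p), sqrt(mean((m - p)^2)), tolerance = 1e-12)
      expect_equal(r_squared(m, p),
                   1 - sum((m - p)^2) / sum((m - mean(m))^2),
                   tolerance = 1e-12)
      # permutation invariance over windows
      o <- sample(n)
      expect_equal(mape(m[o], p[o]), mape(m, p), tolerance = 1e-12)
      expect_equal(rmse(m[o], p[o]), rmse(m, p), tolerance = 1e-12)
    }
  })
})

test_that("Bland-Altman limits behave on degenerate inputs", {
  perfect <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mean_diff, 0)
  expect_equal(perfect$loa_low, 0)
  expect_equal(perfect$loa_high, 0)
  expect_equal(perfect$pct_within, 100)  # points on the limit count as within

  shifted <- bland_altman(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(shifted$mean_diff, 1)
  expect_equal(shifted$sd_diff, 0)
  expect_equal(c(shifted$loa_low, shifted$loa_high), c(1, 1))
  expect_true(shifted$loa_low <= shifted$loa_high)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman coverage of Gaussian differences approaches 95%", {
  withr::with_seed(123, {
    measured <- rnorm(1e5, 1.5, 0.3)
    predicted <- measured - rnorm(1e5, 0.05, 0.2)
  })
  ba <- bland_altman(measured, predicted)
  expect_lt(abs(ba$pct_within - 95.0), 0.3)
  expect_equal(ba$n_points, 1e5)
})

test_that("per-stage MAPE is local to the corrupted stage and counts exceedances", {
  plan <- build_window_plan(tabata_protocol())
  base <- tibble::tibble(stage_index = plan$stage_index,
                         measured = 2, predicted = 2)
  mk <- function(df, model) dplyr::mutate(df, model = model)
  a <- base; a$predicted[a$stage_index %in% 1:3] <- 2 * 1.2   # 20% error
  a$predicted[a$stage_index %in% 4:8] <- 2 * 1.02             # 2% error
  b <- base; b$predicted[b$stage_index %in% c(2, 5)] <- 2 * 1.2
  b$predicted[!b$stage_index %in% c(2, 5)] <- 2 * 1.02
  out <- per_stage_mape(dplyr::bind_rows(mk(a, "A"), mk(b, "B")))
  expect_equal(nrow(out$by_stage), 16)
  expect_equal(out$n_above$n_above_threshold[out$n_above$model == "A"], 3)
  expect_equal(out$n_above$n_above_threshold[out$n_above$model == "B"], 2)

  perfect <- per_stage_mape(mk(base, "P"))
  expect_equal(perfect$by_stage$mape, rep(0, 8))
  expect_equal(perfect$n_above$n_above_threshold, 0)
})

test_that("stage MAPEs aggregate (window-weighted) to the overall MAPE", {
  co <- fixture_cohort()
  ids <- co$subjects$subject_id[1:2]
  lr_ex <- published_lr("exercise"); lr_in <- published_lr("interval")
  f <- cohort_features(co)
  cfgq <- train_config(max_epochs = 10, seed = 1)
  nn_ex <- fit_bpnn(f[f$period == "exercise", ], n_hidden = 4, config = cfgq)
  nn_in <- fit_bpnn(f[f$period == "interval", ], n_hidden = 4, config = cfgq)
  rep <- evaluate_models(co, ids, lr_ex, lr_in, nn_ex, nn_in)
  for (mod in c("lr", "bpnn")) {
    pr <- rep$predictions[rep$predictions$model == mod, ]
    st <- rep$by_stage[rep$by_stage$model == mod, ]
    w <- table(pr$stage_index)
    expect_equal(sum(st$mape * as.numeric(w)) / sum(w),
                 rep$overall$mape[rep$overall$model == mod],
                 tolerance = 1e-10)
  }
})

test_that("a noiseless linear cohort is predicted almost exactly by stepwise regression", {
  cfg <- sim_config(ee_noise_sd = 0, nonlin_gain = 0)
  pc <- pipeline_config(sim = cfg, n_subjects = 8,
                        train = train_config(max_epochs = 25), seed = 4)
  out <- suppressWarnings(run_pipeline(pc))
  lr_mape <- out$report$overall$mape[out$report$overall$model == "lr"]
  expect_lt(lr_mape, 0.1)
  lr_ba <- out$report$bland_altman
  row <- lr_ba[lr_ba$model == "lr" & lr_ba$scope == "overall", ]
  expect_lt(row$loa_high - row$loa_low, 1e-3)  # limits collapse
})

test_that("validation reports round-trip through JSON", {
  co <- fixture_cohort()
  ids <- co$subjects$subject_id[1:2]
  f <- cohort_features(co)
  cfgq <- train_config(max_epochs = 10, seed = 1)
  nn_ex <- fit_bpnn(f[f$period == "exercise", ], n_hidden = 4, config = cfgq)
  nn_in <- fit_bpnn(f[f$period == "interval", ], n_hidden = 4, config = cfgq)
  rep <- evaluate_models(co, ids, published_lr("exercise"),
                         published_lr("interval"), nn_ex, nn_in)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  rep2 <- read_report(path)
  expect_equal(rep2$overall, rep$overall)
  expect_equal(rep2$by_stage, rep$by_stage)
  expect_equal(as.data.frame(rep2$bland_altman),
               as.data.frame(rep$bland_altman))
  expect_equal(rep2$predictions, rep$predictions)
  expect_equal(rep2$n_test_subjects, rep$n_test_subjects)
})
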