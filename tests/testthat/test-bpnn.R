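test_that("logsig matches its closed form and identity", {
  expect_equal(logsig(0), 0.5)
  expect_equal(logsig(log(3)), 0.75)
  withr::with_seed(2, {
    x <- rnorm(100, sd = 10)
    expect_equal(logsig(x) + logsig(-x), rep(1, 100), tolerance = 1e-12)
  })
  expect_equal(logsig(1000), 1)
  expect_equal(logsig(-1000), 0)
  expect_true(all(is.finite(logsig(c(-500, 500)))))
})

test_that("hidden-node heuristic spans 4..15 for the 14-input architecture", {
  expect_equal(heuristic_hidden_range(14, 1), 4:15)
  expect_length(heuristic_hidden_range(14, 1), 12)
  expect_equal(min(heuristic_hidden_range(3, 1)), 4)  # clipped from base 2
  expect_true(all(heuristic_hidden_range(100, 1) <= 15))
})

test_that("initialisation is seeded with bias-augmented weight shapes", {
  a <- init_network(5, 4, 1, seed = 9)
  b <- init_network(5, 4, 1, seed = 9)
  expect_identical(a$w1, b$w1)
  expect_identical(a$w2, b$w2)
  expect_false(identical(a$w1, init_network(5, 4, 1, seed = 10)$w1))
  expect_equal(dim(a$w1), c(4, 6))   # n_hidden x (n_input + 1)
  expect_equal(dim(a$w2), c(1, 5))   # n_output x (n_hidden + 1)
  expect_true(all(abs(a$w1) <= 0.5) && all(abs(a$w2) <= 0.5))
})

test_that("forward pass matches a hand-computed 2-2-1 oracle and stays in (0,1)", {
  m <- init_network(2, 2, 1, seed = 1)
  m$w1[] <- 1; m$w2[] <- 1
  x <- c(0.3, 0.6)
  u <- 1 / (1 + exp(-(x[1] + x[2] + 1)))        # both hidden units equal
  oracle <- 1 / (1 + exp(-(2 * u + 1)))
  expect_equal(bpnn_forward(m, x), oracle, tolerance = 1e-12)

  z <- init_network(3, 4, 1, seed = 2)
  z$w1[] <- 0; z$w2[] <- 0
  expect_equal(bpnn_forward(z, c(1, 2, 3)), 0.5)

  withr::with_seed(3, {
    r <- init_network(6, 5, 1, seed = 4)
    X <- matrix(rnorm(60), 10, 6)
    y <- bpnn_forward(r, X)
    expect_true(all(y > 0 & y < 1))
  })
  expect_error(bpnn_forward(m, c(1, 2, 3)), "n_input")
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(11, {
    for (k in 1:3) {
      m <- init_network(3, 3, 1, seed = 100 + k)
      X <- matrix(runif(15), 5, 3)
      tg <- runif(5, 0.1, 0.9)
      g <- bpnn_gradient(m, X, tg)
      eps <- 1e-5
      for (nm in c("w1", "w2")) {
        num <- m[[nm]] * 0
        for (i in seq_along(num)) {
          up <- m; up[[nm]][i] <- up[[nm]][i] + eps
          dn <- m; dn[[nm]][i] <- dn[[nm]][i] - eps
          num[i] <- (mean((bpnn_forward(up, X) - tg)^2) -
                       mean((bpnn_forward(dn, X) - tg)^2)) / (2 * eps)
        }
        expect_lt(max(abs(g[[nm]] - num) / (abs(num) + 1e-8)), 1e-6)
      }
    }
  })
})

test_that("a momentum-free epoch equals the hand-derived gradient step", {
  m <- init_network(1, 1, 1, seed = 6)
  X <- matrix(c(0.2, 0.8), 2, 1)
  tg <- c(0.3, 0.7)
  lr <- 0.01
  g <- bpnn_gradient(m, X, tg)
  cfg <- train_config(max_epochs = 1, lr0 = lr, momentum = 0,
                      lr_up = 1, lr_down = 1, err_ratio = Inf, goal = 0)
  out <- bpnn_train(m, X, tg, cfg)
  expect_equal(out$model$w1, m$w1 - lr * g$w1, tolerance = 1e-14)
  expect_equal(out$model$w2, m$w2 - lr * g$w2, tolerance = 1e-14)
  expect_length(out$history, 1)
})

test_that("zero-epoch training leaves the network untouched", {
  m <- init_network(4, 3, 1, seed = 8)
  X <- matrix(runif(20), 5, 4)
  out <- bpnn_train(m, X, runif(5, 0.1, 0.9),
                    train_config(max_epochs = 0))
  expect_identical(out$model$w1, m$w1)
  expect_identical(out$model$w2, m$w2)
  expect_length(out$history, 0)
})

test_that("the trainer solves XOR within the epoch budget", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  tg <- c(0.1, 0.9, 0.9, 0.1)
  out <- bpnn_train(init_network(2, 6, 1, seed = 1), X, tg, train_config())
  expect_lt(out$history[length(out$history)], 0.001)
  expect_lte(length(out$history), 5000)
  # monotone-ish: the adaptive rule never accepts a > 4% error increase
  expect_true(all(diff(out$history) <= 0.04 * out$history[-length(out$history)] + 1e-12))
})

test_that("fitted networks predict near their targets on a noiseless problem", {
  withr::with_seed(21, {
    d <- tibble::tibble(a = runif(60), b = runif(60))
    d$y <- 1 + 2 * d$a + 0.5 * d$b
  })
  m <- fit_bpnn(d, target = "y", features = c("a", "b"), n_hidden = 4,
                config = train_config(seed = 5))
  pr <- predict(m, d)
  # goal 0.001 on the [0.1, 0.9] scale ~ sqrt(0.001)/0.8 of the y range
  expect_lt(rmse(d$y, pr), sqrt(0.001) / 0.8 * diff(range(d$y)) * 1.5)
  # predictions stay inside the invertible image of (0, 1)
  rng <- range(d$y)
  pad <- diff(rng) / 8
  expect_true(all(pr > rng[1] - pad & pr < rng[2] + pad))
  # column order in newdata is irrelevant (name-based scaling)
  expect_equal(predict(m, d[, c("b", "a", "y")]), pr)
  expect_error(predict(init_network(2, 2, 1), d), "not been fitted")
})

test_that("hidden-node search reports one RMSE per candidate and the tie rule", {
  withr::with_seed(31, {
    d <- tibble::tibble(a = runif(80), b = runif(80))
    d$y <- d$a + d$b + rnorm(80, sd = 0.05)
  })
  s <- hidden_node_search(d, target = "y", candidates = c(4, 5, 6),
                          config = train_config(max_epochs = 60, seed = 2),
                          features = c("a", "b"))
  expect_equal(s$results$n_hidden, c(4, 5, 6))
  expect_length(s$results$rmse, 3)
  expect_true(s$best %in% c(4, 5, 6))
  # selection mechanics on constructed profiles
  expect_equal(tabataEE:::select_hidden(4:15, c(9, 8, 6, 7, 8, 9, 10, 11,
                                                12, 13, 14, 15)), 6)
  expect_equal(tabataEE:::select_hidden(4:9, rep(1, 6)), 4)
  expect_equal(tabataEE:::select_hidden(c(7, 5, 6), c(2, 3, 2)), 6)
})

test_that("network serialisation round-trips bit-exactly", {
  withr::with_seed(41, {
    d <- tibble::tibble(a = runif(30), b = runif(30))
    d$y <- d$a - d$b + rnorm(30, sd = 0.1)
  })
  m <- fit_bpnn(d, target = "y", features = c("a", "b"), n_hidden = 3,
                config = train_config(max_epochs = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$w1, m$w1)
  expect_identical(m2$w2, m$w2)
  expect_identical(unname(m2$scaling$x_min), unname(m$scaling$x_min))
  expect_identical(predict(m2, d), predict(m, d))
})
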