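test_that("local fits reproduce constants and linear data exactly", {
  x <- sort(runif(20, 0, 10))
  const <- loess_tricube(x, rep(3.5, 20), span = 0.5)
  expect_equal(const$fitted, rep(3.5, 20), tolerance = 1e-12)

  for (span in c(0.3, 0.6, 1)) {
    lin <- loess_tricube(x, 2 * x + 1, span = span, degree = 1)
    expect_equal(lin$fitted, 2 * x + 1, tolerance = 1e-8)
  }
})

test_that("fitted values agree with a per-point weighted least-squares oracle", {
  withr::local_seed(21)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    x <- sort(runif(n, 0, 100))
    y <- runif(n)
    span <- runif(1, 0.3, 0.9)
    degree <- sample(1:2, 1)
    fit <- loess_tricube(x, y, span = span, degree = degree)
    for (i in sample(n, 3)) {
      expect_equal(fit$fitted[i], wls_oracle_at(x, y, span, degree, i),
                   tolerance = 1e-10)
    }
  }
})

test_that("the smoother is linear in the response", {
  withr::local_seed(8)
  x <- sort(runif(25, 0, 10))
  y1 <- runif(25)
  y2 <- runif(25)
  f1 <- loess_tricube(x, y1, 0.6)$fitted
  f2 <- loess_tricube(x, y2, 0.6)$fitted
  f12 <- loess_tricube(x, 2 * y1 - 3 * y2, 0.6)$fitted
  expect_equal(f12, 2 * f1 - 3 * f2, tolerance = 1e-10)
})

test_that("hat trace matches the probed hat matrix and shrinks with span", {
  withr::local_seed(13)
  n <- 30
  x <- sort(runif(n, 0, 50))
  y <- runif(n)
  spans <- c(0.2, 0.35, 0.5, 0.7, 0.9, 1)
  traces <- numeric(length(spans))
  for (j in seq_along(spans)) {
    fit <- loess_tricube(x, y, spans[j], keep_hat = TRUE)
    L <- hat_matrix_probe(x, spans[j], 1)
    expect_equal(fit$hat, L, tolerance = 1e-10)
    expect_equal(as.numeric(L %*% y), fit$fitted, tolerance = 1e-10)
    traces[j] <- fit$hat_trace
    expect_gte(fit$hat_trace, 1)
    expect_lte(fit$hat_trace, n)
  }
  expect_true(all(diff(traces) < 1e-8))
})

test_that("span 1 local-linear fit reproduces ordinary least squares on linear data", {
  x <- sort(runif(15, 0, 5))
  y <- -0.4 * x + 2
  fit <- loess_tricube(x, y, span = 1, degree = 1)
  ols <- stats::lm(y ~ x)
  expect_equal(fit$fitted, unname(stats::fitted(ols)), tolerance = 1e-9)
})

test_that("AICc follows the corrected-AIC formula for linear smoothers", {
  # direct substitution: n = 10, trace = 3, sigma_hat^2 = RSS/n = 1
  fake <- structure(
    list(n = 10L, hat_trace = 3, rss = 10, span = 0.5, degree = 1L),
    class = "loess_tricube"
  )
  expect_equal(loess_aicc(fake), 1 + 2 * 4 / 5)

  # independent recomputation from the probed hat matrix
  withr::local_seed(17)
  x <- sort(runif(20, 0, 10))
  y <- runif(20)
  fit <- loess_tricube(x, y, 0.6)
  L <- hat_matrix_probe(x, 0.6, 1)
  nu <- sum(diag(L))
  rss <- sum((y - L %*% y)^2)
  expect_equal(loess_aicc(fit),
               log(rss / 20) + 1 + 2 * (nu + 1) / (20 - nu - 2),
               tolerance = 1e-10)

  # perfect fit is guarded, not an error
  lin <- loess_tricube(x, 3 * x, 0.6)
  expect_lt(loess_aicc(lin), -20)

  # degenerate: trace too close to n
  tiny <- structure(list(n = 6L, hat_trace = 5, rss = 0.1, span = 0.1, degree = 1L),
                    class = "loess_tricube")
  expect_error(loess_aicc(tiny), class = "survcloak_error_degenerate")
})

test_that("degenerate windows raise a rank error", {
  x <- c(1, 1, 1, 1, 5, 6)
  expect_error(loess_tricube(x, runif(6), span = 0.5),
               class = "survcloak_error_rank")
  expect_error(loess_tricube(sort(runif(10)), runif(10), span = 1.2),
               class = "survcloak_error_validation")
})

test_that("span selection matches an exhaustive 91-point grid oracle", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n <- sample(15:40, 1)
    x <- sort(runif(n, 0, 20))
    y <- exp(-x / 10) + rnorm(n, sd = 0.05)
    sel <- select_span(x, y)
    grid <- seq(0.05, 0.95, length.out = 91)
    grid_aicc <- vapply(grid, function(s) {
      tryCatch(loess_aicc(loess_tricube(x, y, s)), error = function(e) Inf)
    }, numeric(1))
    expect_lte(loess_aicc(sel), min(grid_aicc) + 1e-12)
  }
})

test_that("span selection is exact on linear data and errors when data are too few", {
  x <- seq(0, 10, length.out = 30)
  y <- 1 - 0.07 * x
  sel <- select_span(x, y, degree = 1)
  expect_lt(max(abs(sel$fitted - y)), 1e-8)

  expect_error(select_span(seq_len(4), runif(4), degree = 2),
               class = "survcloak_error_selection")
})

test_that("selection agrees with stats::loess at matched window sizes", {
  # same window size q, tricube weights and local-linear fit: the exact
  # "direct" surface of the reference implementation should coincide
  withr::local_seed(41)
  x <- sort(runif(40, 0, 10))
  y <- sin(x / 2) + rnorm(40, sd = 0.1)
  ours <- loess_tricube(x, y, span = 0.5, degree = 1)
  ref <- stats::loess(y ~ x, span = 0.5, degree = 1, family = "gaussian",
                      surface = "direct")
  expect_equal(ours$fitted, unname(stats::fitted(ref)), tolerance = 1e-6)
})
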