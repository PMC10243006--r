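test_that("zero noise is the identity and y-only noise leaves times untouched", {
  st <- tibble::tibble(time = c(1, 3, 4, 7, 9), surv = c(1, 0.8, 0.6, 0.6, 0.2))
  expect_equal(anonymize_probabilistic(st, noise_pct = 0, axes = c("x", "y"), seed = 1),
               st)
  out <- anonymize_probabilistic(st, noise_pct = 10, axes = "y", seed = 4)
  expect_identical(out$time, st$time)
  expect_false(identical(out$surv, st$surv))
})

test_that("noised output is reproducible from the seed and matches the repair oracle", {
  st <- tibble::tibble(time = c(2, 4, 6, 8, 10), surv = c(1, 0.75, 0.5, 0.4, 0.1))
  a <- anonymize_probabilistic(st, noise_pct = 5, axes = c("x", "y"), seed = 99)
  b <- anonymize_probabilistic(st, noise_pct = 5, axes = c("x", "y"), seed = 99)
  expect_identical(a, b)
  c <- anonymize_probabilistic(st, noise_pct = 5, axes = c("x", "y"), seed = 100)
  expect_false(identical(a, c))

  # independent reconstruction: same draws, then isotone repair
  oracle <- withr::with_seed(99L, {
    x <- st$time * (1 + 0.05 * rnorm(5))
    y <- st$surv * (1 + 0.05 * rnorm(5))
    x <- sort(pmax(x, 0))
    for (i in 2:5) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + max(diff(range(x)), 1) * 1e-9
    list(x = x, y = pmin(pmax(cummin(y), 0), 1))
  })
  expect_equal(a$time, oracle$x)
  expect_equal(a$surv, oracle$y)
})

test_that("repaired output is always a valid staircase sample", {
  withr::local_seed(123)
  for (rep in 1:50) {
    st <- random_staircase()
    out <- anonymize_probabilistic(st, noise_pct = runif(1, 0, 20),
                                   axes = sample(list("x", "y", c("x", "y")), 1)[[1]],
                                   seed = sample.int(1e6, 1))
    expect_true(all(diff(out$time) > 0))
    expect_true(all(diff(out$surv) <= 0))
    expect_true(all(out$surv >= 0 & out$surv <= 1))
  }
})

test_that("unsorted input is rejected", {
  bad <- tibble::tibble(time = c(3, 1, 2), surv = c(1, 0.5, 0.2))
  expect_error(anonymize_probabilistic(bad, 5, seed = 1),
               class = "survcloak_error_validation")
  falling <- tibble::tibble(time = 1:3, surv = c(0.2, 0.5, 0.4))
  expect_error(anonymize_probabilistic(falling, 5, seed = 1),
               class = "survcloak_error_validation")
})

test_that("kNN centroids: k = 1 identity, k = n global collapse", {
  st <- random_staircase(12)
  expect_equal(anonymize_deterministic(st, k = 1), st)
  all_centroid <- anonymize_deterministic(st, k = 12)
  expect_true(all(abs(all_centroid$time - mean(st$time)) < 1e-12))
  expect_true(all(abs(all_centroid$surv - mean(st$surv)) < 1e-12))
  expect_error(anonymize_deterministic(st, k = 0), class = "survcloak_error_validation")
  expect_error(anonymize_deterministic(st, k = 13), class = "survcloak_error_validation")
})

test_that("collinear four-point configuration matches the hand-worked centroids", {
  pts <- tibble::tibble(time = c(1, 2, 3, 4), surv = rep(0.5, 4))
  out <- anonymize_deterministic(pts, k = 2)
  # endpoints move halfway toward the inner neighbour; interior points pair
  # with their nearest neighbour, distance ties broken by lower index
  expect_equal(out$time, c(1.5, 1.5, 2.5, 3.5))
  expect_equal(out$surv, rep(0.5, 4))
})

test_that("centroid replacement agrees with an exhaustive pairwise-distance oracle", {
  withr::local_seed(55)
  for (rep in 1:10) {
    st <- random_staircase(9)
    k <- sample(2:9, 1)
    out <- anonymize_deterministic(st, k = k)
    xy <- cbind(st$time, st$surv)
    for (i in seq_len(9)) {
      d <- sqrt(colSums((t(xy) - xy[i, ])^2))
      nb <- order(d, seq_len(9))[seq_len(k)]
      expect_equal(unlist(out[i, ]), colMeans(xy[nb, , drop = FALSE]),
                   ignore_attr = TRUE)
    }
    # centroids are convex combinations: the cloud never expands beyond the
    # input range on either axis, and the pull is towards the centre of mass
    expect_gte(min(out$time), min(st$time))
    expect_lte(max(out$time), max(st$time))
    expect_gte(min(out$surv), min(st$surv))
    expect_lte(max(out$surv), max(st$surv))
    ctr <- c(mean(st$time), mean(st$surv))
    expect_lte(max(sqrt((out$time - ctr[1])^2 + (out$surv - ctr[2])^2)),
               max(sqrt((st$time - ctr[1])^2 + (st$surv - ctr[2])^2)) + 1e-12)
  }
})
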