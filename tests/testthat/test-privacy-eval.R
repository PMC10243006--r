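test_that("singleton steps are identified from raw event counts", {
  five <- fit_km(data.frame(time = c(1, 2, 3, 4, 5), event = rep(1, 5)))
  expect_equal(step_identifiability(five), c(1, 2, 3, 4, 5))

  tied <- fit_km(data.frame(time = rep(4, 6), event = rep(1, 6)))
  expect_length(step_identifiability(tied), 0)

  withr::local_seed(19)
  for (rep in 1:20) {
    d <- random_dataset()
    km <- fit_km(d)
    oracle <- with(d, sapply(sort(unique(time)), function(t) sum(time == t & event == 1)))
    expect_equal(step_identifiability(km), sort(unique(d$time))[oracle == 1])
  }

  cv <- privacy_curve(simulate_survival(30, seed = 1), method = "loess")
  expect_error(step_identifiability(cv), class = "survcloak_error_validation")
})

test_that("inflection detection finds constructed change points and nothing on lines", {
  x <- 0:10
  expect_length(detect_inflections(data.frame(time = x, surv = 1 - 0.05 * x)), 0)

  knee <- ifelse(x <= 5, 1 - 0.01 * x, 1 - 0.05 - 0.06 * (x - 5))
  expect_equal(detect_inflections(data.frame(time = x, surv = knee)), 5)

  expect_error(detect_inflections(data.frame(time = 1:4, surv = rep(1, 4))),
               class = "survcloak_error_validation")

  # brute-force scan oracle on a noisy smooth curve
  withr::local_seed(23)
  t <- seq(0, 20, length.out = 60)
  y <- exp(-t / 6) + rnorm(60, sd = 0.01)
  y <- rev(sort(y))  # keep it a staircase-like decreasing sample
  got <- detect_inflections(data.frame(time = t, surv = y), sensitivity = 2)
  d2 <- diff(diff(y) / diff(t))
  thr <- max(2 * median(abs(d2)), 1e-12 * max(diff(range(y)), 1))
  exp_hits <- numeric(0); prev <- 0
  for (j in seq_along(d2)) {
    if (abs(d2[j]) > thr) {
      s <- sign(d2[j])
      if (s != prev) exp_hits <- c(exp_hits, t[j + 1])
      prev <- s
    }
  }
  expect_equal(got, exp_hits)
})

test_that("leave-one-out deltas vanish for identical curves and match a raw oracle", {
  d <- simulate_survival(40, seed = 31)
  # removing then re-adding: compare a curve with itself
  cv <- privacy_curve(d, method = "loess")
  self_delta <- survcloak:::compute_delta(cv, cv)
  expect_equal(self_delta$sup_norm, 0)
  expect_equal(self_delta$l1, 0)

  # raw (unsafe) LOO: sup-norm equals brute-force max KM difference
  idx <- 7L
  delta <- leave_one_out_delta(d, idx, method = "none",
                               policy = guard_policy(min_subjects = 5))
  km_full <- fit_km(d)
  km_red <- fit_km(d[-idx, ])
  dense <- seq(0, max(d$time) + 1, length.out = 20000)
  brute <- max(abs(eval_curve(km_full, dense) - eval_curve(km_red, dense)))
  expect_equal(delta$sup_norm, brute, tolerance = 1e-9)
  expect_gte(delta$sup_norm, delta$l1)
  expect_equal(delta$removed_time, d$time[idx])

  expect_error(leave_one_out_delta(d, 0), class = "survcloak_error_validation")
  expect_error(leave_one_out_delta(d, 41), class = "survcloak_error_validation")
})

test_that("raw LOO localisation recovers a singleton event time exactly", {
  withr::local_seed(37)
  for (rep in 1:25) {
    d <- simulate_survival(sample(15:40, 1), seed = 500 + rep)
    km <- fit_km(d)
    singles <- step_identifiability(km)
    if (length(singles) == 0) next
    t_star <- sample(singles, 1)
    idx <- which(d$time == t_star & d$event == 1)[1]
    delta <- leave_one_out_delta(d, idx, method = "none",
                                 policy = guard_policy(min_subjects = 5, min_events = 2))
    expect_equal(delta$raw_new_drop_time, t_star)
  }
})

test_that("smoothed release hides the removed subject's event time", {
  d <- veteran_like_fixture()
  singles <- step_identifiability(fit_km(d))
  idx <- which(d$time == singles[length(singles) %/% 2] & d$event == 1)[1]
  delta <- leave_one_out_delta(d, idx, method = "loess")
  # the raw curves localise exactly; the smoothed curve's inflections are
  # a much coarser signal than the dense raw grid
  expect_equal(delta$raw_new_drop_time, d$time[idx])
  expect_lt(length(delta$inflections_full), nrow(d) / 4)
  td <- tidy(delta)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$sup_norm, delta$sup_norm)
})

test_that("ablation studies are reproducible and honour the target size", {
  d <- veteran_like_fixture()
  rep1 <- ablation_study(d, target_n = 50, seed = 17)
  rep2 <- ablation_study(d, target_n = 50, seed = 17)
  expect_identical(rep1$indices, rep2$indices)
  expect_identical(rep1$curve_subsample, rep2$curve_subsample)
  expect_identical(rep1$curve_reduced, rep2$curve_reduced)
  expect_equal(attr(rep1$curve_subsample, "n_input"), 50L)
  expect_equal(attr(rep1$curve_reduced, "n_input"), 49L)

  # degenerate subsample: target_n = n keeps every subject
  full <- ablation_study(d, target_n = nrow(d), seed = 3)
  expect_setequal(full$indices, seq_len(nrow(d)))

  expect_error(ablation_study(d, target_n = 500, seed = 1),
               class = "survcloak_error_validation")
})
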