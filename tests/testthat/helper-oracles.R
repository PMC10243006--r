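# Independent oracles and random-input generators shared across tests.

# Brute-force product-limit oracle: enumerate the risk set at each distinct
# time directly from the records and multiply the factors. Ties between
# events and censorings at one time: events first, censored subjects stay
# in that time's risk set.
km_oracle <- function(time, event) {
  times <- sort(unique(time))
  surv <- 1
  out <- data.frame(time = times, n_risk = NA_real_, n_event = NA_real_,
                    n_censor = NA_real_, surv = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    c <- sum(time == t & event == 0)
    surv <- surv * (1 - d / at_risk)
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$n_censor[i] <- c
    out$surv[i] <- surv
  }
  out
}

random_dataset <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:20, 1)
  data.frame(
    # discrete times so ties occur often
    time = sample(1:8, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE),
    event = rbinom(n, 1, 0.7)
  )
}

# Weighted least squares at a single target point, built independently of
# the package's hat-row algebra: explicit tricube weights over the
# q = ceiling(span * n) nearest neighbours, then stats::lm.wfit on the
# centred polynomial basis.
wls_oracle_at <- function(x, y, span, degree, i) {
  n <- length(x)
  q <- as.integer(ceiling(span * n - 1e-9))
  d <- abs(x - x[i])
  idx <- order(d)[seq_len(q)]
  dmax <- d[idx[q]]
  u <- d[idx] / dmax
  w <- (1 - pmin(u, 1)^3)^3
  z <- x[idx] - x[i]
  X <- if (degree == 1) cbind(1, z) else cbind(1, z, z^2)
  fit <- stats::lm.wfit(X, y[idx], w)
  unname(fit$coefficients[1])
}

# Hat matrix reconstructed by probing the (linear) smoother with unit
# response vectors; independent of the internal hat-diagonal bookkeeping.
hat_matrix_probe <- function(x, span, degree) {
  n <- length(x)
  L <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n)
    e[j] <- 1
    L[, j] <- loess_tricube(x, e, span = span, degree = degree)$fitted
  }
  L
}

# Random survival staircase sample (strictly increasing times,
# non-increasing surv in [0, 1]) for anonymisation tests.
random_staircase <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:40, 1)
  tibble::tibble(
    time = sort(runif(n, 0, 100)) + seq_len(n) * 1e-6,
    surv = cummin(runif(n))
  )
}
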