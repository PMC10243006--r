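#' Local polynomial regression with tricube weights
#'
#' Fits a LOESS smoother of the kind used to blur survival-curve steps: at
#' each target point x_i a weighted least-squares polynomial of degree 1 or
#' 2 is fitted over the q = ceiling(span * n) nearest neighbours of x_i,
#' with tricube weights w(u) = (1 - |u|^3)^3 on u = |x - x_i| / d_max,
#' where d_max is the distance to the furthest point in the window (points
#' at u = 1 get weight zero). The smoother is linear in `y`, so a hat
#' matrix L with `fitted = L y` exists; its trace is the smoother's
#' effective degrees of freedom and feeds the AICc span criterion
#' ([loess_aicc()]).
#'
#' Distances are taken on the raw time axis (the predictor is univariate
#' time, so no standardisation is applied).
#'
#' @param x Predictor values, sorted non-decreasing (curve times).
#' @param y Responses (survival proportions), same length as `x`.
#' @param span Fraction of points in each local window, in (0, 1].
#' @param degree Local polynomial degree, 1 (default) or 2.
#' @param keep_hat Also return the full n x n hat matrix (used by
#'   diagnostics and tests; the diagonal is always kept).
#' @return A `loess_tricube` object: a list with `x`, `y`, `fitted`,
#'   `residuals`, `span`, `degree`, `q`, `hat_trace`, `hat_diag`, `rss`,
#'   `sigma2` (residual variance on n - trace denominator) and `n`.
#' @export
loess_tricube <- function(x, y, span, degree = 1, keep_hat = FALSE) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_validation("`x` and `y` must be numeric vectors of equal length.")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop_validation("`x` and `y` must be finite.")
  }
  if (is.unsorted(x)) stop_validation("`x` must be sorted non-decreasing.")
  if (!degree %in% c(1, 2)) stop_validation("`degree` must be 1 or 2.")
  n <- length(x)
  if (n < degree + 2) {
    stop_validation(sprintf("Need at least %d points for degree %d.", degree + 2, degree))
  }
  span <- check_number(span, "span")
  if (span <= 0 || span > 1) stop_validation("`span` must be in (0, 1].")
  q <- window_size(span, n)
  if (q < degree + 1) {
    stop_validation(sprintf(
      "span = %.4g gives a window of %d points; degree %d needs at least %d. Increase the span.",
      span, q, degree, degree + 1
    ))
  }

  fitted <- numeric(n)
  hat_diag <- numeric(n)
  hat <- if (keep_hat) matrix(0, n, n) else NULL
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(q)]  # stable: distance ties broken by index
    dmax <- d[idx[q]]
    if (dmax <= 0) {
      abort(sprintf("Local window at x[%d] = %g is degenerate: all x equal.", i, x[i]),
            class = "survcloak_error_rank")
    }
    u <- d[idx] / dmax
    w <- (1 - pmin(u, 1)^3)^3
    z <- x[idx] - x[i]
    li <- local_hat_row(z, w, degree, i, x[i])
    fitted[i] <- sum(li * y[idx])
    pos <- match(i, idx)
    hat_diag[i] <- if (is.na(pos)) 0 else li[pos]
    if (keep_hat) hat[i, idx] <- li
  }
  residuals <- y - fitted
  rss <- sum(residuals^2)
  hat_trace <- sum(hat_diag)
  df_resid <- n - hat_trace
  structure(
    list(
      x = x, y = y, fitted = fitted, residuals = residuals,
      span = span, degree = as.integer(degree), q = q,
      hat_trace = hat_trace, hat_diag = hat_diag, hat = hat,
      rss = rss,
      sigma2 = if (df_resid > sqrt(.Machine$double.eps)) rss / df_resid else 0,
      n = n
    ),
    class = "loess_tricube"
  )
}

# q = ceiling(span * n), with a tolerance so that span = q/n (exact in
# rationals) does not tip over to q + 1 through floating-point noise.
window_size <- function(span, n) {
  as.integer(ceiling(span * n - 1e-9))
}

# Row of the hat matrix for one local fit: l = e1' (X'WX)^{-1} X'W with the
# polynomial basis centred at the target point, so the intercept is the
# fitted value there.
local_hat_row <- function(z, w, degree, i, xi) {
  if (degree == 1) {
    sw <- sum(w)
    swz <- sum(w * z)
    swzz <- sum(w * z^2)
    det <- sw * swzz - swz^2
    if (!is.finite(det) || det <= .Machine$double.eps * max(sw * swzz, 1)) {
      abort(sprintf("Weighted design at x[%d] = %g is numerically rank deficient.", i, xi),
            class = "survcloak_error_rank")
    }
    return(w * (swzz - swz * z) / det)
  }
  X <- cbind(1, z, z^2)
  XtW <- t(X * w)
  A <- XtW %*% X
  sol <- tryCatch(solve(A, XtW), error = function(e) NULL)
  if (is.null(sol)) {
    abort(sprintf("Weighted design at x[%d] = %g is numerically rank deficient.", i, xi),
          class = "survcloak_error_rank")
  }
  sol[1L, ]
}

#' Corrected Akaike information criterion for a LOESS fit
#'
#' The small-sample AIC variant for linear smoothers:
#' AICc = log(sigma_hat^2) + 1 + 2 (nu + 1) / (n - nu - 2), with
#' sigma_hat^2 = RSS / n and nu the hat-matrix trace. Minimising it over
#' the span trades residual error against effective degrees of freedom and
#' behaves well on the modest point counts of a single survival curve.
#' A perfect fit is guarded by flooring sigma_hat^2 at 1e-300 before the
#' log, so exactly-linear inputs yield a very negative value rather than
#' an error.
#'
#' @param fit A `loess_tricube` object.
#' @return The AICc value (smaller is better).
#' @export
loess_aicc <- function(fit) {
  if (!inherits(fit, "loess_tricube")) {
    stop_validation("`fit` must be a `loess_tricube` object.")
  }
  nu <- fit$hat_trace
  n <- fit$n
  if (n - nu - 2 <= 0) {
    abort(sprintf(
      "AICc undefined: n - trace - 2 = %.3g <= 0 (span %.3g too small for n = %d).",
      n - nu - 2, fit$span, n
    ), class = c("survcloak_error_degenerate", "survcloak_error_validation"))
  }
  sigma2_ml <- max(fit$rss / n, 1e-300)
  log(sigma2_ml) + 1 + 2 * (nu + 1) / (n - nu - 2)
}

#' Automated span selection by AICc
#'
#' Chooses the smoothing span that minimises [loess_aicc()]. Because the
#' fit depends on the span only through the integer window size
#' q = ceiling(span * n), the criterion is piecewise constant in the span;
#' the selector therefore enumerates every achievable window size in the
#' search interval and minimises exactly, which is deterministic and at
#' least as good as any grid or line search over the same interval.
#' Ties are broken towards the larger window (more smoothing).
#'
#' @param x,y As in [loess_tricube()].
#' @param degree Local polynomial degree, 1 or 2.
#' @param interval Span search interval, default `c(0.05, 0.95)`.
#' @return The selected `loess_tricube` fit, with the candidate table
#'   (`q`, `span`, `aicc`) attached as `fit$selection`.
#' @export
select_span <- function(x, y, degree = 1, interval = c(0.05, 0.95)) {
  if (!is.numeric(interval) || length(interval) != 2L || anyNA(interval) ||
      interval[1] <= 0 || interval[2] > 1 || interval[1] > interval[2]) {
    stop_validation("`interval` must be an increasing pair within (0, 1].")
  }
  n <- length(x)
  if (n < degree + 2) {
    abort(sprintf("Too few points (n = %d) to select a span for degree %d.", n, degree),
          class = c("survcloak_error_selection", "survcloak_error_validation"))
  }
  q_lo <- max(window_size(interval[1], n), 1L)
  q_hi <- window_size(interval[2], n)
  qs <- seq.int(q_lo, q_hi)
  # representative span for window size q: the largest span in the interval
  # that still yields q points
  spans <- pmin(qs / n, interval[2])
  aiccs <- rep(Inf, length(qs))
  fits <- vector("list", length(qs))
  for (j in seq_along(qs)) {
    fit <- tryCatch(loess_tricube(x, y, span = spans[j], degree = degree),
                    error = function(e) NULL)
    if (is.null(fit)) next
    val <- tryCatch(loess_aicc(fit), error = function(e) Inf)
    aiccs[j] <- val
    fits[[j]] <- fit
  }
  if (all(!is.finite(aiccs) | is.na(aiccs)) || all(aiccs == Inf)) {
    abort(sprintf(
      "No span in [%.3g, %.3g] yields a valid fit for n = %d, degree %d; widen the interval or supply more data.",
      interval[1], interval[2], n, degree
    ), class = c("survcloak_error_selection", "survcloak_error_validation"))
  }
  best <- max(which(aiccs == min(aiccs)))  # ties -> larger window
  fit <- fits[[best]]
  fit$selection <- tibble::tibble(q = qs, span = spans, aicc = aiccs)
  fit
}

#' @method print loess_tricube
#' @export
print.loess_tricube <- function(x, ...) {
  cat(sprintf(
    "Tricube LOESS fit: n = %d, span = %.4g (q = %d), degree = %d\n",
    x$n, x$span, x$q, x$degree
  ))
  cat(sprintf("  hat trace (eff. df) = %.3f, residual SS = %.4g\n",
              x$hat_trace, x$rss))
  invisible(x)
}

#' @method tidy loess_tricube
#' @export
tidy.loess_tricube <- function(x, ...) {
  tibble::tibble(x = x$x, y = x$y, .fitted = x$fitted, .resid = x$residuals)
}

#' @method glance loess_tricube
#' @export
glance.loess_tricube <- function(x, ...) {
  aicc <- if (x$n - x$hat_trace - 2 > 0) loess_aicc(x) else NA_real_
  tibble::tibble(
    n = x$n, span = x$span, degree = x$degree, q = x$q,
    hat_trace = x$hat_trace, sigma2 = x$sigma2, rss = x$rss, aicc = aicc
  )
}

#' @method autoplot loess_tricube
#' @export
autoplot.loess_tricube <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "#2166ac") +
    ggplot2::labs(x = "x", y = "y")
}
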