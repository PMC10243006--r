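#' Probabilistic anonymisation of curve points
#'
#' Perturbs curve points with seeded multiplicative noise before release:
#' each selected coordinate v becomes v * (1 + pct/100 * e) with e drawn
#' i.i.d. standard normal. Noise on the time axis blurs when events
#' occurred; noise on the survival axis blurs how many subjects drop at a
#' time. A monotonicity repair then restores the survival-staircase shape:
#' times are clamped at zero, sorted, and residual ties broken by a minimal
#' offset so they increase strictly; survival values are projected by a
#' running minimum and clipped to [0, 1]. Deterministic for a given seed.
#'
#' When both axes are selected the time-axis draws are taken first, then
#' the survival-axis draws, so single-axis output is reproducible from the
#' same seed.
#'
#' @param points Data frame with `time` (strictly increasing) and `surv`
#'   (non-increasing) — a sampled survival staircase.
#' @param noise_pct Noise magnitude as a percentage of each value, >= 0.
#' @param axes Axes to perturb: subset of `c("x", "y")` (x = time,
#'   y = survival). Default `"y"`.
#' @param seed Integer seed controlling the noise draws.
#' @return A tibble with repaired `time` and `surv`.
#' @export
anonymize_probabilistic <- function(points, noise_pct, axes = "y", seed = 1L) {
  pts <- check_point_cloud(points)
  noise_pct <- check_number(noise_pct, "noise_pct", min = 0)
  axes <- unique(match.arg(axes, c("x", "y"), several.ok = TRUE))
  if (length(axes) == 0L) stop_validation("`axes` must contain \"x\" and/or \"y\".")
  n <- nrow(pts)
  if (is.unsorted(pts$time, strictly = TRUE)) {
    stop_validation("`points$time` must be strictly increasing.")
  }
  if (is.unsorted(rev(pts$surv))) {
    stop_validation("`points$surv` must be non-increasing.")
  }
  x <- pts$time
  y <- pts$surv
  with_seed_or_global(seed, {
    if ("x" %in% axes) x <- x * (1 + noise_pct / 100 * rnorm(n))
    if ("y" %in% axes) y <- y * (1 + noise_pct / 100 * rnorm(n))
  })
  tibble::tibble(
    time = repair_times(x),
    surv = pmin(pmax(cummin(y), 0), 1)
  )
}

# Clamp at zero, sort ascending, then break residual ties with a minimal
# offset so times are strictly increasing.
repair_times <- function(x) {
  x <- sort(pmax(x, 0))
  eps <- max(diff(range(x)), 1) * 1e-9
  for (i in seq_along(x)[-1]) {
    if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  }
  x
}

#' Deterministic anonymisation by k-nearest-neighbour centroids
#'
#' Replaces every curve point by the coordinate-wise mean of its k nearest
#' neighbours in the (time, surv) plane (Euclidean distance; the point
#' itself counts among its neighbours by default, so k = 1 is the
#' identity). With k = n every point collapses to the global centroid —
#' the "pull towards the centre of mass" that makes this mechanism
#' ill-suited to skewed survival data. Distance ties are broken by lower
#' point index, so the result is deterministic.
#'
#' @param points Data frame with `time` and `surv` columns.
#' @param k Neighbourhood size, between 1 and `nrow(points)`.
#' @param include_self Count the query point among its own neighbours
#'   (default `TRUE`).
#' @return A tibble with the centroid-replaced `time` and `surv`.
#' @export
anonymize_deterministic <- function(points, k, include_self = TRUE) {
  pts <- check_point_cloud(points)
  n <- nrow(pts)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k)) {
    stop_validation("`k` must be a single integer.")
  }
  k <- as.integer(k)
  limit <- if (include_self) n else n - 1L
  if (k < 1L || k > limit) {
    stop_validation(sprintf("`k` must be between 1 and %d.", limit))
  }
  xy <- cbind(pts$time, pts$surv)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    ord <- order(d)  # stable: ties broken by lower index
    if (!include_self) ord <- ord[ord != i]
    nb <- ord[seq_len(k)]
    out[i, ] <- colMeans(xy[nb, , drop = FALSE])
  }
  tibble::tibble(time = out[, 1], surv = out[, 2])
}

check_point_cloud <- function(points) {
  if (!is.data.frame(points) || nrow(points) == 0L) {
    stop_validation("`points` must be a non-empty data frame.")
  }
  if (!all(c("time", "surv") %in% names(points))) {
    stop_validation("`points` must have `time` and `surv` columns.")
  }
  if (!all(is.finite(points$time)) || !all(is.finite(points$surv))) {
    stop_validation("`points` coordinates must be finite.")
  }
  tibble::tibble(time = as.numeric(points$time), surv = as.numeric(points$surv))
}
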