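#' Times attributable to a single subject
#'
#' A raw survival curve is disclosive where a step corresponds to a group
#' of size one: an adversary who can place an individual in the study can
#' attribute that event — and its time — to them. This returns the times
#' at which exactly one event occurs. Identifiability is defined on raw
#' counts, so smoothed/anonymised curves are rejected.
#'
#' @param curve A `km_curve` from [fit_km()].
#' @return Numeric vector of singleton-step times.
#' @export
step_identifiability <- function(curve) {
  if (is_privacy_curve(curve)) {
    stop_validation(
      "`curve` is an anonymised release; identifiability is defined on the raw curve's event counts."
    )
  }
  if (!is_km_curve(curve)) stop_validation("`curve` must be a `km_curve`.")
  curve$time[curve$n_event == 1L]
}

#' Detect inflection points of a smoothed curve
#'
#' Flags times where the discrete second difference of the survival values
#' changes sign with magnitude above `sensitivity` times the median
#' absolute second difference. Slopes are divided differences, so uneven
#' time grids are handled. An exactly linear sequence yields no
#' inflections (a small absolute floor absorbs floating-point noise).
#' Deterministic.
#'
#' @param points A data frame with `time` and `surv` (>= 5 rows), e.g. a
#'   smoothed `privacy_curve`.
#' @param sensitivity Non-negative multiplier on the median absolute
#'   second difference (default 3: only slope changes several times the
#'   curve's typical second-difference magnitude count as inflections,
#'   approximating what a reader resolves on a plotted curve).
#' @return Numeric vector of inflection times.
#' @export
detect_inflections <- function(points, sensitivity = 3) {
  pts <- check_point_cloud(points)
  if (nrow(pts) < 5L) stop_validation("Need at least 5 points to detect inflections.")
  sensitivity <- check_number(sensitivity, "sensitivity", min = 0)
  x <- pts$time
  y <- pts$surv
  if (any(diff(x) <= 0)) stop_validation("`points$time` must be strictly increasing.")
  slope <- diff(y) / diff(x)
  d2 <- diff(slope)              # second difference at interior points
  t_int <- x[seq(2L, length(x) - 1L)]
  if (length(d2) < 2L) return(numeric(0))
  floor_abs <- 1e-12 * max(diff(range(y)), 1)
  threshold <- max(sensitivity * median(abs(d2)), floor_abs)
  # A change point is a salient second difference (above threshold) whose
  # sign differs from the previous salient one; the onset of salient
  # curvature counts as the first change point. Sub-threshold wiggle
  # between two salient values of the same sign is ignored.
  hits <- numeric(0)
  prev_sign <- 0
  for (j in seq_along(d2)) {
    if (abs(d2[j]) > threshold) {
      s <- sign(d2[j])
      if (s != prev_sign) hits <- c(hits, t_int[j])
      prev_sign <- s
    }
  }
  hits
}

# Earliest time that is a drop (event time) of the full raw curve but not
# of the reduced one -- the "new drop" a leave-one-out adversary looks
# for. For a removed subject whose event time is a singleton, this equals
# that subject's event time exactly.
raw_new_drop_time <- function(full_km, reduced_km) {
  full_drops <- full_km$time[full_km$n_event > 0L]
  red_drops <- reduced_km$time[reduced_km$n_event > 0L]
  new_drops <- setdiff(full_drops, red_drops)
  if (length(new_drops) == 0L) NA_real_ else min(new_drops)
}

compute_delta <- function(full, reduced, sensitivity = 3) {
  grid <- sort(union(full$time, reduced$time))
  ef <- eval_curve(full, grid)
  er <- eval_curve(reduced, grid)
  diffs <- abs(ef - er)
  smoothed <- curve_method(full) != "none"
  list(
    sup_norm = max(diffs),
    l1 = mean(diffs),
    inflections_full = if (smoothed && nrow(full) >= 5L)
      detect_inflections(full, sensitivity) else numeric(0),
    inflections_reduced = if (smoothed && nrow(reduced) >= 5L)
      detect_inflections(reduced, sensitivity) else numeric(0),
    grid_n = length(grid)
  )
}

#' Leave-one-out comparison of released curves
#'
#' Implements the adversary model against which the anonymisation is
#' evaluated: compare the curve released for the full dataset with the
#' curve released after one subject is withheld (same method, same seed),
#' and ask how well the withheld subject's event time can be localised.
#' Both curves are evaluated on the union of their time grids; the
#' sup-norm and mean absolute difference are reported together with the
#' detected inflection times of each smoothed curve, the raw-curve
#' "new drop" time (the disclosure the smoothing must defeat) and the
#' withheld subject's actual time and status.
#'
#' @param data Subject table with `time` and `event` columns.
#' @param index Row index of the subject to withhold.
#' @param method,... Release method and options, passed to
#'   [privacy_curve()]. Raw (`method = "none"`) comparisons are permitted
#'   here: the curves are evaluation artefacts, not releases.
#' @param sensitivity Inflection-detector sensitivity, see
#'   [detect_inflections()].
#' @param policy Disclosure policy both datasets must pass.
#' @return A `curve_delta` object (list) with fields `sup_norm`, `l1`,
#'   `inflections_full`, `inflections_reduced`, `raw_new_drop_time`,
#'   `removed_time`, `removed_event`, `method`, `grid_n`.
#' @export
leave_one_out_delta <- function(data, index, method = "loess", ...,
                                sensitivity = 3, policy = guard_policy()) {
  data <- validate_survival(data)
  n <- nrow(data)
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index != round(index) || index < 1 || index > n) {
    stop_validation(sprintf("`index` must be an integer in [1, %d].", n))
  }
  index <- as.integer(index)
  reduced_data <- data[-index, , drop = FALSE]
  attr(reduced_data, "site") <- site_label(data)
  full <- privacy_curve(data, method = method, ..., policy = policy,
                        allow_raw = TRUE)
  reduced <- privacy_curve(reduced_data, method = method, ..., policy = policy,
                           allow_raw = TRUE)
  delta <- compute_delta(full, reduced, sensitivity = sensitivity)
  structure(
    c(delta, list(
      raw_new_drop_time = raw_new_drop_time(fit_km(data), fit_km(reduced_data)),
      removed_time = data$time[index],
      removed_event = data$event[index],
      method = curve_method(full)
    )),
    class = "curve_delta"
  )
}

#' @method print curve_delta
#' @export
print.curve_delta <- function(x, ...) {
  cat(sprintf("Leave-one-out curve delta (method %s)\n", x$method))
  cat(sprintf("  sup-norm = %.4g, mean |diff| = %.4g over %d grid points\n",
              x$sup_norm, x$l1, x$grid_n))
  cat(sprintf("  removed subject: time %.4g, event %d\n",
              x$removed_time, as.integer(x$removed_event)))
  cat(sprintf("  raw new-drop time: %s\n", format(x$raw_new_drop_time)))
  if (length(x$inflections_full)) {
    cat("  inflections (full curve):", paste(signif(x$inflections_full, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy curve_delta
#' @export
tidy.curve_delta <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    sup_norm = x$sup_norm,
    l1 = x$l1,
    removed_time = x$removed_time,
    removed_event = x$removed_event,
    raw_new_drop_time = x$raw_new_drop_time,
    inflections_full = list(x$inflections_full),
    inflections_reduced = list(x$inflections_reduced)
  )
}

#' Random ablation study
#'
#' Mirrors the robustness probe of reducing a dataset to a random subset,
#' releasing its curve, then removing one further randomly chosen subject
#' and releasing again: a direct view of how much one subject can move the
#' released curve at a given size. Fully reproducible under `seed`.
#'
#' @param data Subject table.
#' @param target_n Subsample size (<= `nrow(data)`).
#' @param seed Integer seed for the subsample and the extra removal.
#' @param method,... Release method and options for [privacy_curve()].
#' @param sensitivity Inflection-detector sensitivity.
#' @param policy Disclosure policy.
#' @return An `ablation_report`: list with the subsample indices, the two
#'   released curves (`curve_subsample` with `target_n` subjects,
#'   `curve_reduced` with one fewer), the removed subject's time/event and
#'   their `curve_delta`.
#' @export
ablation_study <- function(data, target_n, seed = 1L, method = "loess", ...,
                           sensitivity = 3, policy = guard_policy()) {
  data <- validate_survival(data)
  n <- nrow(data)
  target_n <- check_number(target_n, "target_n", min = 1, max = n)
  if (target_n != round(target_n)) stop_validation("`target_n` must be an integer.")
  target_n <- as.integer(target_n)
  draws <- with_seed_or_global(seed, {
    idx <- sample.int(n, target_n)
    list(idx = idx, drop = sample.int(target_n, 1L))
  })
  sub <- data[draws$idx, , drop = FALSE]
  attr(sub, "site") <- paste0(site_label(data), "_n", target_n)
  sub2 <- sub[-draws$drop, , drop = FALSE]
  attr(sub2, "site") <- paste0(site_label(data), "_n", target_n - 1L)
  curve_sub <- privacy_curve(sub, method = method, ..., policy = policy,
                             allow_raw = TRUE)
  curve_red <- privacy_curve(sub2, method = method, ..., policy = policy,
                             allow_raw = TRUE)
  delta <- compute_delta(curve_sub, curve_red, sensitivity = sensitivity)
  structure(
    list(
      target_n = target_n,
      indices = draws$idx,
      removed_index = draws$idx[draws$drop],
      removed_time = sub$time[draws$drop],
      removed_event = sub$event[draws$drop],
      curve_subsample = curve_sub,
      curve_reduced = curve_red,
      delta = structure(c(delta, list(
        raw_new_drop_time = raw_new_drop_time(fit_km(sub), fit_km(sub2)),
        removed_time = sub$time[draws$drop],
        removed_event = sub$event[draws$drop],
        method = curve_method(curve_sub)
      )), class = "curve_delta")
    ),
    class = "ablation_report"
  )
}

#' @method print ablation_report
#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf(
    "Ablation study: %d -> %d subjects (one further removal at time %.4g)\n",
    x$target_n, x$target_n - 1L, x$removed_time
  ))
  cat(sprintf("  released curves: %d and %d points; sup-norm delta %.4g\n",
              nrow(x$curve_subsample), nrow(x$curve_reduced), x$delta$sup_norm))
  invisible(x)
}
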