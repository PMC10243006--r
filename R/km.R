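#' Fit a Kaplan-Meier (product-limit) survival curve
#'
#' Estimates S(t) = Pr(T > t) for one dataset by the product-limit
#' recursion: at each distinct observed time t_i with d_i events among n_i
#' subjects at risk, S(t_i) = S(t_(i-1)) * (1 - d_i / n_i). Both event and
#' censoring-only times are listed, matching the grid that the smoothing
#' step operates on. Ties between events and censorings at the same time
#' follow the standard convention: events occur first, censored subjects
#' still count in that time's risk set.
#'
#' @param data Subject table with `time` and `event` columns (see
#'   [validate_survival()]).
#' @return A `km_curve`: a tibble with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, plus attributes `n_total` and `site`.
#' @examples
#' fit_km(data.frame(time = c(1, 2, 3, 3, 4), event = c(1, 0, 1, 1, 0)))
#' @export
fit_km <- function(data) {
  data <- validate_survival(data)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = data, conf.type = "none", se.fit = FALSE
  )
  out <- tibble::tibble(
    time = as.numeric(fit$time),
    n_risk = as.integer(fit$n.risk),
    n_event = as.integer(fit$n.event),
    n_censor = as.integer(fit$n.censor),
    surv = as.numeric(fit$surv)
  )
  new_km_curve(out, n_total = nrow(data), site = site_label(data))
}

new_km_curve <- function(points, n_total, site = "site") {
  structure(
    points,
    n_total = as.integer(n_total),
    site = site,
    class = c("km_curve", class(tibble::tibble()))
  )
}

is_km_curve <- function(x) inherits(x, "km_curve")

#' Evaluate a survival curve at arbitrary times
#'
#' Raw product-limit curves are right-continuous step functions: the value
#' at `t` is the `surv` at the largest listed time <= `t`, and 1 before the
#' first listed time. Smoothed/anonymised curves are no longer staircases,
#' so they are evaluated by linear interpolation between their points, with
#' constant extrapolation beyond the ends.
#'
#' @param curve A `km_curve` or `privacy_curve`.
#' @param t Vector of evaluation times, all >= 0.
#' @return Numeric vector of survival probabilities, one per `t`.
#' @export
eval_curve <- function(curve, t) {
  if (!is.data.frame(curve) || nrow(curve) == 0L) {
    stop_validation("`curve` must be a non-empty curve object.")
  }
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop_validation("Evaluation times `t` must be non-negative numbers.")
  }
  if (length(t) == 0L) return(numeric(0))
  x <- curve$time
  y <- curve$surv
  stepwise <- is_km_curve(curve) ||
    (is_privacy_curve(curve) && curve_method(curve) == "none")
  if (nrow(curve) == 1L) {
    if (stepwise) return(ifelse(t < x, 1, y))
    return(rep(y, length(t)))
  }
  if (stepwise) {
    approx(x, y, xout = t, method = "constant", f = 0,
           yleft = 1, yright = y[length(y)], ties = "ordered")$y
  } else {
    approx(x, y, xout = t, method = "linear", rule = 2, ties = "ordered")$y
  }
}

#' Staircase vertices (and optional censoring marks) for plotting
#'
#' Converts a raw curve into the vertex list of its step-function plot,
#' anchored at (0, 1). Censoring-mark coordinates — the glyphs conventional
#' survival plots draw at censoring times — are returned only when
#' explicitly requested: they reveal individual censoring times, which is
#' exactly what the privacy pipeline suppresses.
#'
#' @param curve A `km_curve`.
#' @param include_censor_marks Return censor-mark coordinates? Default
#'   `FALSE`.
#' @return A list with tibbles `vertices` (`time`, `surv`) and
#'   `censor_marks` (`time`, `surv`; empty unless requested).
#' @export
step_points <- function(curve, include_censor_marks = FALSE) {
  if (!is_km_curve(curve)) stop_validation("`curve` must be a `km_curve`.")
  if (nrow(curve) == 0L) stop_validation("`curve` is empty.")
  if (!is_flag(include_censor_marks)) {
    stop_validation("`include_censor_marks` must be TRUE or FALSE.")
  }
  vt <- c(0)
  vs <- c(1)
  prev <- 1
  for (i in seq_len(nrow(curve))) {
    s <- curve$surv[i]
    if (s != prev) {
      vt <- c(vt, curve$time[i], curve$time[i])
      vs <- c(vs, prev, s)
      prev <- s
    }
  }
  last_t <- curve$time[nrow(curve)]
  if (vt[length(vt)] < last_t) {
    vt <- c(vt, last_t)
    vs <- c(vs, prev)
  }
  marks <- tibble::tibble(time = numeric(0), surv = numeric(0))
  if (include_censor_marks) {
    cens <- curve$n_censor > 0
    marks <- tibble::tibble(time = curve$time[cens], surv = curve$surv[cens])
  }
  list(vertices = tibble::tibble(time = vt, surv = vs), censor_marks = marks)
}

#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) {
  tibble::as_tibble(unclass_curve(x))
}

#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  n_total <- attr(x, "n_total", exact = TRUE)
  below <- which(x$surv <= 0.5)
  tibble::tibble(
    n = as.integer(n_total),
    n_event = sum(x$n_event),
    n_censor = sum(x$n_censor),
    median_survival = if (length(below)) x$time[below[1L]] else NA_real_
  )
}

#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, include_censor_marks = FALSE, ...) {
  sp <- step_points(object, include_censor_marks = include_censor_marks)
  p <- ggplot2::ggplot(sp$vertices, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_line(colour = "black") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival proportion")
  if (include_censor_marks && nrow(sp$censor_marks) > 0) {
    p <- p + ggplot2::geom_point(data = sp$censor_marks, shape = 3)
  }
  p
}

unclass_curve <- function(x) {
  attr(x, "n_total") <- NULL
  attr(x, "site") <- NULL
  attr(x, "method") <- NULL
  attr(x, "params") <- NULL
  attr(x, "n_input") <- NULL
  attr(x, "censor_marks_suppressed") <- NULL
  class(x) <- class(tibble::tibble())
  x
}
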