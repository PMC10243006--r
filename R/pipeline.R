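#' Disclosure-control policy for curve release
#'
#' Minimum counts a dataset must meet before any curve — even an
#' anonymised one — leaves the site. The thresholds are conventions of
#' federated-analysis deployments, not statistical constants; tighten them
#' to taste.
#'
#' @param min_subjects Minimum subject count (default 10).
#' @param min_events Minimum number of observed events (default 5).
#' @return A `guard_policy` object.
#' @export
guard_policy <- function(min_subjects = 10, min_events = 5) {
  min_subjects <- check_number(min_subjects, "min_subjects", min = 1)
  min_events <- check_number(min_events, "min_events", min = 1)
  structure(
    list(min_subjects = as.integer(min_subjects), min_events = as.integer(min_events)),
    class = "guard_policy"
  )
}

#' Check a dataset against a disclosure-control policy
#'
#' The server-side gate of the federated workflow: an analysis request is
#' only honoured when the local dataset is large enough. The report names
#' the rule(s) that fired but never echoes data values.
#'
#' @param data Subject table with `time` and `event` columns.
#' @param policy A [guard_policy()].
#' @return A `guard_report`: list with `passed` (flag), `failed_rules`
#'   (character), `site`, and the policy.
#' @export
disclosure_guard <- function(data, policy = guard_policy()) {
  if (!inherits(policy, "guard_policy")) {
    stop_validation("`policy` must be created by `guard_policy()`.")
  }
  data <- validate_survival(data, allow_empty = TRUE)
  failed <- character(0)
  if (nrow(data) < policy$min_subjects) failed <- c(failed, "min_subjects")
  if (sum(data$event) < policy$min_events) failed <- c(failed, "min_events")
  structure(
    list(
      passed = length(failed) == 0L,
      failed_rules = failed,
      site = site_label(data),
      policy = policy
    ),
    class = "guard_report"
  )
}

#' @method print guard_report
#' @export
print.guard_report <- function(x, ...) {
  if (x$passed) {
    cat(sprintf("Disclosure guard: PASS (site %s)\n", x$site))
  } else {
    cat(sprintf("Disclosure guard: REFUSED (site %s); rule(s) fired: %s\n",
                x$site, paste(x$failed_rules, collapse = ", ")))
  }
  invisible(x)
}

new_privacy_curve <- function(points, method, params = list(), site = NULL,
                              n_input = NA_integer_) {
  structure(
    tibble::tibble(time = as.numeric(points$time), surv = as.numeric(points$surv)),
    method = method,
    params = params,
    site = site %||% "site",
    n_input = as.integer(n_input),
    censor_marks_suppressed = TRUE,
    class = c("privacy_curve", class(tibble::tibble()))
  )
}

is_privacy_curve <- function(x) inherits(x, "privacy_curve")

curve_method <- function(curve) attr(curve, "method", exact = TRUE) %||% "none"

#' Privacy-enhanced survival curve for one dataset
#'
#' The end-to-end release path: the dataset must pass the disclosure
#' guard; the Kaplan-Meier curve is fitted; its (time, surv) points are
#' transformed by the chosen anonymisation mechanism; survival values are
#' clipped to [0, 1]; censoring marks are suppressed; and the released
#' object records the method and every parameter (including the seed) so
#' the release is reproducible.
#'
#' Methods:
#' * `"loess"` (default): tricube local-linear smoothing of the curve
#'   points, span chosen automatically by AICc ([select_span()]) unless a
#'   numeric `span` is forced. The smoothing grid is the KM curve's
#'   distinct times (events and censorings), prepended with the anchor
#'   (0, 1) so the smooth starts at full survival; the anchor can be
#'   dropped. The smooth is *not* re-monotonised by default — set
#'   `monotonise = TRUE` to apply the running-minimum projection when a
#'   valid survival function is required.
#' * `"probabilistic"`: seeded multiplicative noise with monotonicity
#'   repair ([anonymize_probabilistic()]).
#' * `"deterministic"`: k-nearest-neighbour centroid replacement
#'   ([anonymize_deterministic()]).
#' * `"none"`: the raw curve points, for internal comparison only;
#'   refused unless `allow_raw = TRUE`, mirroring the server-side posture
#'   that only privacy-enhanced results leave a site.
#'
#' @param data Subject table with `time` and `event` columns.
#' @param method One of `"loess"`, `"probabilistic"`, `"deterministic"`,
#'   `"none"`.
#' @param span `"auto"` (AICc selection) or a number in (0, 1].
#' @param degree Local polynomial degree for LOESS, 1 or 2.
#' @param anchor Prepend the (0, 1) anchor to the smoothing grid.
#' @param monotonise Re-monotonise the smoothed curve by running minimum.
#' @param noise_pct,noise_axes,seed Probabilistic-noise parameters, see
#'   [anonymize_probabilistic()].
#' @param k Neighbourhood size for deterministic anonymisation.
#' @param policy Disclosure policy, see [guard_policy()].
#' @param allow_raw Permit `method = "none"`.
#' @return A `privacy_curve`: tibble of released `(time, surv)` points
#'   with method metadata in attributes; it carries no per-subject counts
#'   and no censoring marks.
#' @export
privacy_curve <- function(data,
                          method = c("loess", "probabilistic", "deterministic", "none"),
                          span = "auto", degree = 1, anchor = TRUE,
                          monotonise = FALSE,
                          noise_pct = 5, noise_axes = "y", seed = 1L,
                          k = 5, policy = guard_policy(), allow_raw = FALSE) {
  method <- match.arg(method)
  data <- validate_survival(data)
  report <- disclosure_guard(data, policy)
  if (!report$passed) {
    stop_disclosure(sprintf(
      "Disclosure guard refused the request: rule(s) fired: %s.",
      paste(report$failed_rules, collapse = ", ")
    ))
  }
  km <- fit_km(data)
  raw <- tibble::tibble(time = km$time, surv = km$surv)
  use_anchor <- isTRUE(anchor) && (nrow(raw) == 0L || raw$time[1L] > 0)
  grid <- if (use_anchor) {
    tibble::tibble(time = c(0, raw$time), surv = c(1, raw$surv))
  } else {
    raw
  }

  if (method == "loess") {
    if (identical(span, "auto")) {
      fit <- select_span(grid$time, grid$surv, degree = degree)
    } else {
      fit <- loess_tricube(grid$time, grid$surv, span = span, degree = degree)
    }
    surv <- pmin(pmax(fit$fitted, 0), 1)
    if (isTRUE(monotonise)) surv <- cummin(surv)
    pts <- tibble::tibble(time = grid$time, surv = surv)
    params <- list(span = fit$span, span_mode = if (identical(span, "auto")) "auto" else "fixed",
                   degree = as.integer(degree), anchor = use_anchor,
                   monotonise = isTRUE(monotonise))
  } else if (method == "probabilistic") {
    pts <- anonymize_probabilistic(grid, noise_pct = noise_pct,
                                   axes = noise_axes, seed = seed)
    pts$surv <- pmin(pmax(pts$surv, 0), 1)
    params <- list(noise_pct = noise_pct, noise_axes = noise_axes, seed = seed)
  } else if (method == "deterministic") {
    pts <- anonymize_deterministic(grid, k = k)
    pts$surv <- pmin(pmax(pts$surv, 0), 1)
    params <- list(k = as.integer(k))
  } else {
    if (!isTRUE(allow_raw)) {
      stop_disclosure(
        "method = \"none\" releases the raw curve and is refused unless `allow_raw = TRUE`."
      )
    }
    pts <- grid
    params <- list()
  }
  new_privacy_curve(pts, method = method, params = params,
                    site = site_label(data), n_input = nrow(data))
}

#' Per-site federated curve generation
#'
#' Runs [privacy_curve()] independently on each site's dataset, the way a
#' federated deployment executes the same server-side function at every
#' participating site. A site failing the disclosure guard yields its
#' guard report instead of a curve and does not block the other sites.
#' Each site's output is a pure function of that site's own data — nothing
#' crosses site boundaries.
#'
#' @param sites Named list of subject tables (one per site).
#' @param ... Passed to [privacy_curve()] (method, options, policy).
#' @return A named list, one `privacy_curve` or `guard_report` per site,
#'   of class `federated_curves`.
#' @export
federate_curves <- function(sites, ...) {
  if (!is.list(sites) || length(sites) == 0L || is.data.frame(sites)) {
    stop_validation("`sites` must be a non-empty list of subject tables.")
  }
  labels <- names(sites) %||% rep("", length(sites))
  labels <- ifelse(nzchar(labels), labels, paste0("site", seq_along(sites)))
  out <- purrr::map2(sites, labels, function(data, label) {
    attr(data, "site") <- label
    report <- disclosure_guard(data, list(...)$policy %||% guard_policy())
    if (!report$passed) return(report)
    privacy_curve(data, ...)
  })
  structure(setNames(out, labels), class = "federated_curves")
}

#' @method tidy privacy_curve
#' @export
tidy.privacy_curve <- function(x, ...) {
  tibble::as_tibble(unclass_curve(x))
}

#' @method glance privacy_curve
#' @export
glance.privacy_curve <- function(x, ...) {
  params <- attr(x, "params", exact = TRUE) %||% list()
  tibble::tibble(
    method = curve_method(x),
    site = attr(x, "site", exact = TRUE),
    n_input = attr(x, "n_input", exact = TRUE),
    n_points = nrow(x),
    span = params$span %||% NA_real_,
    censor_marks_suppressed = isTRUE(attr(x, "censor_marks_suppressed", exact = TRUE))
  )
}

#' @method autoplot privacy_curve
#' @export
autoplot.privacy_curve <- function(object, raw_overlay = NULL, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$time, y = .data$surv))
  if (!is.null(raw_overlay)) {
    sp <- step_points(raw_overlay, include_censor_marks = FALSE)
    p <- p + ggplot2::geom_line(data = sp$vertices, colour = "black")
  }
  geom <- if (curve_method(object) == "none") {
    ggplot2::geom_step(data = dat, colour = "#b2182b")
  } else {
    ggplot2::geom_line(data = dat, colour = "#b2182b")
  }
  p + geom +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival proportion")
}

#' Render curves to an SVG or PNG file
#'
#' Draws one or more released curves (smooth polylines) with an optional
#' raw Kaplan-Meier staircase overlay in black. Censoring tick marks are
#' never drawn for privacy curves.
#'
#' @param curves A `privacy_curve` or list of them.
#' @param raw_overlay Optional `km_curve` drawn as a black staircase.
#' @param path Output file path.
#' @param format `"svg"` or `"png"`; `NULL` infers from the extension.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_curve <- function(curves, raw_overlay = NULL, path, format = NULL,
                         width = 7, height = 5) {
  if (is_privacy_curve(curves)) curves <- list(curves)
  if (!is.list(curves) || length(curves) == 0L ||
      !all(purrr::map_lgl(curves, is_privacy_curve))) {
    stop_validation("`curves` must be one or more `privacy_curve` objects.")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "svg"
  }
  format <- match.arg(format, c("svg", "png"))
  dat <- purrr::map_dfr(curves, function(cv) {
    dplyr::mutate(tidy(cv), site = attr(cv, "site", exact = TRUE) %||% "site")
  })
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$time, y = .data$surv))
  if (!is.null(raw_overlay)) {
    sp <- step_points(raw_overlay, include_censor_marks = FALSE)
    p <- p + ggplot2::geom_line(data = sp$vertices, colour = "black")
  }
  p <- p +
    ggplot2::geom_line(data = dat, ggplot2::aes(colour = .data$site)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival proportion", colour = "site")
  ok <- tryCatch({
    if (format == "svg") {
      grDevices::svg(path, width = width, height = height)
    } else {
      grDevices::png(path, width = width * 96, height = height * 96, res = 96)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
    print(p)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    abort(sprintf("Cannot render to %s.", path), class = "survcloak_error_io")
  }
  invisible(path)
}
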