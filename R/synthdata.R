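#' Simulate right-censored survival data
#'
#' Draws a latent event time E and an independent censoring time C per
#' subject and records `time = min(E, C)`, `event = 1` iff `E <= C` — the
#' independent-censoring setting the product-limit estimator assumes.
#' The defaults emulate the skew typical of survival data (more events at
#' earlier times): Weibull event times with shape 0.8 (decreasing hazard)
#' and exponential censoring tuned to censor roughly 30% of subjects.
#'
#' @param n Subject count.
#' @param event_dist `"weibull"` or `"exponential"`.
#' @param shape,scale Weibull event-time parameters (used when
#'   `event_dist = "weibull"`).
#' @param rate Exponential event-time rate (used when
#'   `event_dist = "exponential"`).
#' @param censor_dist `"uniform"`, `"exponential"`, or `"none"`.
#' @param censor_min,censor_max Uniform censoring-window bounds.
#' @param censor_rate Exponential censoring rate.
#' @param groups Optional named list of per-group overrides; each element
#'   is a list that may set `n`, `shape`, `scale` or `rate`. When a group
#'   omits `n`, subjects are split evenly.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param site Site/study label attached to the dataset.
#' @return A tibble of subject records (`time`, `event`, and `group` when
#'   groups are given).
#' @export
simulate_survival <- function(n,
                              event_dist = c("weibull", "exponential"),
                              shape = 0.8, scale = 100, rate = 0.01,
                              censor_dist = c("exponential", "uniform", "none"),
                              censor_min = 0, censor_max = 500,
                              censor_rate = 0.0042,
                              groups = NULL, seed = NULL, site = "synthetic") {
  event_dist <- match.arg(event_dist)
  censor_dist <- match.arg(censor_dist)
  n <- check_number(n, "n", min = 1)
  if (n != round(n)) stop_validation("`n` must be an integer.")
  n <- as.integer(n)
  for (p in c(shape, scale, rate, censor_rate)) check_number(p, "distribution parameter", min = .Machine$double.xmin)
  check_number(censor_min, "censor_min", min = 0)
  check_number(censor_max, "censor_max", min = 0)
  if (censor_dist == "uniform" && censor_max <= censor_min) {
    stop_validation("`censor_max` must exceed `censor_min`.")
  }

  draw <- function(m, shape., scale., rate.) {
    e <- switch(event_dist,
      weibull = rweibull(m, shape = shape., scale = scale.),
      exponential = rexp(m, rate = rate.)
    )
    cns <- switch(censor_dist,
      uniform = runif(m, censor_min, censor_max),
      exponential = rexp(m, rate = censor_rate),
      none = rep(Inf, m)
    )
    tibble::tibble(time = pmin(e, cns), event = as.numeric(e <= cns))
  }

  out <- with_seed_or_global(seed, {
    if (is.null(groups)) {
      draw(n, shape, scale, rate)
    } else {
      if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
        stop_validation("`groups` must be a named list of per-group parameter lists.")
      }
      sizes <- purrr::map_dbl(groups, ~ .x$n %||% NA_real_)
      if (anyNA(sizes)) {
        base <- n %/% length(groups)
        sizes[is.na(sizes)] <- base
        sizes[1L] <- sizes[1L] + (n - sum(sizes))
      }
      purrr::imap_dfr(groups, function(g, label) {
        i <- match(label, names(groups))
        dplyr::mutate(
          draw(as.integer(sizes[i]), g$shape %||% shape, g$scale %||% scale,
               g$rate %||% rate),
          group = label
        )
      })
    }
  })
  out <- validate_survival(out)
  attr(out, "site") <- site
  out
}

#' Synthetic dataset shaped like a classic lung-cancer trial
#'
#' A fixed-size (137 subjects) synthetic dataset emulating the gross
#' shape of the classic veterans lung-cancer trial data: heavy early-event
#' skew (Weibull shape 0.9, scale 130, so times run from days to a few
#' hundred days) and light censoring (~7%). Only the size and shape are
#' emulated — every value is synthetic, none is a real subject.
#'
#' @param seed Integer seed (default fixed so tests are stable).
#' @return A 137-row tibble of subject records.
#' @export
veteran_like_fixture <- function(seed = 20230606) {
  simulate_survival(
    n = 137, event_dist = "weibull", shape = 0.9, scale = 130,
    censor_dist = "exponential", censor_rate = 5.5e-4,
    seed = seed, site = "veteran_like_synthetic"
  )
}

#' Load a locally supplied export of the veterans lung-cancer dataset
#'
#' The real dataset is public but is not shipped here; supply your own
#' CSV export with `time` and `status` columns. Exports using the
#' 1 = censored / 2 = event convention are handled via
#' `event_coding = "12"`. When the file is absent a classed error is
#' raised so optional real-data checks can skip cleanly.
#'
#' @param path Path to the CSV export.
#' @param event_coding `"01"` or `"12"`.
#' @return A tibble of subject records.
#' @export
load_veteran <- function(path, event_coding = c("01", "12")) {
  event_coding <- match.arg(event_coding)
  if (is.null(path) || !file.exists(path)) {
    abort(
      "No local veteran export found; supply a CSV with `time` and `status` columns to run real-data checks.",
      class = "survcloak_error_optional_data"
    )
  }
  out <- read_survival(path, column_map = c(event = "status"),
                       event_coding = event_coding, site = "veteran")
  out
}
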