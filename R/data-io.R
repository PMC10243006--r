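#' Validate a subject-level survival table
#'
#' Checks the contract every estimation function in survcloak relies on:
#' one row per subject, a non-negative finite `time`, an `event` indicator
#' coded 0/1 (1 = event observed, 0 = right-censored), and an optional
#' `group` label. Record order carries no meaning.
#'
#' @param data A data frame with columns `time` and `event` (and optionally
#'   `group`).
#' @param allow_empty Permit a zero-row table (only useful for plumbing).
#' @return The validated data as a tibble, invisibly unchanged apart from
#'   class.
#' @export
validate_survival <- function(data, allow_empty = FALSE) {
  if (!is.data.frame(data)) {
    stop_validation("`data` must be a data frame of subject records.")
  }
  for (col in c("time", "event")) {
    if (!col %in% names(data)) {
      stop_config(sprintf("Required column `%s` is missing.", col))
    }
  }
  if (nrow(data) == 0L) {
    if (!allow_empty) stop_validation("Survival dataset is empty.")
    return(tibble::as_tibble(data))
  }
  time <- data$time
  event <- data$event
  if (!is.numeric(time)) stop_validation("`time` must be numeric.")
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad) > 0L) {
    stop_validation(sprintf(
      "`time` must be finite and >= 0; first offending row: %d.", bad[1L]
    ))
  }
  if (is.logical(event)) event <- as.numeric(event)
  if (!is.numeric(event) || anyNA(event) || !all(event %in% c(0, 1))) {
    bad <- which(is.na(event) | !(event %in% c(0, 1)))
    stop_validation(sprintf(
      "`event` must be coded 0/1; first offending row: %d.",
      if (length(bad)) bad[1L] else 1L
    ))
  }
  out <- tibble::as_tibble(data)
  out$event <- as.numeric(event)
  out
}

site_label <- function(data, default = "site") {
  lbl <- attr(data, "site", exact = TRUE)
  if (is.null(lbl)) default else as.character(lbl)
}

#' Read subject-level survival records from delimited text
#'
#' Reads a CSV/TSV file with a header row into the subject table used by
#' [fit_km()] and friends. Column names are mapped onto the canonical
#' `time` / `event` / `group` fields; `status` is accepted as an alias for
#' `event`. Parsing is locale-independent (decimal point, no grouping
#' separators) and rows with missing time or event are rejected rather than
#' silently dropped.
#'
#' @param path Path to a delimited text file (UTF-8, header row required).
#' @param delim Field delimiter; `NULL` infers `"\t"` for `.tsv`/`.txt`,
#'   `","` otherwise.
#' @param column_map Named character vector mapping canonical field names
#'   (`time`, `event`, `group`) to the column names used in the file, e.g.
#'   `c(event = "death")`.
#' @param event_coding `"01"` (default; also accepts TRUE/FALSE spellings)
#'   or `"12"` for datasets using the 1 = censored / 2 = event convention.
#' @param site Optional site/study label attached to the result.
#' @return A tibble of validated subject records with columns `time`,
#'   `event` and, when present in the file, `group`.
#' @export
read_survival <- function(path, delim = NULL, column_map = NULL,
                          event_coding = c("01", "12"), site = NULL) {
  event_coding <- match.arg(event_coding)
  if (!file.exists(path)) stop_config(sprintf("File not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = ".", grouping_mark = ""),
    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE
  )
  map <- c(time = "time", event = "event", group = "group")
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
      stop_config("`column_map` must be a named character vector.")
    }
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown)) {
      stop_config(sprintf("Unknown field(s) in `column_map`: %s.",
                          paste(unknown, collapse = ", ")))
    }
    map[names(column_map)] <- column_map
  }
  # `status` is a conventional alias for the event column.
  if (!map[["event"]] %in% names(raw) && is.null(column_map) &&
      "status" %in% names(raw)) {
    map[["event"]] <- "status"
  }
  for (field in c("time", "event")) {
    if (!map[[field]] %in% names(raw)) {
      stop_config(sprintf("Column `%s` (mapped to field `%s`) not found in %s.",
                          map[[field]], field, path))
    }
  }

  time_chr <- raw[[map[["time"]]]]
  event_chr <- raw[[map[["event"]]]]
  miss <- which(is.na(time_chr) | time_chr == "" | is.na(event_chr) | event_chr == "")
  if (length(miss)) {
    stop_validation(sprintf(
      "Missing time or event value at data row %d (rows with missing values are rejected, not dropped).",
      miss[1L]
    ))
  }
  time <- suppressWarnings(as.numeric(time_chr))
  bad <- which(is.na(time))
  if (length(bad)) {
    stop_validation(sprintf("Cannot parse `%s` value %s as a number at data row %d.",
                            map[["time"]], dQuote(time_chr[bad[1L]]), bad[1L]))
  }
  event <- parse_event(event_chr, event_coding, column = map[["event"]])

  out <- tibble::tibble(time = time, event = event)
  if (map[["group"]] %in% names(raw)) out$group <- raw[[map[["group"]]]]
  out <- validate_survival(out)
  attr(out, "site") <- site %||% tools::file_path_sans_ext(basename(path))
  out
}

parse_event <- function(x, event_coding, column = "event") {
  lower <- tolower(x)
  if (event_coding == "12") {
    ok <- lower %in% c("1", "2")
    if (!all(ok)) {
      stop_validation(sprintf(
        "With event coding 1/2, `%s` must be 1 (censored) or 2 (event); bad value %s at data row %d.",
        column, dQuote(x[which(!ok)[1L]]), which(!ok)[1L]
      ))
    }
    return(as.numeric(lower) - 1)
  }
  out <- rep(NA_real_, length(x))
  out[lower %in% c("1", "true", "t")] <- 1
  out[lower %in% c("0", "false", "f")] <- 0
  bad <- which(is.na(out))
  if (length(bad)) {
    stop_validation(sprintf(
      "Cannot parse `%s` value %s as a 0/1 event indicator at data row %d.",
      column, dQuote(x[bad[1L]]), bad[1L]
    ))
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a survival or privacy curve to disk
#'
#' TSV output holds the two columns `time` and `surv` at full double
#' precision, so a read-back reproduces the curve exactly. JSON output
#' additionally carries the method metadata (method name, parameters, seed)
#' of a privacy curve.
#'
#' @param curve A `km_curve` (from [fit_km()]) or `privacy_curve` (from
#'   [privacy_curve()]).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`; `NULL` infers from the extension.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, format = NULL) {
  if (!is.data.frame(curve) || nrow(curve) == 0L) {
    stop_validation("`curve` must be a non-empty curve object.")
  }
  if (!all(c("time", "surv") %in% names(curve))) {
    stop_validation("`curve` must have `time` and `surv` columns.")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  if (format == "tsv") {
    lines <- c("time\tsurv",
               sprintf("%.17g\t%.17g", curve$time, curve$surv))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("Cannot write to %s.", path), class = "survcloak_error_io")
  } else {
    payload <- list(
      method = attr(curve, "method", exact = TRUE) %||% "none",
      params = attr(curve, "params", exact = TRUE) %||% list(),
      site = attr(curve, "site", exact = TRUE),
      n_input = attr(curve, "n_input", exact = TRUE),
      censor_marks_suppressed = attr(curve, "censor_marks_suppressed", exact = TRUE) %||% FALSE,
      points = unname(purrr::map2(curve$time, curve$surv, c))
    )
    ok <- tryCatch({
      # I(17): 17 significant digits, enough to reproduce doubles exactly
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), null = "null")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) abort(sprintf("Cannot write to %s.", path), class = "survcloak_error_io")
  }
  invisible(path)
}

#' Read a curve written by [write_curve()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; `NULL` infers from the extension.
#' @return A tibble with `time` and `surv`; JSON input restores the privacy
#'   curve metadata.
#' @export
read_curve <- function(path, format = NULL) {
  if (!file.exists(path)) stop_config(sprintf("File not found: %s", path))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  if (format == "tsv") {
    # base parser: correctly rounded strtod, so the round trip is exact
    tab <- utils::read.delim(path, sep = "\t", colClasses = "numeric")
    return(tibble::as_tibble(tab))
  }
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- purrr::map(payload$points, ~ as.numeric(unlist(.x)))
  out <- tibble::tibble(
    time = purrr::map_dbl(pts, 1),
    surv = purrr::map_dbl(pts, 2)
  )
  new_privacy_curve(
    out,
    method = payload$method %||% "none",
    params = payload$params %||% list(),
    site = payload$site,
    n_input = payload$n_input
  )
}
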