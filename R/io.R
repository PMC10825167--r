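#' Read a pupil samples CSV
#'
#' Expected columns: `trial_id`, `condition`, `time_s`, `pupil`, and
#' optionally `blink` (0/1). Rows are sorted on read (trial then time), so
#' row order in the file is irrelevant, and each trial's time grid is
#' validated for uniformity.
#'
#' @param path Path to a CSV file.
#' @param unit Pupil unit in the file, `"au"` or `"mm"`.
#' @return A samples tibble with the unit recorded as an attribute.
#' @export
read_samples <- function(path, unit = c("au", "mm")) {
  unit <- match.arg(unit)
  d <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("trial_id", "condition", "time_s", "pupil")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    abort(paste0("samples file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  d <- dplyr::arrange(d, .data$trial_id, .data$time_s)
  for (g in split(d$time_s, d$trial_id)) trace_rate(g)
  set_pupil_unit(d, unit)
}

#' Write a pupil samples CSV
#'
#' @param samples A samples tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  assert_samples(samples)
  readr::write_csv(samples, path)
  invisible(path)
}

#' Read a session configuration file
#'
#' YAML key-value file with the [session_config()] fields. Derived
#' quantities (tagging period and frequency) are always computed from
#' `half_period_s`, never read, and the frames/refresh timing is checked
#' for consistency on construction.
#'
#' @param path Path to a YAML file.
#' @return A [session_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(session_config))
  unknown <- setdiff(names(raw), c(allowed, "period_s", "tag_frequency_hz"))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(session_config, raw[intersect(names(raw), allowed)])
}

fmt9 <- function(x) {
  if (is.double(x)) sprintf("%.9g", x) else x
}

#' Write analysis results to disk
#'
#' Writes the per-condition tagging table as CSV and the equiluminance
#' estimate as JSON. Numeric values are serialised as decimal text with 9
#' significant digits, so writing, re-reading and re-writing is
#' byte-stable. An estimate without a phase transition has its phase fields
#' as JSON `null`, never absent.
#'
#' @param results A [tag_table()] tibble (may be empty: header-only CSV).
#' @param estimate A `pftm_estimate`, or `NULL` to skip the JSON.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, estimate, csv_path,
                          json_path = NULL) {
  out <- dplyr::mutate(results, dplyr::across(dplyr::where(is.double), fmt9))
  readr::write_csv(out, csv_path)
  paths <- csv_path
  if (!is.null(estimate) && !is.null(json_path)) {
    stopifnot(inherits(estimate, "pftm_estimate"))
    pt <- estimate$phase_transition
    found <- isTRUE(pt$found)
    num <- function(x) if (is.null(x) || is.na(x)) NULL else as.numeric(fmt9(x))
    obj <- list(
      min_luminance = num(estimate$min_luminance),
      ratio = num(estimate$ratio),
      raw_argmin = num(estimate$raw_argmin),
      boundary = estimate$boundary,
      phase_start = if (found) num(pt$start) else NULL,
      phase_midpoint = if (found) num(pt$midpoint) else NULL,
      phase_end = if (found) num(pt$end) else NULL,
      confirmed = if (found) estimate$confirmed else NULL,
      combined_luminance = if (found) num(estimate$combined_luminance) else NULL,
      combined_ratio = if (found) num(estimate$combined_ratio) else NULL,
      fixed_luminance = num(estimate$fixed_luminance),
      phase_tolerance = num(estimate$phase_tolerance)
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, null = "null",
                         digits = NA, always_decimal = FALSE)
    paths <- c(paths, json_path)
  }
  invisible(paths)
}

#' Read a 2AFC response table CSV
#'
#' @param path CSV with columns `level`, `n_chose`, `n_total`.
#' @return A response tibble for [fit_quick_mle()].
#' @export
read_responses <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c("level", "n_chose", "n_total"), names(d))
  if (length(missing)) {
    abort(paste0("responses file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dplyr::arrange(d, .data$level)
}
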