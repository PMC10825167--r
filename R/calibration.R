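#' Pupil-size calibration from an artificial pupil
#'
#' Video eye trackers report pupil size in arbitrary units. Recording a black
#' artificial-pupil target of known physical diameter at the participant's
#' eye position gives a scale factor theta = reference_mm / sqrt(units), and
#' raw samples are then converted with diameter = theta * sqrt(data). The
#' square-root mapping assumes the tracker reports pupil *area* counts.
#'
#' Calibration is optional: the equiluminance minimum is located by
#' comparing amplitudes within a session, which is invariant to a common
#' scale, so the pipeline runs identically on arbitrary units.
#'
#' @param artificial_units Arbitrary-unit value recorded from the artificial
#'   pupil target (> 0).
#' @param reference_mm Physical diameter of the target in mm (default 8).
#' @return A `pftm_calibration` object with fields `scale` (mm per sqrt
#'   unit), `source_units`, and `reference_mm`.
#' @examples
#' calibration_factor(1600)    # scale 0.2
#' @export
calibration_factor <- function(artificial_units, reference_mm = 8) {
  assert_number(artificial_units, "artificial_units", 0, strict = TRUE)
  assert_number(reference_mm, "reference_mm", 0, strict = TRUE)
  structure(
    list(
      scale = reference_mm / sqrt(artificial_units),
      source_units = artificial_units,
      reference_mm = reference_mm
    ),
    class = "pftm_calibration"
  )
}

#' @export
print.pftm_calibration <- function(x, ...) {
  cat(sprintf("<pupil calibration> theta = %.6g mm/sqrt(unit) (%g mm target at %g units)\n",
              x$scale, x$reference_mm, x$source_units))
  invisible(x)
}

#' Convert arbitrary-unit pupil samples to millimetres
#'
#' @param samples Pupil samples tibble (see [validate_session()]) in
#'   arbitrary units; all values must be >= 0.
#' @param factor A [calibration_factor()].
#' @return The samples with `pupil` mapped to `scale * sqrt(pupil)` and the
#'   unit attribute set to `"mm"`. The time axis is untouched.
#' @export
apply_calibration <- function(samples, factor) {
  stopifnot(inherits(factor, "pftm_calibration"))
  if (!"pupil" %in% names(samples)) abort("samples must have a `pupil` column")
  if (identical(pupil_unit(samples), "mm")) {
    abort("samples are already calibrated to mm")
  }
  if (any(samples$pupil < 0, na.rm = TRUE)) {
    abort("raw pupil values must be >= 0 (sqrt mapping)")
  }
  out <- dplyr::mutate(samples, pupil = factor$scale * sqrt(.data$pupil))
  set_pupil_unit(out, "mm")
}
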