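#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Quick-function fit
#'
#' @param x A `pftm_quick_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `fixed`.
#' @export
tidy.pftm_quick_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "gamma", "lambda"),
    estimate = c(x$alpha, x$beta, x$gamma, x$lambda),
    fixed = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' @rdname tidy.pftm_quick_fit
#' @return `glance()`: one row with `pse`, `logLik`, `n_obs`, `n_levels`,
#'   `separable`, `boundary`.
#' @export
glance.pftm_quick_fit <- function(x, ...) {
  tibble::tibble(
    pse = pse(x),
    logLik = x$loglik,
    n_obs = x$n_obs,
    n_levels = nrow(x$data),
    separable = x$separable,
    boundary = x$boundary
  )
}

#' Tidy an equiluminance estimate
#'
#' @param x A `pftm_estimate`.
#' @param ... Unused.
#' @return One row per reported landmark: `term`, `estimate`.
#' @export
tidy.pftm_estimate <- function(x, ...) {
  pt <- x$phase_transition
  tibble::tibble(
    term = c("min_luminance", "ratio", "raw_argmin",
             "phase_start", "phase_midpoint", "phase_end",
             "combined_luminance", "combined_ratio"),
    estimate = c(x$min_luminance, x$ratio, x$raw_argmin,
                 if (isTRUE(pt$found)) c(pt$start, pt$midpoint, pt$end)
                 else rep(NA_real_, 3),
                 x$combined_luminance, x$combined_ratio)
  )
}

#' @rdname tidy.pftm_estimate
#' @return `glance()`: one row with the headline estimate and its flags.
#' @export
glance.pftm_estimate <- function(x, ...) {
  tibble::tibble(
    min_luminance = x$min_luminance,
    ratio = x$ratio,
    confirmed = x$confirmed,
    boundary = x$boundary,
    phase_found = isTRUE(x$phase_transition$found),
    spline_df = x$fit$df
  )
}
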