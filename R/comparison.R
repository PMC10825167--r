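#' Correlation between two equiluminance methods
#'
#' Pearson's r or Spearman's rho (Pearson correlation of midranks), with the
#' Fisher z transform (`atanh`) as effect size and a one-tailed p-value from
#' the t approximation `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (upper tail: the directional hypothesis is positive
#' agreement between methods).
#'
#' @param data Data frame holding one row per participant.
#' @param x,y Columns with the two methods' ratios (tidy-eval).
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `method`, `estimate`, `fisher_z`, `statistic`
#'   (the t value), `df`, `p_one_tailed`, `n`. `fisher_z` is `Inf` for a
#'   perfect correlation.
#' @examples
#' correlate_methods(pftm_example_ratios("wide"), flicker, pftm)
#' @export
correlate_methods <- function(data, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n != length(yv)) abort("`x` and `y` must be paired (equal length)")
  if (n < 3) abort("need at least 3 paired observations")
  if (anyNA(xv) || anyNA(yv)) abort("missing values in the paired ratios")
  if (sd(xv) == 0 || sd(yv) == 0) abort("constant input: correlation undefined")
  if (method == "spearman") {
    xv <- rank(xv); yv <- rank(yv)  # midranks for ties
  }
  r <- stats::cor(xv, yv)
  if (abs(r) >= 1 - 1e-12) r <- sign(r)  # fp-perfect correlation
  tstat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(n - 2) / sqrt(1 - r^2)
  tibble::tibble(
    method = method,
    estimate = r,
    fisher_z = atanh(r),
    statistic = tstat,
    df = n - 2,
    p_one_tailed = pt(tstat, n - 2, lower.tail = FALSE),
    n = n
  )
}

#' Bland-Altman limits of agreement
#'
#' Differences are taken as `second - first`. Reports the mean difference
#' and the limits of agreement mean +/- 1.96 SD (SD with n - 1), each with
#' its 95% confidence interval: `mean +/- t * SD / sqrt(n)` for the mean and
#' `limit +/- t * SD * sqrt(3 / n)` for the limits, with `t` the 0.975
#' quantile on `n - 1` df.
#'
#' @param data Data frame with one row per participant.
#' @param first,second Columns with the two methods' values (tidy-eval).
#' @return A one-row tibble: `mean_diff`, `lo`, `hi`, `mean_ci_lo`,
#'   `mean_ci_hi`, `lo_ci_lo`, `lo_ci_hi`, `hi_ci_lo`, `hi_ci_hi`, `sd_diff`,
#'   `n`.
#' @examples
#' bland_altman(pftm_example_ratios("wide"), motion, pftm)
#' @export
bland_altman <- function(data, first, second) {
  a <- dplyr::pull(data, {{ first }})
  b <- dplyr::pull(data, {{ second }})
  if (length(a) != length(b)) abort("unpaired inputs")
  n <- length(a)
  if (n < 2) abort("need at least 2 pairs")
  d <- b - a
  m <- mean(d)
  s <- sd(d)
  tq <- qt(0.975, n - 1)
  tibble::tibble(
    mean_diff = m,
    lo = m - 1.96 * s,
    hi = m + 1.96 * s,
    mean_ci_lo = m - tq * s / sqrt(n),
    mean_ci_hi = m + tq * s / sqrt(n),
    lo_ci_lo = m - 1.96 * s - tq * s * sqrt(3 / n),
    lo_ci_hi = m - 1.96 * s + tq * s * sqrt(3 / n),
    hi_ci_lo = m + 1.96 * s - tq * s * sqrt(3 / n),
    hi_ci_hi = m + 1.96 * s + tq * s * sqrt(3 / n),
    sd_diff = s,
    n = n
  )
}

#' Per-method summary of equiluminance ratios
#'
#' Column means and standard errors (SD / sqrt(n)) of a long
#' participant-by-method ratio table. The table must be complete: every
#' participant measured with every method.
#'
#' @param data Long data frame with participant, method and ratio columns.
#' @param participant,method,ratio Column names (tidy-eval).
#' @return A tibble with one row per method: `method`, `mean`, `sem`, `n`.
#' @examples
#' summarise_ratios(pftm_example_ratios())
#' @export
summarise_ratios <- function(data, participant = participant,
                             method = method, ratio = ratio) {
  d <- dplyr::select(data,
                     participant = {{ participant }},
                     method = {{ method }},
                     ratio = {{ ratio }})
  if (anyNA(d$ratio)) abort("missing ratio cells")
  counts <- dplyr::count(d, .data$participant, .data$method)
  full <- tidyr::expand_grid(participant = unique(d$participant),
                             method = unique(d$method))
  if (nrow(counts) != nrow(full) || any(counts$n != 1)) {
    abort("ratio table is incomplete: every participant needs one value per method")
  }
  d |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean = mean(.data$ratio),
      sem = if (dplyr::n() > 1) sd(.data$ratio) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Example ratios: eight observers, three methods
#'
#' Red : green equiluminance ratios for eight human observers, each measured
#' with heterochromatic minimum flicker, minimum motion (2AFC), and pupil
#' frequency tagging. Bundled as the worked example for the method-agreement
#' statistics.
#'
#' @param format `"long"` (participant, method, ratio; default) or
#'   `"wide"` (one column per method).
#' @return A tibble.
#' @examples
#' summarise_ratios(pftm_example_ratios())
#' @export
pftm_example_ratios <- function(format = c("long", "wide")) {
  format <- match.arg(format)
  wide <- tibble::tibble(
    participant = 1:8,
    flicker = c(0.83, 0.81, 0.93, 0.88, 0.86, 0.84, 1.01, 0.86),
    motion  = c(0.84, 0.94, 0.87, 0.94, 0.84, 0.79, 1.09, 0.79),
    pftm    = c(0.89, 0.79, 0.90, 0.82, 0.88, 0.74, 0.96, 0.79)
  )
  if (format == "wide") return(wide)
  tidyr::pivot_longer(wide, -"participant",
                      names_to = "method", values_to = "ratio")
}
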