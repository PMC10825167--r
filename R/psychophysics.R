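check_quick_params <- function(alpha, beta, gamma, lambda) {
  assert_number(alpha, "alpha", 0, strict = TRUE)
  assert_number(beta, "beta", 0, strict = TRUE)
  assert_number(gamma, "gamma", 0)
  assert_number(lambda, "lambda", 0)
  if (gamma + lambda >= 1) abort("`gamma` + `lambda` must be < 1")
  invisible(NULL)
}

#' Quick (Weibull-type) psychometric function
#'
#' `P(x) = gamma + (1 - gamma - lambda) * (1 - 2^(-(x / alpha)^beta))`.
#' With symmetric asymptotes (`gamma = lambda`) the curve passes exactly
#' half-way at `x = alpha`; for a 0-to-1 direction task (`gamma = lambda =
#' 0`) that half-way point is the 50% point of subjective equality.
#'
#' @param x Stimulus level(s), >= 0 (cd/m^2 here).
#' @param alpha Threshold parameter (> 0).
#' @param beta Slope parameter (> 0).
#' @param gamma Lower asymptote (guess rate).
#' @param lambda Lapse rate; upper asymptote is `1 - lambda`.
#' @return Probabilities, same length as `x`.
#' @examples
#' quick_pf(22, alpha = 22, beta = 3)  # 0.5
#' @export
quick_pf <- function(x, alpha, beta, gamma = 0, lambda = 0) {
  check_quick_params(alpha, beta, gamma, lambda)
  if (any(x < 0)) abort("`x` must be >= 0")
  gamma + (1 - gamma - lambda) * (1 - 2^(-(x / alpha)^beta))
}

# Binomial log-likelihood up to the additive choose() constant; written out
# so expected (non-integer) counts are also valid data.
quick_loglik <- function(alpha, beta, gamma, lambda, level, n_chose, n_total) {
  p <- quick_pf(level, alpha, beta, gamma, lambda)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(n_chose * log(p) + (n_total - n_chose) * log(1 - p))
}

#' Maximum-likelihood Quick-function fit to 2AFC data
#'
#' Fits `alpha` and `beta` by maximising the binomial log-likelihood of a
#' constant-stimuli response table, with `gamma` and `lambda` held fixed.
#' To avoid local optima the optimiser is started from every combination of
#' a log-spaced `alpha` grid over the stimulus range and
#' `beta` in {1, 2, 4, 8}.
#'
#' Perfectly separable data (every level answered all-one-way) leave the
#' slope unidentified: the fit is returned with `separable = TRUE` and
#' `beta` capped at its search bound. Responses that are all 0 or all 1
#' overall leave the PSE unidentifiable and are an error.
#'
#' @param responses Tibble with columns `level`, `n_chose`, `n_total`.
#' @param gamma,lambda Fixed asymptotes (defaults 0, appropriate for a
#'   left/right direction task coded as proportion rightward).
#' @param beta_max Upper bound on the slope (boundary flag beyond it).
#' @return A `pftm_quick_fit`: `alpha`, `beta`, `gamma`, `lambda`,
#'   `loglik`, `n_obs`, `separable`, `boundary`, and the data.
#' @export
fit_quick_mle <- function(responses, gamma = 0, lambda = 0, beta_max = 64) {
  needed <- c("level", "n_chose", "n_total")
  if (!all(needed %in% names(responses))) {
    abort("`responses` must have columns level, n_chose, n_total")
  }
  check_quick_params(1, 1, gamma, lambda)
  level <- responses$level; n_chose <- responses$n_chose; n_total <- responses$n_total
  if (any(n_chose < 0) || any(n_chose > n_total) || any(n_total < 1)) {
    abort("need 0 <= n_chose <= n_total with n_total >= 1 at every level")
  }
  if (length(unique(level)) < 2) abort("need responses at >= 2 distinct levels")
  if (sum(n_chose) == 0 || sum(n_chose) == sum(n_total)) {
    abort("all responses identical: point of subjective equality is unidentifiable")
  }
  separable <- all(n_chose == 0 | n_chose == n_total)

  pos <- level[level > 0]
  alpha_grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 8))
  starts <- expand.grid(alpha = alpha_grid, beta = c(1, 2, 4, 8))
  nll <- function(par) {
    -quick_loglik(exp(par[1]), exp(par[2]), gamma, lambda,
                  level, n_chose, n_total)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(log(c(starts$alpha[i], starts$beta[i])), nll,
            method = "L-BFGS-B",
            lower = log(c(min(pos) / 100, 0.05)),
            upper = log(c(max(level) * 100, beta_max))),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("Quick-function fit failed from every start")
  alpha <- exp(best$par[1]); beta <- exp(best$par[2])
  structure(
    list(
      alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
      loglik = -best$value,
      n_obs = sum(n_total),
      separable = separable,
      boundary = separable || beta > beta_max * 0.99,
      data = tibble::as_tibble(responses[needed])
    ),
    class = "pftm_quick_fit"
  )
}

#' @export
print.pftm_quick_fit <- function(x, ...) {
  cat(sprintf("<Quick fit> alpha = %.4g, beta = %.3g (gamma = %g, lambda = %g), logLik %.2f%s\n",
              x$alpha, x$beta, x$gamma, x$lambda, x$loglik,
              if (x$boundary) " [boundary/separable]" else ""))
  invisible(x)
}

#' Point of subjective equality of a Quick fit
#'
#' The stimulus level where the fitted psychometric function crosses 50%.
#' Closed form: `alpha * (-log2((0.5 - lambda) / (1 - gamma - lambda)))^(1 /
#' beta)`, which reduces to `alpha` whenever `gamma = lambda`.
#'
#' @param params A `pftm_quick_fit` or a list with `alpha`, `beta`,
#'   `gamma`, `lambda`.
#' @return The PSE in stimulus units.
#' @export
pse <- function(params) {
  p <- params
  check_quick_params(p$alpha, p$beta, p$gamma, p$lambda)
  if (0.5 <= p$gamma || 0.5 >= 1 - p$lambda) {
    abort("50% lies outside the asymptotes [gamma, 1 - lambda]; PSE undefined")
  }
  q <- (0.5 - p$gamma) / (1 - p$gamma - p$lambda)
  p$alpha * (-log2(1 - q))^(1 / p$beta)
}

#' Summarise minimum-flicker matches
#'
#' Each repeat of the flicker task yields one matched variable (green)
#' luminance at which perceived flicker is minimal; the setting is reported
#' as fixed / match per repeat, summarised by mean and SD.
#'
#' @param matches Matched variable luminances (cd/m^2), all > 0.
#' @param fixed_luminance The fixed (red) luminance (cd/m^2).
#' @return A one-row tibble: `mean_ratio`, `sd_ratio`, `n`.
#' @examples
#' flicker_summary(c(25, 26.5, 24.8), fixed_luminance = 21.04)
#' @export
flicker_summary <- function(matches, fixed_luminance) {
  if (!length(matches)) abort("need at least one flicker match")
  if (any(!is.finite(matches)) || any(matches <= 0)) {
    abort("matches must all be finite and > 0")
  }
  assert_number(fixed_luminance, "fixed_luminance", 0, strict = TRUE)
  r <- fixed_luminance / matches
  tibble::tibble(
    mean_ratio = mean(r),
    sd_ratio = if (length(r) > 1) sd(r) else 0,
    n = length(r)
  )
}
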