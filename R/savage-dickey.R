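#' Savage-Dickey Bayes factor for a point null
#'
#' For a parameter nested at a point null value, the Bayes factor in
#' favour of the null is the ratio of the posterior to the prior density
#' at that value. The posterior density is estimated from the draws either
#' by a normal approximation (default; exact when the posterior is
#' Gaussian) or by a kernel density estimator.
#'
#' Positive `logBF01` favours the null (the data concentrate posterior
#' mass at the null relative to the prior).
#'
#' @param posterior_draws numeric vector of posterior draws of the
#'   parameter.
#' @param prior_density_at_null prior density evaluated at the null value
#'   (must be > 0), e.g. `dnorm(0, 0, prior_sd)` for the package's
#'   zero-centred coefficient priors.
#' @param null null value (default 0).
#' @param estimator `"normal"` or `"kernel"`.
#' @return `logBF01`, the log Bayes factor in favour of the null.
#' @export
savage_dickey_bf01 <- function(posterior_draws, prior_density_at_null,
                               null = 0, estimator = c("normal", "kernel")) {
  estimator <- match.arg(estimator)
  if (!is.finite(prior_density_at_null) || prior_density_at_null <= 0)
    stop("prior density at the null must be positive")
  post_d <- if (estimator == "normal") {
    stats::dnorm(null, mean(posterior_draws), stats::sd(posterior_draws))
  } else {
    d <- stats::density(posterior_draws)
    stats::approx(d$x, d$y, xout = null, rule = 2)$y
  }
  if (post_d <= 0) post_d <- .Machine$double.xmin
  log(post_d) - log(prior_density_at_null)
}
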