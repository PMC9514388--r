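#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates exact leave-one-out expected log predictive density from a
#' single posterior sample. For each observation the importance ratios are
#' the inverse pointwise likelihoods; the largest 20% of log ratios are
#' stabilised by replacing them with expected order statistics of a
#' generalised Pareto distribution fitted to the tail (Pareto smoothing),
#' then truncated at the raw maximum. Observations whose tail-shape
#' estimate k-hat exceeds 0.7 are flagged as unreliable.
#'
#' @param loglik S x N pointwise log-likelihood matrix (or a [gewls()]
#'   fit, from which it is extracted), with S >= 500 draws recommended.
#' @param tail_frac fraction of draws in the smoothed tail.
#' @return An object of class `"gew_loo"`: `elpd_loo`, `se`, `pointwise`
#'   (per-observation elpd), `pareto_k`, and counts of flagged
#'   observations.
#' @export
psis_loo <- function(loglik, tail_frac = 0.2) {
  if (inherits(loglik, "gewls")) loglik <- log_lik(loglik)
  if (!all(is.finite(loglik))) stop("log-likelihood matrix has non-finite entries")
  S <- nrow(loglik); N <- ncol(loglik)
  pointwise <- numeric(N); khat <- numeric(N)
  M <- ceiling(tail_frac * S)
  for (i in seq_len(N)) {
    lw <- -loglik[, i]
    lw <- lw - max(lw)
    ord <- order(lw)
    tail_ix <- ord[(S - M + 1):S]
    cutoff <- lw[ord[S - M]]
    exc <- exp(lw[tail_ix]) - exp(cutoff)
    fit <- gpd_fit(exc)
    khat[i] <- fit$k
    if (is.finite(fit$k) && fit$sigma > 0) {
      q <- (seq_len(M) - 0.5) / M
      smoothed <- log(gpd_quantile(q, fit$k, fit$sigma) + exp(cutoff))
      smoothed <- pmin(smoothed, 0)  # truncate at the raw maximum (= 0 after shift)
      lw[tail_ix[order(exc)]] <- smoothed
    }
    lw <- lw - logsumexp(lw)
    pointwise[i] <- logsumexp(lw + loglik[, i])
  }
  structure(list(elpd_loo = sum(pointwise),
                 se = sqrt(N) * stats::sd(pointwise),
                 pointwise = pointwise,
                 pareto_k = khat,
                 n_bad = sum(khat > 0.7),
                 n_warn = sum(khat > 0.5 & khat <= 0.7)),
            class = "gew_loo")
}

#' @export
print.gew_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo = %.1f (SE %.1f), N = %d\n",
              x$elpd_loo, x$se, length(x$pointwise)))
  cat(sprintf("  Pareto k-hat: %d > 0.7 (bad), %d in (0.5, 0.7]\n",
              x$n_bad, x$n_warn))
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Zhang & Stephens (2009) profile-posterior fit of the generalised Pareto
# distribution to tail exceedances; returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || stats::sd(x) < 1e-300) return(list(k = Inf, sigma = 0))
  prior_bs <- 3
  m_grid <- 30 + floor(sqrt(n))
  jj <- seq_len(m_grid)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m_grid / (jj - 0.5))) / prior_bs / xstar
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- n * (log(bs / ks) + ks - 1)
  w <- exp(L - logsumexp(L))
  b_hat <- sum(bs * w)
  k_hat <- -mean(log1p(-b_hat * x))
  list(k = k_hat, sigma = k_hat / b_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * ((1 - p)^(-k) - 1) / k
}

#' Model probabilities from LOO results
#'
#' Pseudo-BMA+ weights: a Bayesian bootstrap (seeded Dirichlet reweighting
#' of the pointwise elpd contributions) propagates the uncertainty of the
#' elpd estimates into the model weights, which therefore do not collapse
#' to 0/1 for moderate elpd differences.
#'
#' @param loos list of [psis_loo()] results computed on the same
#'   observations.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return Named numeric weights in `(0, 1)` summing to 1.
#' @export
model_probabilities <- function(loos, n_boot = 1000, seed = 1) {
  stopifnot(length(loos) >= 2)
  N <- length(loos[[1]]$pointwise)
  if (!all(vapply(loos, function(l) length(l$pointwise) == N, logical(1))))
    stop("models were not evaluated on the same observations")
  pw <- vapply(loos, `[[`, numeric(N), "pointwise")
  set.seed(seed)
  wsum <- numeric(ncol(pw))
  for (b in seq_len(n_boot)) {
    g <- stats::rexp(N)
    om <- g / sum(g)
    elpd_b <- N * colSums(pw * om)
    wsum <- wsum + exp(elpd_b - logsumexp(elpd_b))
  }
  w <- wsum / n_boot
  w <- w / sum(w)
  names(w) <- names(loos) %||% paste0("model", seq_along(loos))
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative plausibility of two models
#'
#' Ratio of two model probabilities: how many times more plausible the
#' first model is than the second.
#'
#' @param weights numeric vector of model probabilities (at least 2).
#' @return `weights[1] / weights[2]`.
#' @export
model_odds <- function(weights) {
  stopifnot(length(weights) >= 2, all(weights > 0))
  unname(weights[1] / weights[2])
}

#' Compare two fitted models by PSIS-LOO
#'
#' @param ... named [gewls()] fits (or precomputed [psis_loo()] objects)
#'   of the same data.
#' @param seed seed for the bootstrap weights.
#' @return A data.frame with elpd_loo, SE and pseudo-BMA+ weight per
#'   model.
#' @export
loo_compare <- function(..., seed = 1) {
  fits <- list(...)
  loos <- lapply(fits, function(f) if (inherits(f, "gew_loo")) f else psis_loo(f))
  w <- model_probabilities(loos, seed = seed)
  data.frame(model = names(w),
             elpd_loo = vapply(loos, `[[`, numeric(1), "elpd_loo"),
             se = vapply(loos, `[[`, numeric(1), "se"),
             p_model = as.numeric(w),
             row.names = NULL)
}
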