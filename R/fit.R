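#' Weakly informative prior settings
#'
#' Zero-centred normal priors on the fixed effects of the location and
#' scale linear predictors and half-normal priors on the participant
#' random-effect SDs. For the Von Mises branch the location predictor
#' lives on the half-tangent link scale and the scale predictor on log
#' concentration, so unit-scale priors are weakly informative. For the
#' Gaussian branch (pixel-scale responses) `autoscale = TRUE` widens the
#' location prior to `2.5 * (sd(y) + |mean(y)|)` and centres the log-SD
#' prior at `log(sd(y))`.
#'
#' @param b_loc_sd prior SD of location-predictor coefficients.
#' @param b_scale_sd prior SD of scale-predictor coefficients.
#' @param re_sd half-normal scale of the random-effect SDs.
#' @param autoscale rescale Gaussian-branch priors from the response.
#' @return An object of class `"gew_priors"`.
#' @export
gew_priors <- function(b_loc_sd = 1, b_scale_sd = 1, re_sd = 0.5,
                       autoscale = TRUE) {
  stopifnot(b_loc_sd > 0, b_scale_sd > 0, re_sd > 0)
  structure(list(b_loc_sd = b_loc_sd, b_scale_sd = b_scale_sd,
                 re_sd = re_sd, autoscale = autoscale),
            class = "gew_priors")
}

# Resolve priors into per-coefficient mean/sd vectors for a concrete design.
resolve_priors <- function(priors, family, y, P1, P2) {
  bloc_mean <- rep(0, P1); bscale_mean <- rep(0, P2)
  bloc_sd <- rep(priors$b_loc_sd, P1); bscale_sd <- rep(priors$b_scale_sd, P2)
  re_sd_loc <- priors$re_sd; re_sd_scale <- priors$re_sd
  if (family == "gaussian" && priors$autoscale) {
    s <- stats::sd(y); m <- abs(mean(y))
    bloc_sd <- rep(2.5 * (s + m), P1)
    bscale_mean <- rep(log(s), P2)
    bscale_sd <- rep(1.5, P2)
    re_sd_loc <- 0.5 * s
    re_sd_scale <- 0.5
  }
  list(bloc_mean = bloc_mean, bloc_sd = bloc_sd,
       bscale_mean = bscale_mean, bscale_sd = bscale_sd,
       re_sd_loc = re_sd_loc, re_sd_scale = re_sd_scale)
}

#' Von Mises log density
#'
#' `log[ exp(k cos(theta - mu)) / (2 pi I0(k)) ]`, computed with the
#' exponentially-scaled Bessel function so large concentrations do not
#' overflow. At `k = 0` this is the uniform circle, `log(1 / 2pi)`.
#'
#' @param theta_rad,mu_rad angle and location in radians.
#' @param kappa concentration (>= 0).
#' @return Log density values.
#' @export
vonmises_logpdf <- function(theta_rad, mu_rad, kappa) {
  if (any(kappa < 0)) stop("concentration k must be >= 0")
  n <- max(length(theta_rad), length(mu_rad), length(kappa))
  theta_rad <- rep_len(theta_rad, n); mu_rad <- rep_len(mu_rad, n)
  kappa <- rep_len(kappa, n)
  mapply(cpp_vm_logpdf_one, theta_rad, mu_rad, kappa)
}

# Assemble the model_data list consumed by the C++ engine.
build_model_data <- function(y, family, Xloc, Xscale, pid_index, J, re_scale,
                             rp) {
  list(y = as.numeric(y),
       family = if (family == "vonmises") 0L else 1L,
       Xloc = Xloc, Xscale = Xscale,
       pid = as.integer(pid_index), J = as.integer(J),
       re_scale = isTRUE(re_scale),
       bloc_mean = rp$bloc_mean, bloc_sd = rp$bloc_sd,
       bscale_mean = rp$bscale_mean, bscale_sd = rp$bscale_sd,
       re_sd_loc = rp$re_sd_loc, re_sd_scale = rp$re_sd_scale)
}

param_names <- function(Xloc, Xscale, pids, re_scale) {
  nm <- c(paste0("b_loc[", colnames(Xloc), "]"),
          paste0("b_scale[", colnames(Xscale), "]"))
  if (length(pids)) {
    nm <- c(nm, paste0("u_loc[", pids, "]"))
    if (re_scale) nm <- c(nm, paste0("u_scale[", pids, "]"))
    nm <- c(nm, "log_sigma_loc")
    if (re_scale) nm <- c(nm, "log_sigma_scale")
  }
  nm
}

# Moment-based starting values: least squares for the Gaussian branch,
# link-transformed circular cell statistics for the Von Mises branch.
init_values <- function(y, family, Xloc, Xscale, npar) {
  init <- rep(0, npar)
  P1 <- ncol(Xloc); P2 <- ncol(Xscale)
  if (family == "gaussian") {
    fit <- stats::lm.fit(Xloc, y)
    b <- fit$coefficients; b[is.na(b)] <- 0
    init[seq_len(P1)] <- b
    s <- stats::sd(fit$residuals)
    ic <- which(colnames(Xscale) %in% c("(Intercept)"))
    if (length(ic)) init[P1 + ic] <- log(max(s, 1e-3)) else
      init[P1 + seq_len(P2)][apply(Xscale, 2, function(cl) all(cl %in% c(0, 1)))] <-
        log(max(s, 1e-3))
  } else {
    khat <- kappa_mle(y * 180 / pi)
    if (!is.finite(khat)) khat <- 50
    lk <- log(max(khat, 0.05))
    ind <- apply(Xscale, 2, function(cl) all(cl %in% c(0, 1)))
    ic <- which(colnames(Xscale) %in% c("(Intercept)"))
    if (length(ic)) init[P1 + ic] <- lk else init[P1 + which(ind)] <- lk
  }
  init
}

#' Fit a Bayesian location-scale mixed model for wheel responses
#'
#' The single fitting engine behind all analyses. For the angular indices
#' the likelihood is Von Mises: the *location* linear predictor maps to the
#' circular mean (the bias) through a half-tangent link
#' `mu = 2 atan(eta)`, and the *scale* predictor maps to the concentration
#' (the uncertainty, reported as circular variance) through a log link.
#' For perceived intensity the likelihood is Gaussian with an identity
#' mean link and a log link on the residual SD. Participant random
#' intercepts enter the location predictor and, by default, the scale
#' predictor as well.
#'
#' Sampling uses an adaptive Metropolis-within-Gibbs scheme (coordinate
#' updates, per-coordinate step sizes adapted during warmup) with multiple
#' chains, split-Rhat and effective-sample-size diagnostics, and pointwise
#' log-likelihoods for cross-validation. `method = "map"` replaces MCMC by
#' a maximum-a-posteriori fit with a Laplace (multivariate normal)
#' approximation, useful for fast checks and large simulation studies.
#'
#' @param formula model formula for the location predictor. For the Von
#'   Mises family the response is the centred error *in degrees* (converted
#'   to radians internally); for the Gaussian family it is the raw
#'   response (e.g. radius in pixels). Use `~ 0 + emotion:mask:intensity`
#'   for cell-means coding.
#' @param scale one-sided formula for the scale predictor (log
#'   concentration or log residual SD). Defaults to the location
#'   structure.
#' @param data data.frame holding the response and predictors, one row per
#'   trial.
#' @param family `"vonmises"` or `"gaussian"`.
#' @param random name of the participant identifier column, or `NULL` for
#'   no random effects.
#' @param random_scale also place participant intercepts on the scale
#'   predictor.
#' @param priors a [gew_priors()] object.
#' @param method `"mcmc"` or `"map"`.
#' @param chains,warmup,iter,thin MCMC settings (per chain).
#' @param laplace_draws draws taken from the Laplace approximation when
#'   `method = "map"`.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param pointwise keep the pointwise log-likelihood matrix (needed for
#'   PSIS-LOO).
#' @param contrasts optional contrasts list passed to
#'   [stats::model.matrix()], e.g. `list(mask = "contr.sum")`.
#' @return An object of class `"gewls"`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(8, seed = 7)
#' tab <- prepare_model_table(cohort$trials)
#' fit <- gewls(error_deg ~ 0 + emotion:mask, data = tab,
#'              method = "map", seed = 7)
#' summary(fit)
#' }
#' @export
gewls <- function(formula, scale = NULL, data,
                  family = c("vonmises", "gaussian"),
                  random = "participant_id", random_scale = TRUE,
                  priors = gew_priors(), method = c("mcmc", "map"),
                  chains = 4, warmup = 1000, iter = 1000, thin = 1,
                  laplace_draws = 1000, seed = 1, pointwise = TRUE,
                  contrasts = NULL) {
  family <- match.arg(family)
  method <- match.arg(method)
  if (nrow(data) == 0) stop("no data to fit")
  cl <- match.call()

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (family == "vonmises") {
    if (any(abs(y) > 360)) stop("angular response should be in degrees")
    y_work <- wrap_deg(y) * pi / 180
  } else y_work <- y
  Xloc <- stats::model.matrix(formula, mf, contrasts.arg = contrasts)
  if (qr(Xloc)$rank < ncol(Xloc)) stop("location design matrix is rank deficient")
  if (is.null(scale)) {
    # angular models are location-scale by construction; the Gaussian branch
    # defaults to a homoscedastic residual
    scale <- if (family == "vonmises") formula[-2] else ~1
  }
  Xscale <- stats::model.matrix(scale, stats::model.frame(scale, data),
                                contrasts.arg = contrasts)
  if (qr(Xscale)$rank < ncol(Xscale)) stop("scale design matrix is rank deficient")

  if (!is.null(random)) {
    pid <- factor(data[[random]])
    pid_index <- as.integer(pid) - 1L
    J <- nlevels(pid)
    pids <- levels(pid)
  } else {
    pid_index <- rep(-1L, nrow(data)); J <- 0L; pids <- character(0)
  }

  rp <- resolve_priors(priors, family, y_work, ncol(Xloc), ncol(Xscale))
  md <- build_model_data(y_work, family, Xloc, Xscale, pid_index, J,
                         random_scale, rp)
  nm <- param_names(Xloc, Xscale, pids, random_scale)
  npar <- length(nm)
  init <- init_values(y_work, family, Xloc, Xscale, npar)

  if (method == "mcmc") {
    runs <- lapply(seq_len(chains), function(ch) {
      set.seed(seed + ch - 1L)
      jit <- init + stats::rnorm(npar, 0, 0.05)
      cpp_amwg(md, jit, n_warmup = warmup, n_save = iter, thin = thin,
               want_loglik = pointwise)
    })
    draws <- do.call(rbind, lapply(runs, `[[`, "draws"))
    colnames(draws) <- nm
    loglik <- if (pointwise) do.call(rbind, lapply(runs, `[[`, "loglik")) else NULL
    chain_id <- rep(seq_len(chains), each = iter)
    diag <- mcmc_diagnostics(draws, chain_id, nm)
    accept <- rowMeans(do.call(cbind, lapply(runs, `[[`, "accept_rate")))
  } else {
    # optimise in the non-centred parameterisation (u = sigma * z): the
    # centred joint mode is degenerate at sigma = 0
    md_nc <- md
    md_nc$noncentered <- J > 0
    map <- map_laplace(md_nc, init, laplace_draws, seed,
                       fixed_idx = grep("^log_sigma", nm))
    draws <- map$draws
    colnames(draws) <- nm
    if (J > 0) {
      u_cols <- grep("^u_loc\\[", nm)
      draws[, u_cols] <- draws[, u_cols] * exp(draws[, "log_sigma_loc"])
      map$par[u_cols] <- map$par[u_cols] * exp(map$par[match("log_sigma_loc", nm)])
      if (random_scale) {
        us_cols <- grep("^u_scale\\[", nm)
        draws[, us_cols] <- draws[, us_cols] * exp(draws[, "log_sigma_scale"])
        map$par[us_cols] <- map$par[us_cols] *
          exp(map$par[match("log_sigma_scale", nm)])
      }
    }
    loglik <- if (pointwise) cpp_pointwise_loglik(draws, md) else NULL
    chain_id <- rep(1L, nrow(draws))
    diag <- list(rhat = stats::setNames(rep(NA_real_, npar), nm),
                 ess = stats::setNames(rep(NA_real_, npar), nm),
                 converged = map$converged, map = map$par, lp = map$lp)
    accept <- NULL
  }

  structure(
    list(draws = draws, loglik = loglik, chain_id = chain_id,
         diagnostics = diag, accept_rate = accept,
         family = family, formula = formula, scale_formula = scale,
         random = random, random_scale = random_scale,
         priors = priors, resolved_priors = rp,
         model_data = md, data = data, xlevels = stats::.getXlevels(stats::terms(mf), mf),
         contrasts_arg = contrasts,
         n_obs = nrow(data), n_participants = J, participants = pids,
         method = method, seed = seed, call = cl),
    class = "gewls")
}

# MAP + Laplace approximation: BFGS on the negative log posterior (in the
# non-centred parameterisation when random effects are present), then
# multivariate-normal draws around the mode. Hyperparameters listed in
# `fixed_idx` (the random-effect log-SDs) are held at their mode and the
# remaining block is drawn from the conditional Gaussian (Schur
# complement) - the plug-in treatment familiar from classical mixed-model
# software, which avoids the variance inflation a joint Gaussian in the
# non-centred space produces.
map_laplace <- function(md, init, n_draws, seed, fixed_idx = integer(0)) {
  negll <- function(p) -cpp_log_posterior(p, md)
  neggr <- function(p) -cpp_log_posterior_grad(p, md)
  opt <- stats::optim(init, negll, neggr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  H <- stats::optimHess(opt$par, negll, neggr)
  free <- setdiff(seq_along(init), fixed_idx)
  Hf <- H[free, free, drop = FALSE]
  ch <- tryCatch(chol(Hf), error = function(e) NULL)
  tries <- 0
  while (is.null(ch) && tries < 6) {
    tries <- tries + 1
    Hf <- Hf + diag(10^(tries - 4), nrow(Hf))
    ch <- tryCatch(chol(Hf), error = function(e) NULL)
  }
  if (is.null(ch)) stop("Laplace approximation failed: Hessian not positive definite")
  set.seed(seed)
  z <- matrix(stats::rnorm(n_draws * length(free)), length(free))
  draws <- matrix(opt$par, n_draws, length(init), byrow = TRUE)
  # Hf = R'R (R upper triangular): x = mode + R^{-1} z has covariance Hf^{-1}
  draws[, free] <- t(opt$par[free] + backsolve(ch, z))
  list(par = opt$par, lp = -opt$value, draws = draws,
       converged = opt$convergence == 0)
}

# Split-Rhat and a simple autocorrelation-based effective sample size.
mcmc_diagnostics <- function(draws, chain_id, nm) {
  chains <- split(seq_len(nrow(draws)), chain_id)
  halves <- unlist(lapply(chains, function(ix) {
    h <- length(ix) %/% 2
    list(ix[seq_len(h)], ix[h + seq_len(h)])
  }), recursive = FALSE)
  rhat <- apply(draws, 2, function(x) {
    m <- vapply(halves, function(ix) mean(x[ix]), numeric(1))
    v <- vapply(halves, function(ix) stats::var(x[ix]), numeric(1))
    n <- length(halves[[1]]); mch <- length(halves)
    W <- mean(v); B <- n * stats::var(m)
    if (W < 1e-300) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  ess <- apply(draws, 2, function(x) {
    n <- length(x)
    if (stats::var(x) < 1e-300) return(n)
    acf_ <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
    pos <- which(acf_ < 0.05)
    L <- if (length(pos)) pos[1] else length(acf_)
    max(1, n / (1 + 2 * sum(acf_[seq_len(L)])))
  })
  names(rhat) <- names(ess) <- nm
  list(rhat = rhat, ess = ess,
       converged = all(is.finite(rhat)) && max(rhat) < 1.05)
}

#' Pointwise log-likelihood matrix of a fit
#'
#' @param fit a [gewls()] object.
#' @return An S x N matrix (draws by observations).
#' @export
log_lik <- function(fit) {
  stopifnot(inherits(fit, "gewls"))
  if (!is.null(fit$loglik)) return(fit$loglik)
  cpp_pointwise_loglik(fit$draws, fit$model_data)
}
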