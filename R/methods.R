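#' @export
print.gewls <- function(x, ...) {
  cat(sprintf("Bayesian location-scale %s mixed model (%s)\n",
              if (x$family == "vonmises") "Von Mises" else "Gaussian",
              if (x$method == "mcmc") "MCMC" else "MAP + Laplace"))
  cat("  location: ", deparse(x$formula), "\n", sep = "")
  cat("  scale:    ", deparse(x$scale_formula), "\n", sep = "")
  cat(sprintf("  %d observations, %d participants, %d posterior draws\n",
              x$n_obs, x$n_participants, nrow(x$draws)))
  if (x$method == "mcmc") {
    mr <- max(x$diagnostics$rhat)
    cat(sprintf("  max split-Rhat %.3f (%s)\n", mr,
                if (mr < 1.05) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
summary.gewls <- function(object, prob = 0.95, fixed_only = TRUE, ...) {
  d <- object$draws
  if (fixed_only) d <- d[, !grepl("^u_", colnames(d)), drop = FALSE]
  tab <- t(apply(d, 2, function(x) {
    h <- hpdi(x, prob)
    c(median = stats::median(x), sd = stats::sd(x), lower = h[1], upper = h[2])
  }))
  tab <- data.frame(parameter = rownames(tab), tab, row.names = NULL)
  tab$rhat <- object$diagnostics$rhat[tab$parameter]
  tab$ess <- object$diagnostics$ess[tab$parameter]
  structure(list(table = tab, prob = prob, family = object$family,
                 method = object$method, converged = object$diagnostics$converged),
            class = "summary.gewls")
}

#' @export
print.summary.gewls <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (%d%% HPDI, %s)\n", round(100 * x$prob),
              x$method))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gewls <- function(object, ...) {
  d <- object$draws
  fe <- d[, grepl("^b_", colnames(d)), drop = FALSE]
  apply(fe, 2, stats::median)
}

#' Posterior draws of condition parameters for new data
#'
#' Evaluates the location and scale linear predictors for each row of
#' `newdata` (population level: random effects at zero) and maps them
#' through the links: circular mean in degrees and concentration /
#' circular variance for the Von Mises family, mean and residual SD for
#' the Gaussian family.
#'
#' @param object a [gewls()] fit.
#' @param newdata data.frame of predictor combinations; defaults to the
#'   unique combinations observed in the fitted data.
#' @param type `"draws"` for full posterior draws (list of matrices,
#'   draws x rows) or `"summary"` for medians with HPDI bounds.
#' @param prob HPDI mass for `type = "summary"`.
#' @param ... unused.
#' @export
predict.gewls <- function(object, newdata = NULL, type = c("summary", "draws"),
                          prob = 0.95, ...) {
  type <- match.arg(type)
  vars <- unique(c(all.vars(object$formula[-2]), all.vars(object$scale_formula)))
  if (is.null(newdata)) {
    newdata <- unique(object$data[vars])
    rownames(newdata) <- NULL
  }
  for (v in names(object$xlevels))
    newdata[[v]] <- factor(newdata[[v]], levels = object$xlevels[[v]])
  Xl <- stats::model.matrix(object$formula[-2], newdata,
                            contrasts.arg = object$contrasts_arg)
  Xs <- stats::model.matrix(object$scale_formula, newdata,
                            contrasts.arg = object$contrasts_arg)
  d <- object$draws
  bl <- d[, grepl("^b_loc\\[", colnames(d)), drop = FALSE]
  bs <- d[, grepl("^b_scale\\[", colnames(d)), drop = FALSE]
  eta_l <- bl %*% t(Xl); eta_s <- bs %*% t(Xs)
  if (object$family == "vonmises") {
    out <- list(mu_deg = 2 * atan(eta_l) * 180 / pi,
                kappa = exp(eta_s))
    out$circvar <- kappa_to_circvar(out$kappa)
    dim(out$circvar) <- dim(out$kappa)
  } else {
    out <- list(mean = eta_l, sd = exp(eta_s))
  }
  if (type == "draws") return(c(out, list(newdata = newdata)))
  summ <- lapply(out, function(m) {
    t(apply(m, 2, function(x) c(median = stats::median(x), hpdi(x, prob))))
  })
  cbind(newdata, do.call(cbind, lapply(names(summ), function(nm) {
    s <- as.data.frame(summ[[nm]])
    names(s) <- paste0(nm, c("", "_lower", "_upper"))
    s
  })))
}

#' Simulate responses from the posterior predictive distribution
#'
#' Each simulation draws one posterior parameter vector (including the
#' fitted participant effects) and generates a full replicate response
#' vector for the modelled trials.
#'
#' @param object a [gewls()] fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A data.frame with `nsim` columns; angular responses are centred
#'   errors in degrees, Gaussian responses on the response scale.
#' @export
simulate.gewls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  md <- object$model_data
  S <- nrow(object$draws)
  pick <- sample.int(S, nsim, replace = nsim > S)
  sims <- vapply(pick, function(s) {
    par <- object$draws[s, ]
    P1 <- ncol(md$Xloc); P2 <- ncol(md$Xscale)
    eta_l <- as.numeric(md$Xloc %*% par[seq_len(P1)])
    eta_s <- as.numeric(md$Xscale %*% par[P1 + seq_len(P2)])
    if (md$J > 0) {
      eta_l <- eta_l + par[P1 + P2 + md$pid + 1]
      if (md$re_scale) eta_s <- eta_s + par[P1 + P2 + md$J + md$pid + 1]
    }
    if (object$family == "vonmises") {
      mu <- 2 * atan(eta_l); k <- exp(eta_s)
      vapply(seq_along(mu), function(i) rvonmises(1, mu[i], k[i]),
             numeric(1)) * 180 / pi
    } else {
      stats::rnorm(length(eta_l), eta_l, exp(eta_s))
    }
  }, numeric(length(md$y)))
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
residuals.gewls <- function(object, ...) {
  md <- object$model_data
  par <- apply(object$draws, 2, stats::median)
  P1 <- ncol(md$Xloc); P2 <- ncol(md$Xscale)
  eta_l <- as.numeric(md$Xloc %*% par[seq_len(P1)])
  if (md$J > 0) eta_l <- eta_l + par[P1 + P2 + md$pid + 1]
  if (object$family == "vonmises")
    wrap_deg((md$y - 2 * atan(eta_l)) * 180 / pi)
  else md$y - eta_l
}

#' @export
plot.gewls <- function(x, pars = NULL, ...) {
  d <- x$draws
  if (is.null(pars)) {
    fe <- colnames(d)[grepl("^b_", colnames(d))]
    pars <- utils::head(fe, 4)
  }
  old <- graphics::par(mfrow = c(length(pars), 2), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    graphics::plot(d[, p], type = "l", main = paste("trace:", p),
                   xlab = "", ylab = "")
    graphics::plot(stats::density(d[, p]), main = paste("density:", p),
                   xlab = "", ylab = "")
  }
  invisible(x)
}
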