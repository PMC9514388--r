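test_that("design matrices have the expected structure", {
  tab <- small_table()
  fit <- small_vm_fit()
  # cell-means coding: one location and one scale coefficient per cell
  expect_equal(ncol(fit$model_data$Xloc), 24)
  expect_equal(ncol(fit$model_data$Xscale), 24)
  # factorial with vs without the three-way interaction: 5 fewer columns
  X_full <- model.matrix(~ emotion * mask * intensity, tab)
  X_red <- model.matrix(~ emotion * mask * intensity
                        - emotion:mask:intensity, tab)
  expect_equal(ncol(X_full) - ncol(X_red), 5)
  # sum-coded mask: +/-1 balancing to zero on a balanced design
  Xs <- model.matrix(~ mask, tab, contrasts.arg = list(mask = "contr.sum"))
  expect_setequal(unique(Xs[, "mask1"]), c(-1, 1))
  expect_equal(sum(Xs[, "mask1"]), 0)
})

test_that("rank-deficient designs are rejected", {
  tab <- small_table()
  tab$dup <- as.numeric(tab$mask == "yes")
  expect_error(gewls(error_deg ~ 0 + mask + dup, data = tab,
                     family = "vonmises", method = "map"),
               "rank deficient")
})

test_that("Von Mises log density is normalised, symmetric and uniform at k=0", {
  expect_equal(vonmises_logpdf(c(-2, 0.5, 3), 0, 0), rep(log(1 / (2 * pi)), 3))
  for (k in c(0.5, 2, 10)) {
    Z <- integrate(function(t) exp(vonmises_logpdf(t, 0.3, k)),
                   -pi, pi, rel.tol = 1e-12)$value
    expect_equal(Z, 1, tolerance = 1e-8)
  }
  d <- 0.7
  expect_equal(vonmises_logpdf(1 + d, 1, 4), vonmises_logpdf(1 - d, 1, 4))
  expect_error(vonmises_logpdf(0, 0, -2), ">= 0")
  # draws concentrate as k grows
  set.seed(41)
  spread <- vapply(c(1, 5, 25), function(k)
    var(rvonmises(2000, 0, k)), numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("log posterior reduces to the prior without data and is additive", {
  tab <- small_table()[1:40, ]
  fit <- gewls(error_deg ~ 1, data = tab, family = "vonmises",
               method = "map", laplace_draws = 10, seed = 1)
  md <- fit$model_data
  # no data: only the prior remains
  md0 <- md
  md0$y <- numeric(0)
  md0$Xloc <- md$Xloc[0, , drop = FALSE]
  md0$Xscale <- md$Xscale[0, , drop = FALSE]
  md0$pid <- integer(0)
  set.seed(2)
  theta <- rnorm(length(fit$diagnostics$map), 0, 0.5)
  rp <- fit$resolved_priors
  J <- md$J
  lp_manual <- sum(dnorm(theta[1], rp$bloc_mean, rp$bloc_sd, log = TRUE)) +
    sum(dnorm(theta[2], rp$bscale_mean, rp$bscale_sd, log = TRUE)) +
    sum(dnorm(theta[2 + seq_len(J)], 0, exp(theta[2 + 2 * J + 1]), log = TRUE)) +
    sum(dnorm(theta[2 + J + seq_len(J)], 0, exp(theta[2 + 2 * J + 2]), log = TRUE)) +
    sum(log(2) + dnorm(exp(theta[2 + 2 * J + 1:2]), 0, rp$re_sd_loc, log = TRUE) +
          theta[2 + 2 * J + 1:2])
  expect_equal(gewmask:::cpp_log_posterior(theta, md0), lp_manual,
               tolerance = 1e-10)

  # duplicating an observation adds exactly its pointwise log-likelihood
  md1 <- md
  md1$y <- c(md$y, md$y[5])
  md1$Xloc <- md$Xloc[c(seq_along(md$y), 5), , drop = FALSE]
  md1$Xscale <- md$Xscale[c(seq_along(md$y), 5), , drop = FALSE]
  md1$pid <- c(md$pid, md$pid[5])
  ll5 <- gewmask:::cpp_pointwise_loglik(matrix(theta, 1), md)[1, 5]
  expect_equal(gewmask:::cpp_log_posterior(theta, md1),
               gewmask:::cpp_log_posterior(theta, md) + ll5,
               tolerance = 1e-10)

  # analytic gradient agrees with finite differences
  g <- gewmask:::cpp_log_posterior_grad(theta, md)
  gn <- vapply(seq_along(theta), function(i) {
    h <- 1e-6; e1 <- e2 <- theta; e1[i] <- e1[i] + h; e2[i] <- e2[i] - h
    (gewmask:::cpp_log_posterior(e1, md) -
       gewmask:::cpp_log_posterior(e2, md)) / (2 * h)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-5)
})

test_that("prior-only sampling reproduces the prior scale", {
  md0 <- list(y = numeric(0), family = 0L,
              Xloc = matrix(numeric(0), 0, 1, dimnames = list(NULL, "b")),
              Xscale = matrix(numeric(0), 0, 1, dimnames = list(NULL, "b")),
              pid = integer(0), J = 0L, re_scale = FALSE,
              bloc_mean = 0, bloc_sd = 1, bscale_mean = 0, bscale_sd = 1,
              re_sd_loc = 0.5, re_sd_scale = 0.5)
  set.seed(43)
  out <- gewmask:::cpp_amwg(md0, c(0, 0), n_warmup = 500, n_save = 4000,
                            thin = 1, want_loglik = FALSE)
  expect_lt(abs(sd(out$draws[, 1]) - 1), 0.1)
  expect_lt(abs(mean(out$draws[, 1])), 0.1)
})

test_that("MCMC runs are seed-reproducible and diagnosed", {
  tab <- small_table()[1:120, ]
  f1 <- gewls(error_deg ~ 1, data = tab, family = "vonmises",
              chains = 2, warmup = 150, iter = 150, seed = 9)
  f2 <- gewls(error_deg ~ 1, data = tab, family = "vonmises",
              chains = 2, warmup = 150, iter = 150, seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(is.finite(f1$diagnostics$rhat)))
  expect_equal(length(f1$diagnostics$rhat), ncol(f1$draws))
  expect_true(is.logical(f1$diagnostics$converged))
})

test_that("Gaussian branch reproduces balanced cell means", {
  fit <- small_px_fit()
  tab <- small_table()
  pr <- predict(fit)
  obs <- aggregate(radius_px ~ emotion + mask + intensity, tab, mean)
  m <- merge(pr, obs, by = c("emotion", "mask", "intensity"))
  # cell posterior medians track sample means within posterior spread
  expect_lt(max(abs(m$mean - m$radius_px)), 8)
  expect_gt(cor(m$mean, m$radius_px), 0.99)
})

test_that("cell posteriors are link-transformed coefficient draws", {
  fit <- small_vm_fit()
  cp <- cell_posteriors(fit)
  expect_equal(nrow(cp$cells), 24)
  expect_true(all(cp$circvar > 0 & cp$circvar <= 1))
  # cell-means coding: cell posterior equals the coefficient mapped by link
  cell1 <- cp$cells[1, ]
  col <- sprintf("b_loc[emotion%s:mask%s:intensity%s]",
                 cell1$emotion, cell1$mask, cell1$intensity)
  expect_true(col %in% colnames(fit$draws))
  expect_equal(cp$mu_deg[, 1],
               unname(2 * atan(fit$draws[, col]) * 180 / pi),
               tolerance = 1e-12)
})

test_that("posterior-predictive simulation and residuals match the model frame", {
  fit <- small_vm_fit()
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n_obs, 2))
  expect_true(all(abs(sims) <= 180 + 1e-9))
  res <- residuals(fit)
  expect_equal(length(res), fit$n_obs)
  expect_true(all(res > -180 & res <= 180))
  expect_lt(abs(median(res)), 10)
})

test_that("printed summaries expose the fitted structure", {
  fit <- small_vm_fit()
  expect_output(print(fit), "Von Mises")
  s <- summary(fit)
  expect_s3_class(s, "summary.gewls")
  expect_true(all(c("median", "lower", "upper") %in% names(s$table)))
  expect_true(all(s$table$lower <= s$table$median + 1e-12))
  expect_equal(length(coef(fit)), 48)
})
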