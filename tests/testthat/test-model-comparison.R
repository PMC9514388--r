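# conjugate normal-mean model with known sd: analytic posterior, cheap
# exact leave-one-out refits
conj_post <- function(y, sigma, tau) {
  v <- 1 / (length(y) / sigma^2 + 1 / tau^2)
  c(mean = v * sum(y) / sigma^2, sd = sqrt(v))
}

test_that("PSIS-LOO matches exact refit LOO on a small conjugate model", {
  set.seed(61)
  N <- 30; sigma <- 1.5; tau <- 2
  y <- rnorm(N, 1, sigma)
  p <- conj_post(y, sigma, tau)
  draws <- rnorm(4000, p["mean"], p["sd"])
  ll <- vapply(y, function(yi) dnorm(yi, draws, sigma, log = TRUE),
               numeric(4000))
  lo <- psis_loo(ll)
  exact <- sum(vapply(seq_len(N), function(i) {
    pi_ <- conj_post(y[-i], sigma, tau)
    di <- rnorm(4e4, pi_["mean"], pi_["sd"])
    log(mean(dnorm(y[i], di, sigma)))
  }, numeric(1)))
  expect_lt(abs(lo$elpd_loo - exact), 0.5)
  expect_true(all(lo$pareto_k < 0.7))
  # pointwise contributions sum to the total
  expect_equal(sum(lo$pointwise), lo$elpd_loo, tolerance = 1e-8)
  expect_equal(lo$se, sqrt(N) * sd(lo$pointwise))
})

test_that("PSIS-LOO is additive over duplicated data and order-invariant", {
  set.seed(62)
  y <- rnorm(25, 0, 1)
  draws <- rnorm(2000, mean(y), 0.2)
  ll <- vapply(y, function(yi) dnorm(yi, draws, 1, log = TRUE), numeric(2000))
  lo1 <- psis_loo(ll)
  lo2 <- psis_loo(cbind(ll, ll))
  expect_lt(abs(lo2$elpd_loo - 2 * lo1$elpd_loo), 0.05)
  perm <- sample(25)
  lo3 <- psis_loo(ll[, perm])
  expect_equal(sort(lo3$pointwise), sort(lo1$pointwise), tolerance = 1e-12)
  expect_equal(lo3$elpd_loo, lo1$elpd_loo, tolerance = 1e-12)
  ll_bad <- ll; ll_bad[1, 1] <- NaN
  expect_error(psis_loo(ll_bad), "non-finite")
})

test_that("model weights respect symmetry, dominance and determinism", {
  set.seed(63)
  y <- rnorm(40)
  draws <- rnorm(1500, 0, 1)
  ll <- vapply(y, function(yi) dnorm(yi, draws, 1, log = TRUE), numeric(1500))
  a <- psis_loo(ll)
  # identical models split 50/50 exactly
  w_eq <- model_probabilities(list(m1 = a, m2 = a), seed = 5)
  expect_equal(unname(w_eq), c(0.5, 0.5))
  # uniformly better model dominates
  b <- a; b$pointwise <- a$pointwise + 0.1
  w_dom <- model_probabilities(list(worse = a, better = b), seed = 5)
  expect_gt(w_dom["better"], 0.5)
  expect_equal(sum(w_dom), 1)
  # seeded bootstrap reproducibility
  w2 <- model_probabilities(list(worse = a, better = b), seed = 5)
  expect_equal(w_dom, w2, tolerance = 1e-12)
  # scale consistency: common pointwise shift leaves weights unchanged
  a2 <- a; a2$pointwise <- a$pointwise + 3
  b2 <- b; b2$pointwise <- b$pointwise + 3
  w_shift <- model_probabilities(list(worse = a2, better = b2), seed = 5)
  expect_equal(w_shift, w_dom, tolerance = 1e-10)
  # mismatched N
  short <- a; short$pointwise <- a$pointwise[1:10]
  expect_error(model_probabilities(list(a, short)), "same observations")
})

test_that("model odds reproduce printed plausibility multiples", {
  expect_equal(model_odds(c(0.723, 0.277)), 2.6, tolerance = 0.05)
  expect_equal(model_odds(c(0.753, 0.247)), 3.0, tolerance = 0.05)
})

test_that("Savage-Dickey matches the conjugate closed form", {
  set.seed(64)
  sigma <- 1; tau <- 1; n <- 20
  y <- rnorm(n, 0.15, sigma)
  p <- conj_post(y, sigma, tau)
  bf_exact <- dnorm(0, p["mean"], p["sd"]) / dnorm(0, 0, tau)
  draws <- rnorm(5e4, p["mean"], p["sd"])
  bf_norm <- exp(savage_dickey_bf01(draws, dnorm(0, 0, tau)))
  bf_kern <- exp(savage_dickey_bf01(draws, dnorm(0, 0, tau),
                                    estimator = "kernel"))
  expect_lt(abs(bf_norm / bf_exact - 1), 0.05)
  expect_lt(abs(bf_kern / bf_exact - 1), 0.05)
  # posterior = prior (no data): logBF01 = 0
  prior_draws <- rnorm(2e5, 0, tau)
  expect_lt(abs(savage_dickey_bf01(prior_draws, dnorm(0, 0, tau))), 0.02)
  expect_error(savage_dickey_bf01(draws, 0), "positive")
})

test_that("null effects earn positive null evidence in most replicates", {
  set.seed(65)
  sigma <- 1; tau <- 1
  lb <- replicate(40, {
    y <- rnorm(60, 0, sigma)   # true effect is zero
    p <- conj_post(y, sigma, tau)
    savage_dickey_bf01(rnorm(4000, p["mean"], p["sd"]), dnorm(0, 0, tau))
  })
  expect_gt(mean(lb > 0), 0.8)
})

test_that("loo_compare summarises fits on shared data", {
  tab <- small_table()[1:480, ]
  f1 <- gewls(error_deg ~ 0 + mask, data = tab, family = "vonmises",
              method = "map", seed = 2)
  f2 <- gewls(error_deg ~ 1, data = tab, family = "vonmises",
              method = "map", seed = 2)
  cmp <- loo_compare(with_mask = f1, intercept = f2, seed = 2)
  expect_equal(nrow(cmp), 2)
  expect_equal(sum(cmp$p_model), 1)
  expect_true(all(is.finite(cmp$elpd_loo)))
})
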