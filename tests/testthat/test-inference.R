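test_that("HPDI is the shortest window of sorted draws", {
  # uniform grid 1..1000: any window of 950 draws spans 949 steps; the
  # tie-break picks the first (lowest)
  h <- hpdi(1:1000, 0.95)
  expect_equal(h, c(1, 950))
  expect_equal(diff(h), 949)
  # constant draws collapse to a point
  expect_equal(hpdi(rep(3.3, 500)), c(3.3, 3.3))
  # large-sample normal: near the +/-1.96 quantiles
  set.seed(51)
  h <- hpdi(rnorm(1e5), 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  expect_warning(hpdi(rnorm(50)), "unstable")
})

test_that("identical cells give null contrasts and the decision rule holds", {
  set.seed(52)
  mu <- rnorm(500, 5, 2); cv <- runif(500, 0.2, 0.4)
  cp <- fake_cellpost(
    mu_list = list("anger.yes.full" = mu, "anger.yes.subtle" = mu,
                   "anger.no.full" = mu, "anger.no.subtle" = mu),
    cv_list = list("anger.yes.full" = cv, "anger.yes.subtle" = cv,
                   "anger.no.full" = cv, "anger.no.subtle" = cv))
  d <- mask_delta(cp)
  expect_equal(d$median, 0)
  expect_false(d$significant)
  r <- mask_ratio(cp)
  expect_equal(r$median, 1)
  expect_false(r$significant)
  ii <- intensity_interaction(cp)
  expect_equal(ii$median, 0); expect_false(ii$significant)
  ri <- ratio_interaction(cp)
  expect_equal(ri$median, 1); expect_false(ri$significant)

  # decision rule: significant exactly when the null is outside the HPDI
  for (i in 1:20) {
    x <- rnorm(1000, rnorm(1, 0, 1), 0.5)
    cs <- gewmask:::new_contrast("c", x, 0)
    expect_identical(cs$significant, 0 < cs$hpdi_low | 0 > cs$hpdi_high)
  }
})

test_that("bias deltas wrap near the antipode instead of jumping 360", {
  set.seed(53)
  cp <- fake_cellpost(
    mu_list = list("fear.yes.full" = rnorm(2000, 176, 2),
                   "fear.no.full" = rnorm(2000, -176, 2)),
    cv_list = list("fear.yes.full" = runif(2000, .3, .4),
                   "fear.no.full" = runif(2000, .3, .4)))
  d <- mask_delta(cp)
  expect_true(all(abs(d$median) <= 180))
  expect_lt(abs(d$median + 8), 1)   # 176 - (-176) = 352 wraps to -8
})

test_that("drawwise ratio medians differ from ratio of medians when skewed", {
  # regression point: contrasts must be computed drawwise, because with
  # skewed (chi-square-like) variance posteriors the median of the ratio
  # is not the ratio of the medians
  set.seed(54)
  num <- 0.2 + 0.1 * rnorm(4000)^2
  den <- 0.15 + 0.05 * rnorm(4000)^2
  drawwise <- median(num / den)
  of_medians <- median(num) / median(den)
  expect_gt(abs(drawwise - of_medians), 0.02)
})

test_that("interaction contrasts commute with drawwise arithmetic", {
  set.seed(55)
  mk <- function(m) rnorm(1000, m, 1)
  mu <- list("sadness.yes.full" = mk(20), "sadness.no.full" = mk(10),
             "sadness.yes.subtle" = mk(5), "sadness.no.subtle" = mk(12))
  cv <- lapply(mu, function(x) runif(1000, 0.2, 0.5))
  names(cv) <- names(mu)
  cp <- fake_cellpost(mu, cv)
  ii <- intensity_interaction(cp)
  manual <- (mu[["sadness.yes.full"]] - mu[["sadness.no.full"]]) -
    (mu[["sadness.yes.subtle"]] - mu[["sadness.no.subtle"]])
  expect_equal(ii$median, median(manual), tolerance = 1e-12)
  ri <- ratio_interaction(cp)
  manual_r <- (cv[["sadness.yes.full"]] / cv[["sadness.no.full"]]) /
    (cv[["sadness.yes.subtle"]] / cv[["sadness.no.subtle"]])
  expect_equal(ri$median, median(manual_r), tolerance = 1e-12)
  # sign convention: full-minus-subtle
  expect_gt(ii$median, 0)
})

test_that("a mask effect confined to subtle expressions is detected", {
  set.seed(56)
  mk <- function(m, s = 0.8) rnorm(3000, m, s)
  mu <- list("fear.yes.full" = mk(0), "fear.no.full" = mk(0),
             "fear.yes.subtle" = mk(12), "fear.no.subtle" = mk(0))
  cv <- lapply(mu, function(x) runif(3000, 0.3, 0.32))
  names(cv) <- names(mu)
  cp <- fake_cellpost(mu, cv)
  ii <- intensity_interaction(cp)
  expect_true(ii$significant)
  expect_lt(ii$median, 0)     # mask delta larger for subtle => negative
})

test_that("results tables mirror the condition-by-contrast layout", {
  rt <- results_table(small_vm_fit())
  expect_setequal(names(rt), c("emotion", "parameter", "mask_yes", "mask_no",
                               "contrast", "significant"))
  expect_equal(nrow(rt), 12)   # 6 emotions x (bias, uncertainty)
  expect_setequal(unique(rt$parameter), c("bias", "uncertainty"))
  # asterisk appears exactly on significant contrasts
  expect_identical(grepl("\\*$", rt$contrast), rt$significant)

  rt_px <- results_table(small_px_fit())
  expect_equal(nrow(rt_px), 6)
  expect_true(all(rt_px$parameter == "intensity"))
  # masked faces are perceived as less intense under the generator defaults;
  # at 8 participants most, but not necessarily all, deltas reach the
  # decision threshold
  deltas <- mask_delta(cell_posteriors(small_px_fit()))
  expect_true(all(deltas$median < 0))
  expect_gte(sum(deltas$significant), 4)
})

test_that("label frequencies are relative within condition", {
  freqs <- label_frequencies(small_cohort()$trials)
  sums <- aggregate(freq ~ emotion + mask + intensity, freqs, sum)
  expect_equal(sums$freq, rep(1, nrow(sums)), tolerance = 1e-12)
  # for emotions generated with a small bias, the displayed emotion is the
  # modal unmasked full-intensity response (sadness/anger biases exceed a
  # segment width by design, shifting their mode to a neighbour)
  top <- subset(freqs, mask == "no" & intensity == "full")
  for (e in c("surprise", "happiness", "disgust", "fear")) {
    f <- top[top$emotion == e, ]
    # the displayed emotion draws well over its uniform share (1/17) and
    # sits near the top; dispersion spreads mass onto neighbouring
    # segments at n = 80 per condition, so the exact mode can vary
    ord <- f$response_label[order(f$freq, decreasing = TRUE)]
    expect_lte(which(ord == e), 4)
    expect_gte(f$freq[f$response_label == e], 2 / 17)
  }
})
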