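test_that("score centring is exact and idempotent", {
  expect_equal(as.numeric(center_scores(c(10, 20, 30))), c(-10, 0, 10))
  set.seed(71)
  s <- rnorm(50, 15, 6)
  cs <- center_scores(s)
  expect_lt(abs(mean(cs)), 1e-12)
  expect_equal(attr(cs, "center"), mean(s))
  expect_equal(as.numeric(center_scores(as.numeric(cs))), as.numeric(cs))
  expect_warning(center_scores(c(3, 3, 3)), "constant")
})

test_that("the subtle-only subset halves each participant's trials", {
  tab <- small_table()
  sub <- tab[tab$intensity == "subtle", ]
  expect_equal(as.numeric(table(sub$participant_id)),
               rep(120, length(unique(tab$participant_id))))
})

test_that("null trait effects produce covering HPDIs and null-favouring BFs", {
  # generator has no trait-performance link, so trait terms are true nulls
  ex <- apply_exclusion(small_cohort())
  tab <- small_table()
  tr <- fit_trait_model(tab, ex$participants, "tas", "bias_uncertainty",
                        "all", method = "map", seed = 72)
  expect_equal(nrow(tr), 4)
  expect_setequal(unique(tr$index), c("bias", "uncertainty"))
  covers0 <- tr$hpdi_low <= 0 & tr$hpdi_high >= 0
  expect_true(all(covers0))
  expect_true(all(tr$logBF01 > 0))
  expect_true(all(is.finite(tr$logBF01)))

  tr_sub <- fit_trait_model(tab, ex$participants, "aq", "intensity",
                            "subtle_only", method = "map", seed = 72)
  expect_equal(unique(tr_sub$subset), "subtle_only")
  expect_equal(nrow(tr_sub), 2)
})

test_that("a known trait-by-mask slope on intensity is recovered", {
  set.seed(73)
  J <- 60; n_per <- 40
  pid <- rep(sprintf("P%02d", 1:J), each = n_per)
  trait <- rnorm(J, 15, 6)
  mask <- rep(rep(c("no", "yes"), each = n_per / 2), J)
  mask_s <- ifelse(mask == "no", 1, -1)       # contr.sum: first level +1
  tc <- trait[match(pid, sprintf("P%02d", 1:J))] - mean(trait)
  b_trait <- 1.2; b_int <- 0.8
  y <- 150 + b_trait * tc + b_int * tc * mask_s +
    rnorm(J * n_per, 0, 20) + rep(rnorm(J, 0, 10), each = n_per)
  tab <- data.frame(participant_id = pid, emotion = "anger", mask = mask,
                    intensity = "full", error_deg = 0, radius_px = pmax(0, y))
  parts <- data.frame(participant_id = sprintf("P%02d", 1:J), tas = trait)
  tr <- fit_trait_model(tab, parts, "tas", "intensity", "all",
                        include_emotion = FALSE, method = "map", seed = 73)
  est_main <- tr[tr$term == "trait", ]
  est_int <- tr[tr$term == "trait_x_mask", ]
  # independent oracle: restricted-ML mixed model on the same data
  or <- lme4::lmer(radius_px ~ mask_s * tc + (1 | participant_id),
                   data = cbind(tab, mask_s = mask_s, tc = tc))
  oc <- summary(or)$coefficients
  expect_lt(abs(est_main$estimate - oc["tc", "Estimate"]), 0.15)
  expect_lt(abs(est_int$estimate - oc["mask_s:tc", "Estimate"]), 0.05)
  expect_lt(abs(est_int$sd - oc["mask_s:tc", "Std. Error"]), 0.03)
  # and the generating interaction slope is inside its interval
  expect_gt(b_int, est_int$hpdi_low); expect_lt(b_int, est_int$hpdi_high)
})

test_that("centring does not move the interaction posterior", {
  set.seed(74)
  ex <- apply_exclusion(small_cohort())
  tab <- small_table()
  parts <- ex$participants
  tr1 <- fit_trait_model(tab, parts, "tas", "intensity", "all",
                         method = "map", seed = 74)
  parts2 <- parts
  parts2$tas <- parts$tas + 100   # shift: centring should absorb it
  tr2 <- fit_trait_model(tab, parts2, "tas", "intensity", "all",
                         method = "map", seed = 74)
  i1 <- tr1[tr1$term == "trait_x_mask", ]
  i2 <- tr2[tr2$term == "trait_x_mask", ]
  expect_equal(i1$estimate, i2$estimate, tolerance = 1e-6)
})

test_that("swapping mask labels flips only the interaction sign", {
  set.seed(75)
  ex <- apply_exclusion(small_cohort())
  tab <- small_table()
  tr1 <- fit_trait_model(tab, ex$participants, "tas", "intensity", "all",
                         method = "map", seed = 75)
  tab2 <- tab
  tab2$mask <- factor(tab$mask, levels = c("yes", "no"))
  tr2 <- fit_trait_model(tab2, ex$participants, "tas", "intensity", "all",
                         method = "map", seed = 75)
  i1 <- tr1[tr1$term == "trait_x_mask", "estimate"]
  i2 <- tr2[tr2$term == "trait_x_mask", "estimate"]
  m1 <- tr1[tr1$term == "trait", "estimate"]
  m2 <- tr2[tr2$term == "trait", "estimate"]
  expect_lt(abs(i1 + i2), 0.02)
  expect_lt(abs(m1 - m2), 0.02)
})

test_that("missing scores for retained participants are an error", {
  ex <- apply_exclusion(small_cohort())
  parts <- ex$participants[-1, ]
  expect_error(fit_trait_model(small_table(), parts, "tas", "intensity",
                               method = "map"),
               "missing tas")
})
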