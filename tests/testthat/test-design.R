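spec <- design_spec()

test_that("generated design reproduces the trial structure exactly", {
  des <- generate_design(spec, "P001", seed = 3)
  expect_equal(nrow(des), 274)
  expect_equal(sum(des$trial_type == "emotion"), 240)
  expect_equal(sum(des$trial_type == "neutral"), 20)
  expect_equal(sum(des$trial_type == "catch"), 14)
  expect_equal(as.numeric(table(des$block)), c(137, 137))
  expect_equal(as.numeric(table(des$block[des$trial_type == "catch"])), c(7, 7))
  # every emotional cell appears exactly once (exhaustive count)
  emo <- des[des$trial_type == "emotion", ]
  counts <- table(emo$identity, emo$emotion, emo$mask, emo$intensity)
  expect_true(all(counts == 1))
  expect_equal(sum(counts), 240)
  # neutral trials have no expression intensity
  expect_true(all(des$intensity[des$trial_type == "neutral"] == "none"))
})

test_that("design order is seed-deterministic, counts are seed-invariant", {
  d1 <- generate_design(spec, "P001", seed = 11)
  d2 <- generate_design(spec, "P001", seed = 11)
  d3 <- generate_design(spec, "P001", seed = 12)
  expect_identical(d1, d2)
  expect_false(identical(d1$identity, d3$identity))
  expect_equal(table(d3$trial_type), table(d1$trial_type))
  expect_equal(as.numeric(table(d3$block)), c(137, 137))
})

test_that("inconsistent design specifications are rejected", {
  expect_error(design_spec(n_catch = 13), "blocks")
})

test_that("degenerate concentrations produce the expected error distributions", {
  cells <- expand.grid(emotion = "disgust", mask = "yes", intensity = "full",
                       stringsAsFactors = FALSE)
  one_cell <- function(mu, cv) {
    cells$mu_deg <- mu; cells$circvar <- cv
    cells$intensity_px <- 150; cells$intensity_sd_px <- 10
    default_truth(cells = cells, re_sd_loc_deg = 0, re_sd_logk = 0)
  }
  des <- data.frame(participant_id = "P001", trial_type = "emotion",
                    emotion = "disgust", mask = "yes", intensity = "full")
  des <- des[rep(1, 5000), ]

  # near-infinite concentration: all centred errors collapse onto the bias
  tr <- simulate_responses(des, one_cell(0, kappa_to_circvar(1e8)), seed = 21)
  tab <- prepare_model_table(tr)
  expect_lt(max(abs(tab$error_deg)), 0.05)

  # zero concentration: uniform circle, circular variance near 1
  tr0 <- simulate_responses(des, one_cell(0, 1), seed = 22)
  tab0 <- prepare_model_table(tr0)
  expect_lt(abs(circular_variance(tab0$error_deg) - 1), 0.03)
})

test_that("pooled circular mean recovers an 18-degree masked-disgust bias", {
  truth <- default_truth()
  truth$cells$mu_deg[truth$cells$emotion == "disgust" &
                       truth$cells$mask == "yes"] <- 18
  co <- simulate_cohort(200, truth = truth, seed = 23)
  tab <- prepare_model_table(co$trials)
  cell <- tab[tab$emotion == "disgust" & tab$mask == "yes", ]
  expect_lt(abs(circular_mean(cell$error_deg) - 18), 2)
})

test_that("concentration MLE recovers generator truth across the kappa range", {
  # single-sample MLE at n = 5000 carries ~1.5% sampling error, so the
  # recovery check is on the replicate-averaged estimate
  set.seed(24)
  for (k in c(1, 5, 15)) {
    khat <- replicate(40, kappa_mle(rvonmises(5000, 0, k) * 180 / pi))
    expect_lt(abs(mean(khat) - k) / k, 0.02)
    mu_hat <- replicate(10, circular_mean(rvonmises(5000, 0.35, k) * 180 / pi))
    expect_lt(abs(mean(mu_hat) - 0.35 * 180 / pi), 1)
  }
})

test_that("catch correctness tracks the assigned accuracy", {
  des <- data.frame(participant_id = "P001", trial_type = "catch",
                    emotion = "none", mask = "none", intensity = "none")
  des <- des[rep(1, 700), ]
  eff <- list(loc_deg = c(P001 = 0), logk = c(P001 = 0),
              catch_accuracy = c(P001 = 0.8))
  tr <- simulate_responses(des, seed = 25, participant_effects = eff)
  expect_lt(abs(mean(tr$catch_correct) - 0.8), 0.05)
  # quota model: realised rate equals the assigned accuracy up to rounding
  trq <- simulate_responses(des, seed = 25, participant_effects = eff,
                            catch_model = "quota")
  expect_equal(mean(trq$catch_correct), round(0.8 * 700) / 700)
})

test_that("missing truth cells are reported", {
  truth <- default_truth()
  truth$cells <- truth$cells[truth$cells$emotion != "fear", ]
  des <- generate_design(spec, "P001", seed = 1)
  expect_error(simulate_responses(des, truth), "missing design cells")
})

test_that("simulated cohorts join, reproduce and vary only in order", {
  co <- small_cohort()
  expect_setequal(unique(co$trials$participant_id),
                  co$participants$participant_id)
  co2 <- simulate_cohort(8, seed = 101)
  expect_identical(co$trials, co2$trials)
  co3 <- simulate_cohort(8, seed = 102)
  expect_false(identical(co$trials$identity, co3$trials$identity))
  expect_equal(table(co3$trials$trial_type), table(co$trials$trial_type))
})

test_that("trait scores match their generating moments", {
  co <- simulate_cohort(1000, seed = 26)
  expect_lt(abs(mean(co$participants$tas) - 14.9), 0.5)
  expect_lt(abs(mean(co$participants$aq) - 52.1), 0.7)
  expect_lt(abs(sd(co$participants$tas) - 6.62), 0.5)
})

test_that("truth tables round-trip through YAML", {
  truth <- default_truth(re_sd_loc_deg = 3.3, tas_mean = 16)
  path <- tempfile(fileext = ".yaml")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$cells$mu_deg, truth$cells$mu_deg)
  expect_equal(back$cells$kappa, truth$cells$kappa)
  expect_equal(back$re_sd_loc_deg, 3.3)
  expect_equal(back$tas_mean, 16)
})

test_that("cohort CSV files round-trip", {
  dir <- tempfile()
  co <- small_cohort()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$trials), nrow(co$trials))
  expect_equal(back$participants$tas, co$participants$tas)
})
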