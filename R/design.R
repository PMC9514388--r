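#' Experimental design specification
#'
#' The trial structure of the recognition task: 10 face identities by 6
#' basic emotions by mask (worn / not worn) by expression intensity (full =
#' 100%, subtle = 40%) gives 240 emotional trials; 10 identities by mask
#' give 20 neutral trials; 14 attention-check (catch) trials complete a
#' 274-trial session split into 2 blocks of 137 with 7 catch trials each.
#'
#' @param n_identities number of face identities.
#' @param emotions displayed emotion labels.
#' @param mask_levels mask factor levels, reference first.
#' @param intensity_levels expression-intensity levels.
#' @param n_neutral_per_mask neutral faces per mask level.
#' @param n_catch total catch trials.
#' @param n_blocks number of blocks.
#' @return An object of class `"gew_design_spec"`.
#' @export
design_spec <- function(n_identities = 10,
                        emotions = c("anger", "disgust", "fear",
                                     "happiness", "sadness", "surprise"),
                        mask_levels = c("no", "yes"),
                        intensity_levels = c("full", "subtle"),
                        n_neutral_per_mask = 10,
                        n_catch = 14,
                        n_blocks = 2) {
  n_emotional <- n_identities * length(emotions) *
    length(mask_levels) * length(intensity_levels)
  n_neutral <- n_neutral_per_mask * length(mask_levels)
  n_total <- n_emotional + n_neutral + n_catch
  if (n_total %% n_blocks != 0 || n_catch %% n_blocks != 0 ||
      n_emotional %% n_blocks != 0 || n_neutral %% n_blocks != 0)
    stop("design does not split evenly into ", n_blocks, " blocks")
  structure(
    list(n_identities = n_identities, emotions = emotions,
         mask_levels = mask_levels, intensity_levels = intensity_levels,
         n_neutral_per_mask = n_neutral_per_mask, n_catch = n_catch,
         n_blocks = n_blocks,
         n_emotional = n_emotional, n_neutral = n_neutral, n_total = n_total,
         trials_per_block = n_total / n_blocks,
         catch_per_block = n_catch / n_blocks),
    class = "gew_design_spec")
}

#' @export
print.gew_design_spec <- function(x, ...) {
  cat(sprintf(
    "GEW task design: %d emotional + %d neutral + %d catch = %d trials (%d blocks of %d)\n",
    x$n_emotional, x$n_neutral, x$n_catch, x$n_total, x$n_blocks,
    x$trials_per_block))
  invisible(x)
}

# Cohort-level block composition: each (emotion, mask, intensity) cell
# splits its identities evenly between blocks, as do neutral and catch
# trials. Composition is fixed across participants of a cohort; only the
# within-block presentation order varies by participant.
block_composition <- function(spec, seed) {
  set.seed(seed)
  ids <- c(sprintf("F%02d", seq_len(spec$n_identities / 2)),
           sprintf("M%02d", seq_len(spec$n_identities - spec$n_identities / 2)))
  half <- spec$n_identities / spec$n_blocks
  emo <- expand.grid(identity = ids, emotion = spec$emotions,
                     mask = spec$mask_levels, intensity = spec$intensity_levels,
                     stringsAsFactors = FALSE)
  emo$trial_type <- "emotion"
  cell <- interaction(emo$emotion, emo$mask, emo$intensity, drop = TRUE)
  emo$block <- NA_integer_
  for (cl in levels(cell)) {
    rows <- which(cell == cl)
    emo$block[sample(rows)] <- rep(seq_len(spec$n_blocks), each = half)
  }
  neu <- expand.grid(identity = ids, mask = spec$mask_levels,
                     stringsAsFactors = FALSE)
  neu$emotion <- "neutral"; neu$intensity <- "none"; neu$trial_type <- "neutral"
  neu$block <- NA_integer_
  for (m in spec$mask_levels) {
    rows <- which(neu$mask == m)
    neu$block[sample(rows)] <- rep(seq_len(spec$n_blocks),
                                   each = spec$n_neutral_per_mask / spec$n_blocks)
  }
  cat_df <- data.frame(identity = sprintf("C%02d", seq_len(spec$n_catch)),
                       emotion = "none", mask = "none", intensity = "none",
                       trial_type = "catch",
                       block = rep(seq_len(spec$n_blocks),
                                   each = spec$catch_per_block))
  cols <- c("block", "trial_type", "emotion", "mask", "intensity", "identity")
  rbind(emo[cols], neu[cols], cat_df[cols])
}

#' Generate one participant's trial sequence
#'
#' Builds the full 274-trial design for a participant: the block
#' composition is taken as given (fixed across a cohort) and the trial
#' order within each block is a seeded permutation. Blocks are not
#' reshuffled relative to each other.
#'
#' @param spec a [design_spec()].
#' @param participant_id identifier recorded on every trial.
#' @param seed integer seed for the within-block permutations.
#' @param composition optional block composition from an enclosing cohort;
#'   by default a fresh composition seeded by `seed` is used.
#' @return A data.frame of trials (no responses) with columns
#'   `participant_id`, `block`, `trial_index`, `trial_type`, `emotion`,
#'   `mask`, `intensity`, `identity`.
#' @export
generate_design <- function(spec = design_spec(), participant_id = "P001",
                            seed = 1, composition = NULL) {
  if (is.null(composition)) composition <- block_composition(spec, seed)
  set.seed(seed)
  ordered <- do.call(rbind, lapply(seq_len(spec$n_blocks), function(b) {
    blk <- composition[composition$block == b, ]
    blk[sample(nrow(blk)), ]
  }))
  ordered$participant_id <- participant_id
  ordered$trial_index <- seq_len(nrow(ordered))
  rownames(ordered) <- NULL
  ordered[c("participant_id", "block", "trial_index", "trial_type",
            "emotion", "mask", "intensity", "identity")]
}

#' Generating ("truth") parameters for synthetic cohorts
#'
#' One row per (emotion, mask, intensity) cell with the generating bias
#' `mu_deg`, uncertainty (as circular variance, converted internally to a
#' Von Mises concentration), mean perceived intensity and radial noise SD,
#' plus cohort-level parameters: participant random-effect SDs for location
#' (degrees) and log-concentration, catch-accuracy Beta parameters,
#' trait-score means/SDs, and the neutral-trial response model.
#'
#' Cell defaults are loosely calibrated to the magnitudes reported for this
#' paradigm (e.g. a ~18 degree disgust bias only under a mask, uncertainty
#' roughly doubling under a mask, intensities of 130-200 px); they are
#' plausible generator settings, not ground truth for any real dataset.
#'
#' @param cells optional replacement data.frame with columns `emotion`,
#'   `mask`, `intensity`, `mu_deg`, `circvar`, `intensity_px`,
#'   `intensity_sd_px`.
#' @param re_sd_loc_deg SD of participant location effects (degrees).
#' @param re_sd_logk SD of participant log-concentration effects.
#' @param catch_beta shape parameters of the Beta distribution of
#'   per-participant catch accuracy.
#' @param tas_mean,tas_sd,aq_mean,aq_sd trait-score moments.
#' @param neutral_circvar,neutral_radius_px,neutral_radius_sd_px neutral-
#'   trial response model (low-radius, high-spread clicks).
#' @return An object of class `"gew_truth"`.
#' @export
default_truth <- function(cells = NULL,
                          re_sd_loc_deg = 4, re_sd_logk = 0.2,
                          catch_beta = c(24, 1),
                          tas_mean = 14.9, tas_sd = 6.62,
                          aq_mean = 52.1, aq_sd = 8.53,
                          neutral_circvar = 0.9, neutral_radius_px = 40,
                          neutral_radius_sd_px = 25) {
  if (is.null(cells)) {
    base <- data.frame(
      emotion  = rep(c("surprise", "sadness", "happiness",
                       "fear", "disgust", "anger"), each = 2),
      mask     = rep(c("yes", "no"), 6),
      mu_deg   = c(-0.6, -0.8, 24.3, 29.3, 2.6, 2.8,
                   6.3, 5.5, 17.7, -0.7, -22.4, -20.2),
      circvar  = c(0.44, 0.17, 0.53, 0.42, 0.42, 0.16,
                   0.48, 0.47, 0.45, 0.20, 0.47, 0.28),
      int_base = c(137, 181, 128, 148, 135, 174,
                   134, 156, 166, 197, 154, 164))
    cells <- do.call(rbind, lapply(c("full", "subtle"), function(lv) {
      d <- base
      d$intensity <- lv
      # subtle expressions are perceived less intense, and more so when masked
      d$intensity_px <- d$int_base + if (lv == "full") 15 else
        -15 - ifelse(d$mask == "yes", 10, 0)
      d
    }))
    cells$int_base <- NULL
    cells$intensity_sd_px <- 40
  }
  stopifnot(all(c("emotion", "mask", "intensity", "mu_deg", "circvar",
                  "intensity_px", "intensity_sd_px") %in% names(cells)),
            all(cells$circvar > 0 & cells$circvar <= 1),
            all(cells$intensity_px >= 0),
            re_sd_loc_deg >= 0, re_sd_logk >= 0)
  cells$kappa <- circvar_to_kappa(cells$circvar)
  structure(
    list(cells = cells,
         re_sd_loc_deg = re_sd_loc_deg, re_sd_logk = re_sd_logk,
         catch_beta = catch_beta,
         tas_mean = tas_mean, tas_sd = tas_sd,
         aq_mean = aq_mean, aq_sd = aq_sd,
         neutral_circvar = neutral_circvar,
         neutral_radius_px = neutral_radius_px,
         neutral_radius_sd_px = neutral_radius_sd_px),
    class = "gew_truth")
}

#' Read / write a truth table as YAML
#'
#' Round-trips the synthetic-cohort generating parameters through a YAML
#' file so simulation experiments are fully declared by configuration.
#'
#' @param path YAML file path.
#' @return `read_truth()` returns a `"gew_truth"` object.
#' @export
read_truth <- function(path) {
  cfg <- yaml::read_yaml(path)
  cells <- as.data.frame(lapply(cfg$cells, unlist), stringsAsFactors = FALSE)
  default_truth(cells = cells,
                re_sd_loc_deg = cfg$re_sd_loc_deg, re_sd_logk = cfg$re_sd_logk,
                catch_beta = unlist(cfg$catch_beta),
                tas_mean = cfg$tas_mean, tas_sd = cfg$tas_sd,
                aq_mean = cfg$aq_mean, aq_sd = cfg$aq_sd,
                neutral_circvar = cfg$neutral_circvar,
                neutral_radius_px = cfg$neutral_radius_px,
                neutral_radius_sd_px = cfg$neutral_radius_sd_px)
}

#' @rdname read_truth
#' @param truth a `"gew_truth"` object.
#' @export
write_truth <- function(truth, path) {
  cells <- truth$cells
  cells$kappa <- NULL
  yaml::write_yaml(
    list(cells = as.list(cells),
         re_sd_loc_deg = truth$re_sd_loc_deg, re_sd_logk = truth$re_sd_logk,
         catch_beta = truth$catch_beta,
         tas_mean = truth$tas_mean, tas_sd = truth$tas_sd,
         aq_mean = truth$aq_mean, aq_sd = truth$aq_sd,
         neutral_circvar = truth$neutral_circvar,
         neutral_radius_px = truth$neutral_radius_px,
         neutral_radius_sd_px = truth$neutral_radius_sd_px),
    path)
  invisible(path)
}

#' Draw Von Mises random angles
#'
#' Best-Fisher rejection sampling, vectorised in batches; reduces to
#' uniform draws on the circle at `kappa = 0`.
#'
#' @param n number of draws.
#' @param mu_rad location (radians).
#' @param kappa concentration (>= 0).
#' @return Angles in radians, wrapped to `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu_rad = 0, kappa = 1) {
  stopifnot(kappa >= 0, is.finite(kappa))
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8)
    return(wrap_deg(stats::runif(n, -180, 180)) * pi / 180)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.6))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[keep] - 0.5) * acos(pmax(-1, pmin(1, f[keep]))))
  }
  theta <- mu_rad + out[seq_len(n)]
  wrap_deg(theta * 180 / pi) * pi / 180
}

#' Simulate click responses for a trial design
#'
#' Forward model of the analysis assumptions. Emotional trials draw a
#' centred error from Von Mises(`mu_cell` + participant location effect,
#' `kappa_cell * exp(participant scale effect)`) around the displayed
#' emotion's correct angle, and a radius from the cell's Gaussian intensity
#' model truncated at zero. Neutral trials draw low-radius, high-spread
#' clicks; catch trials receive a Bernoulli correctness flag from the
#' participant's catch accuracy.
#'
#' @param design trial table from [generate_design()].
#' @param truth a [default_truth()] object covering all design cells.
#' @param geometry a [gew_geometry()].
#' @param seed integer seed.
#' @param participant_effects optional named list with `loc_deg`, `logk`
#'   and `catch_accuracy` per participant; drawn from `truth` when absent.
#' @param catch_model `"bernoulli"` draws each catch flag independently
#'   with the participant's accuracy; `"quota"` fixes the number of
#'   correct catch trials at `round(accuracy * n_catch)` (randomly
#'   placed), so the realised rate equals the assigned accuracy.
#' @return The design with added `click_x_px`, `click_y_px` and
#'   `catch_correct` columns.
#' @export
simulate_responses <- function(design, truth = default_truth(),
                               geometry = gew_geometry(), seed = 1,
                               participant_effects = NULL,
                               catch_model = c("bernoulli", "quota")) {
  catch_model <- match.arg(catch_model)
  set.seed(seed)
  pids <- unique(design$participant_id)
  if (is.null(participant_effects)) {
    participant_effects <- list(
      loc_deg = stats::setNames(stats::rnorm(length(pids), 0, truth$re_sd_loc_deg), pids),
      logk = stats::setNames(stats::rnorm(length(pids), 0, truth$re_sd_logk), pids),
      catch_accuracy = stats::setNames(
        stats::rbeta(length(pids), truth$catch_beta[1], truth$catch_beta[2]), pids))
  }
  cells <- truth$cells
  key <- function(e, m, i) paste(e, m, i, sep = ".")
  rownames(cells) <- key(cells$emotion, cells$mask, cells$intensity)

  n <- nrow(design)
  angle <- radius <- rep(NA_real_, n)
  catch_correct <- rep(NA, n)

  emo <- design$trial_type == "emotion"
  if (any(emo)) {
    k_cell <- key(design$emotion[emo], design$mask[emo], design$intensity[emo])
    miss <- setdiff(unique(k_cell), rownames(cells))
    if (length(miss))
      stop("truth table is missing design cells: ", paste(miss, collapse = ", "))
    cell <- cells[k_cell, ]
    pid <- design$participant_id[emo]
    mu <- (cell$mu_deg + participant_effects$loc_deg[pid]) * pi / 180
    kap <- cell$kappa * exp(participant_effects$logk[pid])
    err <- vapply(seq_along(mu), function(i) rvonmises(1, mu[i], kap[i]), numeric(1))
    angle[emo] <- wrap360(correct_angle(design$emotion[emo], geometry) +
                            err * 180 / pi)
    radius[emo] <- pmax(0, stats::rnorm(sum(emo), cell$intensity_px,
                                        cell$intensity_sd_px))
  }
  neu <- design$trial_type == "neutral"
  if (any(neu)) {
    kap0 <- circvar_to_kappa(truth$neutral_circvar)
    angle[neu] <- wrap360(rvonmises(sum(neu), 0, kap0) * 180 / pi)
    radius[neu] <- pmax(0, stats::rnorm(sum(neu), truth$neutral_radius_px,
                                        truth$neutral_radius_sd_px))
  }
  ctch <- design$trial_type == "catch"
  if (any(ctch)) {
    if (catch_model == "bernoulli") {
      acc <- participant_effects$catch_accuracy[design$participant_id[ctch]]
      catch_correct[ctch] <- stats::runif(sum(ctch)) < acc
    } else {
      for (p in unique(design$participant_id[ctch])) {
        rows <- which(ctch & design$participant_id == p)
        n_ok <- round(participant_effects$catch_accuracy[p] * length(rows))
        flags <- rep(FALSE, length(rows))
        flags[sample(length(rows), n_ok)] <- TRUE
        catch_correct[rows] <- flags
      }
    }
  }

  out <- design
  xy <- polar_to_click(ifelse(is.na(radius), 0, radius),
                       ifelse(is.na(angle), 0, angle), geometry)
  out$click_x_px <- ifelse(is.na(radius), NA_real_, xy$x)
  out$click_y_px <- ifelse(is.na(radius), NA_real_, xy$y)
  out$catch_correct <- catch_correct
  out
}

#' Simulate a complete synthetic cohort
#'
#' Generates `n_participants` full sessions (design + responses) plus a
#' participant table with TAS-20 and AQ trait scores and the assigned catch
#' accuracy. Block composition is drawn once at cohort level; within-block
#' order and all responses are drawn per participant from seeds derived
#' from `seed`.
#'
#' `n_low_catch` participants (default 0) are forced to a sub-threshold
#' catch accuracy (uniform on 0.3-0.7), which supports exclusion-rule
#' fixtures such as a 139-participant cohort retaining 129. Cohort catch
#' flags use the quota model (realised accuracy = assigned accuracy, see
#' [simulate_responses()]) so such fixtures are exact; clean participants
#' are kept at assigned accuracy >= 0.76.
#'
#' @param n_participants cohort size.
#' @param truth a [default_truth()].
#' @param spec a [design_spec()].
#' @param geometry a [gew_geometry()].
#' @param seed integer master seed.
#' @param n_low_catch number of participants assigned failing catch
#'   accuracy.
#' @return A list with data.frames `trials` and `participants`.
#' @export
simulate_cohort <- function(n_participants, truth = default_truth(),
                            spec = design_spec(), geometry = gew_geometry(),
                            seed = 1, n_low_catch = 0) {
  stopifnot(n_participants >= 1, n_low_catch <= n_participants)
  set.seed(seed)
  pids <- sprintf("P%03d", seq_len(n_participants))
  pseeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  composition <- block_composition(spec, seed)

  set.seed(seed + 1L)
  eff <- list(
    loc_deg = stats::setNames(stats::rnorm(n_participants, 0, truth$re_sd_loc_deg), pids),
    logk = stats::setNames(stats::rnorm(n_participants, 0, truth$re_sd_logk), pids),
    catch_accuracy = stats::setNames(
      stats::rbeta(n_participants, truth$catch_beta[1], truth$catch_beta[2]), pids))
  eff$catch_accuracy <- pmax(eff$catch_accuracy, 0.76)  # clean by default
  if (n_low_catch > 0) {
    low <- sample(pids, n_low_catch)
    eff$catch_accuracy[low] <- stats::runif(n_low_catch, 0.3, 0.7)
  }
  tas <- pmax(0, round(stats::rnorm(n_participants, truth$tas_mean, truth$tas_sd)))
  aq <- pmax(0, round(stats::rnorm(n_participants, truth$aq_mean, truth$aq_sd)))

  trials <- do.call(rbind, lapply(seq_len(n_participants), function(i) {
    des <- generate_design(spec, pids[i], seed = pseeds[i],
                           composition = composition)
    simulate_responses(des, truth, geometry, seed = pseeds[i],
                       participant_effects = eff, catch_model = "quota")
  }))
  rownames(trials) <- NULL
  participants <- data.frame(participant_id = pids, tas = tas, aq = aq,
                             catch_accuracy_true = unname(eff$catch_accuracy))
  list(trials = trials, participants = participants)
}

#' Write a simulated cohort to CSV files
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of `trials.csv` and `participants.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tp <- file.path(dir, "trials.csv")
  pp <- file.path(dir, "participants.csv")
  utils::write.csv(cohort$trials, tp, row.names = FALSE)
  utils::write.csv(cohort$participants, pp, row.names = FALSE)
  invisible(c(trials = tp, participants = pp))
}

#' Read a cohort from CSV files
#'
#' @param dir directory containing `trials.csv` and `participants.csv`.
#' @return A list with data.frames `trials` and `participants`.
#' @export
read_cohort <- function(dir) {
  list(trials = utils::read.csv(file.path(dir, "trials.csv")),
       participants = utils::read.csv(file.path(dir, "participants.csv")))
}
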