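#' Default pipeline configuration
#'
#' All knobs of the end-to-end analysis in one list: geometry, design,
#' generating truth, cohort size, exclusion threshold, HPDI mass, prior
#' scales, sampler settings and seed. Any entry can be overridden in a
#' YAML file read by [read_config()].
#'
#' @param n_participants simulated cohort size.
#' @param seed master seed.
#' @return A `"gew_config"` list.
#' @export
default_config <- function(n_participants = 20, seed = 1) {
  structure(
    list(n_participants = n_participants,
         n_low_catch = 0,
         exclusion_threshold = 0.75,
         hpdi_mass = 0.95,
         sampler = list(method = "map", chains = 2, warmup = 500,
                        iter = 500, laplace_draws = 1000),
         priors = list(b_loc_sd = 1, b_scale_sd = 1, re_sd = 0.5),
         seed = seed),
    class = "gew_config")
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override [default_config()] entries;
#' validation rejects out-of-range thresholds.
#'
#' @param path YAML file path.
#' @return A `"gew_config"` list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      utils::modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$exclusion_threshold < 0 || cfg$exclusion_threshold > 1)
    stop("exclusion_threshold must lie in [0, 1]")
  if (cfg$hpdi_mass <= 0 || cfg$hpdi_mass > 1)
    stop("hpdi_mass must lie in (0, 1]")
  if (cfg$n_participants < 1) stop("n_participants must be >= 1")
  structure(cfg, class = "gew_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, stage, cfg, extra = list()) {
  man <- c(list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
                timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the analysis pipeline
#'
#' Orchestrates the full workflow on a synthetic cohort, writing plain
#' CSV/JSON artifacts to `out_dir`. Stages build on each other; each run
#' writes a `manifest.json` recording the seed and a hash of the
#' configuration that produced the outputs.
#'
#' Stages: `"simulate"` (cohort CSVs), `"preprocess"` (analysis table and
#' exclusion report), `"indices"` (descriptive bias / uncertainty /
#' intensity table), `"fit"` (posterior draws and diagnostics for the
#' angular and intensity models), `"contrasts"` (mask-effect and
#' interaction tables), `"compare"` (LOO comparison of the full and
#' reduced intensity models), `"traits"` (TAS/AQ covariate results), and
#' `"report"` (all of the above plus a label-frequency figure). Earlier
#' stages are run automatically when their artifacts are missing.
#'
#' @param command one of the stage names above.
#' @param config a `"gew_config"` list or the path of a YAML file.
#' @param out_dir output directory.
#' @return Invisibly, a list of the artifacts produced.
#' @export
run_pipeline <- function(command = c("simulate", "preprocess", "indices",
                                     "fit", "contrasts", "compare",
                                     "traits", "report"),
                         config = default_config(), out_dir = "gew_output") {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("simulate", "preprocess", "indices", "fit", "contrasts",
              "compare", "traits", "report")
  todo <- stages[seq_len(match(command, stages))]
  if (command != "report") todo <- setdiff(todo, "report")
  arts <- list()

  message("stage: simulate")
  if ("simulate" %in% todo &&
      !file.exists(file.path(out_dir, "trials.csv"))) {
    cohort <- simulate_cohort(cfg$n_participants, seed = cfg$seed,
                              n_low_catch = cfg$n_low_catch)
    write_cohort(cohort, out_dir)
  }
  cohort <- read_cohort(out_dir)
  arts$trials <- file.path(out_dir, "trials.csv")

  if (any(c("preprocess", "indices", "fit", "contrasts", "compare",
            "traits", "report") %in% todo)) {
    message("stage: preprocess")
    excl <- apply_exclusion(cohort, cfg$exclusion_threshold)
    tab <- prepare_model_table(excl$trials)
    utils::write.csv(tab, file.path(out_dir, "analysis_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(excl$report, file.path(out_dir, "exclusions.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    arts$analysis_table <- tab
    arts$exclusions <- excl$report
  }

  if (any(c("indices", "report") %in% todo)) {
    message("stage: indices")
    idx <- condition_indices(tab)
    utils::write.csv(idx, file.path(out_dir, "indices.csv"), row.names = FALSE)
    arts$indices <- idx
  }

  if (any(c("fit", "contrasts", "compare", "traits", "report") %in% todo)) {
    message("stage: fit")
    sm <- cfg$sampler
    pr <- gew_priors(b_loc_sd = cfg$priors$b_loc_sd,
                     b_scale_sd = cfg$priors$b_scale_sd,
                     re_sd = cfg$priors$re_sd)
    fit_args <- list(data = tab, priors = pr, method = sm$method,
                     chains = sm$chains, warmup = sm$warmup, iter = sm$iter,
                     laplace_draws = sm$laplace_draws, seed = cfg$seed)
    fit_vm <- do.call(gewls, c(list(
      error_deg ~ 0 + emotion:mask:intensity, family = "vonmises"), fit_args))
    fit_px <- do.call(gewls, c(list(
      radius_px ~ 0 + emotion:mask:intensity, family = "gaussian"), fit_args))
    for (nm in c("vonmises", "gaussian")) {
      f <- if (nm == "vonmises") fit_vm else fit_px
      utils::write.csv(as.data.frame(f$draws),
                       file.path(out_dir, paste0("draws_", nm, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(seed = cfg$seed, method = f$method,
             rhat = as.list(f$diagnostics$rhat),
             converged = f$diagnostics$converged),
        file.path(out_dir, paste0("diagnostics_", nm, ".json")),
        auto_unbox = TRUE, pretty = TRUE)
    }
    arts$fit_vonmises <- fit_vm
    arts$fit_gaussian <- fit_px
  }

  if (any(c("contrasts", "report") %in% todo)) {
    message("stage: contrasts")
    tdir <- file.path(out_dir, "results_tables")
    dir.create(tdir, showWarnings = FALSE)
    rt_vm <- results_table(fit_vm)
    rt_px <- results_table(fit_px)
    cp_vm <- cell_posteriors(fit_vm); cp_px <- cell_posteriors(fit_px)
    inter <- rbind(
      cbind(parameter = "bias", intensity_interaction(cp_vm)),
      cbind(parameter = "uncertainty", ratio_interaction(cp_vm)),
      cbind(parameter = "intensity", intensity_interaction(cp_px)))
    utils::write.csv(rt_vm, file.path(tdir, "mask_effect_angular.csv"),
                     row.names = FALSE)
    utils::write.csv(rt_px, file.path(tdir, "mask_effect_intensity.csv"),
                     row.names = FALSE)
    utils::write.csv(inter, file.path(tdir, "intensity_interactions.csv"),
                     row.names = FALSE)
    arts$results <- list(angular = rt_vm, intensity = rt_px,
                         interactions = inter)
  }

  if (any(c("compare", "report") %in% todo)) {
    message("stage: compare")
    reduced <- do.call(gewls, c(list(
      error_deg ~ emotion * mask * intensity
        - emotion:mask:intensity, family = "vonmises"), fit_args))
    full <- do.call(gewls, c(list(
      error_deg ~ emotion * mask * intensity, family = "vonmises"), fit_args))
    cmp <- loo_compare(full = full, reduced = reduced, seed = cfg$seed)
    jsonlite::write_json(cmp, file.path(out_dir, "comparison.json"),
                         pretty = TRUE, digits = NA)
    arts$comparison <- cmp
  }

  if (any(c("traits", "report") %in% todo)) {
    message("stage: traits")
    parts <- excl$participants
    tr <- do.call(rbind, lapply(c("tas", "aq"), function(t)
      rbind(fit_trait_model(tab, parts, t, "bias_uncertainty", "all",
                            method = "map", seed = cfg$seed),
            fit_trait_model(tab, parts, t, "intensity", "all",
                            method = "map", seed = cfg$seed))))
    jsonlite::write_json(as.data.frame(tr),
                         file.path(out_dir, "traits_results.json"),
                         pretty = TRUE, digits = NA)
    arts$traits <- tr
  }

  if ("report" %in% todo) {
    message("stage: report")
    freqs <- label_frequencies(excl$trials)
    utils::write.csv(freqs, file.path(out_dir, "label_frequencies.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "label_frequencies.png"),
                   width = 900, height = 900)
    plot_label_frequencies(freqs)
    grDevices::dev.off()
    arts$label_frequencies <- freqs
  }

  write_manifest(out_dir, command, cfg)
  invisible(arts)
}
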