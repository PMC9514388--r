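#' Centre trait scores
#'
#' Mean-centres a vector of questionnaire totals (TAS-20 or AQ); the
#' original mean is attached as an attribute so reports can state it.
#' Centring is idempotent up to floating error.
#'
#' @param scores numeric scores for >= 2 participants.
#' @return Centred scores with attribute `"center"`.
#' @export
center_scores <- function(scores) {
  stopifnot(length(scores) >= 2)
  if (stats::sd(scores) == 0) warning("trait scores are constant (zero variance)")
  structure(scores - mean(scores), center = mean(scores))
}

#' Trait-covariate models of the perception-space indices
#'
#' Fits the location-scale model with a centred trait score (TAS-20 or
#' AQ), a sum-coded mask factor and their interaction as fixed effects,
#' optionally restricted to subtle expressions. With sum contrasts the
#' mask main effect is half the masked-unmasked difference and the
#' trait coefficient is the trait slope at the average of the two mask
#' conditions. The displayed emotion enters as a cell-means nuisance
#' factor by default so trait effects are not confounded with the emotion
#' mix.
#'
#' One Von Mises fit yields both the bias results (trait terms on the
#' location predictor) and the uncertainty results (trait terms on the
#' scale predictor); a Gaussian fit on the radius yields the perceived-
#' intensity results. Each reported coefficient carries its posterior
#' median, SD, 95% HPDI and a Savage-Dickey `logBF01` against 0.
#'
#' @param analysis_table table from [prepare_model_table()].
#' @param participants participant table with the trait score column.
#' @param trait `"tas"` or `"aq"` (column name in `participants`).
#' @param index `"bias_uncertainty"` (one Von Mises fit covering both
#'   angular indices) or `"intensity"`.
#' @param subset `"all"` or `"subtle_only"`.
#' @param include_emotion keep the emotion nuisance factor.
#' @param ... passed to [gewls()] (e.g. `method = "map"`, seeds, chains).
#' @return A `"gew_traits"` data.frame: one row per reported coefficient
#'   with `trait`, `index`, `subset`, `term`, `estimate`, `sd`,
#'   `hpdi_low`, `hpdi_high`, `logBF01`; the fit is attached as attribute
#'   `"fit"`.
#' @export
fit_trait_model <- function(analysis_table, participants,
                            trait = c("tas", "aq"),
                            index = c("bias_uncertainty", "intensity"),
                            subset = c("all", "subtle_only"),
                            include_emotion = TRUE, ...) {
  trait <- match.arg(trait)
  index <- match.arg(index)
  subset <- match.arg(subset)
  if (!trait %in% names(participants))
    stop("participants table has no '", trait, "' column")

  tab <- analysis_table
  if (subset == "subtle_only") tab <- tab[tab$intensity == "subtle", ]
  sc <- participants[[trait]][match(tab$participant_id,
                                    participants$participant_id)]
  if (anyNA(sc))
    stop("missing ", trait, " scores for retained participants")
  tab$trait_c <- as.numeric(center_scores(sc))
  if (!is.factor(tab$mask)) tab$mask <- factor(tab$mask, levels = c("no", "yes"))

  rhs <- if (include_emotion) "0 + emotion + mask * trait_c" else "mask * trait_c"
  fam <- if (index == "intensity") "gaussian" else "vonmises"
  resp <- if (index == "intensity") "radius_px" else "error_deg"
  form <- stats::as.formula(paste(resp, "~", rhs))
  fit <- gewls(form, data = tab, family = fam,
               contrasts = list(mask = "contr.sum"), ...)

  terms_loc <- c(main = "b_loc[trait_c]", interaction = "b_loc[mask1:trait_c]")
  terms_scale <- c(main = "b_scale[trait_c]", interaction = "b_scale[mask1:trait_c]")
  wanted <- if (index == "intensity") {
    data.frame(index = "intensity", par = terms_loc, prior = "loc")
  } else {
    rbind(data.frame(index = "bias", par = terms_loc, prior = "loc"),
          data.frame(index = "uncertainty", par = terms_scale, prior = "scale"))
  }
  wanted$term <- rep(c("trait", "trait_x_mask"), nrow(wanted) / 2)

  rp <- fit$resolved_priors
  out <- do.call(rbind, lapply(seq_len(nrow(wanted)), function(i) {
    par <- wanted$par[i]
    if (!par %in% colnames(fit$draws))
      stop("coefficient not found in fit: ", par)
    dr <- fit$draws[, par]
    prior_sd <- if (wanted$prior[i] == "loc") rp$bloc_sd[1] else rp$bscale_sd[1]
    h <- hpdi(dr)
    data.frame(trait = trait, index = wanted$index[i], subset = subset,
               term = wanted$term[i],
               estimate = stats::median(dr), sd = stats::sd(dr),
               hpdi_low = h[1], hpdi_high = h[2],
               logBF01 = savage_dickey_bf01(dr, stats::dnorm(0, 0, prior_sd)))
  }))
  rownames(out) <- NULL
  structure(out, fit = fit, class = c("gew_traits", "data.frame"))
}

#' @export
print.gew_traits <- function(x, digits = 4, ...) {
  tab <- as.data.frame(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
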