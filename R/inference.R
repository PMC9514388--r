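#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * S)` of the
#' sorted draws. Width ties between candidate windows are broken by the
#' first (lowest) window.
#'
#' @param draws numeric vector of posterior draws (>= 100 for a stable
#'   interval; fewer is allowed but warned about).
#' @param mass interval probability mass.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass <= 1)
  S <- length(draws)
  if (S < 100) warning("fewer than 100 draws: HPDI is unstable")
  x <- sort(draws)
  m <- ceiling(mass * S)
  if (m >= S) return(c(x[1], x[S]))
  widths <- x[m:S] - x[1:(S - m + 1)]
  i <- which.min(widths)   # which.min takes the first minimum: lowest window
  c(x[i], x[i + m - 1])
}

new_contrast <- function(name, draws, null_value) {
  h <- hpdi(draws)
  data.frame(name = name,
             median = stats::median(draws),
             hpdi_low = h[1], hpdi_high = h[2],
             null_value = null_value,
             significant = null_value < h[1] | null_value > h[2])
}

#' Condition-cell posteriors of a fitted model
#'
#' Posterior draws of the cell parameters for every (emotion, mask,
#' intensity) combination: circular mean in degrees and circular variance
#' for a Von Mises fit, mean intensity (px) for a Gaussian fit. Random
#' effects are set to zero (population level).
#'
#' @param fit a [gewls()] fit whose data contain `emotion`, `mask` and
#'   `intensity` columns.
#' @return An object of class `"gew_cellpost"`: a list with the cell
#'   data.frame `cells` and draw matrices (`mu_deg` and `circvar`, or
#'   `mean`), draws in rows and cells in columns.
#' @export
cell_posteriors <- function(fit) {
  stopifnot(inherits(fit, "gewls"))
  vars <- c("emotion", "mask", "intensity")
  if (!all(vars %in% names(fit$data)))
    stop("fit data must contain emotion, mask and intensity columns")
  cells <- unique(fit$data[vars])
  cells <- cells[order(cells$emotion, cells$mask, cells$intensity), ]
  rownames(cells) <- NULL
  pr <- stats::predict(fit, newdata = cells, type = "draws")
  out <- list(cells = cells, family = fit$family)
  if (fit$family == "vonmises") {
    out$mu_deg <- pr$mu_deg
    out$circvar <- pr$circvar
  } else {
    out$mean <- pr$mean
  }
  structure(out, class = "gew_cellpost")
}

#' @export
print.gew_cellpost <- function(x, ...) {
  cat(sprintf("Posterior cell draws: %d cells x %d draws (%s)\n",
              nrow(x$cells),
              nrow(if (x$family == "vonmises") x$mu_deg else x$mean),
              x$family))
  invisible(x)
}

# drawwise circular mean across a set of cell columns (matrix draws x cells)
circ_rowmean_deg <- function(m) {
  a <- m * pi / 180
  atan2(rowMeans(sin(a)), rowMeans(cos(a))) * 180 / pi
}

cell_cols <- function(cp, emotion, mask = NULL, intensity = NULL) {
  sel <- cp$cells$emotion == emotion
  if (!is.null(mask)) sel <- sel & cp$cells$mask == mask
  if (!is.null(intensity)) sel <- sel & cp$cells$intensity == intensity
  which(sel)
}

# marginal draws for one emotion x mask condition (averaged over intensity
# unless a level is given): circular average for bias, plain average for
# variance-like and intensity measures
marginal_draws <- function(cp, measure, emotion, mask, intensity = NULL) {
  cols <- cell_cols(cp, emotion, mask, intensity)
  if (!length(cols)) stop("no cells for ", emotion, " / mask=", mask)
  m <- cp[[measure]][, cols, drop = FALSE]
  if (measure == "mu_deg") circ_rowmean_deg(m) else rowMeans(m)
}

#' Mask-effect contrasts per displayed emotion
#'
#' `mask_delta()` computes the drawwise difference masked minus unmasked
#' (circular difference for the bias, plain difference for perceived
#' intensity); the null value is 0. `mask_ratio()` computes the drawwise
#' ratio of circular-variance draws (the conventional comparison for
#' variance-like measures); the null value is 1. Both are summarised by
#' the posterior median and 95% HPDI, with a contrast flagged significant
#' when the null value falls outside the interval.
#'
#' @param cellpost a [cell_posteriors()] object.
#' @param emotions emotions to contrast; default all present.
#' @param intensity restrict to one expression-intensity level instead of
#'   averaging over levels.
#' @return A `"gew_contrasts"` data.frame: one row per emotion with
#'   `median`, `hpdi_low`, `hpdi_high`, `null_value`, `significant`.
#' @export
mask_delta <- function(cellpost, emotions = NULL, intensity = NULL) {
  measure <- if (cellpost$family == "vonmises") "mu_deg" else "mean"
  if (is.null(emotions)) emotions <- unique(cellpost$cells$emotion)
  out <- do.call(rbind, lapply(emotions, function(e) {
    dy <- marginal_draws(cellpost, measure, e, "yes", intensity)
    dn <- marginal_draws(cellpost, measure, e, "no", intensity)
    delta <- if (measure == "mu_deg") wrap_deg(dy - dn) else dy - dn
    cbind(emotion = e, new_contrast(paste0("delta_mask[", e, "]"), delta, 0))
  }))
  structure(out, class = c("gew_contrasts", "data.frame"))
}

#' @rdname mask_delta
#' @export
mask_ratio <- function(cellpost, emotions = NULL, intensity = NULL) {
  if (cellpost$family != "vonmises")
    stop("uncertainty ratios require a Von Mises fit")
  if (is.null(emotions)) emotions <- unique(cellpost$cells$emotion)
  out <- do.call(rbind, lapply(emotions, function(e) {
    vy <- marginal_draws(cellpost, "circvar", e, "yes", intensity)
    vn <- marginal_draws(cellpost, "circvar", e, "no", intensity)
    ok <- vn > 0
    if (!all(ok)) message(sum(!ok), " zero-denominator draws excluded")
    cbind(emotion = e,
          new_contrast(paste0("ratio_mask[", e, "]"), vy[ok] / vn[ok], 1))
  }))
  structure(out, class = c("gew_contrasts", "data.frame"))
}

#' Expression-intensity interaction contrasts
#'
#' Second-order contrasts comparing the mask effect between full and
#' subtle expressions, computed drawwise within the same fit:
#' `intensity_interaction()` is the difference of mask deltas
#' (full minus subtle, null 0); `ratio_interaction()` is the ratio of mask
#' uncertainty ratios (full over subtle, null 1).
#'
#' @inheritParams mask_delta
#' @return A `"gew_contrasts"` data.frame, one row per emotion.
#' @export
intensity_interaction <- function(cellpost, emotions = NULL) {
  measure <- if (cellpost$family == "vonmises") "mu_deg" else "mean"
  if (is.null(emotions)) emotions <- unique(cellpost$cells$emotion)
  out <- do.call(rbind, lapply(emotions, function(e) {
    d <- lapply(c(full = "full", subtle = "subtle"), function(lv) {
      dy <- marginal_draws(cellpost, measure, e, "yes", lv)
      dn <- marginal_draws(cellpost, measure, e, "no", lv)
      if (measure == "mu_deg") wrap_deg(dy - dn) else dy - dn
    })
    cbind(emotion = e,
          new_contrast(paste0("delta_intensity[", e, "]"),
                       d$full - d$subtle, 0))
  }))
  structure(out, class = c("gew_contrasts", "data.frame"))
}

#' @rdname intensity_interaction
#' @export
ratio_interaction <- function(cellpost, emotions = NULL) {
  if (cellpost$family != "vonmises")
    stop("uncertainty ratios require a Von Mises fit")
  if (is.null(emotions)) emotions <- unique(cellpost$cells$emotion)
  out <- do.call(rbind, lapply(emotions, function(e) {
    r <- lapply(c(full = "full", subtle = "subtle"), function(lv) {
      vy <- marginal_draws(cellpost, "circvar", e, "yes", lv)
      vn <- marginal_draws(cellpost, "circvar", e, "no", lv)
      vy / vn
    })
    cbind(emotion = e,
          new_contrast(paste0("ratio_intensity[", e, "]"),
                       r$full / r$subtle, 1))
  }))
  structure(out, class = c("gew_contrasts", "data.frame"))
}

#' @export
print.gew_contrasts <- function(x, digits = 3, ...) {
  tab <- as.data.frame(x)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  tab$sig <- ifelse(tab$significant, "*", "")
  print(tab[setdiff(names(tab), "significant")], row.names = FALSE)
  invisible(x)
}

fmt_cell <- function(draws, digits = 3) {
  h <- hpdi(draws)
  sprintf(paste0("%.", digits, "f [%.", digits, "f, %.", digits, "f]"),
          stats::median(draws), h[1], h[2])
}

#' Mask-effect results table
#'
#' Per-emotion summary table in the conventional layout: the masked and
#' unmasked condition posteriors (median and 95% HPDI) and their contrast
#' (delta for bias and perceived intensity, ratio for uncertainty), with
#' an asterisk marking contrasts whose HPDI excludes the null value.
#'
#' @param fit a [gewls()] fit with `emotion`, `mask`, `intensity` columns.
#' @param digits digits in the formatted columns.
#' @return A data.frame with columns `emotion`, `parameter`, `mask_yes`,
#'   `mask_no`, `contrast`, `significant`.
#' @export
results_table <- function(fit, digits = 3) {
  cp <- cell_posteriors(fit)
  emotions <- unique(cp$cells$emotion)
  rows <- list()
  if (cp$family == "vonmises") {
    dl <- mask_delta(cp); rt <- mask_ratio(cp)
    for (e in emotions) {
      dy <- marginal_draws(cp, "mu_deg", e, "yes")
      dn <- marginal_draws(cp, "mu_deg", e, "no")
      cd <- dl[dl$emotion == e, ]
      rows[[length(rows) + 1]] <- data.frame(
        emotion = e, parameter = "bias",
        mask_yes = fmt_cell(dy, digits), mask_no = fmt_cell(dn, digits),
        contrast = paste0(fmt_cell(wrap_deg(dy - dn), digits),
                          ifelse(cd$significant, "*", "")),
        significant = cd$significant)
    }
    for (e in emotions) {
      vy <- marginal_draws(cp, "circvar", e, "yes")
      vn <- marginal_draws(cp, "circvar", e, "no")
      cr <- rt[rt$emotion == e, ]
      rows[[length(rows) + 1]] <- data.frame(
        emotion = e, parameter = "uncertainty",
        mask_yes = fmt_cell(vy, digits), mask_no = fmt_cell(vn, digits),
        contrast = paste0(fmt_cell(vy / vn, digits),
                          ifelse(cr$significant, "*", "")),
        significant = cr$significant)
    }
  } else {
    dl <- mask_delta(cp)
    for (e in emotions) {
      dy <- marginal_draws(cp, "mean", e, "yes")
      dn <- marginal_draws(cp, "mean", e, "no")
      cd <- dl[dl$emotion == e, ]
      rows[[length(rows) + 1]] <- data.frame(
        emotion = e, parameter = "intensity",
        mask_yes = fmt_cell(dy, digits), mask_no = fmt_cell(dn, digits),
        contrast = paste0(fmt_cell(dy - dn, digits),
                          ifelse(cd$significant, "*", "")),
        significant = cd$significant)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Response-label frequencies per condition
#'
#' Classifies every emotional-trial click into a wheel label (or
#' "neutral") via [assign_label()] and tabulates relative frequencies per
#' (emotion, mask, intensity) condition — the descriptive view of where
#' responses land on the wheel.
#'
#' @param trials trial table with click coordinates.
#' @param geometry a [gew_geometry()].
#' @return A data.frame with `emotion`, `mask`, `intensity`,
#'   `response_label`, `freq` (relative within condition).
#' @export
label_frequencies <- function(trials, geometry = gew_geometry()) {
  emo <- trials[trials$trial_type == "emotion", ]
  pol <- click_to_polar(emo$click_x_px, emo$click_y_px, geometry)
  lab <- assign_label(pol$angle_deg, pol$radius_px, geometry)
  lab <- factor(lab, levels = c(geometry$labels, "neutral"))
  cond <- interaction(emo$emotion, emo$mask, emo$intensity, drop = TRUE)
  out <- do.call(rbind, lapply(levels(cond), function(cl) {
    sel <- cond == cl
    tt <- table(lab[sel]) / sum(sel)
    parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
    data.frame(emotion = parts[1], mask = parts[2], intensity = parts[3],
               response_label = names(tt), freq = as.numeric(tt))
  }))
  rownames(out) <- NULL
  out
}

#' Plot label-frequency panels
#'
#' Bar panels of response-label frequencies, one panel per displayed
#' emotion, bars in the clockwise wheel order, split by mask condition.
#'
#' @param freqs output of [label_frequencies()].
#' @param intensity restrict to one intensity level (default: aggregate).
#' @export
plot_label_frequencies <- function(freqs, intensity = NULL) {
  if (!is.null(intensity)) freqs <- freqs[freqs$intensity == intensity, ]
  emotions <- unique(freqs$emotion)
  old <- graphics::par(mfrow = c(ceiling(length(emotions) / 2), 2),
                       mar = c(6, 3, 2, 1))
  on.exit(graphics::par(old))
  labs <- unique(freqs$response_label)
  for (e in emotions) {
    f <- freqs[freqs$emotion == e, ]
    m <- vapply(c("yes", "no"), function(mk) {
      vapply(labs, function(l) {
        v <- f$freq[f$mask == mk & f$response_label == l]
        if (length(v)) mean(v) else 0
      }, numeric(1))
    }, numeric(length(labs)))
    graphics::barplot(t(m), beside = TRUE, names.arg = labs, las = 2,
                      cex.names = 0.6, main = e,
                      legend.text = c("mask", "no mask"),
                      args.legend = list(cex = 0.6, bty = "n"))
  }
  invisible(freqs)
}
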