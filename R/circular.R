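#' Circular mean of angular errors
#'
#' Argument of the mean resultant vector of the angles, wrapped to
#' `(-180, 180]`. This is the *bias* index: a non-zero value is a
#' systematic clockwise (+) or anticlockwise (-) shift of responses.
#'
#' A sample whose resultant length is numerically zero (e.g. a perfectly
#' antipodal pair) has no defined mean direction; this is signalled with an
#' error rather than silently returning 0.
#'
#' @param angles_deg numeric vector of angles in degrees (n >= 1).
#' @return Circular mean in degrees.
#' @export
circular_mean <- function(angles_deg) {
  stopifnot(length(angles_deg) >= 1)
  a <- angles_deg * pi / 180
  s <- mean(sin(a)); c <- mean(cos(a))
  if (sqrt(s^2 + c^2) < 1e-12)
    stop("mean direction undefined: resultant length is zero")
  wrap_deg(atan2(s, c) * 180 / pi)
}

#' Mean resultant length
#'
#' Norm of the mean unit vector of the angles, in `[0, 1]`: 1 when all
#' angles coincide, 0 for perfectly balanced (e.g. uniform) samples.
#'
#' @inheritParams circular_mean
#' @return Resultant length R-bar in `[0, 1]`.
#' @export
resultant_length <- function(angles_deg) {
  stopifnot(length(angles_deg) >= 1)
  a <- angles_deg * pi / 180
  min(1, sqrt(mean(sin(a))^2 + mean(cos(a))^2))
}

#' Circular variance of angular errors
#'
#' Sample circular variance `1 - R-bar` (Fisher's uncorrected definition),
#' bounded in `[0, 1]`. This is the *uncertainty* index: 0 when all
#' responses concentrate on a single point, 1 when they are uniform around
#' the wheel.
#'
#' @inheritParams circular_mean
#' @return Circular variance in `[0, 1]`.
#' @export
circular_variance <- function(angles_deg) {
  1 - resultant_length(angles_deg)
}

# I1(k)/I0(k) with exponentially-scaled Bessel functions; the asymptotic
# expansion takes over where the scaled functions lose accuracy (A1 is
# within 1e-12 of the expansion long before that).
A1 <- function(k) {
  out <- numeric(length(k))
  big <- k > 700
  out[big] <- 1 - 1 / (2 * k[big]) - 1 / (8 * k[big]^2) - 1 / (8 * k[big]^3)
  if (any(!big))
    out[!big] <- besselI(k[!big], 1, expon.scaled = TRUE) /
      besselI(k[!big], 0, expon.scaled = TRUE)
  out
}

#' Von Mises concentration to circular variance
#'
#' Maps the concentration parameter k of a Von Mises distribution to its
#' circular variance `1 - I1(k)/I0(k)` (ratio of modified Bessel functions
#' of the first kind). The transform is strictly decreasing: 1 at k = 0
#' (uniform on the circle, maximum uncertainty) and tending to 0 as k grows
#' (all mass on a point, minimum uncertainty).
#'
#' @param kappa non-negative concentration value(s).
#' @return Circular variance in `[0, 1]`.
#' @examples
#' kappa_to_circvar(0)    # 1: uniform responses
#' kappa_to_circvar(2)    # ~0.302
#' @export
kappa_to_circvar <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop("kappa must be finite and >= 0")
  1 - A1(kappa)
}

#' Circular variance to Von Mises concentration
#'
#' Inverse of [kappa_to_circvar()] by monotone root finding on the Bessel
#' ratio.
#'
#' @param v circular variance value(s) in `(0, 1]`.
#' @return Concentration k >= 0.
#' @export
circvar_to_kappa <- function(v) {
  vapply(v, function(vi) {
    if (!is.finite(vi) || vi < 0 || vi > 1) stop("circular variance must lie in [0, 1]")
    if (vi == 0) return(Inf)
    if (vi >= 1) return(0)
    r <- 1 - vi
    stats::uniroot(function(k) A1(k) - r, c(1e-10, 1e8), tol = 1e-12)$root
  }, numeric(1))
}

#' Maximum-likelihood Von Mises concentration
#'
#' Solves `A1(k) = R-bar` for k by monotone root finding, where R-bar is
#' the sample mean resultant length. Under Von Mises data and large n,
#' `kappa_to_circvar(kappa_mle(x))` approaches the sample circular
#' variance.
#'
#' @inheritParams circular_mean
#' @return The MLE k-hat; `Inf` (with a warning) when R-bar is numerically 1.
#' @export
kappa_mle <- function(angles_deg) {
  stopifnot(length(angles_deg) >= 2)
  r <- resultant_length(angles_deg)
  if (r >= 1 - 1e-12) {
    warning("resultant length is 1: concentration unbounded")
    return(Inf)
  }
  if (r < 1e-12) return(0)
  stats::uniroot(function(k) A1(k) - r, c(1e-10, 1e8), tol = 1e-12)$root
}

#' Mean perceived intensity
#'
#' Arithmetic mean of radial click distances (pixels from the wheel
#' centre).
#'
#' @param radii_px non-negative radial distances in pixels.
#' @return Mean radius in pixels.
#' @export
perceived_intensity <- function(radii_px) {
  if (any(radii_px < 0)) stop("radii must be non-negative")
  mean(radii_px)
}

#' Descriptive perception-space indices per condition
#'
#' Computes bias (circular mean of centred errors), uncertainty (circular
#' variance) and perceived intensity (mean radius) for every combination of
#' the grouping columns, plus pooled rows per (emotion, mask, intensity)
#' condition collapsed over participants.
#'
#' @param analysis_table a table from [prepare_model_table()] with columns
#'   `participant_id`, `emotion`, `mask`, `intensity`, `error_deg`,
#'   `radius_px`.
#' @param by character vector of grouping columns for the per-group rows.
#' @return A data.frame with columns `n`, `bias_deg`, `uncertainty`,
#'   `intensity_px` plus the grouping columns; pooled rows carry
#'   `participant_id = "pooled"`.
#' @export
condition_indices <- function(analysis_table,
                              by = c("participant_id", "emotion", "mask", "intensity")) {
  stopifnot(all(c(by, "error_deg", "radius_px") %in% names(analysis_table)))
  one <- function(df, keys) {
    cbind(keys,
          data.frame(n = nrow(df),
                     bias_deg = circular_mean(df$error_deg),
                     uncertainty = circular_variance(df$error_deg),
                     intensity_px = perceived_intensity(df$radius_px)))
  }
  split_by <- function(tab, cols) {
    keys <- interaction(tab[cols], drop = TRUE, lex.order = TRUE)
    pieces <- split(tab, keys)
    do.call(rbind, lapply(pieces, function(df) {
      one(df, df[1, cols, drop = FALSE])
    }))
  }
  per_group <- split_by(analysis_table, by)
  if ("participant_id" %in% by) {
    pooled <- split_by(analysis_table, setdiff(by, "participant_id"))
    pooled <- cbind(participant_id = "pooled", pooled)
    per_group <- rbind(per_group, pooled[names(per_group)])
  }
  rownames(per_group) <- NULL
  per_group
}
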