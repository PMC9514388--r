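#' Geometry of the Geneva Emotion Wheel
#'
#' Describes the circular response instrument: 16 emotion terms arranged
#' clockwise around a wheel of a given pixel size, each occupying a 22.5
#' degree segment with 4 intensity circles per segment, and a central
#' neutral zone. Wheel angles are measured in degrees, clockwise-positive,
#' starting at the 12 o'clock direction, and normalised to `[0, 360)`.
#' Screen pixel coordinates follow the usual image convention (y grows
#' downward); conversions invert y so wheel angles are geometric.
#'
#' The default label layout places the six basic emotions (anger, disgust,
#' fear, happiness, sadness, surprise) in distinct segments with "interest"
#' adjacent to happiness, matching the confusion structure typically seen
#' between happiness, interest and surprise. Any 16-label layout can be
#' supplied, either directly or via a YAML configuration
#' (see [read_geometry()]).
#'
#' @param labels character vector of 16 distinct emotion terms in clockwise
#'   wheel order.
#' @param display_size_px width/height of the rendered wheel in pixels.
#' @param center_px numeric length-2 `(x, y)` pixel centre of the wheel.
#' @param ring_radii_px increasing radii (px) of the 4 intensity circles.
#' @param reference_angle_deg wheel angle of the first label's segment
#'   centre.
#' @param neutral_radius_px clicks closer to the centre than this are
#'   classified "neutral"; defaults to half the innermost ring radius.
#' @return An object of class `"gew_geometry"`.
#' @examples
#' geo <- gew_geometry()
#' correct_angle("happiness", geo)
#' @export
gew_geometry <- function(labels = gew_default_labels(),
                         display_size_px = 300,
                         center_px = c(display_size_px / 2, display_size_px / 2),
                         ring_radii_px = display_size_px / 2 * c(0.2, 0.433, 0.667, 0.9),
                         reference_angle_deg = 0,
                         neutral_radius_px = ring_radii_px[1] / 2) {
  labels <- as.character(labels)
  if (length(labels) != 16L || anyDuplicated(labels))
    stop("a wheel layout needs exactly 16 distinct labels")
  basic <- c("anger", "disgust", "fear", "happiness", "sadness", "surprise")
  missing_basic <- setdiff(basic, labels)
  if (length(missing_basic))
    stop("layout must contain the six basic emotions; missing: ",
         paste(missing_basic, collapse = ", "))
  if (length(center_px) != 2L || !all(is.finite(center_px)))
    stop("center_px must be two finite numbers")
  if (length(ring_radii_px) != 4L || any(diff(ring_radii_px) <= 0) ||
      any(ring_radii_px <= 0))
    stop("ring_radii_px must be 4 increasing positive radii")
  if (!is.finite(neutral_radius_px) || neutral_radius_px < 0)
    stop("neutral_radius_px must be a non-negative number")
  structure(
    list(labels = labels,
         display_size_px = display_size_px,
         center_px = as.numeric(center_px),
         ring_radii_px = as.numeric(ring_radii_px),
         n_rings = 4L,
         segment_width_deg = 360 / 16,
         reference_angle_deg = as.numeric(reference_angle_deg) %% 360,
         neutral_radius_px = as.numeric(neutral_radius_px),
         orientation = "clockwise"),
    class = "gew_geometry")
}

#' Default 16-term wheel layout
#'
#' Clockwise label order used when no layout is configured. It respects the
#' wheel's organisation by valence (negative left, positive right) and
#' control (high top, low bottom), keeps the six basic emotions in distinct
#' segments and places interest between happiness and surprise.
#'
#' @return Character vector of 16 emotion terms.
#' @export
gew_default_labels <- function() {
  c("pride", "elation", "happiness", "interest",
    "surprise", "satisfaction", "relief", "hope",
    "fear", "sadness", "guilt", "shame",
    "envy", "disgust", "contempt", "anger")
}

#' @export
print.gew_geometry <- function(x, ...) {
  cat("Geneva Emotion Wheel geometry\n")
  cat(sprintf("  %d labels (clockwise): %s, ...\n", length(x$labels),
              paste(utils::head(x$labels, 4), collapse = ", ")))
  cat(sprintf("  display %g px, centre (%g, %g)\n", x$display_size_px,
              x$center_px[1], x$center_px[2]))
  cat(sprintf("  ring radii (px): %s; neutral zone < %g px\n",
              paste(x$ring_radii_px, collapse = ", "), x$neutral_radius_px))
  cat(sprintf("  reference angle %g deg (first label: %s)\n",
              x$reference_angle_deg, x$labels[1]))
  invisible(x)
}

#' Wrap angles to a half-open interval
#'
#' `wrap_deg()` maps any angle to `(-180, 180]` (so -180 becomes +180 and
#' the antipode has a single representative); `wrap360()` maps to
#' `[0, 360)`.
#'
#' @param x numeric vector of angles in degrees.
#' @return Wrapped angles, same length as `x`.
#' @export
wrap_deg <- function(x) {
  if (!all(is.finite(x))) stop("angles must be finite")
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' @rdname wrap_deg
#' @export
wrap360 <- function(x) {
  if (!all(is.finite(x))) stop("angles must be finite")
  x %% 360
}

#' Convert a screen click to polar wheel coordinates
#'
#' Radius is the Euclidean pixel distance from the wheel centre (the
#' perceived-intensity reading); the angle is the response orientation in
#' wheel convention (degrees clockwise from 12 o'clock, `[0, 360)`). A
#' click exactly at the centre has angle 0 by convention.
#'
#' @param x,y click coordinates in pixels (y downward, image convention).
#' @param geometry a [gew_geometry()] object.
#' @return A data.frame with columns `radius_px` and `angle_deg`.
#' @export
click_to_polar <- function(x, y, geometry = gew_geometry()) {
  if (!all(is.finite(x), is.finite(y))) stop("click coordinates must be finite")
  dx <- x - geometry$center_px[1]
  dy_up <- geometry$center_px[2] - y   # invert screen y
  r <- sqrt(dx^2 + dy_up^2)
  ang <- (atan2(dx, dy_up) * 180 / pi) %% 360  # clockwise from up
  ang[r == 0] <- 0
  data.frame(radius_px = r, angle_deg = ang)
}

#' Convert polar wheel coordinates back to screen pixels
#'
#' Inverse of [click_to_polar()]; used by the response simulator.
#'
#' @param radius_px,angle_deg polar coordinates in wheel convention.
#' @inheritParams click_to_polar
#' @return A data.frame with columns `x` and `y` (pixels).
#' @export
polar_to_click <- function(radius_px, angle_deg, geometry = gew_geometry()) {
  if (any(radius_px < 0)) stop("radius must be non-negative")
  a <- angle_deg * pi / 180
  data.frame(x = geometry$center_px[1] + radius_px * sin(a),
             y = geometry$center_px[2] - radius_px * cos(a))
}

#' Correct wheel angle of a displayed emotion
#'
#' The wheel is divided into 16 equal 22.5-degree segments; the correct
#' angle of an emotion is the centre of its segment, with the first label
#' centred at `reference_angle_deg` and subsequent labels following
#' clockwise.
#'
#' @param emotion character vector of labels present in `geometry$labels`.
#' @inheritParams click_to_polar
#' @return Wheel angles in degrees, `[0, 360)`.
#' @export
correct_angle <- function(emotion, geometry = gew_geometry()) {
  idx <- match(emotion, geometry$labels)
  if (anyNA(idx))
    stop("unknown emotion label(s): ",
         paste(unique(emotion[is.na(idx)]), collapse = ", "))
  (geometry$reference_angle_deg + (idx - 1) * geometry$segment_width_deg) %% 360
}

#' Centred angular error of a response
#'
#' Signed deviation of the response angle from the displayed emotion's
#' correct angle, wrapped to `(-180, 180]`. Positive values are clockwise
#' shifts on the wheel, negative values anticlockwise.
#'
#' @param response_angle_deg,correct_angle_deg angles in degrees.
#' @return Wrapped signed errors in degrees.
#' @export
centered_error <- function(response_angle_deg, correct_angle_deg) {
  wrap_deg(response_angle_deg - correct_angle_deg)
}

#' Classify a wheel position as an emotion label or neutral
#'
#' Returns the label of the 22.5-degree segment containing the angle, or
#' `"neutral"` when the radius falls inside the central neutral zone.
#' An angle exactly on a segment boundary belongs to the clockwise-following
#' segment (half-open segments).
#'
#' @param angle_deg,radius_px polar coordinates in wheel convention.
#' @inheritParams click_to_polar
#' @return Character vector of labels (or `"neutral"`).
#' @export
assign_label <- function(angle_deg, radius_px, geometry = gew_geometry()) {
  w <- geometry$segment_width_deg
  rel <- (angle_deg - geometry$reference_angle_deg + w / 2) %% 360
  idx <- (floor(rel / w) %% 16) + 1
  out <- geometry$labels[idx]
  out[radius_px < geometry$neutral_radius_px] <- "neutral"
  out
}

#' Read / write a wheel geometry as YAML
#'
#' The configuration lists the ordered labels, display size, centre, ring
#' radii, reference angle and neutral-zone radius, so a deployed wheel
#' layout can be declared without touching code.
#'
#' @param path file path of a YAML geometry configuration.
#' @return `read_geometry()` returns a `"gew_geometry"`;
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  gew_geometry(labels = cfg$labels,
               display_size_px = cfg$display_size_px,
               center_px = unlist(cfg$center_px),
               ring_radii_px = unlist(cfg$ring_radii_px),
               reference_angle_deg = cfg$reference_angle_deg,
               neutral_radius_px = cfg$neutral_radius_px)
}

#' @rdname read_geometry
#' @param geometry a [gew_geometry()] object to serialise.
#' @export
write_geometry <- function(geometry, path) {
  yaml::write_yaml(
    list(labels = geometry$labels,
         display_size_px = geometry$display_size_px,
         center_px = geometry$center_px,
         ring_radii_px = geometry$ring_radii_px,
         reference_angle_deg = geometry$reference_angle_deg,
         neutral_radius_px = geometry$neutral_radius_px),
    path)
  invisible(path)
}
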