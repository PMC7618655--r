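# Anatomical tibiofemoral angle (aTFA) from landmark midpoints.
#
# Two axis recipes are supported. FTS fits the femoral axis through the
# midpoints of the proximal and distal femoral shaft pairs; FNTS replaces
# the distal anchor with the femoral notch-pair midpoint. Both use the same
# tibial axis through the proximal/distal tibial shaft-pair midpoints. The
# reported angle is the signed deviation of the tibial axis from the distal
# prolongation of the femoral axis: 0 means perfectly straight alignment,
# positive = valgus (distal tibia deviates laterally), negative = varus —
# for a left knee in AP image orientation, where lateral is +x.

axis_line <- function(anchor, direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-9) stop("axis_line: degenerate axis (coincident anchor midpoints)")
  structure(list(anchor = as.numeric(anchor),
                 direction = as.numeric(direction) / nrm),
            class = "axis_line")
}

#' Femoral axis, FTS construction
#'
#' Line through the midpoints of the proximal ("red") and distal ("yellow")
#' femoral shaft pairs, oriented proximally (away from the joint).
#'
#' @param l a [landmark_set()] with the mandatory roles.
#' @return an `axis_line` (anchor + unit direction).
#' @export
femoral_axis_fts <- function(l) {
  prox <- midpoint(role_points(l, "femoral_shaft_pair_proximal"))
  dist <- midpoint(role_points(l, "femoral_shaft_pair_distal"))
  axis_line(dist, prox - dist)
}

#' Femoral axis, FNTS construction
#'
#' Line through the proximal femoral shaft-pair midpoint and the femoral
#' notch-pair midpoint, oriented proximally.
#'
#' @inheritParams femoral_axis_fts
#' @return an `axis_line`.
#' @export
femoral_axis_fnts <- function(l) {
  prox <- midpoint(role_points(l, "femoral_shaft_pair_proximal"))
  notch <- midpoint(role_points(l, "femoral_notch_pair"))
  axis_line(notch, prox - notch)
}

#' Tibial axis
#'
#' Line through the proximal ("black") and distal ("blue") tibial shaft-pair
#' midpoints, oriented distally (away from the joint).
#'
#' @inheritParams femoral_axis_fts
#' @return an `axis_line`.
#' @export
tibial_axis <- function(l) {
  prox <- midpoint(role_points(l, "tibial_shaft_pair_proximal"))
  dist <- midpoint(role_points(l, "tibial_shaft_pair_distal"))
  axis_line(prox, dist - prox)
}

#' Signed anatomical tibiofemoral angle
#'
#' Measures the angle between the distal prolongation of the femoral axis
#' and the tibial axis direction; valgus (lateral deviation of the distal
#' tibia) is positive, varus negative. The sign convention is fixed for left
#' knees in AP image orientation; right-knee landmark sets must be
#' pre-mirrored (see [flip_to_left()]) and flagged via `laterality`.
#'
#' @param l a [landmark_set()].
#' @param method "fnts" (default) or "fts".
#' @param laterality only "left" is accepted; mirror right knees first.
#' @return list of class `atfa_result`: `angle` (degrees), `method`,
#'   `laterality`.
#' @export
atfa <- function(l, method = c("fnts", "fts"), laterality = "left") {
  method <- match.arg(method)
  if (!identical(laterality, "left")) {
    stop("atfa: sign convention is defined for left knees; flip right knees first (flip_to_left)")
  }
  fem <- if (method == "fts") femoral_axis_fts(l) else femoral_axis_fnts(l)
  tib <- tibial_axis(l)
  f <- -fem$direction   # distal prolongation of the femoral axis
  t <- tib$direction
  cross <- f[1] * t[2] - f[2] * t[1]
  dotp <- max(-1, min(1, sum(f * t)))
  # In the y-down frame, a tibia tipping toward +x (lateral/valgus) gives a
  # negative cross product against a distally pointing femoral axis.
  angle <- -atan2(cross, dotp) * 180 / pi
  structure(list(angle = angle, method = toupper(method),
                 laterality = laterality),
            class = "atfa_result")
}

#' @export
print.atfa_result <- function(x, ...) {
  cat(sprintf("aTFA (%s, %s knee): %+.1f deg [%s]\n", x$method, x$laterality,
              x$angle,
              if (x$angle > 0) "valgus" else if (x$angle < 0) "varus" else "neutral"))
  invisible(x)
}
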