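# Two-stage localization: the global model scans the (downscaled) whole
# radiograph for two reference points — the tibial plateau corners — which
# fix the position, orientation and scale of a similarity reference frame;
# the local model then searches inside that frame and its detections are
# mapped back to original image coordinates.

#' Reference-frame specification
#'
#' The two reference points land on canonical anchors inside the crop: a
#' horizontal pair at `anchor_y_frac` of the crop height, separated by
#' `anchor_sep_frac` of the crop width. The defaults centre the plateau pair
#' at mid-height with a separation of 0.17 of the crop width: the knee
#' outline spans roughly five plateau widths proximodistally, so a smaller
#' separation is required for the frame to cover the distal femur above and
#' the full proximal tibia below (a half-width separation would crop away
#' every shaft landmark).
#'
#' @param crop_size square crop side in pixels.
#' @param anchor_sep_frac anchor separation as a fraction of crop width.
#' @param anchor_y_frac anchor height as a fraction of crop height.
#' @return list of class `frame_spec` with `crop_size`, `anchor_left`,
#'   `anchor_right`.
#' @export
frame_spec <- function(crop_size = 128L, anchor_sep_frac = 0.17,
                       anchor_y_frac = 0.5) {
  crop_size <- as.integer(crop_size)
  stopifnot(crop_size >= 8L, anchor_sep_frac > 0, anchor_sep_frac <= 1,
            anchor_y_frac > 0, anchor_y_frac < 1)
  cx <- (crop_size - 1) / 2
  y <- (crop_size - 1) * anchor_y_frac
  half <- (crop_size - 1) * anchor_sep_frac / 2
  structure(list(crop_size = crop_size,
                 anchor_left = c(cx - half, y),
                 anchor_right = c(cx + half, y)),
            class = "frame_spec")
}

#' Aspect-preserving resize transform onto a square network input
#'
#' Returns the similarity transform mapping original-image coordinates to
#' the `size`-pixel input (top-left anchored, scale = size / max dimension;
#' the short side is padded with the image minimum).
#'
#' @param image grayscale matrix.
#' @param size target square side.
#' @return list with `transform` and the resampled `input` matrix.
#' @export
resize_for_input <- function(image, size) {
  s <- size / max(dim(image))
  t <- similarity_transform(scale = s)
  list(transform = t,
       input = resample_to_frame(image, t, size))
}

#' Build the reference frame from two detected reference points
#'
#' @param ref_left,ref_right reference points (left/right plateau corner) in
#'   image coordinates; must be at least 1 px apart.
#' @param fspec a [frame_spec()].
#' @return a [similarity_transform()] mapping image -> crop coordinates.
#' @export
make_frame <- function(ref_left, ref_right, fspec) {
  if (sqrt(sum((ref_left - ref_right)^2)) < 1) {
    stop("make_frame: reference points closer than 1 px (degenerate frame)")
  }
  transform_between_point_pairs(ref_left, ref_right,
                                fspec$anchor_left, fspec$anchor_right)
}

#' Resample an image into a frame
#'
#' Bilinear sampling of the source at the inverse-transformed crop grid;
#' out-of-bounds source pixels take the image minimum (radiograph
#' backgrounds are dark, so padding never attracts heatmap mass).
#'
#' @param image grayscale matrix.
#' @param t image -> crop [similarity_transform()].
#' @param crop_size square crop side.
#' @return crop matrix (crop_size x crop_size).
#' @export
resample_to_frame <- function(image, t, crop_size) {
  inv <- transform_invert(t)
  gx <- rep(0:(crop_size - 1), each = crop_size)
  gy <- rep(0:(crop_size - 1), times = crop_size)
  src <- transform_apply(inv, cbind(gx, gy))
  vals <- bilinear_sample_cpp(image, src[, 1], src[, 2], min(image))
  matrix(vals, crop_size, crop_size)
}

#' Global search: detect the two reference points
#'
#' Runs the global model on the aspect-preserving resized image and maps the
#' decoded points back to original-image coordinates. Output order is fixed
#' by schema role: left plateau corner first.
#'
#' @param image grayscale matrix (original resolution).
#' @param global_model model with 2 output channels (left, right corner).
#' @return list with `ref_left`, `ref_right` (image coordinates) and the
#'   resize `transform`.
#' @export
global_search <- function(image, global_model) {
  rz <- resize_for_input(image, global_model$config$input_size)
  pts_in <- predict_landmarks(global_model, rz$input)
  pts <- transform_apply(transform_invert(rz$transform), pts_in)
  if (sqrt(sum((pts[1, ] - pts[2, ])^2)) < 1) {
    stop("global_search: predicted reference points closer than 1 px (degenerate frame)")
  }
  list(ref_left = pts[1, ], ref_right = pts[2, ], transform = rz$transform)
}

#' Full two-stage localization
#'
#' global search -> reference frame -> local search -> map back.
#'
#' @param image grayscale matrix.
#' @param global_model 2-channel model for the reference points.
#' @param local_model model with one channel per schema landmark.
#' @param fspec a [frame_spec()]; its crop size must match the local model
#'   input.
#' @param schema the landmark schema of the local model's channels.
#' @return a [landmark_set()] in image coordinates, with the frame transform
#'   attached as attribute `frame`.
#' @export
localize <- function(image, global_model, local_model, fspec, schema) {
  if (fspec$crop_size != local_model$config$input_size) {
    stop("localize: frame_spec crop_size must equal the local model input size")
  }
  if (local_model$config$n_landmarks != schema$n_points) {
    stop("localize: local model channels and schema point count differ")
  }
  gs <- tryCatch(global_search(image, global_model),
                 error = function(e) stop("localize [global stage]: ",
                                          conditionMessage(e), call. = FALSE))
  t <- make_frame(gs$ref_left, gs$ref_right, fspec)
  crop <- resample_to_frame(image, t, fspec$crop_size)
  pts_crop <- tryCatch(predict_landmarks(local_model, crop),
                       error = function(e) stop("localize [local stage]: ",
                                                conditionMessage(e), call. = FALSE))
  pts <- transform_apply(transform_invert(t), pts_crop)
  out <- landmark_set(pts, schema)
  attr(out, "frame") <- t
  out
}

#' Build the global-stage training dataset
#'
#' Resizes each phantom image to the global input size and maps the two
#' plateau-corner ground-truth landmarks into that frame.
#'
#' @param samples list of `phantom_sample`s.
#' @param input_size global model input side.
#' @return list of `list(image, landmarks)` (landmarks: 2 x 2, left first).
#' @export
make_global_dataset <- function(samples, input_size = 64L) {
  lapply(samples, function(s) {
    rz <- resize_for_input(s$image, input_size)
    corners <- rbind(role_points(s$landmarks, "plateau_corner_left"),
                     role_points(s$landmarks, "plateau_corner_right"))
    list(image = rz$input,
         landmarks = transform_apply(rz$transform, corners))
  })
}

#' Build the local-stage training dataset
#'
#' Constructs the reference frame from the ground-truth plateau corners —
#' optionally jittered to emulate global-stage error — resamples the crop
#' and maps all ground-truth landmarks into it.
#'
#' @param samples list of `phantom_sample`s.
#' @param fspec a [frame_spec()].
#' @param jitter_sd Gaussian sd (original-image pixels) added to each
#'   reference point before building the frame; 0 disables.
#' @param seed jitter seed.
#' @return list of `list(image, landmarks)` in crop coordinates.
#' @export
make_local_dataset <- function(samples, fspec = frame_spec(),
                               jitter_sd = 2, seed = 1L) {
  stopifnot(jitter_sd >= 0)
  set.seed(seed)
  lapply(samples, function(s) {
    cl <- as.numeric(role_points(s$landmarks, "plateau_corner_left"))
    cr <- as.numeric(role_points(s$landmarks, "plateau_corner_right"))
    if (jitter_sd > 0) {
      cl <- cl + rnorm(2, sd = jitter_sd)
      cr <- cr + rnorm(2, sd = jitter_sd)
    }
    t <- make_frame(cl, cr, fspec)
    list(image = resample_to_frame(s$image, t, fspec$crop_size),
         landmarks = transform_apply(t, s$landmarks$points))
  })
}
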