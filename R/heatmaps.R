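# Heatmap encoding/decoding and the wing loss.
#
# Heatmap pixel j (0-based) covers input pixels [j*s, (j+1)*s) for stride s;
# its centre sits at input coordinate j*s + (s-1)/2. Encoding places an
# isotropic Gaussian (peak value 1 as a continuous function) at the scaled
# landmark; decoding is a spatial soft-argmax: softmax(beta * map) weights an
# expectation over pixel coordinates, giving sub-pixel estimates and exact
# gradients for coordinate losses.

input_to_hm <- function(p, stride) (p - (stride - 1) / 2) / stride
hm_to_input <- function(p, stride) p * stride + (stride - 1) / 2

#' Encode landmarks as Gaussian target heatmaps
#'
#' @param landmarks a [landmark_set()] or n x 2 matrix in input-pixel
#'   coordinates of the model frame.
#' @param config a [model_config()] (uses `input_size`, `heatmap_stride`,
#'   `heatmap_sigma`).
#' @return array (h, w, K) with attribute `stride`.
#' @export
encode_heatmaps <- function(landmarks, config) {
  pts <- if (inherits(landmarks, "landmark_set")) landmarks$points else as.matrix(landmarks)
  S <- config$input_size
  bad <- which(pts[, 1] < 0 | pts[, 1] > S - 1 | pts[, 2] < 0 | pts[, 2] > S - 1)
  if (length(bad)) {
    stop("encode_heatmaps: landmarks outside input bounds at indices: ",
         paste(bad, collapse = ", "))
  }
  h <- S %/% config$heatmap_stride
  xs <- 0:(h - 1)
  hmx <- input_to_hm(pts[, 1], config$heatmap_stride)
  hmy <- input_to_hm(pts[, 2], config$heatmap_stride)
  K <- nrow(pts)
  out <- array(0, c(h, h, K))
  s2 <- 2 * config$heatmap_sigma^2
  for (k in seq_len(K)) {
    gx <- exp(-(xs - hmx[k])^2 / s2)
    gy <- exp(-(xs - hmy[k])^2 / s2)
    out[, , k] <- outer(gy, gx)  # rows = y, cols = x
  }
  attr(out, "stride") <- config$heatmap_stride
  out
}

# Soft-argmax over a (h*w, n_maps) matrix of flattened maps (column-major:
# y fastest). Returns hm-coordinate expectations and, optionally, what the
# loss backward needs.
softargmax_mat <- function(hmat, h, w, beta) {
  z <- beta * hmat
  z <- sweep(z, 2L, apply(z, 2L, max), `-`)
  e <- exp(z)
  p <- sweep(e, 2L, colSums(e), `/`)
  ys <- rep(0:(h - 1), times = w)
  xs <- rep(0:(w - 1), each = h)
  list(p = p, x = colSums(p * xs), y = colSums(p * ys), xs = xs, ys = ys)
}

#' Decode heatmaps to landmark coordinates (soft-argmax)
#'
#' Each map is turned into a spatial softmax distribution
#' (`softmax(beta * map)`) and the expected (x, y) is rescaled to input
#' pixels. An all-constant map decodes to the map centre (the softmax of a
#' constant is uniform) with a warning.
#'
#' @param hm array (h, w, K) from [encode_heatmaps()], or a model output
#'   batch (h, w, B, K) — for a batch a list of matrices is returned.
#' @param config a [model_config()]; provides stride and beta.
#' @return K x 2 matrix of input-frame coordinates (or list of them).
#' @export
decode_heatmaps <- function(hm, config) {
  stride <- config$heatmap_stride; beta <- config$beta
  d <- dim(hm)
  decode_one <- function(flat, h, w) {
    rng <- apply(flat, 2L, function(v) max(v) - min(v))
    if (any(rng == 0)) {
      warning("decode_heatmaps: constant map(s) decoded to the map centre")
    }
    sm <- softargmax_mat(flat, h, w, beta)
    cbind(x = hm_to_input(sm$x, stride), y = hm_to_input(sm$y, stride))
  }
  if (length(d) == 3L) {
    decode_one(matrix(hm, d[1] * d[2], d[3]), d[1], d[2])
  } else if (length(d) == 4L) {
    lapply(seq_len(d[3]), function(b) {
      decode_one(matrix(hm[, , b, , drop = FALSE], d[1] * d[2], d[4]),
                 d[1], d[2])
    })
  } else stop("decode_heatmaps: expected a (h, w, K) or (h, w, B, K) array")
}

#' Wing loss parameters
#'
#' `C = w - w*log(1 + w/epsilon)` makes the logarithmic and linear branches
#' meet continuously at |x| = w.
#'
#' @param w nonlinearity range, pixels.
#' @param epsilon curvature parameter, pixels.
#' @return list with `w`, `epsilon`, `C`.
#' @export
wing_params <- function(w = 10, epsilon = 2) {
  stopifnot(w > 0, epsilon > 0)
  list(w = w, epsilon = epsilon, C = w - w * log(1 + w / epsilon))
}

#' Wing loss between predicted and target landmarks
#'
#' Mean over all coordinate residuals x of `w*log(1 + |x|/epsilon)` when
#' |x| < w, else `|x| - C` — logarithmic near zero to emphasise small
#' localization errors, linear in the tails.
#'
#' @param pred,target landmark sets or n x 2 matrices with equal point
#'   counts (coordinates in pixels).
#' @param params a [wing_params()].
#' @return scalar loss in pixels.
#' @export
wing_loss <- function(pred, target, params = wing_params()) {
  p <- if (inherits(pred, "landmark_set")) pred$points else as.matrix(pred)
  t <- if (inherits(target, "landmark_set")) target$points else as.matrix(target)
  if (!all(dim(p) == dim(t))) stop("wing_loss: point counts differ")
  r <- abs(p - t)
  mean(ifelse(r < params$w,
              params$w * log1p(r / params$epsilon),
              r - params$C))
}

# d(wing)/d(residual) for signed residuals, elementwise (no mean factor).
wing_grad <- function(r, params) {
  ar <- abs(r)
  g <- ifelse(ar < params$w, params$w / (params$epsilon + ar), 1)
  g * sign(r)
}
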