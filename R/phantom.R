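# Synthetic left-knee AP phantom: two bright bone-like shafts meeting at a
# joint, rendered over a dark background, with exact landmark ground truth.
# The femoral shaft axis, the femoral notch midpoint and the tibial shaft
# axis are collinear/consistent by construction, so the FTS and FNTS angle
# recipes share a single generating truth (spec'd true aTFA).

# Direction conventions (y-down image frame): dirvec(psi) points "down the
# limb"; psi = 0 is straight down, psi > 0 tips the distal end laterally
# (+x, the lateral side of a left knee in AP orientation = valgus side).
dirvec <- function(psi_rad) c(sin(psi_rad), cos(psi_rad))
perpvec <- function(psi_rad) c(cos(psi_rad), -sin(psi_rad))  # medial->lateral

#' Specification of a synthetic knee phantom
#'
#' @param image_size square image side, pixels.
#' @param true_atfa generating anatomical tibiofemoral angle, degrees
#'   (valgus positive, varus negative); |true_atfa| <= 30.
#' @param femoral_shaft_width,tibial_shaft_width shaft widths, pixels. The
#'   tibial width also sets the plateau-corner separation used as the
#'   evaluation reference length.
#' @param joint_center `c(x, y)` of the joint gap centre, pixels.
#' @param shaft_length femoral shaft length, pixels (tibia uses 0.95x).
#' @param global_rotation whole-knee pose rotation, degrees (lateral tilt of
#'   the femoral axis).
#' @param intensity_noise_sd additive Gaussian noise sd, 8-bit gray levels.
#' @param blur_sigma Gaussian blur sd, pixels.
#' @param implant render a brighter polygonal insert at the joint (post-op
#'   phantoms).
#' @param seed RNG seed for the noise stream.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L, true_atfa = 0,
                         femoral_shaft_width = 44, tibial_shaft_width = 48,
                         joint_center = c(128, 120), shaft_length = 100,
                         global_rotation = 0, intensity_noise_sd = 4,
                         blur_sigma = 1.2, implant = FALSE, seed = 1L) {
  stopifnot(femoral_shaft_width > 0, tibial_shaft_width > 0,
            shaft_length > 2 * max(femoral_shaft_width, tibial_shaft_width),
            abs(true_atfa) <= 30, image_size >= 64)
  structure(list(image_size = as.integer(image_size), true_atfa = true_atfa,
                 femoral_shaft_width = femoral_shaft_width,
                 tibial_shaft_width = tibial_shaft_width,
                 joint_center = as.numeric(joint_center),
                 shaft_length = shaft_length,
                 global_rotation = global_rotation,
                 intensity_noise_sd = intensity_noise_sd,
                 blur_sigma = blur_sigma, implant = isTRUE(implant),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Landmark/outline geometry shared by rendering and ground truth.  Returns
# the 40 landmarks, the two bone polygons and the schema.
phantom_geometry <- function(spec) {
  J <- spec$joint_center
  g <- spec$global_rotation * pi / 180
  a <- spec$true_atfa * pi / 180
  df <- dirvec(g); nf <- perpvec(g)           # femoral axis (distal dir)
  dt <- dirvec(g + a); nt <- perpvec(g + a)   # tibial axis (distal dir)
  Lf <- spec$shaft_length; wf <- spec$femoral_shaft_width
  gap <- 0.06 * Lf  # joint-space half-gap scales with the bone
  Lt <- 0.95 * spec$shaft_length; Wt <- spec$tibial_shaft_width
  fpt <- function(s, off) J - s * df + off * nf   # femur point (s up from joint)
  tpt <- function(s, off) J + s * dt + off * nt   # tibia point (s down)
  hw <- wf / 2
  # femur anchors
  s_top <- gap + Lf; s_red <- gap + 0.78 * Lf; s_m1 <- gap + 0.60 * Lf
  s_yel <- gap + 0.40 * Lf; s_cond <- gap + 0.10 * Lf; s_bot <- gap
  f <- list(
    redL = fpt(s_red, -hw),        redR = fpt(s_red, hw),
    yelL = fpt(s_yel, -hw),        yelR = fpt(s_yel, hw),
    ntchL = fpt(gap, -0.16 * wf),  ntchR = fpt(gap, 0.16 * wf),
    topL = fpt(s_top, -hw),        topR = fpt(s_top, hw),
    m1L = fpt(s_m1, -hw),          m1R = fpt(s_m1, hw),
    condL = fpt(s_cond, -0.85 * wf), condR = fpt(s_cond, 0.85 * wf),
    botL = fpt(s_bot, -0.72 * wf), botR = fpt(s_bot, 0.72 * wf),
    apex = fpt(gap + 0.16 * Lf, 0),
    m3L = fpt(gap + 0.89 * Lf, -hw), m3R = fpt(gap + 0.89 * Lf, hw),
    topM = fpt(s_top, 0))
  # m2: midpoint of the yellow->condyle outline segment (stays on the edge)
  f$m2L <- (f$yelL + f$condL) / 2
  f$m2R <- (f$yelR + f$condR) / 2
  # tibia anchors
  t_s <- list(p = gap, sh = gap + 0.12 * Lt, bk = gap + 0.30 * Lt,
              m4 = gap + 0.55 * Lt, bl = gap + 0.82 * Lt, bt = gap + Lt)
  tb <- list(
    cornL = tpt(t_s$p, -Wt / 2),    cornR = tpt(t_s$p, Wt / 2),
    blkL = tpt(t_s$bk, -0.40 * Wt), blkR = tpt(t_s$bk, 0.40 * Wt),
    bluL = tpt(t_s$bl, -0.33 * Wt), bluR = tpt(t_s$bl, 0.33 * Wt),
    shL = tpt(t_s$sh, -0.46 * Wt),  shR = tpt(t_s$sh, 0.46 * Wt),
    m4L = tpt(t_s$m4, -0.36 * Wt),  m4R = tpt(t_s$m4, 0.36 * Wt),
    botL = tpt(t_s$bt, -0.33 * Wt), botR = tpt(t_s$bt, 0.33 * Wt),
    botM = tpt(t_s$bt, 0),
    tmL = tpt(t_s$p, -0.25 * Wt),   tmR = tpt(t_s$p, 0.25 * Wt))
  # m5/m6: midpoints of outline segments black->m4 and blue->bottom
  tb$m5L <- (tb$blkL + tb$m4L) / 2; tb$m5R <- (tb$blkR + tb$m4R) / 2
  tb$m6L <- (tb$bluL + tb$botL) / 2; tb$m6R <- (tb$bluR + tb$botR) / 2
  tb$topM <- tpt(t_s$p, 0)

  pts <- rbind(f$redL, f$redR, f$yelL, f$yelR, f$ntchL, f$ntchR,   # 1..6
               f$topL, f$topR, f$m1L, f$m1R, f$condL, f$condR,     # 7..12
               f$botL, f$botR, f$apex, f$m2L, f$m2R, f$m3L, f$m3R, # 13..19
               f$topM,                                             # 20
               tb$cornL, tb$cornR, tb$blkL, tb$blkR, tb$bluL, tb$bluR, # 21..26
               tb$shL, tb$shR, tb$m4L, tb$m4R, tb$botL, tb$botR,   # 27..32
               tb$botM, tb$tmL, tb$tmR, tb$m5L, tb$m5R, tb$m6L,    # 33..38
               tb$m6R, tb$topM)                                    # 39..40
  schema <- landmark_schema(
    n_points = 40L,
    roles = list(
      femoral_shaft_pair_proximal = c(1L, 2L),
      femoral_shaft_pair_distal   = c(3L, 4L),
      femoral_notch_pair          = c(5L, 6L),
      tibial_shaft_pair_proximal  = c(23L, 24L),
      tibial_shaft_pair_distal    = c(25L, 26L),
      plateau_corner_left  = 21L,
      plateau_corner_right = 22L),
    curves = list(
      femur = c(7L, 18L, 1L, 9L, 3L, 16L, 11L, 13L, 5L, 15L, 6L, 14L, 12L,
                17L, 4L, 10L, 2L, 19L, 8L, 20L, 7L),
      tibia = c(21L, 27L, 23L, 36L, 29L, 25L, 38L, 31L, 33L, 32L, 39L, 26L,
                30L, 37L, 24L, 28L, 22L, 35L, 40L, 34L, 21L)))
  femur_poly <- rbind(f$topL, f$m3L, f$redL, f$m1L, f$yelL, f$m2L, f$condL,
                      f$botL, f$ntchL, f$apex, f$ntchR, f$botR, f$condR,
                      f$m2R, f$yelR, f$m1R, f$redR, f$m3R, f$topR, f$topM)
  tibia_poly <- rbind(tb$cornL, tb$shL, tb$blkL, tb$m5L, tb$m4L, tb$bluL,
                      tb$m6L, tb$botL, tb$botM, tb$botR, tb$m6R, tb$bluR,
                      tb$m4R, tb$m5R, tb$blkR, tb$shR, tb$cornR, tb$tmR,
                      tb$topM, tb$tmL)
  implant_poly <- rbind(fpt(gap, -0.65 * wf), fpt(gap + 0.12 * Lf, -0.75 * wf),
                        fpt(gap + 0.12 * Lf, 0.75 * wf), fpt(gap, 0.65 * wf),
                        tpt(gap + 0.06 * Lt, 0.40 * Wt),
                        tpt(gap + 0.06 * Lt, -0.40 * Wt))
  list(points = pts, schema = schema, femur = femur_poly, tibia = tibia_poly,
       implant = implant_poly)
}

# Even-odd polygon rasterization on the 0-based pixel-centre grid.
polygon_mask <- function(size, poly) {
  px <- rep(0:(size - 1), each = size)   # x per pixel (column-major H x W)
  py <- rep(0:(size - 1), times = size)  # y
  n <- nrow(poly)
  inside <- rep(FALSE, size * size)
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]; x2 <- poly[i, 1]; y2 <- poly[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  matrix(inside, nrow = size, ncol = size)
}

# Separable Gaussian blur with edge renormalisation (band-matrix products).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  n <- nrow(img)
  B <- matrix(0, n, n)
  for (d in -r:r) {
    idx <- seq_len(n)
    src <- idx + d
    ok <- src >= 1 & src <= n
    B[cbind(idx[ok], src[ok])] <- B[cbind(idx[ok], src[ok])] + k[d + r + 1]
  }
  B <- B / rowSums(B)
  B %*% img %*% t(B)
}

#' Generate one synthetic knee phantom
#'
#' Deterministic for a fixed spec (including its seed). The femoral shaft
#' midpoints and the notch midpoint are collinear by construction and the
#' tibial axis subtends `spec$true_atfa` with the femoral axis prolongation,
#' so FTS and FNTS on the ground-truth landmarks both recover the generating
#' angle (to floating-point precision).
#'
#' @param spec a [phantom_spec()].
#' @param render render the image (set FALSE for landmark-only work; the
#'   `image` element is then NULL).
#' @return object of class `phantom_sample`: list(image, landmarks, spec).
#' @export
generate_phantom <- function(spec, render = TRUE) {
  geo <- phantom_geometry(spec)
  S <- spec$image_size
  oob <- which(geo$points[, 1] < 0 | geo$points[, 1] > S - 1 |
               geo$points[, 2] < 0 | geo$points[, 2] > S - 1)
  if (length(oob)) {
    stop(sprintf(paste0("generate_phantom: landmark %d at (%.1f, %.1f) is ",
                        "outside the %dpx image; reduce shaft_length (%.0f), ",
                        "global_rotation (%.1f deg) or move joint_center ",
                        "(%.0f, %.0f)"),
                 oob[1], geo$points[oob[1], 1], geo$points[oob[1], 2], S,
                 spec$shaft_length, spec$global_rotation,
                 spec$joint_center[1], spec$joint_center[2]))
  }
  lm <- landmark_set(geo$points, geo$schema)
  img <- NULL
  if (render) {
    img <- matrix(0.08, S, S)
    img[polygon_mask(S, geo$tibia)] <- 0.82
    img[polygon_mask(S, geo$femur)] <- 0.88
    if (spec$implant) img[polygon_mask(S, geo$implant)] <- 1.0
    img <- gaussian_blur(img, spec$blur_sigma)
    set.seed(spec$seed)
    img <- img + matrix(rnorm(S * S, sd = spec$intensity_noise_sd / 255), S, S)
    img <- pmin(pmax(img, 0), 1)
  }
  structure(list(image = img, landmarks = lm, spec = spec),
            class = "phantom_sample")
}

default_spec_ranges <- function(image_size = 256L) {
  # ranges chosen so every draw satisfies the spec invariants
  # (shaft_length > 2*max(width); all landmarks inside the image for any
  # |pose| <= 10 deg and |aTFA| <= 15 deg); spatial quantities scale with
  # the image size (stated for 256 px)
  s <- image_size / 256
  list(true_atfa = c(-15, 15), global_rotation = c(-10, 10),
       femoral_shaft_width = s * c(36, 44), tibial_shaft_width = s * c(40, 46),
       joint_center_x = s * c(116, 140), joint_center_y = s * c(114, 130),
       shaft_length = s * c(94, 106), intensity_noise_sd = c(4, 4),
       blur_sigma = c(1.2, 1.2))
}

#' Generate a phantom dataset
#'
#' Draws phantom parameters uniformly from `spec_ranges` (see
#' `kneemark:::default_spec_ranges()` for the stated defaults) with a single
#' seeded stream. When `dir` is given, writes 8-bit PGM images, PTS landmark
#' files, a schema file and a `manifest.csv` (id, image, pts, laterality,
#' true_atfa).
#'
#' @param n number of samples (>= 1).
#' @param spec_ranges named list of `c(lo, hi)` ranges; unnamed entries fall
#'   back to the defaults.
#' @param seed integer seed controlling all draws and per-sample noise.
#' @param dir optional output directory.
#' @param render render images (FALSE = landmarks only, no files written).
#' @param image_size,implant passed through to [phantom_spec()].
#' @return list with `samples` (list of phantom_sample), `manifest`
#'   (data.frame) and `schema`.
#' @export
generate_dataset <- function(n, spec_ranges = list(), seed = 1L, dir = NULL,
                             render = TRUE, image_size = 256L,
                             implant = FALSE) {
  stopifnot(n >= 1)
  rng <- utils::modifyList(default_spec_ranges(image_size), spec_ranges)
  set.seed(seed)
  draw <- function(nm) runif(n, rng[[nm]][1], rng[[nm]][2])
  pars <- lapply(stats::setNames(nm = names(rng)), draw)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(image_size = image_size,
                       true_atfa = pars$true_atfa[i],
                       femoral_shaft_width = pars$femoral_shaft_width[i],
                       tibial_shaft_width = pars$tibial_shaft_width[i],
                       joint_center = c(pars$joint_center_x[i],
                                        pars$joint_center_y[i]),
                       shaft_length = pars$shaft_length[i],
                       global_rotation = pars$global_rotation[i],
                       intensity_noise_sd = pars$intensity_noise_sd[i],
                       blur_sigma = pars$blur_sigma[i],
                       implant = implant, seed = sub_seeds[i])
    samples[[i]] <- generate_phantom(sp, render = render)
  }
  ids <- sprintf("phantom_%04d", seq_len(n))
  manifest <- data.frame(id = ids,
                         image = paste0(ids, ".pgm"),
                         pts = paste0(ids, ".pts"),
                         laterality = "left",
                         true_atfa = pars$true_atfa,
                         stringsAsFactors = FALSE)
  schema <- samples[[1]]$landmarks$schema
  if (!is.null(dir) && render) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_pgm(samples[[i]]$image, file.path(dir, manifest$image[i]))
      write_pts(samples[[i]]$landmarks, file.path(dir, manifest$pts[i]))
    }
    write_schema(schema, file.path(dir, "schema.txt"))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest, schema = schema)
}
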