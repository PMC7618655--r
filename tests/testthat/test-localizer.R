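test_that("frames send reference points to the canonical anchors", {
  fsp <- frame_spec(128)
  t <- make_frame(c(100, 150), c(140, 160), fsp)
  expect_equal(unname(transform_apply(t, c(100, 150))),
               unname(fsp$anchor_left), tolerance = 1e-9)
  expect_equal(unname(transform_apply(t, c(140, 160))),
               unname(fsp$anchor_right), tolerance = 1e-9)
  # refs already at anchors -> identity
  tid <- make_frame(fsp$anchor_left, fsp$anchor_right, fsp)
  expect_equal(tid$scale, 1, tolerance = 1e-12)
  expect_equal(tid$rotation, 0, tolerance = 1e-12)
  expect_error(make_frame(c(5, 5), c(5.5, 5), fsp), "degenerate")
})

test_that("frame rotation and scale follow the reference pair", {
  fsp <- frame_spec(128)
  mid <- c(120, 130); half <- c(20, 0)
  rot <- function(v, deg) {
    th <- deg * pi / 180
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }
  t0 <- make_frame(mid - half, mid + half, fsp)
  t10 <- make_frame(mid - rot(half, 10), mid + rot(half, 10), fsp)
  expect_equal(t10$rotation - t0$rotation, -10 * pi / 180, tolerance = 1e-9)
  t2 <- make_frame(mid - 2 * half, mid + 2 * half, fsp)
  expect_equal(t2$scale, t0$scale / 2, tolerance = 1e-12)
})

test_that("to-frame/from-frame round trip is exact on landmark sets", {
  set.seed(61)
  fsp <- frame_spec(128)
  for (i in 1:100) {
    r1 <- runif(2, 40, 100); r2 <- r1 + runif(2, 10, 60)
    t <- make_frame(r1, r2, fsp)
    pts <- matrix(runif(40, 0, 255), 20, 2)
    back <- transform_apply(transform_invert(t), transform_apply(t, pts))
    expect_lt(max(abs(back - pts)), 1e-6)
  }
})

test_that("resampling into an identity frame reproduces the image", {
  ph <- cached_phantom(7)
  crop <- resample_to_frame(ph$image, similarity_transform(),
                            ph$spec$image_size)
  expect_lt(max(abs(crop - ph$image)), 1e-6)
  # fully out-of-bounds frame: constant fill at the image minimum
  t_off <- similarity_transform(translation = c(-5000, -5000))
  far <- resample_to_frame(ph$image, t_off, 32)
  expect_equal(unique(as.vector(far)), min(ph$image))
})

test_that("2x downscaling preserves mean intensity of the covered region", {
  ph <- cached_phantom(7)
  t <- similarity_transform(scale = 0.5)
  small <- resample_to_frame(ph$image, t, 128)
  expect_equal(mean(small), mean(ph$image), tolerance = 0.02 * mean(ph$image))
})

test_that("global search with an oracle model recovers the plateau corners", {
  ph <- cached_phantom(7)
  gcfg <- model_config(depth = 4L, width = 2L, n_landmarks = 2L,
                       input_size = 64L, heatmap_stride = 1L,
                       heatmap_sigma = 1.5)
  rz <- resize_for_input(ph$image, 64)
  corners <- rbind(role_points(ph$landmarks, "plateau_corner_left"),
                   role_points(ph$landmarks, "plateau_corner_right"))
  om <- fixed_oracle(gcfg, transform_apply(rz$transform, corners))
  gs <- global_search(ph$image, om)
  # 0.5 px in the 64px frame scales by 4 in the original image
  expect_lt(max(abs(gs$ref_left - corners[1, ])), 2)
  expect_lt(max(abs(gs$ref_right - corners[2, ])), 2)
  # untrained model on a blank image: the near-zero head decodes both
  # channels to the map centre, which is exactly the documented
  # degenerate-frame failure (error, never a silent fallback)
  m <- build_hourglass(model_config(depth = 2L, width = 2L,
                                    n_landmarks = 2L, input_size = 64L,
                                    heatmap_stride = 4L, seed = 12))
  blank <- matrix(0.2, 256, 256) + 1e-3 * matrix(runif(256^2), 256)
  expect_error(global_search(blank, m), "degenerate")
  # on a structured (noise) image the same untrained model must return
  # finite points without crashing
  set.seed(3)
  m$params$head2.W <- matrix(rnorm(length(m$params$head2.W), sd = 3),
                             nrow(m$params$head2.W))
  noisy <- matrix(runif(256^2), 256)
  gs0 <- global_search(noisy, m)
  expect_true(all(is.finite(c(gs0$ref_left, gs0$ref_right))))
})

test_that("oracle-driven two-stage pipeline recovers ground truth", {
  fsp <- frame_spec(128, anchor_sep_frac = 0.17)
  gcfg <- model_config(depth = 4L, width = 2L, n_landmarks = 2L,
                       input_size = 64L, heatmap_stride = 1L)
  lcfg <- model_config(depth = 4L, width = 2L, n_landmarks = 40L,
                       input_size = 128L, heatmap_stride = 1L)
  d <- generate_dataset(10, seed = 31)
  errs <- vapply(d$samples, function(s) {
    corners <- rbind(role_points(s$landmarks, "plateau_corner_left"),
                     role_points(s$landmarks, "plateau_corner_right"))
    rz <- resize_for_input(s$image, 64)
    gm <- fixed_oracle(gcfg, transform_apply(rz$transform, corners))
    # the local oracle must emit heatmaps in the frame the pipeline will
    # actually build, i.e. from the global stage's decoded corners
    gs <- global_search(s$image, gm)
    t <- make_frame(gs$ref_left, gs$ref_right, fsp)
    lm <- fixed_oracle(lcfg, transform_apply(t, s$landmarks$points))
    pred <- localize(s$image, gm, lm, fsp, s$landmarks$schema)
    max(p2p(pred, s$landmarks))
  }, 0)
  expect_lt(max(errs), 1)
})

test_that("oracle pipeline is equivariant to input translation", {
  ph <- generate_phantom(phantom_spec(true_atfa = -6, seed = 8,
                                      joint_center = c(116, 112)))
  fsp <- frame_spec(128, anchor_sep_frac = 0.17)
  gcfg <- model_config(depth = 4L, width = 2L, n_landmarks = 2L,
                       input_size = 64L, heatmap_stride = 1L)
  lcfg <- model_config(depth = 4L, width = 2L, n_landmarks = 40L,
                       input_size = 128L, heatmap_stride = 1L)
  run_oracle <- function(img, lmset) {
    corners <- rbind(role_points(lmset, "plateau_corner_left"),
                     role_points(lmset, "plateau_corner_right"))
    rz <- resize_for_input(img, 64)
    gm <- fixed_oracle(gcfg, transform_apply(rz$transform, corners))
    t <- make_frame(corners[1, ], corners[2, ], fsp)
    lm <- fixed_oracle(lcfg, transform_apply(t, lmset$points))
    localize(img, gm, lm, fsp, lmset$schema)
  }
  base <- run_oracle(ph$image, ph$landmarks)
  dx <- 20L; dy <- 12L
  shifted <- matrix(min(ph$image), 256, 256)
  shifted[(dy + 1):256, (dx + 1):256] <-
    ph$image[1:(256 - dy), 1:(256 - dx)]
  lm_shift <- landmark_set(sweep(ph$landmarks$points, 2, c(dx, dy), `+`),
                           ph$landmarks$schema)
  moved <- run_oracle(shifted, lm_shift)
  delta <- moved$points - base$points
  expect_lt(max(abs(delta[, 1] - dx)), 1)
  expect_lt(max(abs(delta[, 2] - dy)), 1)
})

test_that("localize validates model/schema/frame compatibility", {
  sch <- tiny_schema()
  gm <- build_hourglass(model_config(depth = 2L, width = 2L,
                                     n_landmarks = 2L, input_size = 64L))
  lm <- build_hourglass(model_config(depth = 2L, width = 2L,
                                     n_landmarks = 5L, input_size = 128L))
  img <- matrix(0.5, 128, 128)
  expect_error(localize(img, gm, lm, frame_spec(64), sch), "crop_size")
  expect_error(localize(img, gm, lm, frame_spec(128), sch), "differ")
})
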