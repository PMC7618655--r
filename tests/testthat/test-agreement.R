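test_that("p2p is the per-point Euclidean distance", {
  l <- straight_tiny_set()
  expect_equal(p2p(l, l), rep(0, 12))
  pts <- l$points
  pts[1, ] <- pts[1, ] + c(3, 4)
  expect_equal(p2p(landmark_set(pts, l$schema), l)[1], 5)
  set.seed(55)
  a <- matrix(runif(40, 0, 100), 20, 2)
  b <- matrix(runif(40, 0, 100), 20, 2)
  brute <- vapply(1:20, function(i) {
    sqrt((a[i, 1] - b[i, 1])^2 + (a[i, 2] - b[i, 2])^2)
  }, 0)
  expect_equal(p2p(a, b), brute, tolerance = 1e-12)
})

test_that("p2c measures distance to the own-bone polyline", {
  # straight 3-point polyline along y = 0
  gt <- rbind(c(0, 0), c(10, 0), c(20, 0))
  curves <- list(bone = 1:3)
  # prediction slid along the boundary tangent: P2C ~ 0, P2P > 0
  pred <- rbind(c(3, 0), c(10, 0), c(20, 0))
  sch <- NULL  # use matrices + explicit curves through the internal helper
  d <- kneemark:::dist_to_polyline(pred, gt)
  expect_lt(max(d), 1e-12)
  expect_gt(sqrt(sum((pred[1, ] - gt[1, ])^2)), 0)
  # off-curve point: clamped projection
  expect_equal(kneemark:::dist_to_polyline(rbind(c(25, 5)), gt)[1],
               sqrt(25 + 25))
})

test_that("p2c agrees with dense polyline sampling", {
  ph <- cached_phantom(7)
  gt <- ph$landmarks
  set.seed(19)
  pred <- landmark_set(gt$points + matrix(rnorm(80, sd = 3), 40, 2),
                       gt$schema)
  impl <- p2c(pred, gt)
  # sampling oracle: 1e4 points per segment on the own-bone polyline
  curves <- gt$schema$curves
  owner <- rep(NA_integer_, 40)
  for (ci in seq_along(curves)) owner[curves[[ci]]] <- ci
  brute <- vapply(1:40, function(i) {
    poly <- gt$points[curves[[owner[i]]], ]
    dmin <- Inf
    for (s in seq_len(nrow(poly) - 1)) {
      tt <- seq(0, 1, length.out = 1e4)
      sx <- poly[s, 1] + tt * (poly[s + 1, 1] - poly[s, 1])
      sy <- poly[s, 2] + tt * (poly[s + 1, 2] - poly[s, 2])
      dmin <- min(dmin, sqrt((sx - pred$points[i, 1])^2 +
                               (sy - pred$points[i, 2])^2))
    }
    dmin
  }, 0)
  expect_lt(max(abs(impl - brute)), 1e-3)
  expect_true(all(impl <= p2p(pred, gt) + 1e-12))
})

test_that("reference_length reads the plateau corner separation", {
  l <- straight_tiny_set()
  pts <- l$points
  pts[11, ] <- c(0, 0); pts[12, ] <- c(30, 0)
  expect_equal(reference_length(landmark_set(pts, l$schema)), 30)
  pts[12, ] <- pts[11, ]
  expect_error(reference_length(landmark_set(pts, l$schema)), "zero reference")
})

test_that("summaries use linear-interpolation percentiles", {
  expect_equal(summarize_localization(rep(3.2, 7)),
               c(mean = 3.2, median = 3.2, p95 = 3.2))
  s <- summarize_localization(1:100)
  expect_equal(unname(s["median"]), 50.5)
  expect_equal(unname(s["p95"]), 95.05)
  expect_equal(summarize_localization(sample(1:100)), s)
  expect_error(summarize_localization(numeric(0)), "empty")
})

test_that("ICC(2,1) matches an independent ANOVA mean-squares oracle", {
  icc_oracle <- function(a, b) {
    # independent route: two-way ANOVA via stats::aov
    n <- length(a)
    df <- data.frame(y = c(a, b),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  }
  set.seed(71)
  for (n in c(6, 10)) {
    a <- rnorm(n, 5, 2)
    b <- a + rnorm(n, 0.3, 0.8)
    expect_equal(icc_agreement(a, b)$icc, icc_oracle(a, b),
                 tolerance = 1e-9)
  }
})

test_that("ICC edge behaviour: identity, bias penalty, degeneracies", {
  a <- c(1, 3, 5, 7, 9, 11)
  expect_equal(icc_agreement(a, a)$icc, 1)
  set.seed(3)
  big <- rnorm(200, 0, 3)
  r <- icc_agreement(big, big + 2)
  expect_lt(r$icc, 1)
  expect_gt(r$icc, 0)
  expect_true(r$ci[1] <= r$icc && r$icc <= r$ci[2])
  expect_error(icc_agreement(1:2, 2:3), "at least 3")
  flat <- icc_agreement(rep(1, 5), rep(1, 5))
  expect_true(is.na(flat$icc))
  expect_match(flat$flag, "undefined")
})

test_that("MAD agreement matches direct formula evaluation", {
  expect_equal(mad_agreement(1:5, 1:5), list(mad = 0, sd = 0, n = 5L))
  r <- mad_agreement(c(1, 0), c(0, 1))  # differences 1, -1
  expect_equal(r$mad, 1); expect_equal(r$sd, 0)
  set.seed(12)
  a <- rnorm(50); b <- rnorm(50)
  r2 <- mad_agreement(a, b)
  expect_equal(r2$mad, mean(abs(a - b)), tolerance = 1e-12)
  expect_equal(r2$sd, sd(abs(a - b)), tolerance = 1e-12)
  k <- 3.7
  expect_equal(mad_agreement(k * a, k * b)$mad, k * r2$mad,
               tolerance = 1e-12)
})

test_that("Bland-Altman bias/sd/limits and antisymmetry", {
  a <- c(1, 2, 3, 4)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$sd, 0)
  expect_equal(bland_altman(a, a - 0.5)$bias, 0.5)
  set.seed(44)
  x <- rnorm(30); y <- x + rnorm(30, 0.2, 0.5)
  r <- bland_altman(x, y)
  expect_equal(r$bias, mean(x - y), tolerance = 1e-12)
  expect_equal(r$sd, sd(x - y), tolerance = 1e-12)
  expect_equal(r$loa, r$bias + c(-1.96, 1.96) * r$sd)
  expect_equal(bland_altman(y, x)$bias, -r$bias)
})

test_that("evaluate_run reproduces known jitter statistics", {
  d <- generate_dataset(40, seed = 21, render = FALSE)
  gt <- setNames(lapply(d$samples, `[[`, "landmarks"), d$manifest$id)
  # exact predictions: all-zero errors, perfect agreement
  r0 <- evaluate_run(gt, gt)
  expect_equal(r0$localization$mean, c(0, 0))
  expect_equal(r0$agreement$mad, c(0, 0))
  expect_equal(r0$agreement$baa_bias, c(0, 0))
  expect_equal(r0$agreement$icc, c(1, 1))
  # iid Gaussian jitter sd 1: mean P2P ~ E|N2(0,I)| = sqrt(pi/2)
  set.seed(99)
  pred <- lapply(gt, function(l) {
    landmark_set(l$points + matrix(rnorm(80), 40, 2), l$schema)
  })
  r1 <- evaluate_run(gt, pred)
  expected_rp2p <- mean(100 * sqrt(pi / 2) / r1$per_image$ref_length)
  expect_equal(r1$localization$mean[1], expected_rp2p, tolerance = 0.08)
  expect_true(all(r1$per_image$rP2C <= r1$per_image$rP2P + 1e-12))
  # deterministic rerun
  r2 <- evaluate_run(gt, pred)
  expect_identical(r1$localization, r2$localization)
  # missing predictions: run continues on the intersection
  expect_warning(r3 <- evaluate_run(gt, pred[-(1:2)]), "missing")
  expect_equal(nrow(r3$per_image), 38L)
  expect_equal(sort(r3$missing), sort(d$manifest$id[1:2]))
})
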