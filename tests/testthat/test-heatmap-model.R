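test_that("wing loss matches the closed form and is continuous at |x| = w", {
  wp <- wing_params(w = 10, epsilon = 2)
  expect_equal(wing_loss(cbind(0, 0), cbind(0, 0), wp), 0)
  # single residual x = 1 (one coordinate differs): mean over 2 residuals
  expect_equal(wing_loss(cbind(1, 0), cbind(0, 0), wp),
               10 * log(1.5) / 2)
  # both branches at |x| = w
  log_branch <- wp$w * log(1 + wp$w / wp$epsilon)
  lin_branch <- wp$w - wp$C
  expect_equal(log_branch, 10 * log(6))
  expect_lt(abs(log_branch - lin_branch), 1e-9)
})

test_that("wing loss equals brute-force piecewise evaluation on random residuals", {
  wp <- wing_params()
  set.seed(31)
  r <- runif(1000, -40, 40)
  brute <- vapply(r, function(x) {
    if (abs(x) < wp$w) wp$w * log(1 + abs(x) / wp$epsilon) else abs(x) - wp$C
  }, 0)
  impl <- vapply(r, function(x) wing_loss(cbind(x, 0), cbind(0, 0), wp) * 2, 0)
  expect_lt(max(abs(impl - brute)), 1e-9)
  # even, nonnegative, zero iff zero
  expect_equal(impl, vapply(-r, function(x) {
    wing_loss(cbind(x, 0), cbind(0, 0), wp) * 2
  }, 0))
  expect_true(all(brute[r != 0] > 0))
})

test_that("heatmap encode/decode round-trips interior landmarks", {
  cfg <- model_config(depth = 4L, width = 4L, n_landmarks = 5L,
                      input_size = 64L, heatmap_stride = 1L,
                      heatmap_sigma = 1.5)
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    pts <- cbind(runif(5, 5, 58), runif(5, 5, 58))
    dec <- decode_heatmaps(encode_heatmaps(pts, cfg), cfg)
    worst <- max(worst, sqrt(rowSums((dec - pts)^2)))
  }
  expect_lt(worst, 0.5)
})

test_that("encoding centres peak at the landmark; coincident landmarks share maps", {
  cfg <- model_config(depth = 2L, width = 2L, n_landmarks = 2L,
                      input_size = 32L, heatmap_stride = 1L)
  hm <- encode_heatmaps(rbind(c(16, 16), c(16, 16)), cfg)
  idx <- which(hm[, , 1] == max(hm[, , 1]), arr.ind = TRUE)
  expect_equal(unname(idx), matrix(c(17, 17), 1))  # 0-based (16,16)
  expect_identical(hm[, , 1], hm[, , 2])
  expect_error(encode_heatmaps(rbind(c(100, 5), c(5, 5)), cfg), "indices: 1")
})

test_that("decoding handles impulses, symmetric maps and constants", {
  cfg <- model_config(depth = 2L, width = 2L, n_landmarks = 1L,
                      input_size = 64L, heatmap_stride = 1L)
  imp <- array(0, c(64, 64, 1))
  imp[21, 11, 1] <- 1  # 0-based (x=10, y=20)
  dec <- decode_heatmaps(imp, cfg)
  expect_equal(unname(dec[1, ]), c(10, 20), tolerance = 1e-4)

  two <- array(0, c(64, 64, 1))
  two[11, 11, 1] <- 1; two[11, 31, 1] <- 1  # x = 10 and 30, y = 10
  dec2 <- decode_heatmaps(two, cfg)
  expect_equal(unname(dec2[1, ]), c(20, 10), tolerance = 1e-4)

  unif <- array(0.5, c(64, 64, 1))
  expect_warning(dec3 <- decode_heatmaps(unif, cfg), "constant")
  expect_equal(unname(dec3[1, ]), c(31.5, 31.5))
})

test_that("hourglass forward obeys shape/finiteness contracts", {
  cfg <- model_config(depth = 2L, width = 4L, n_landmarks = 3L,
                      input_size = 64L, heatmap_stride = 4L, seed = 5)
  m <- build_hourglass(cfg)
  x <- array(0, c(64, 64, 2, 1))
  hm <- model_heatmaps(m, x)
  expect_equal(dim(hm), c(16L, 16L, 2L, 3L))
  expect_true(all(is.finite(hm)))
  # doubling width leaves output shapes unchanged
  m2 <- build_hourglass(model_config(depth = 2L, width = 8L, n_landmarks = 3L,
                                     input_size = 64L, heatmap_stride = 4L))
  expect_equal(dim(model_heatmaps(m2, x)), dim(hm))
  expect_error(model_config(depth = 4L, width = 4L, n_landmarks = 3L,
                            input_size = 60L), "divisible")
})

test_that("attention coefficients are sigmoidal gates in (0,1)", {
  cfg <- model_config(depth = 1L, width = 4L, n_landmarks = 1L,
                      input_size = 16L, heatmap_stride = 1L, seed = 3)
  m <- build_hourglass(cfg)
  set.seed(4)
  x <- array(runif(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  g <- array(runif(8 * 8 * 2 * 4), c(8, 8, 2, 4))
  ag <- kneemark:::ag_fw(m$params, "l1.ag", x, g)
  expect_true(all(ag$a > 0 & ag$a < 1))
  expect_true(all(abs(ag$out) <= abs(x)))
  # all-zero gating signal: coefficients constant over space per batch item
  g0 <- array(0, dim(g))
  x0 <- array(rep(1, length(x)), dim(x))
  ag0 <- kneemark:::ag_fw(m$params, "l1.ag", x0, g0)
  expect_lt(diff(range(ag0$a)), 1e-12)
})

test_that("backprop matches central finite differences on a tiny model", {
  cfg <- model_config(depth = 2L, width = 3L, n_landmarks = 2L,
                      input_size = 16L, heatmap_stride = 2L, seed = 7)
  m <- build_hourglass(cfg)
  set.seed(42)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  targ <- list(matrix(c(4, 5, 10, 11), 2, 2, byrow = TRUE),
               matrix(c(8, 3, 6, 12), 2, 2, byrow = TRUE))
  wp <- wing_params()
  lossfn <- function(mm) {
    kneemark:::coord_loss(kneemark:::hg_forward(mm, x)$hm, targ, cfg, wp)$loss
  }
  fw <- kneemark:::hg_forward(m, x, keep_cache = TRUE)
  cl <- kneemark:::coord_loss(fw$hm, targ, cfg, wp)
  gr <- kneemark:::hg_backward(m, fw$cache, cl$dhm)
  eps <- 1e-5
  set.seed(1)
  for (nm in sample(names(m$params), 10)) {
    w <- m$params[[nm]]
    for (ii in sample(length(w), min(2, length(w)))) {
      mp <- m; mp$params[[nm]][ii] <- w[ii] + eps
      mm2 <- m; mm2$params[[nm]][ii] <- w[ii] - eps
      num <- (lossfn(mp) - lossfn(mm2)) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-3)
    }
  }
})

test_that("a short training run is reproducible and reduces the loss", {
  set.seed(8)
  samples <- lapply(1:6, function(i) {
    img <- matrix(0.1, 32, 32)
    cx <- sample(8:24, 1); cy <- sample(8:24, 1)
    img[cy + (-2:2), cx + (-2:2)] <- 1
    list(image = img, landmarks = cbind(cx - 1, cy - 1))
  })
  cfg <- model_config(depth = 2L, width = 4L, n_landmarks = 1L,
                      input_size = 32L, heatmap_stride = 2L, seed = 2)
  tc <- train_config(epochs = 4L, learning_rate = 2e-3, batch_size = 3L,
                     seed = 9)
  f1 <- train_stage(build_hourglass(cfg), samples, tc)
  expect_true(all(is.finite(f1$history$train_loss)))
  expect_lt(tail(f1$history$val_loss, 1), f1$history$val_loss[1])
  f2 <- train_stage(build_hourglass(cfg), samples, tc)
  expect_identical(f1$history, f2$history)
  expect_error(train_stage(build_hourglass(cfg), list(), tc), "empty")
})
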