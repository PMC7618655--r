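# Localization metrics (P2P / P2C, relative to the tibial-plateau reference
# length) and method-agreement statistics (ICC(2,1), mean absolute
# difference, Bland-Altman).

#' Point-to-point distances
#'
#' Euclidean distance between each predicted point and its ground-truth
#' counterpart. Per-image values are conventionally the mean over points.
#'
#' @param pred,gt landmark sets (or n x 2 matrices) with matching schemas.
#' @return numeric vector of per-point distances, pixels.
#' @export
p2p <- function(pred, gt) {
  p <- if (inherits(pred, "landmark_set")) pred$points else as.matrix(pred)
  g <- if (inherits(gt, "landmark_set")) gt$points else as.matrix(gt)
  if (nrow(p) != nrow(g)) stop("p2p: schema/point-count mismatch")
  sqrt(rowSums((p - g)^2))
}

# Minimum distance from points to an open polyline (clamped point-to-segment
# projections).
dist_to_polyline <- function(pts, poly) {
  n_seg <- nrow(poly) - 1L
  d2 <- matrix(Inf, nrow(pts), n_seg)
  for (s in seq_len(n_seg)) {
    a <- poly[s, ]; b <- poly[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2[, s] <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
      next
    }
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2[, s] <- (pts[, 1] - (a[1] + t * ab[1]))^2 +
               (pts[, 2] - (a[2] + t * ab[2]))^2
  }
  sqrt(apply(d2, 1L, min))
}

#' Point-to-curve distances
#'
#' Distance from each predicted point to the ground-truth bone outline its
#' counterpart belongs to: the minimum clamped point-to-segment distance
#' over the polyline of that point's own bone (never the other bone's
#' contour, which would give spuriously small values).
#'
#' @param pred,gt landmark sets with matching schemas.
#' @param curves named list of ordered ground-truth index vectors, one open
#'   polyline per bone; defaults to `gt$schema$curves`.
#' @return numeric vector of per-point distances, pixels.
#' @export
p2c <- function(pred, gt, curves = NULL) {
  p <- if (inherits(pred, "landmark_set")) pred$points else as.matrix(pred)
  g <- if (inherits(gt, "landmark_set")) gt$points else as.matrix(gt)
  if (nrow(p) != nrow(g)) stop("p2c: schema/point-count mismatch")
  if (is.null(curves)) curves <- gt$schema$curves
  if (is.null(curves)) stop("p2c: no curve topology available")
  owner <- rep(NA_integer_, nrow(p))
  for (ci in seq_along(curves)) owner[curves[[ci]]] <- ci
  if (anyNA(owner)) {
    stop("p2c: point index not on any polyline: ",
         paste(which(is.na(owner)), collapse = ", "))
  }
  out <- numeric(nrow(p))
  for (ci in seq_along(curves)) {
    idx <- which(owner == ci)
    out[idx] <- dist_to_polyline(p[idx, , drop = FALSE],
                                 g[curves[[ci]], , drop = FALSE])
  }
  out
}

#' Reference length: tibial plateau corner separation
#'
#' Distance between the two plateau-corner ground-truth landmarks (the
#' "tibial shaft width" reference used to express rP2P/rP2C as percentages).
#'
#' @param gt a [landmark_set()] with plateau-corner roles.
#' @return positive scalar, pixels.
#' @export
reference_length <- function(gt) {
  a <- role_points(gt, "plateau_corner_left")
  b <- role_points(gt, "plateau_corner_right")
  len <- sqrt(sum((a - b)^2))
  if (len == 0) stop("reference_length: coincident plateau corners (zero reference length)")
  len
}

#' Summarise per-image localization values
#'
#' 95th percentile by linear interpolation between closest order statistics
#' (R's quantile type 7) — "95%ile" has several conventions; this one is the
#' declared choice.
#'
#' @param values numeric vector of per-image values (n >= 1).
#' @return named vector: mean, median, p95.
#' @export
summarize_localization <- function(values) {
  if (!length(values)) stop("summarize_localization: empty input")
  c(mean = mean(values), median = median(values),
    p95 = unname(quantile(values, 0.95, type = 7)))
}

#' Intraclass correlation ICC(2,1) with 95% CI
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' computed from the two-way ANOVA mean squares; the confidence interval
#' uses the standard F-distribution formula (Satterthwaite degrees of
#' freedom for the lower/upper bounds).
#'
#' @param a,b paired measurement series (n >= 3).
#' @param conf confidence level (default 0.95).
#' @return list: `icc`, `ci` (length 2), `n`, `flag` (NULL, or a string when
#'   the ICC is undefined because total variance is zero).
#' @export
icc_agreement <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3L) stop("icc_agreement: need at least 3 paired values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("icc_agreement: non-finite values")
  k <- 2L
  x <- cbind(a, b)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)         # subjects
  ssc <- n * sum((col_m - grand)^2)         # raters/methods
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr == 0 && msc == 0 && mse == 0)) {
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                flag = "zero total variance: ICC undefined"))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf
  aa <- k * icc / (n * (1 - icc))
  bb <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci = c(lower, upper), n = n, flag = NULL)
}

#' Mean absolute difference between paired series
#'
#' @param a,b paired series (n >= 1).
#' @return list: `mad` (mean of |a - b|), `sd` (n-1 denominator; 0 when
#'   n = 1), `n`.
#' @export
mad_agreement <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  d <- abs(a - b)
  list(mad = mean(d), sd = if (length(d) > 1L) sd(d) else 0, n = length(d))
}

#' Bland-Altman analysis
#'
#' Bias = mean(a - b), sd with n-1 denominator, 95% limits of agreement
#' bias +/- 1.96 sd. Optionally writes a difference-vs-mean plot (PDF).
#'
#' @param a,b paired series (n >= 2).
#' @param plot_file optional path for a Bland-Altman plot.
#' @return list: `bias`, `sd`, `loa` (length-2 limits), `n`.
#' @export
bland_altman <- function(a, b, plot_file = NULL) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("bland_altman: need at least 2 pairs")
  d <- a - b
  bias <- mean(d); s <- sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  if (!is.null(plot_file)) {
    grDevices::pdf(plot_file, width = 5, height = 4)
    on.exit(grDevices::dev.off())
    graphics::plot((a + b) / 2, d, xlab = "mean of methods",
                   ylab = "difference (a - b)", main = "Bland-Altman",
                   pch = 19, cex = 0.6)
    graphics::abline(h = c(bias, loa), lty = c(1, 2, 2), col = "grey30")
  }
  list(bias = bias, sd = s, loa = loa, n = length(a))
}
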