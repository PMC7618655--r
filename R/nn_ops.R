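# Minimal reverse-mode layers over (H, W, B, C) arrays. Convolutions are
# stride-1 "same"; resolution changes go through 2x2 mean pooling and
# nearest-neighbour upsampling, which keeps every backward pass exact.

conv_fw <- function(x, W, b, k, want_col = FALSE) {
  d <- dim(x)
  col <- NULL
  if (k == 1L) {
    y <- matrix(x, prod(d[1:3]), d[4]) %*% W
  } else {
    col <- im2col_cpp(x, d, k, k)
    y <- col %*% W
  }
  y <- y + rep(b, each = nrow(y))
  list(y = array(y, c(d[1:3], ncol(W))),
       col = if (want_col && k > 1L) col)
}

# Returns list(dx, dW, db). `col` is the forward-pass im2col matrix when it
# was kept (training); otherwise it is recomputed.
conv_bw <- function(dy, x, W, k, col = NULL) {
  d <- dim(x)
  dmat <- matrix(dy, prod(d[1:3]), dim(dy)[4])
  if (k == 1L) {
    xmat <- matrix(x, prod(d[1:3]), d[4])
    dW <- crossprod(xmat, dmat)
    dx <- array(dmat %*% t(W), d)
  } else {
    if (is.null(col)) col <- im2col_cpp(x, d, k, k)
    dW <- crossprod(col, dmat)
    dx <- col2im_cpp(dmat %*% t(W), d, k, k)
  }
  list(dx = dx, dW = dW, db = colSums(dmat))
}

relu_fw <- function(x) (x > 0) * x
relu_bw <- function(dy, x) dy * (x > 0)

pool2_fw <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[1], 2L)
  (x[o, o, , , drop = FALSE] + x[o + 1L, o, , , drop = FALSE] +
   x[o, o + 1L, , , drop = FALSE] + x[o + 1L, o + 1L, , , drop = FALSE]) / 4
}

pool2_bw <- function(dy) up2_fw(dy) / 4

up2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

up2_bw <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[1], 2L)
  dy[o, o, , , drop = FALSE] + dy[o + 1L, o, , , drop = FALSE] +
    dy[o, o + 1L, , , drop = FALSE] + dy[o + 1L, o + 1L, , , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# He-style initialisation for a k x k, cin -> cout convolution.
conv_init <- function(k, cin, cout, gen) {
  list(W = matrix(gen(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
                  k * k * cin, cout),
       b = rep(0, cout))
}
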