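# Attention-gated hourglass heatmap network.
#
# Architecture: a small stem brings the input down to the heatmap resolution
# (input_size / heatmap_stride), a single hourglass of `depth` levels with a
# residual block on each encoder/skip/decoder path follows, and a 1x1-conv
# head emits one response map per landmark. Each skip connection passes
# through an additive attention gate whose gating signal is the coarser
# decoder feature (two 1x1 projections, add, ReLU, 1x1 projection, sigmoid,
# nearest upsample), so irrelevant encoder features are suppressed before
# being merged.

#' Hourglass model configuration
#'
#' @param depth number of pooling levels in the hourglass (4 in both search
#'   stages at desk scale; the reference regime uses 4 global / 6 local).
#' @param width initial number of channels N (desk-scale defaults 8-32;
#'   reference regime 32 global / 256 local).
#' @param n_landmarks output channels (one heatmap per landmark).
#' @param input_size square input side, pixels; must be divisible by
#'   `heatmap_stride * 2^depth`.
#' @param heatmap_sigma Gaussian sd for target/oracle heatmap encoding, in
#'   heatmap pixels.
#' @param heatmap_stride input pixels per heatmap pixel (stem downsampling).
#' @param beta soft-argmax temperature used when decoding heatmaps.
#' @param seed parameter-initialisation seed.
#' @return object of class `model_config`.
#' @export
model_config <- function(depth = 4L, width = 8L, n_landmarks,
                         input_size = 64L, heatmap_sigma = 1.5,
                         heatmap_stride = 4L, beta = 25, seed = 1L) {
  depth <- as.integer(depth); width <- as.integer(width)
  input_size <- as.integer(input_size); heatmap_stride <- as.integer(heatmap_stride)
  stopifnot(depth >= 1L, width >= 1L, n_landmarks >= 1L,
            heatmap_stride %in% c(1L, 2L, 4L))
  if (input_size %% (2L^depth) != 0L) {
    stop(sprintf("model_config: input_size %d not divisible by 2^depth = %d",
                 input_size, 2L^depth))
  }
  hm <- input_size %/% heatmap_stride
  if (hm %% (2L^depth) != 0L) {
    stop(sprintf(paste0("model_config: heatmap size %d (input/stride) not ",
                        "divisible by 2^depth = %d"), hm, 2L^depth))
  }
  structure(list(depth = depth, width = width,
                 n_landmarks = as.integer(n_landmarks),
                 input_size = input_size, heatmap_sigma = heatmap_sigma,
                 heatmap_stride = heatmap_stride,
                 att_channels = max(1L, width %/% 2L),
                 beta = beta, seed = as.integer(seed)),
            class = "model_config")
}

#' Build an attention-gated hourglass model
#'
#' @param config a [model_config()].
#' @return object of class `hg_model` with elements `config` and `params`
#'   (flat named list of weight matrices / bias vectors).
#' @export
build_hourglass <- function(config) {
  stopifnot(inherits(config, "model_config"))
  N <- config$width; M <- config$att_channels; K <- config$n_landmarks
  set.seed(config$seed)
  gen <- rnorm
  p <- list()
  put <- function(p, name, k, cin, cout) {
    cv <- conv_init(k, cin, cout, gen)
    p[[paste0(name, ".W")]] <- cv$W
    p[[paste0(name, ".b")]] <- cv$b
    p
  }
  p <- put(p, "stem1", 5L, 1L, N)
  p <- put(p, "stem2", 3L, N, N)
  for (i in seq_len(config$depth)) {
    li <- paste0("l", i)
    p <- put(p, paste0(li, ".skip"), 3L, N, N)
    p <- put(p, paste0(li, ".down"), 3L, N, N)
    p <- put(p, paste0(li, ".up"), 3L, N, N)
    p <- put(p, paste0(li, ".ag.x"), 1L, N, M)
    p <- put(p, paste0(li, ".ag.g"), 1L, N, M)
    p <- put(p, paste0(li, ".ag.psi"), 1L, M, 1L)
  }
  p <- put(p, "bottom", 3L, N, N)
  p <- put(p, "head1", 1L, N, N)
  p <- put(p, "head2", 1L, N, K)
  # near-zero output head: initial heatmaps ~ 0 so the soft-argmax starts
  # from a uniform distribution (map centre) instead of a saturated argmax
  # at a random pixel — without this the coordinate loss barely trains
  p$head2.W <- p$head2.W * 0.02
  structure(list(config = config, params = p), class = "hg_model")
}

res_fw <- function(p, name, x, keep = FALSE) {
  cv <- conv_fw(x, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]], 3L,
                want_col = keep)
  pre <- x + cv$y
  list(out = relu_fw(pre), x = x, pre = pre, col = cv$col)
}

res_bw <- function(p, grads, name, cache, dy) {
  dpre <- relu_bw(dy, cache$pre)
  cb <- conv_bw(dpre, cache$x, p[[paste0(name, ".W")]], 3L, col = cache$col)
  grads[[paste0(name, ".W")]] <- grads[[paste0(name, ".W")]] + cb$dW
  grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] + cb$db
  list(grads = grads, dx = dpre + cb$dx)
}

# Attention gate: alpha = sigmoid(psi(relu(Wx x + up(Wg g)))), out = x * alpha.
ag_fw <- function(p, name, x, g) {
  xg <- conv_fw(x, p[[paste0(name, ".x.W")]], p[[paste0(name, ".x.b")]], 1L)$y
  gg <- up2_fw(conv_fw(g, p[[paste0(name, ".g.W")]], p[[paste0(name, ".g.b")]], 1L)$y)
  pre <- xg + gg
  s <- relu_fw(pre)
  e <- conv_fw(s, p[[paste0(name, ".psi.W")]], p[[paste0(name, ".psi.b")]], 1L)$y
  a <- sigmoid(e)
  list(out = x * as.vector(a), x = x, g = g, pre = pre, s = s, a = a)
}

ag_bw <- function(p, grads, name, cache, dy) {
  d <- dim(cache$x)
  dx1 <- dy * as.vector(cache$a)
  da <- array(rowSums(matrix(dy * cache$x, prod(d[1:3]), d[4])), c(d[1:3], 1L))
  de <- da * cache$a * (1 - cache$a)
  cb_psi <- conv_bw(de, cache$s, p[[paste0(name, ".psi.W")]], 1L)
  dsr <- relu_bw(cb_psi$dx, cache$pre)
  cb_x <- conv_bw(dsr, cache$x, p[[paste0(name, ".x.W")]], 1L)
  cb_g <- conv_bw(up2_bw(dsr), cache$g, p[[paste0(name, ".g.W")]], 1L)
  for (nm in c("psi", "x", "g")) {
    cb <- switch(nm, psi = cb_psi, x = cb_x, g = cb_g)
    grads[[paste0(name, ".", nm, ".W")]] <- grads[[paste0(name, ".", nm, ".W")]] + cb$dW
    grads[[paste0(name, ".", nm, ".b")]] <- grads[[paste0(name, ".", nm, ".b")]] + cb$db
  }
  list(grads = grads, dx = dx1 + cb_x$dx, dg = cb_g$dx)
}

hg_level_fw <- function(p, x, i, depth, keep = FALSE) {
  if (i > depth) {
    rb <- res_fw(p, "bottom", x, keep)
    return(list(out = rb$out, bottom = rb))
  }
  li <- paste0("l", i)
  sk <- res_fw(p, paste0(li, ".skip"), x, keep)
  dn <- res_fw(p, paste0(li, ".down"), pool2_fw(x), keep)
  sub <- hg_level_fw(p, dn$out, i + 1L, depth, keep)
  up <- res_fw(p, paste0(li, ".up"), sub$out, keep)
  ag <- ag_fw(p, paste0(li, ".ag"), sk$out, up$out)
  list(out = ag$out + up2_fw(up$out),
       sk = sk, dn = dn, sub = sub, up = up, ag = ag)
}

hg_level_bw <- function(p, grads, cache, dy, i, depth) {
  if (i > depth) {
    rb <- res_bw(p, grads, "bottom", cache$bottom, dy)
    return(rb)
  }
  li <- paste0("l", i)
  dlow_main <- up2_bw(dy)
  agb <- ag_bw(p, grads, paste0(li, ".ag"), cache$ag, dy)
  grads <- agb$grads
  dup <- dlow_main + agb$dg
  upb <- res_bw(p, grads, paste0(li, ".up"), cache$up, dup)
  grads <- upb$grads
  subb <- hg_level_bw(p, grads, cache$sub, upb$dx, i + 1L, depth)
  grads <- subb$grads
  dnb <- res_bw(p, grads, paste0(li, ".down"), cache$dn, subb$dx)
  grads <- dnb$grads
  skb <- res_bw(p, grads, paste0(li, ".skip"), cache$sk, agb$dx)
  grads <- skb$grads
  list(grads = grads, dx = pool2_bw(dnb$dx) + skb$dx)
}

hg_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params; cfg <- model$config
  if (length(dim(x)) != 4L) stop("hg_forward: input must be (H, W, B, 1)")
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size) {
    stop(sprintf("hg_forward: input is %dx%d but the model expects %dx%d",
                 dim(x)[1], dim(x)[2], cfg$input_size, cfg$input_size))
  }
  # stem: stride 4 pools the raw input once before the first conv (the
  # heatmap lives at 1/4 resolution anyway and this halves the stem cost),
  # then conv5 -> relu -> pool -> conv3 -> relu lands on the heatmap grid.
  x0 <- if (cfg$heatmap_stride == 4L) pool2_fw(x) else x
  cv1 <- conv_fw(x0, p$stem1.W, p$stem1.b, 5L, want_col = keep_cache)
  s1r <- relu_fw(cv1$y)
  h1 <- if (cfg$heatmap_stride >= 2L) pool2_fw(s1r) else s1r
  cv2 <- conv_fw(h1, p$stem2.W, p$stem2.b, 3L, want_col = keep_cache)
  h2 <- relu_fw(cv2$y)
  hg <- hg_level_fw(p, h2, 1L, cfg$depth, keep = keep_cache)
  e1 <- conv_fw(hg$out, p$head1.W, p$head1.b, 1L)$y; e1r <- relu_fw(e1)
  hm <- conv_fw(e1r, p$head2.W, p$head2.b, 1L)$y
  cache <- if (keep_cache) {
    list(x0 = x0, s1 = cv1$y, s1col = cv1$col, s1r = s1r, h1 = h1,
         s2 = cv2$y, s2col = cv2$col, hg = hg, e1 = e1, e1r = e1r)
  }
  list(hm = hm, cache = cache)
}

hg_backward <- function(model, cache, dhm) {
  p <- model$params; cfg <- model$config
  grads <- lapply(p, function(w) {
    if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else rep(0, length(w))
  })
  cb2 <- conv_bw(dhm, cache$e1r, p$head2.W, 1L)
  grads$head2.W <- grads$head2.W + cb2$dW; grads$head2.b <- grads$head2.b + cb2$db
  de1 <- relu_bw(cb2$dx, cache$e1)
  cb1 <- conv_bw(de1, cache$hg$out, p$head1.W, 1L)
  grads$head1.W <- grads$head1.W + cb1$dW; grads$head1.b <- grads$head1.b + cb1$db
  hgb <- hg_level_bw(p, grads, cache$hg, cb1$dx, 1L, cfg$depth)
  grads <- hgb$grads
  ds2 <- relu_bw(hgb$dx, cache$s2)
  cbs2 <- conv_bw(ds2, cache$h1, p$stem2.W, 3L, col = cache$s2col)
  grads$stem2.W <- grads$stem2.W + cbs2$dW; grads$stem2.b <- grads$stem2.b + cbs2$db
  ds1r <- if (cfg$heatmap_stride >= 2L) pool2_bw(cbs2$dx) else cbs2$dx
  ds1 <- relu_bw(ds1r, cache$s1)
  cbs1 <- conv_bw(ds1, cache$x0, p$stem1.W, 5L, col = cache$s1col)
  grads$stem1.W <- grads$stem1.W + cbs1$dW; grads$stem1.b <- grads$stem1.b + cbs1$db
  grads
}

#' Compute heatmaps for a batch of input images
#'
#' Generic over model kinds so that trained networks and plug-in oracle
#' models share the localization pipeline.
#'
#' @param model an `hg_model` or `oracle_model`.
#' @param x input array (H, W, B, 1) in [0, 1].
#' @return heatmap array (h, w, B, n_landmarks).
#' @export
model_heatmaps <- function(model, x) UseMethod("model_heatmaps")

#' @export
model_heatmaps.hg_model <- function(model, x) hg_forward(model, x)$hm

#' @export
model_heatmaps.oracle_model <- function(model, x) model$fn(x)

#' Plug-in oracle model emitting prescribed heatmaps
#'
#' Test/diagnostic stand-in for a trained network: carries a function that
#' maps an input batch to heatmaps (typically [encode_heatmaps()] of known
#' ground truth), plus the config the pipeline needs for sizing/decoding.
#'
#' @param config a [model_config()].
#' @param fn function(x) -> heatmap array (h, w, B, n_landmarks).
#' @return object of classes `oracle_model`.
#' @export
oracle_model <- function(config, fn) {
  structure(list(config = config, fn = fn), class = "oracle_model")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is R's native serialized form; a JSON sidecar
#' (`<path>.json`) records the config and a parameter checksum so
#' checkpoints are self-describing.
#'
#' @param model an `hg_model`.
#' @param path checkpoint path (conventionally `.rds`).
#' @return `path` (save) / the model (load), invisibly for save.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(package = "kneemark",
               version = as.character(utils::packageVersion("kneemark")),
               config = unclass(model$config),
               n_params = sum(vapply(model$params, length, 1L)),
               param_checksum = sum(vapply(model$params, sum, 1.0)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hg_model")) stop("load_model: not an hg_model checkpoint")
  model
}
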