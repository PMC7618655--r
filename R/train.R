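# Training: Adam on the wing loss evaluated on soft-argmax-decoded
# coordinates (the network regresses landmark positions through its
# heatmaps; the loss is a coordinate loss, so it is applied after decoding).

#' Training configuration
#'
#' @param epochs number of passes over the training split.
#' @param learning_rate Adam step size (reference regime: 1e-4; desk-scale
#'   runs typically use a larger rate because they take far fewer steps).
#' @param batch_size minibatch size.
#' @param val_frac fraction of the dataset held out for validation loss
#'   (at least one sample).
#' @param wing a [wing_params()].
#' @param lr_decay_at fraction of epochs after which the rate is multiplied
#'   by `lr_decay_factor` (step decay; sharpens final localization).
#' @param lr_decay_factor multiplicative decay factor (1 = no decay).
#' @param seed shuffling seed.
#' @param verbose print per-epoch losses.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 20L, learning_rate = 1e-4,
                         batch_size = 16L, val_frac = 0.1,
                         wing = wing_params(), lr_decay_at = 0.7,
                         lr_decay_factor = 0.3, seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L,
            val_frac >= 0, val_frac < 1, lr_decay_at > 0, lr_decay_at <= 1,
            lr_decay_factor > 0, lr_decay_factor <= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), val_frac = val_frac,
                 wing = wing, lr_decay_at = lr_decay_at,
                 lr_decay_factor = lr_decay_factor, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

stack_batch <- function(images) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  array(unlist(images, use.names = FALSE), c(H, W, length(images), 1L))
}

# Loss (and gradients w.r.t. the heatmaps) for one forward pass.
coord_loss <- function(hm, targets, config, wing) {
  d <- dim(hm)                       # (h, w, B, K)
  hw <- d[1] * d[2]; m <- d[3] * d[4]
  flat <- matrix(hm, hw, m)          # columns: (b, k), b fastest
  sm <- softargmax_mat(flat, d[1], d[2], config$beta)
  stride <- config$heatmap_stride
  xin <- hm_to_input(sm$x, stride); yin <- hm_to_input(sm$y, stride)
  tx <- as.vector(vapply(seq_len(d[4]), function(k) {
    vapply(targets, function(t) t[k, 1], 0)
  }, numeric(d[3])))
  ty <- as.vector(vapply(seq_len(d[4]), function(k) {
    vapply(targets, function(t) t[k, 2], 0)
  }, numeric(d[3])))
  rx <- xin - tx; ry <- yin - ty
  loss <- mean(c(vapply(abs(c(rx, ry)), function(r) {
    if (r < wing$w) wing$w * log1p(r / wing$epsilon) else r - wing$C
  }, 0)))
  dxh <- wing_grad(rx, wing) / (2 * m) * stride
  dyh <- wing_grad(ry, wing) / (2 * m) * stride
  dflat <- config$beta * sm$p *
    (sweep(matrix(sm$xs, hw, m), 2L, sm$x) * rep(dxh, each = hw) +
     sweep(matrix(sm$ys, hw, m), 2L, sm$y) * rep(dyh, each = hw))
  list(loss = loss, dhm = array(dflat, d),
       pred = cbind(xin, yin), resid = cbind(rx, ry))
}

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train one search stage
#'
#' Minimises the wing loss on decoded coordinates with Adam. Deterministic
#' for a fixed seed (single-threaded numeric kernels assumed). Emits a
#' per-epoch loss history; validation samples are split off the tail of a
#' seeded permutation and never trained on.
#'
#' @param model an `hg_model` from [build_hourglass()].
#' @param dataset list of samples, each `list(image = matrix, landmarks =
#'   K x 2 matrix)` in the stage's input frame.
#' @param cfg a [train_config()].
#' @return list with `model` (trained) and `history` (data.frame epoch,
#'   train_loss, val_loss).
#' @export
train_stage <- function(model, dataset, cfg = train_config()) {
  if (!length(dataset)) stop("train_stage: empty dataset")
  config <- model$config
  set.seed(cfg$seed)
  n <- length(dataset)
  perm <- sample.int(n)
  n_val <- max(1L, min(n - 1L, round(cfg$val_frac * n)))
  val_idx <- if (n >= 2L) tail(perm, n_val) else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  eval_loss <- function(idx) {
    tot <- 0
    for (start in seq(1L, length(idx), by = cfg$batch_size)) {
      bi <- idx[start:min(start + cfg$batch_size - 1L, length(idx))]
      x <- stack_batch(lapply(dataset[bi], `[[`, "image"))
      hm <- hg_forward(model, x, keep_cache = FALSE)$hm
      cl <- coord_loss(hm, lapply(dataset[bi], `[[`, "landmarks"), config,
                       cfg$wing)
      tot <- tot + cl$loss * length(bi)
    }
    tot / length(idx)
  }
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate *
      if (epoch > cfg$lr_decay_at * cfg$epochs) cfg$lr_decay_factor else 1
    ord <- sample(tr_idx)
    ep_loss <- 0
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      x <- stack_batch(lapply(dataset[bi], `[[`, "image"))
      fw <- hg_forward(model, x, keep_cache = TRUE)
      cl <- coord_loss(fw$hm, lapply(dataset[bi], `[[`, "landmarks"),
                       config, cfg$wing)
      grads <- hg_backward(model, fw$cache, cl$dhm)
      st <- adam_step(model$params, grads, state, lr)
      model$params <- st$params; state <- st$state
      ep_loss <- ep_loss + cl$loss * length(bi)
    }
    vl <- if (length(val_idx)) eval_loss(val_idx) else NA_real_
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = ep_loss / length(ord),
                                val_loss = vl))
    if (cfg$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      history$train_loss[epoch], vl))
    }
  }
  list(model = model, history = history)
}

#' Predict landmarks for a single image in the model's input frame
#'
#' @param model an `hg_model` or `oracle_model`.
#' @param image matrix already sized to the model's input.
#' @return K x 2 matrix of input-frame coordinates.
#' @export
predict_landmarks <- function(model, image) {
  x <- array(image, c(nrow(image), ncol(image), 1L, 1L))
  hm <- model_heatmaps(model, x)
  decode_heatmaps(hm, model$config)[[1]]
}
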