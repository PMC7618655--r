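# Shared fixtures, all built in code.

# Minimal role-complete schema over 12 points.
tiny_schema <- function() {
  landmark_schema(12L, roles = list(
    femoral_shaft_pair_proximal = c(1L, 2L),
    femoral_shaft_pair_distal   = c(3L, 4L),
    femoral_notch_pair          = c(5L, 6L),
    tibial_shaft_pair_proximal  = c(7L, 8L),
    tibial_shaft_pair_distal    = c(9L, 10L),
    plateau_corner_left  = 11L,
    plateau_corner_right = 12L))
}

# Straight-knee landmark set on the tiny schema: femoral axis vertical
# through x = 50, notch midpoint and tibial axis collinear with it.
straight_tiny_set <- function() {
  pts <- rbind(c(40, 10), c(60, 10),    # femoral proximal pair
               c(40, 60), c(60, 60),    # femoral distal pair
               c(45, 80), c(55, 80),    # notch pair
               c(42, 100), c(58, 100),  # tibial proximal pair
               c(44, 150), c(56, 150),  # tibial distal pair
               c(38, 85), c(62, 85))    # plateau corners
  landmark_set(pts, tiny_schema())
}

random_transform <- function() {
  similarity_transform(scale = runif(1, 0.3, 3),
                       rotation = runif(1, -pi, pi),
                       translation = runif(2, -50, 50))
}

# Oracle model emitting ground-truth heatmaps regardless of image content.
fixed_oracle <- function(config, pts_input_frame) {
  oracle_model(config, function(x) {
    B <- dim(x)[3]
    hm1 <- encode_heatmaps(pts_input_frame, config)
    h <- dim(hm1)[1]
    out <- array(0, c(h, h, B, dim(hm1)[3]))
    for (b in seq_len(B)) out[, , b, ] <- hm1
    out
  })
}

# Small rendered phantom cached per test session (rendering is ~0.1 s).
cached_phantom <- local({
  env <- new.env()
  function(atfa_deg = 7, seed = 5) {
    key <- paste0("p", atfa_deg, "_", seed)
    if (is.null(env[[key]])) {
      env[[key]] <- generate_phantom(
        phantom_spec(true_atfa = atfa_deg, global_rotation = -4, seed = seed))
    }
    env[[key]]
  }
})
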