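# Shared fixtures: small geometries, desk-scale synthetic configs, and
# brute-force oracles kept deliberately naive and independent of the
# implementation paths they check.

# two-pool geometry used throughout the fast tests (input 50 -> output 28
# for a 28-px tile, margin 11, no natural-output crop)
tiny_geometry <- function() unet_geometry(2, c(1, 1, 1), c(1, 2))

# classic four-pool reference geometry (input 572 -> output 388)
classic_geometry <- function() unet_geometry(4, rep(2, 5), rep(2, 4))

tiny_synth_config <- function(..., seed = 7, noise_sd = 0, blur_sigma_px = 0.5) {
  synth_config(image_height_px = 64, image_width_px = 64, noise_sd = noise_sd,
               blur_sigma_px = blur_sigma_px, seed = seed, ...)
}

tiny_network_spec <- function(...) {
  network_spec(tiny_geometry(), base_channels = 4, channel_cap = 32,
               dropout_rate = 0.2, dropout_before_final_convs = 1, ...)
}

# naive per-pixel distance-to-segment dilation of a polyline (double loop)
naive_polyline_dilation <- function(h, w, pts, radius) {
  count <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    dmin <- Inf
    for (s in seq_len(nrow(pts) - 1)) {
      a <- pts[s, ]; b <- pts[s + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) 0 else
        max(0, min(1, ((i - a[1]) * ab[1] + (j - a[2]) * ab[2]) / len2))
      p <- a + t * ab
      dmin <- min(dmin, sqrt((i - p[1])^2 + (j - p[2])^2))
    }
    if (dmin <= radius) count <- count + 1L
  }
  count
}

# naive valid 2-D convolution (quadruple loop) as an oracle for the kernels
naive_conv_valid <- function(x, W, b) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  ho <- dim(x)[1] - k + 1; wo <- dim(x)[2] - k + 1
  out <- array(0, c(ho, wo, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], ho, wo)
    for (ci in seq_len(cin))
      for (kj in seq_len(k))
        for (ki in seq_len(k))
          acc <- acc + W[ki, kj, ci, co] *
            x[(ki - 1) + seq_len(ho), (kj - 1) + seq_len(wo), ci]
    out[, , co] <- acc
  }
  out
}

# identity "network": each tile output is the content of its output window,
# read from the padded image (what a perfect identity model would return)
identity_tile_outputs <- function(image, layout) {
  padded <- pad_for_tiles(image, layout)
  m <- layout$margin_px
  t <- layout$output_tile_px
  lapply(seq_len(nrow(layout$tile_origins)), function(i) {
    o <- layout$tile_origins[i, ]
    padded[(o[1] + m + 1):(o[1] + m + t), (o[2] + m + 1):(o[2] + m + t),
           drop = FALSE]
  })
}

# translation-equivariant inference stub: 5x5 box blur with reflect boundary
box_blur_reflect <- function(img) {
  p <- mirror_pad(img, 2, 2, 2, 2)
  x <- array(p, c(dim(p), 1))
  W <- array(1 / 25, c(5, 5, 1, 1))
  wristseg:::.conv_valid_forward(x, W, 0)[, , 1]
}

# AUC as the normalized Mann-Whitney U statistic via explicit pair counting
pairwise_auc <- function(conf, truth) {
  pos <- conf[truth]; neg <- conf[!truth]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# random preprocessed-like examination with given labels (no rendering cost)
stub_prediction_table <- function(n_exams, seed = 1) {
  withr::with_seed(seed, {
    truth <- stats::runif(n_exams) < 0.6
    cast <- stats::runif(n_exams) < 0.3
    rows <- lapply(seq_len(n_exams), function(i) {
      base <- if (truth[i]) stats::rbeta(2, 4, 2) else stats::rbeta(2, 2, 4)
      data.frame(image_id = sprintf("e%03d_%s", i, c("pa", "lat")),
                 exam_id = sprintf("e%03d", i),
                 view = c("postero_anterior", "lateral"),
                 max_confidence = base, cast = cast[i], truth = truth[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
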