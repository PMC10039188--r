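#' Segmentation network specification
#'
#' Declarative description of the valid-padding U-Net: the spatial geometry
#' (pooling steps and convolutions per stage), the channel schedule, batch
#' normalization, and the dropout applied before the final convolutions. The
#' default geometry has 25 convolutional layers and seven pooling /
#' upsampling steps; every convolution is 3 x 3 valid with batch norm and
#' ReLU, except the last, which maps to a single channel read through a
#' sigmoid.
#'
#' @param geometry A [unet_geometry()].
#' @param base_channels Channels at the top level (default 16).
#' @param channel_growth Channel multiplier per pooling step (default 2).
#' @param channel_cap Upper bound on channels per level (default 256).
#' @param dropout_rate Dropout probability before the final convolutions.
#' @param dropout_before_final_convs Number of trailing convolutions preceded
#'   by dropout (default 3; clamped to the top decoder stage's length).
#' @param batch_norm Use batch normalization after every hidden convolution.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(geometry = unet_geometry(), base_channels = 16,
                         channel_growth = 2, channel_cap = 256,
                         dropout_rate = 0.5, dropout_before_final_convs = 3,
                         batch_norm = TRUE) {
  stopifnot(inherits(geometry, "unet_geometry"), base_channels >= 1,
            channel_growth >= 1, channel_cap >= base_channels,
            dropout_rate >= 0, dropout_rate < 1,
            dropout_before_final_convs >= 0)
  if (any(geometry$convs_per_stage_down < 1) || any(geometry$convs_per_stage_up < 1))
    stop("network_spec requires at least one convolution per stage")
  structure(list(geometry = geometry,
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 channel_cap = as.integer(channel_cap),
                 dropout_rate = dropout_rate,
                 dropout_before_final_convs = as.integer(dropout_before_final_convs),
                 batch_norm = isTRUE(batch_norm)),
            class = "network_spec")
}

#' Auxiliary classification head specification
#'
#' A patch-level fracture classifier attached during the second training
#' phase: global average and global max pooling are applied to the outputs of
#' the bottleneck and of succeeding decoder stages, concatenated, and passed
#' through fully connected layers to a single sigmoid unit. The head is a
#' training aid only; inference never reads it.
#'
#' @param tap_points Character vector of stage identifiers to pool from:
#'   `"bottom"` or `"dec1"` ... `"decP"` (deepest decoder stage first).
#' @param fc_hidden_layers Number of hidden fully connected layers (the
#'   single output unit comes on top of these).
#' @return An object of class `aux_head_spec`.
#' @export
aux_head_spec <- function(tap_points = c("bottom", "dec1", "dec2"),
                          fc_hidden_layers = 4) {
  stopifnot(length(tap_points) >= 1, fc_hidden_layers >= 1)
  structure(list(tap_points = tap_points,
                 poolings = c("global_average", "global_max"),
                 fc_hidden_layers = as.integer(fc_hidden_layers)),
            class = "aux_head_spec")
}

# per-level channel schedule, index 1 = top level, index P+1 = bottleneck
level_channels <- function(spec) {
  P <- spec$geometry$pool_steps
  as.integer(pmin(spec$base_channels * spec$channel_growth^(0:P),
                  spec$channel_cap))
}

# Ordered table of convolution units with channel bookkeeping. Stage names:
# enc1..encP (encoder), bot (bottleneck), dec1..decP (decoder, deepest first).
build_unit_table <- function(spec) {
  g <- spec$geometry
  P <- g$pool_steps
  ch <- level_channels(spec)
  units <- list()
  add <- function(stage, j, cin, cout, bn, act, dropout) {
    units[[length(units) + 1L]] <<- list(
      key = sprintf("%s.c%d", stage, j), stage = stage,
      cin = cin, cout = cout, bn = bn, act = act, dropout = dropout)
  }
  for (s in seq_len(P)) {
    nc <- g$convs_per_stage_down[s]
    for (j in seq_len(nc))
      add(sprintf("enc%d", s), j,
          cin = if (j == 1) (if (s == 1) 1L else ch[s - 1]) else ch[s],
          cout = ch[s], bn = spec$batch_norm, act = "relu", dropout = 0)
  }
  for (j in seq_len(g$convs_per_stage_down[P + 1]))
    add("bot", j, cin = if (j == 1) ch[P] else ch[P + 1], cout = ch[P + 1],
        bn = spec$batch_norm, act = "relu", dropout = 0)
  for (s in seq_len(P)) {
    li <- P + 1L - s                     # level index of this decoder stage
    nc <- g$convs_per_stage_up[s]
    is_top <- s == P
    ndrop <- if (is_top) min(spec$dropout_before_final_convs, nc) else 0L
    for (j in seq_len(nc)) {
      last <- is_top && j == nc
      add(sprintf("dec%d", s), j,
          cin = if (j == 1) ch[li] + ch[li + 1] else ch[li],
          cout = if (last) 1L else ch[li],
          bn = spec$batch_norm && !last,
          act = if (last) "logit" else "relu",
          dropout = if (j > nc - ndrop) spec$dropout_rate else 0)
    }
  }
  units
}

#' Number of convolutional layers a specification builds
#'
#' @param spec A [network_spec()].
#' @return Integer count of convolution layers.
#' @export
conv_layer_count <- function(spec) length(build_unit_table(spec))

#' Build the segmentation model
#'
#' Instantiates seeded parameters (He-initialized convolution weights, unit
#' batch-norm scale, zero shifts) for the specification, optionally with the
#' auxiliary classification head. The model maps an input tile of the size
#' given by [required_input_size()] to a per-pixel fracture-confidence tile
#' in (0, 1) of the corresponding natural output size.
#'
#' @param spec A [network_spec()].
#' @param aux An [aux_head_spec()], or `NULL` for a segmentation-only model.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `unet_model`.
#' @export
build_model <- function(spec, aux = NULL, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(aux)) stopifnot(inherits(aux, "aux_head_spec"))
  units <- build_unit_table(spec)
  par <- list()
  buf <- list()
  withr::with_seed(as.integer(seed), {
    for (u in units) {
      k <- spec$geometry$kernel_size
      sd <- sqrt(2 / (k * k * u$cin))
      par[[paste0(u$key, ".W")]] <-
        array(stats::rnorm(k * k * u$cin * u$cout, 0, sd), c(k, k, u$cin, u$cout))
      par[[paste0(u$key, ".b")]] <- numeric(u$cout)
      if (u$bn) {
        par[[paste0(u$key, ".g")]] <- rep(1, u$cout)
        par[[paste0(u$key, ".be")]] <- numeric(u$cout)
        buf[[paste0(u$key, ".rm")]] <- numeric(u$cout)
        buf[[paste0(u$key, ".rv")]] <- rep(1, u$cout)
      }
    }
  })
  model <- structure(list(spec = spec, aux = NULL, units = units,
                          par = par, buf = buf),
                     class = "unet_model")
  if (!is.null(aux)) model <- attach_aux_head(model, aux, seed = seed + 1L)
  model
}

# Channel count of a tap point's output
tap_channels <- function(spec, tap) {
  ch <- level_channels(spec)
  P <- spec$geometry$pool_steps
  if (tap == "bottom") return(ch[P + 1])
  s <- as.integer(sub("^dec", "", tap))
  if (is.na(s) || s < 1 || s > P) stop("unknown tap point: ", tap)
  li <- P + 1L - s
  if (s == P) {
    # top stage ends in the 1-channel output conv; tap its widest hidden conv
    stop("tap on the top decoder stage is not supported (it ends in the output layer)")
  }
  ch[li]
}

#' Attach the auxiliary classification head to a model
#'
#' @param model A [build_model()] result.
#' @param aux An [aux_head_spec()].
#' @param seed Seed for the head's parameter initialization.
#' @return The model with the head attached.
#' @export
attach_aux_head <- function(model, aux, seed = 1L) {
  stopifnot(inherits(model, "unet_model"), inherits(aux, "aux_head_spec"))
  nin <- 2L * sum(vapply(aux$tap_points, tap_channels, integer(1),
                         spec = model$spec))
  widths <- pmax(2L, as.integer(round(nin / 2^seq_len(aux$fc_hidden_layers))))
  dims <- c(nin, widths, 1L)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(length(dims) - 1L)) {
      model$par[[sprintf("aux.fc%d.W", k)]] <-
        matrix(stats::rnorm(dims[k + 1] * dims[k], 0, sqrt(2 / dims[k])),
               dims[k + 1], dims[k])
      model$par[[sprintf("aux.fc%d.b", k)]] <- numeric(dims[k + 1])
    }
  })
  model$aux <- aux
  model$aux_dims <- dims
  model
}

# ---- forward / backward -------------------------------------------------

as_batch3 <- function(x) { dim(x) <- c(dim(x), 1L); x }  # HxW -> HxWx1

get_sample <- function(xb, n) {
  d <- dim(xb)
  a <- xb[, , , n, drop = FALSE]
  dim(a) <- d[1:3]
  a
}

set_sample <- function(xb, n, a) { xb[, , , n] <- a; xb }

center_crop_batch <- function(xb, h, w) {
  d <- dim(xb)
  or <- (d[1] - h) %/% 2L
  oc <- (d[2] - w) %/% 2L
  xb[or + seq_len(h), oc + seq_len(w), , , drop = FALSE]
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# One convolution unit (conv + optional BN + activation) on a 4-D batch.
# The heavy lifting happens in the fused C++ kernel; dropout (only ever
# applied before the small full-resolution decoder convolutions) stays in R.
unit_forward <- function(model, u, xb, train, keep_cache) {
  par <- model$par
  key <- u$key
  cache <- if (keep_cache) list(u = u) else NULL

  if (train && u$dropout > 0) {
    keep <- 1 - u$dropout
    dmask <- array(stats::rbinom(length(xb), 1L, keep) / keep, dim(xb))
    xb <- xb * dmask
    if (keep_cache) cache$dmask <- dmask
  }
  if (keep_cache) cache$x <- xb

  bn <- u$bn
  r <- .unit_forward(xb, par[[paste0(key, ".W")]], par[[paste0(key, ".b")]],
                     bn,
                     if (bn) par[[paste0(key, ".g")]] else numeric(u$cout),
                     if (bn) par[[paste0(key, ".be")]] else numeric(u$cout),
                     if (bn) model$buf[[paste0(key, ".rm")]] else numeric(u$cout),
                     if (bn) model$buf[[paste0(key, ".rv")]] else numeric(u$cout),
                     train, bn_momentum, bn_eps, u$act == "relu", keep_cache)
  if (bn && train) {
    model$buf[[paste0(key, ".rm")]] <- as.numeric(r$run_mean)
    model$buf[[paste0(key, ".rv")]] <- as.numeric(r$run_var)
  }
  if (keep_cache) {
    cache$y <- r$y
    if (bn && train) {
      cache$xhat <- r$xhat
      cache$inv_sd <- as.numeric(r$inv_sd)
    }
  }
  list(y = r$y, cache = cache, model = model)
}

unit_backward <- function(model, cache, gy) {
  u <- cache$u
  key <- u$key
  par <- model$par
  bn <- u$bn
  r <- .unit_backward(cache$x, par[[paste0(key, ".W")]], cache$y, gy,
                      bn,
                      if (bn) par[[paste0(key, ".g")]] else numeric(u$cout),
                      if (bn) cache$xhat else array(0, c(1, 1, 1, 1)),
                      if (bn) cache$inv_sd else numeric(u$cout),
                      u$act == "relu")
  grads <- list()
  grads[[paste0(key, ".W")]] <- r$gw
  grads[[paste0(key, ".b")]] <- as.numeric(r$gb)
  if (bn) {
    grads[[paste0(key, ".g")]] <- as.numeric(r$ggamma)
    grads[[paste0(key, ".be")]] <- as.numeric(r$gbeta)
  }
  gx <- r$gx
  if (!is.null(cache$dmask)) gx <- gx * cache$dmask
  list(gx = gx, grads = grads)
}

pool_forward_batch <- function(xb) .pool_forward_batch(xb)
pool_backward_batch <- function(gy, idx) .pool_backward_batch(gy, idx)
upsample_forward_batch <- function(xb) .upsample_forward_batch(xb)
upsample_backward_batch <- function(gy) .upsample_backward_batch(gy)

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Full network forward. xb: H x W x 1 x N batch of preprocessed input windows.
# Returns logits (natural-output spatial size, 1 channel), optional aux
# logits, and (when train) the caches needed for the backward pass.
net_forward <- function(model, xb, train = FALSE, with_aux = FALSE) {
  spec <- model$spec
  g <- spec$geometry
  P <- g$pool_steps
  if (with_aux && is.null(model$aux))
    stop("model has no auxiliary head")
  hin <- dim(xb)[1]
  if (is.na(output_size_given_input(g, hin)) ||
      is.na(output_size_given_input(g, dim(xb)[2])))
    stop("input size ", hin, "x", dim(xb)[2], " is infeasible for this ",
         "geometry; use required_input_size() to pick a tile size")
  keep <- train
  units <- model$units
  by_stage <- split(seq_along(units),
                    vapply(units, `[[`, character(1), "stage"))
  run_stage <- function(stage, xb) {
    caches <- list()
    for (i in by_stage[[stage]]) {
      r <- unit_forward(model, units[[i]], xb, train, keep)
      model <<- r$model
      xb <- r$y
      caches[[length(caches) + 1L]] <- r$cache
    }
    list(y = xb, caches = caches)
  }

  cache <- list(enc = list(), dec = list())
  skips <- list()
  x <- xb
  for (s in seq_len(P)) {
    r <- run_stage(sprintf("enc%d", s), x)
    skips[[s]] <- r$y
    p <- pool_forward_batch(r$y)
    if (keep) cache$enc[[s]] <- list(units = r$caches, pool_idx = p$idx)
    x <- p$y
  }
  r <- run_stage("bot", x)
  if (keep) cache$bot <- r$caches
  x <- r$y

  taps <- list()
  if (!is.null(model$aux) && "bottom" %in% model$aux$tap_points)
    taps[["bottom"]] <- x

  crop_info <- list()
  for (s in seq_len(P)) {
    up <- upsample_forward_batch(x)
    skip <- skips[[P + 1L - s]]
    dh <- dim(up)[1]; dw <- dim(up)[2]
    sk <- center_crop_batch(skip, dh, dw)
    crop_info[[s]] <- c(skip_h = dim(skip)[1], skip_w = dim(skip)[2],
                        h = dh, w = dw)
    x <- concat_channels(sk, up)
    r <- run_stage(sprintf("dec%d", s), x)
    if (keep) cache$dec[[s]] <- r$caches
    x <- r$y
    tp <- sprintf("dec%d", s)
    if (!is.null(model$aux) && tp %in% model$aux$tap_points)
      taps[[tp]] <- x
  }
  if (keep) cache$crop_info <- crop_info
  skips_dims <- lapply(skips, dim)
  if (keep) cache$skip_dims <- skips_dims

  out <- list(logits = x, model = model)
  if (with_aux) {
    ar <- aux_forward(model, taps, keep)
    out$aux_logits <- ar$logits
    if (keep) cache$aux <- ar$cache
  }
  if (keep) out$cache <- cache
  out
}

aux_forward <- function(model, taps, keep_cache) {
  aux <- model$aux
  n <- dim(taps[[1]])[4]
  feats <- matrix(0, model$aux_dims[1], n)
  pos <- 0L
  argmax <- list()
  for (tp in aux$tap_points) {
    t <- taps[[tp]]
    cc <- dim(t)[3]
    am <- array(0L, c(cc, n))
    for (i in seq_len(n)) for (c in seq_len(cc)) {
      tc <- t[, , c, i]
      feats[pos + c, i] <- mean(tc)
      j <- which.max(tc)
      feats[pos + cc + c, i] <- tc[j]
      am[c, i] <- j
    }
    argmax[[tp]] <- am
    pos <- pos + 2L * cc
  }
  h <- feats
  fc_cache <- list()
  nlay <- length(model$aux_dims) - 1L
  for (k in seq_len(nlay)) {
    W <- model$par[[sprintf("aux.fc%d.W", k)]]
    b <- model$par[[sprintf("aux.fc%d.b", k)]]
    z <- W %*% h + b
    if (k < nlay) {
      hn <- z * (z > 0)
      if (keep_cache) fc_cache[[k]] <- list(h = h, relu = z > 0)
      h <- hn
    } else {
      if (keep_cache) fc_cache[[k]] <- list(h = h, relu = NULL)
      h <- z
    }
  }
  cache <- if (keep_cache) list(taps = taps, argmax = argmax,
                                fc = fc_cache, n = n) else NULL
  list(logits = as.numeric(h), cache = cache)
}

# Backward through the aux head; returns grads for fc weights plus the
# gradient to inject at each tap tensor.
aux_backward <- function(model, cache, g_logits) {
  aux <- model$aux
  n <- cache$n
  grads <- list()
  gh <- matrix(g_logits, 1, n)
  nlay <- length(model$aux_dims) - 1L
  for (k in rev(seq_len(nlay))) {
    fc <- cache$fc[[k]]
    W <- model$par[[sprintf("aux.fc%d.W", k)]]
    grads[[sprintf("aux.fc%d.W", k)]] <- gh %*% t(fc$h)
    grads[[sprintf("aux.fc%d.b", k)]] <- rowSums(gh)
    gh <- t(W) %*% gh
    if (k > 1L) gh <- gh * cache$fc[[k - 1L]]$relu
  }
  # gh is now gradient wrt the pooled feature vector
  tap_grads <- list()
  pos <- 0L
  for (tp in aux$tap_points) {
    t <- cache$taps[[tp]]
    d <- dim(t)
    cc <- d[3]
    gt <- array(0, d)
    npx <- d[1] * d[2]
    for (i in seq_len(n)) for (c in seq_len(cc)) {
      gt[, , c, i] <- gh[pos + c, i] / npx        # global average pooling
      j <- cache$argmax[[tp]][c, i]               # global max pooling
      slab <- gt[, , c, i]
      slab[j] <- slab[j] + gh[pos + cc + c, i]
      gt[, , c, i] <- slab
    }
    tap_grads[[tp]] <- gt
    pos <- pos + 2L * cc
  }
  list(grads = grads, tap_grads = tap_grads)
}

# Full backward pass. g_logits matches the logits shape; aux_tap_grads /
# aux_grads come from aux_backward (or are NULL in phase 1).
net_backward <- function(model, cache, g_logits, aux = NULL) {
  g <- model$spec$geometry
  P <- g$pool_steps
  units <- model$units
  by_stage <- split(seq_along(units),
                    vapply(units, `[[`, character(1), "stage"))
  grads <- if (is.null(aux)) list() else aux$grads

  back_stage <- function(stage_caches, gy) {
    for (i in rev(seq_along(stage_caches))) {
      r <- unit_backward(model, stage_caches[[i]], gy)
      gy <- r$gx
      for (nm in names(r$grads))
        grads[[nm]] <<- if (is.null(grads[[nm]])) r$grads[[nm]] else
          grads[[nm]] + r$grads[[nm]]
    }
    gy
  }

  skip_grads <- vector("list", P)
  gy <- g_logits
  for (s in rev(seq_len(P))) {
    tp <- sprintf("dec%d", s)
    if (!is.null(aux) && !is.null(aux$tap_grads[[tp]]))
      gy <- gy + aux$tap_grads[[tp]]
    gy <- back_stage(cache$dec[[s]], gy)
    ci <- cache$crop_info[[s]]
    nch_skip <- cache$skip_dims[[P + 1L - s]][3]
    g_sk <- gy[, , seq_len(nch_skip), , drop = FALSE]
    g_up <- gy[, , nch_skip + seq_len(dim(gy)[3] - nch_skip), , drop = FALSE]
    sd <- cache$skip_dims[[P + 1L - s]]
    gsk_full <- array(0, sd)
    or <- (ci["skip_h"] - ci["h"]) %/% 2L
    oc <- (ci["skip_w"] - ci["w"]) %/% 2L
    gsk_full[or + seq_len(ci["h"]), oc + seq_len(ci["w"]), , ] <- g_sk
    skip_grads[[P + 1L - s]] <- gsk_full
    gy <- upsample_backward_batch(g_up)
  }
  if (!is.null(aux) && !is.null(aux$tap_grads[["bottom"]]))
    gy <- gy + aux$tap_grads[["bottom"]]
  gy <- back_stage(cache$bot, gy)
  for (s in rev(seq_len(P))) {
    gy <- pool_backward_batch(gy, cache$enc[[s]]$pool_idx)
    gy <- gy + skip_grads[[s]]
    gy <- back_stage(cache$enc[[s]]$units, gy)
  }
  grads
}

#' Run the model on a single input tile
#'
#' Evaluation-mode forward pass (dropout off, batch norm using running
#' statistics): deterministic and batch-size invariant. The confidence tile
#' has the network's natural output size for the given input (see
#' [output_size_given_input()]); tiled prediction center-crops it to the
#' layout's output tile. The auxiliary probability is returned only if the
#' model carries the head; prediction pipelines do not consume it.
#'
#' @param model A [build_model()] result.
#' @param tile Numeric matrix, preprocessed to `[0, 1]`, of a feasible input
#'   size for the model's geometry.
#' @param with_aux Also evaluate the auxiliary head, if present.
#' @return List with `confidence` (matrix, values in (0, 1)) and
#'   `aux_probability` (scalar or `NULL`).
#' @export
model_confidence <- function(model, tile, with_aux = FALSE) {
  stopifnot(inherits(model, "unet_model"), is.matrix(tile))
  xb <- array(tile, c(dim(tile), 1L, 1L))
  r <- net_forward(model, xb, train = FALSE,
                   with_aux = with_aux && !is.null(model$aux))
  conf <- stats::plogis(r$logits[, , 1L, 1L])
  aux_p <- if (!is.null(r$aux_logits)) stats::plogis(r$aux_logits[1L]) else NULL
  list(confidence = conf, aux_probability = aux_p)
}

#' Tiled full-image inference
#'
#' Splits the image into output tiles, runs the network on each mirror-padded
#' input window, center-crops the natural outputs to the tile size and
#' stitches them into a full-image confidence map. With a [shift_plan()],
#' inference is repeated at each tile-grid offset and the maps are averaged
#' (25 passes under the default plan).
#'
#' @param model A [build_model()] result.
#' @param image Preprocessed image matrix (values in `[0, 1]`).
#' @param output_tile Output tile side in pixels (default 130).
#' @param shift A [shift_plan()] for shift-and-average ensembling, or `NULL`
#'   for a single pass.
#' @return Confidence-map matrix with the shape of `image`.
#' @export
predict_confidence_map <- function(model, image, output_tile = 130,
                                   shift = NULL) {
  stopifnot(inherits(model, "unet_model"), is.matrix(image))
  g <- model$spec$geometry
  infer <- function(img) {
    layout <- plan_tiles(dim(img), g, output_tile)
    padded <- pad_for_tiles(img, layout)
    tiles <- lapply(seq_len(nrow(layout$tile_origins)), function(t) {
      win <- tile_input_window(padded, layout, t)
      conf <- model_confidence(model, win)$confidence
      cp <- layout$crop_px
      to <- layout$output_tile_px
      conf[cp + seq_len(to), cp + seq_len(to), drop = FALSE]
    })
    stitch(tiles, layout)
  }
  if (is.null(shift)) infer(image) else shift_average(infer, image, shift)
}

#' Save a model with its specification embedded
#'
#' The serialized file carries the network specification and geometry so a
#' prediction run can verify tile-size compatibility, plus the selected
#' operating threshold when one has been chosen.
#'
#' @param model A [build_model()] result.
#' @param path Destination `.rds` path.
#' @param threshold Optional operating threshold to embed.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, threshold = NULL) {
  stopifnot(inherits(model, "unet_model"))
  obj <- list(format = "wristseg_model_v1", model = model,
              threshold = threshold)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path `.rds` path.
#' @return The model, with any embedded threshold as attribute `"threshold"`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "wristseg_model_v1"))
    stop(path, " is not a serialized wristseg model")
  m <- obj$model
  attr(m, "threshold") <- obj$threshold
  m
}
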