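#' Training configuration
#'
#' Two-phase schedule: phase 1 trains the segmentation loss alone with Adam
#' at `lr_phase1`, monitored by validation segmentation accuracy with
#' patience-based early stopping; phase 2 attaches the auxiliary patch
#' classifier and trains on the sum of the segmentation and auxiliary binary
#' cross-entropies at `lr_phase2` for `phase2_epochs` epochs.
#'
#' @param lr_phase1 Phase-1 learning rate (default 0.001).
#' @param lr_phase2 Phase-2 learning rate (default 0.0025).
#' @param val_fraction Fraction of examinations held out for validation
#'   (default 0.1).
#' @param phase1_patience_epochs Epochs without validation improvement before
#'   phase 1 stops (default 5).
#' @param phase1_max_epochs Hard cap on phase-1 epochs (default 5, the length
#'   of the modelled schedule).
#' @param phase2_epochs Phase-2 epochs (default 3).
#' @param batch_size Patches per optimizer step (default 8).
#' @param oversample_positive Extra copies of each fracture-containing patch
#'   per epoch (default 0: every tile of every image once per epoch).
#' @param seed Master seed for the split, shuffling, dropout and
#'   initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_phase1 = 0.001, lr_phase2 = 0.0025,
                         val_fraction = 0.1,
                         phase1_patience_epochs = 5, phase1_max_epochs = 5,
                         phase2_epochs = 3, batch_size = 8,
                         oversample_positive = 0, seed = 1L) {
  stopifnot(lr_phase1 > 0, lr_phase2 > 0,
            val_fraction > 0, val_fraction < 1,
            phase1_patience_epochs >= 1, phase1_max_epochs >= 1,
            phase2_epochs >= 0, batch_size >= 1, oversample_positive >= 0)
  structure(list(optimizer = "adam",
                 lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 loss = "binary_cross_entropy",
                 val_fraction = val_fraction,
                 phase1_patience_epochs = as.integer(phase1_patience_epochs),
                 phase1_max_epochs = as.integer(phase1_max_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 batch_size = as.integer(batch_size),
                 oversample_positive = as.integer(oversample_positive),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Examination-wise validation split
#'
#' Both views of an examination always land on the same side. Seeded,
#' disjoint, exhaustive.
#'
#' @param exams List of examinations.
#' @param val_fraction Fraction assigned to validation.
#' @param seed Integer seed.
#' @return List with `train` and `val` examination lists.
#' @export
split_validation <- function(exams, val_fraction = 0.1, seed = 1L) {
  n <- length(exams)
  if (n < 2) stop("need at least 2 examinations to split")
  nv <- round(n * val_fraction)
  if (nv < 1 || nv >= n)
    stop("val_fraction ", val_fraction, " yields an empty split side for n = ", n)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, nv))
  list(train = exams[-idx], val = exams[idx])
}

#' Enumerate training patches of one image
#'
#' One patch per tile of the layout. Each patch pairs the mirror-padded input
#' window with the output-tile-sized mask target; the auxiliary target is
#' whether the fracture drawing intersects the patch's output window (within
#' the image).
#'
#' @param image Preprocessed image matrix.
#' @param mask Aligned 0/1 mask matrix.
#' @param layout A [plan_tiles()] layout for `dim(image)`.
#' @param seed Optional seed; when given, the patch order is shuffled.
#' @param oversample_positive Extra copies of each `aux_target = TRUE` patch.
#' @param materialize Extract pixel data now (`TRUE`) or return descriptors
#'   only (`FALSE`; use [extract_patch()] later).
#' @return List of patch samples: each has `tile`, `origin`, `aux_target`,
#'   and (when materialized) `input_window` and `target_mask`.
#' @export
sample_patches <- function(image, mask, layout, seed = NULL,
                           oversample_positive = 0, materialize = TRUE) {
  stopifnot(inherits(layout, "tile_layout"))
  if (!all(dim(image) == dim(mask)))
    stop("mask/image misalignment: ", paste(dim(image), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"))
  if (!all(dim(image) == layout$image_shape))
    stop("layout does not match the image shape")
  t <- layout$output_tile_px
  h <- layout$image_shape[1]; w <- layout$image_shape[2]
  n <- nrow(layout$tile_origins)
  patches <- lapply(seq_len(n), function(i) {
    o <- layout$tile_origins[i, ]
    rr <- (o[1] + 1):min(o[1] + t, h)
    cc <- (o[2] + 1):min(o[2] + t, w)
    list(tile = i, origin = o,
         aux_target = sum(mask[rr, cc]) > 0)
  })
  if (oversample_positive > 0) {
    pos <- Filter(function(p) p$aux_target, patches)
    patches <- c(patches, rep(pos, oversample_positive))
  }
  if (!is.null(seed))
    patches <- withr::with_seed(as.integer(seed),
                                patches[sample.int(length(patches))])
  if (materialize) {
    padded <- pad_for_tiles(image, layout)
    patches <- lapply(patches, function(p)
      c(p, extract_patch_padded(padded, mask, layout, p$tile)))
  }
  patches
}

# Window extraction given the already-padded image.
extract_window_padded <- function(padded, layout, tile) {
  o <- layout$tile_origins[tile, ]
  n <- layout$input_tile_px
  padded[(o[1] + 1):(o[1] + n), (o[2] + 1):(o[2] + n), drop = FALSE]
}

# Output-tile-sized mask target; mirror-pads only when the output window
# extends beyond the image (images smaller than the tile).
tile_target_mask <- function(mask, layout, tile) {
  o <- layout$tile_origins[tile, ]
  t <- layout$output_tile_px
  if (o[1] + t <= nrow(mask) && o[2] + t <= ncol(mask)) {
    tm <- mask[(o[1] + 1):(o[1] + t), (o[2] + 1):(o[2] + t), drop = FALSE]
  } else {
    m <- layout$margin_px
    pm <- pad_for_tiles(mask, layout)
    tm <- pm[(o[1] + m + 1):(o[1] + m + t),
             (o[2] + m + 1):(o[2] + m + t), drop = FALSE]
  }
  (tm != 0) * 1
}

extract_patch_padded <- function(padded, mask, layout, tile) {
  list(input_window = extract_window_padded(padded, layout, tile),
       target_mask = tile_target_mask(mask, layout, tile))
}

#' Extract one patch sample from an image
#'
#' @param image,mask Image and aligned 0/1 mask.
#' @param layout A [plan_tiles()] layout.
#' @param tile Tile index.
#' @return List with `input_window` (input-tile-sized, mirror-padded at the
#'   borders) and `target_mask` (output-tile-sized).
#' @export
extract_patch <- function(image, mask, layout, tile) {
  extract_patch_padded(pad_for_tiles(image, layout), mask, layout, tile)
}

# Numerically stable binary cross-entropy on logits; mean over elements.
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

# Segmentation loss on the center crop of the logits (the output-tile core)
# plus optional auxiliary loss; returns loss components and the gradients
# needed by the backward pass.
batch_loss <- function(logits, targets, crop_px, aux_logits = NULL,
                       aux_targets = NULL, aux_weight = 1) {
  d <- dim(logits)
  t <- dim(targets)[1]
  n <- d[4]
  idx_r <- crop_px + seq_len(t)
  core <- logits[idx_r, idx_r, 1L, , drop = FALSE]
  dim(core) <- c(t, t, n)
  p <- stats::plogis(core)
  seg_loss <- bce_with_logits(core, targets)
  g_core <- (p - targets) / length(targets)
  g_logits <- array(0, d)
  g_logits[idx_r, idx_r, 1L, ] <- g_core
  out <- list(seg_loss = seg_loss, total = seg_loss, g_logits = g_logits)
  if (!is.null(aux_logits)) {
    pa <- stats::plogis(aux_logits)
    aux_loss <- bce_with_logits(aux_logits, aux_targets)
    out$aux_loss <- aux_loss
    out$total <- seg_loss + aux_weight * aux_loss
    out$g_aux <- aux_weight * (pa - aux_targets) / length(aux_targets)
  }
  out
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(par = par, state = state)
}

# Pixel- and image-level validation accuracy of the current model.
validation_accuracy <- function(model, val_exams, output_tile) {
  correct_px <- 0; total_px <- 0; correct_img <- 0; total_img <- 0
  for (ex in val_exams) {
    for (v in c("pa", "lat")) {
      img <- ex[[v]]$pixels
      msk <- ex[[paste0(v, "_mask")]]
      map <- predict_confidence_map(model, img, output_tile)
      correct_px <- correct_px + sum((map >= 0.5) == (msk > 0))
      total_px <- total_px + length(map)
      correct_img <- correct_img + ((max(map) >= 0.5) == ex$fracture)
      total_img <- total_img + 1
    }
  }
  c(pixel = correct_px / total_px, image = correct_img / total_img)
}

#' Two-phase training of the segmentation network
#'
#' Phase 1 trains the segmentation path alone (Adam, `lr_phase1`, per-pixel
#' binary cross-entropy) until the validation segmentation accuracy stops
#' improving (patience) or the epoch cap is reached. Phase 2 attaches the
#' auxiliary patch classifier and continues on the summed loss (Adam,
#' `lr_phase2`) for `phase2_epochs` epochs. The returned model is the
#' checkpoint with the best validation pixel accuracy seen at any epoch.
#'
#' @param model_spec A [network_spec()].
#' @param exams List of examinations with preprocessed pixels in `[0, 1]`
#'   and aligned masks (`pa`/`lat` radiographs, `pa_mask`/`lat_mask`), e.g.
#'   from [generate_dataset()] + [preprocess_exam()].
#' @param cfg A [train_config()].
#' @param aux An [aux_head_spec()] for phase 2 (`NULL` skips phase 2).
#' @param output_tile Output tile side for patch extraction and validation
#'   inference (default 130).
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint), `history` (one row per
#'   epoch: phase, epoch, train_loss, val_pixel_acc, val_image_acc) and
#'   `split` (the train/val examination split).
#' @export
train_two_phase <- function(model_spec, exams, cfg = train_config(),
                            aux = aux_head_spec(), output_tile = 130,
                            verbose = FALSE) {
  stopifnot(inherits(model_spec, "network_spec"), inherits(cfg, "train_config"))
  if (length(exams) == 0) stop("no training data")
  split <- split_validation(exams, cfg$val_fraction, cfg$seed)

  shape <- dim(split$train[[1]]$pa$pixels)
  layout <- plan_tiles(shape, model_spec$geometry, output_tile)
  index <- list()
  for (i in seq_along(split$train)) {
    ex <- split$train[[i]]
    for (v in c("pa", "lat")) {
      if (!all(dim(ex[[v]]$pixels) == shape))
        stop("all training images must share one shape at desk scale")
      ps <- sample_patches(ex[[v]]$pixels, ex[[paste0(v, "_mask")]], layout,
                           materialize = FALSE,
                           oversample_positive = cfg$oversample_positive)
      for (p in ps)
        index[[length(index) + 1L]] <- list(exam = i, view = v, tile = p$tile,
                                            aux_target = p$aux_target)
    }
  }

  # mirror-padded images are reused across epochs (each patch window is a
  # contiguous block of them)
  padded_cache <- lapply(split$train, function(ex)
    list(pa = pad_for_tiles(ex$pa$pixels, layout),
         lat = pad_for_tiles(ex$lat$pixels, layout)))

  model <- build_model(model_spec, aux = NULL, seed = cfg$seed)
  history <- list()
  best <- list(acc = -Inf, par = NULL, buf = NULL, aux = NULL)

  run_epoch <- function(model, state, lr, phase, epoch) {
    order <- sample.int(length(index))
    losses <- c()
    bs <- cfg$batch_size
    for (b0 in seq(1, length(index), by = bs)) {
      sel <- order[b0:min(b0 + bs - 1L, length(index))]
      nb <- length(sel)
      xb <- array(0, c(layout$input_tile_px, layout$input_tile_px, 1L, nb))
      tb <- array(0, c(output_tile, output_tile, nb))
      at <- numeric(nb)
      for (k in seq_len(nb)) {
        it <- index[[sel[k]]]
        ex <- split$train[[it$exam]]
        xb[, , 1L, k] <- extract_window_padded(padded_cache[[it$exam]][[it$view]],
                                               layout, it$tile)
        tb[, , k] <- tile_target_mask(ex[[paste0(it$view, "_mask")]],
                                      layout, it$tile)
        at[k] <- as.numeric(it$aux_target)
      }
      with_aux <- phase == 2 && !is.null(model$aux)
      fw <- net_forward(model, xb, train = TRUE, with_aux = with_aux)
      model <- fw$model
      ls <- batch_loss(fw$logits, tb, layout$crop_px,
                       aux_logits = if (with_aux) fw$aux_logits else NULL,
                       aux_targets = if (with_aux) at else NULL)
      if (!is.finite(ls$total))
        stop("training diverged (non-finite loss) in phase ", phase,
             ", epoch ", epoch, "; last finite losses: ",
             paste(utils::tail(round(losses, 4), 5), collapse = " "))
      aux_bw <- if (with_aux)
        aux_backward(model, fw$cache$aux, ls$g_aux) else NULL
      grads <- net_backward(model, fw$cache, ls$g_logits, aux = aux_bw)
      st <- adam_step(model$par, grads, state, lr)
      model$par <- st$par
      state <- st$state
      losses <- c(losses, ls$total)
    }
    list(model = model, state = state, loss = mean(losses))
  }

  note_epoch <- function(model, phase, epoch, loss) {
    acc <- validation_accuracy(model, split$val, output_tile)
    history[[length(history) + 1L]] <<- data.frame(
      phase = phase, epoch = epoch, train_loss = loss,
      val_pixel_acc = acc["pixel"], val_image_acc = acc["image"],
      row.names = NULL)
    if (acc["pixel"] >= best$acc) {
      best <<- list(acc = acc["pixel"], par = model$par, buf = model$buf,
                    aux = model$aux, aux_dims = model$aux_dims)
    }
    if (verbose)
      message(sprintf("phase %d epoch %d: loss %.4f, val pixel acc %.4f",
                      phase, epoch, loss, acc["pixel"]))
    acc["pixel"]
  }

  withr::with_seed(cfg$seed + 1L, {
    # phase 1: segmentation only
    state <- adam_init(model$par)
    best_epoch <- 0L; best_p1 <- -Inf
    for (epoch in seq_len(cfg$phase1_max_epochs)) {
      r <- run_epoch(model, state, cfg$lr_phase1, 1L, epoch)
      model <- r$model; state <- r$state
      acc <- note_epoch(model, 1L, epoch, r$loss)
      if (acc > best_p1) { best_p1 <- acc; best_epoch <- epoch }
      if (epoch - best_epoch >= cfg$phase1_patience_epochs) break
    }
    # phase 2: attach the auxiliary head, summed loss
    if (!is.null(aux) && cfg$phase2_epochs > 0) {
      model <- attach_aux_head(model, aux, seed = cfg$seed + 1000L)
      state <- adam_init(model$par)
      for (epoch in seq_len(cfg$phase2_epochs)) {
        r <- run_epoch(model, state, cfg$lr_phase2, 2L, epoch)
        model <- r$model; state <- r$state
        note_epoch(model, 2L, epoch, r$loss)
      }
    }
  })

  model$par <- best$par
  model$buf <- best$buf
  model$aux <- best$aux
  model$aux_dims <- best$aux_dims
  list(model = model, history = do.call(rbind, history), split = split)
}

#' Select the operating threshold on validation confidences
#'
#' Scans the observed per-image maximum confidences as candidate cutoffs
#' (decision rule: positive iff max confidence >= threshold) and returns the
#' one maximizing classification accuracy; ties break toward the largest
#' (most specific) threshold.
#'
#' @param confidences Per-image maximum confidence values.
#' @param labels Logical (or 0/1) ground-truth labels.
#' @return The selected threshold, with the achieved accuracy as attribute
#'   `"accuracy"`.
#' @export
select_threshold <- function(confidences, labels) {
  labels <- as.logical(labels)
  stopifnot(length(confidences) == length(labels))
  if (all(labels) || !any(labels))
    stop("threshold selection needs at least one positive and one negative")
  cand <- sort(unique(confidences))
  acc <- vapply(cand, function(t) mean((confidences >= t) == labels),
                numeric(1))
  best <- max(acc)
  thr <- max(cand[acc == best])
  structure(thr, accuracy = best)
}

#' Preprocess an examination in place
#'
#' Applies [preprocess_radiograph()] to both views (and their masks, when
#' present).
#'
#' @param ex An examination with pixel data.
#' @param config A [preprocess_config()].
#' @return The examination with standardized pixels and resampled masks.
#' @export
preprocess_exam <- function(ex, config = preprocess_config()) {
  for (v in c("pa", "lat")) {
    mk <- ex[[paste0(v, "_mask")]]
    pp <- preprocess_radiograph(ex[[v]], config, mask = mk)
    if (!is.null(mk)) ex[[paste0(v, "_mask")]] <- attr(pp, "mask")
    attr(pp, "mask") <- NULL
    ex[[v]] <- pp
  }
  ex
}

#' Predict max confidences for a list of examinations
#'
#' Runs tiled inference on both views of each examination and records the
#' per-image maximum confidence, yielding the prediction table consumed by
#' the evaluation layer.
#'
#' @param model A trained [build_model()] result.
#' @param exams List of preprocessed examinations.
#' @param output_tile Output tile side (default 130).
#' @param shift Optional [shift_plan()] for shift-and-average inference.
#' @return Data frame with columns `image_id, exam_id, view, max_confidence,
#'   cast, truth`.
#' @export
predict_exams <- function(model, exams, output_tile = 130, shift = NULL) {
  rows <- list()
  for (ex in exams) {
    for (v in c("pa", "lat")) {
      map <- predict_confidence_map(model, ex[[v]]$pixels, output_tile,
                                    shift = shift)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = paste0(ex$exam_id, "_", v),
        exam_id = ex$exam_id,
        view = ex[[v]]$view,
        max_confidence = max(map),
        cast = ex$cast,
        truth = ex$fracture,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
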