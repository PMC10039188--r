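#' Mirror-pad a 2-D image
#'
#' Reflects the image about its borders (without repeating the edge pixel),
#' tiling reflectively when the pad exceeds the image size. This is the edge
#' extension used to supply the valid-padding network with context beyond the
#' image frame without introducing intensity discontinuities.
#'
#' @param image Numeric matrix.
#' @param top,bottom,left,right Nonnegative pad widths in pixels.
#' @return The padded matrix.
#' @export
mirror_pad <- function(image, top = 0, bottom = 0, left = 0, right = 0) {
  stopifnot(is.matrix(image), top >= 0, bottom >= 0, left >= 0, right >= 0)
  if (nrow(image) < 2 || ncol(image) < 2)
    stop("mirror padding needs at least 2 pixels per dimension")
  ri <- reflect_index(seq.int(1 - top, nrow(image) + bottom), nrow(image))
  ci <- reflect_index(seq.int(1 - left, ncol(image) + right), ncol(image))
  image[ri, ci, drop = FALSE]
}

# Fold arbitrary (possibly non-positive) 1-based positions back into 1..n by
# reflection with period 2(n-1), edge pixels not duplicated.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n - 2L)        # R modulo is nonnegative
  ifelse(m < n, m + 1L, 2L * n - 1L - m)
}

#' Plan a valid-padding tiling of an image
#'
#' Covers the image with square output tiles laid on a regular grid; the last
#' row/column of tiles is shifted inward when the image size is not a multiple
#' of the tile size, and the doubly-covered strip is owned by the later tile.
#' Each output tile corresponds to a larger input window (the tile expanded by
#' `margin_px` on every side) read from a mirror-padded copy of the image.
#'
#' @param image_shape Integer (rows, cols) of the image to tile.
#' @param g A [unet_geometry()] used to derive the input window size.
#' @param output_tile Side of the square output tile in pixels (default 130).
#' @return A `tile_layout` object with fields `output_tile_px`,
#'   `input_tile_px`, `margin_px`, `crop_px` (crop from the network's natural
#'   output down to the tile), `tile_origins` (0-based (row, col) output-space
#'   origins), `image_shape`, `pad` (top/bottom/left/right pad widths) and
#'   `padded_shape`.
#' @export
plan_tiles <- function(image_shape, g, output_tile = 130) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 1), output_tile >= 1)
  image_shape <- as.integer(image_shape)
  req <- required_input_size(g, output_tile)
  if ((req$input_px - output_tile) %% 2L != 0L)
    stop("input size ", req$input_px, " and output tile ", output_tile,
         " give a non-integral margin; choose a compatible tile size")
  if ((req$actual_output_px - output_tile) %% 2L != 0L)
    stop("natural output ", req$actual_output_px, " cannot be center-cropped to ",
         output_tile)
  margin <- (req$input_px - output_tile) %/% 2L
  crop <- (req$actual_output_px - output_tile) %/% 2L

  axis_origins <- function(n) {
    t <- as.integer(output_tile)
    if (n <= t) return(0L)
    k <- ceiling(n / t)
    o <- as.integer((seq_len(k) - 1L) * t)
    o[k] <- n - t
    o
  }
  ro <- axis_origins(image_shape[1])
  co <- axis_origins(image_shape[2])
  origins <- as.matrix(expand.grid(row = ro, col = co, KEEP.OUT.ATTRS = FALSE))
  storage.mode(origins) <- "integer"

  overhang <- pmax(0L, as.integer(output_tile) - image_shape)
  pad <- c(top = margin, bottom = margin + overhang[1],
           left = margin, right = margin + overhang[2])
  structure(
    list(output_tile_px = as.integer(output_tile),
         input_tile_px = req$input_px,
         natural_output_px = req$actual_output_px,
         margin_px = margin,
         crop_px = crop,
         row_origins = ro,
         col_origins = co,
         tile_origins = origins,
         image_shape = image_shape,
         pad = pad,
         padded_shape = image_shape + c(pad["top"] + pad["bottom"],
                                        pad["left"] + pad["right"])),
    class = "tile_layout")
}

#' @export
print.tile_layout <- function(x, ...) {
  cat("Tile layout: ", nrow(x$tile_origins), " tile(s) of ", x$output_tile_px,
      "x", x$output_tile_px, " over a ", x$image_shape[1], "x", x$image_shape[2],
      " image\n", sep = "")
  cat("  input window ", x$input_tile_px, "px, margin ", x$margin_px,
      "px, natural output ", x$natural_output_px, "px (crop ", x$crop_px,
      ")\n", sep = "")
  invisible(x)
}

#' Mirror-pad an image according to a tile layout
#'
#' @param image Numeric matrix matching `layout$image_shape`.
#' @param layout A [plan_tiles()] layout.
#' @return The padded image; input windows are contiguous blocks of it.
#' @export
pad_for_tiles <- function(image, layout) {
  stopifnot(inherits(layout, "tile_layout"),
            all(dim(image) == layout$image_shape))
  mirror_pad(image, top = layout$pad["top"], bottom = layout$pad["bottom"],
             left = layout$pad["left"], right = layout$pad["right"])
}

#' Extract the input window of one tile from a padded image
#'
#' @param padded Image padded with [pad_for_tiles()].
#' @param layout A [plan_tiles()] layout.
#' @param tile Tile index (row of `layout$tile_origins`).
#' @return The `input_tile_px` x `input_tile_px` input window.
#' @export
tile_input_window <- function(padded, layout, tile) {
  stopifnot(inherits(layout, "tile_layout"),
            all(dim(padded) == layout$padded_shape))
  o <- layout$tile_origins[tile, ]
  n <- layout$input_tile_px
  padded[(o[1] + 1):(o[1] + n), (o[2] + 1):(o[2] + n), drop = FALSE]
}

# Region of the image (1-based row/col ranges) owned by each tile. Tiles are
# laid left-to-right, top-to-bottom; the inward-shifted last tile owns the
# strip it shares with its predecessor. The regions partition the image.
tile_owned_regions <- function(layout) {
  t <- layout$output_tile_px
  axis_regions <- function(origins, n) {
    k <- length(origins)
    lapply(seq_len(k), function(i) {
      start <- if (i == 1L) origins[1] else max(origins[i], origins[i - 1] + t)
      end <- min(origins[i] + t, n)
      c(start + 1L, end)  # 1-based inclusive
    })
  }
  list(rows = axis_regions(layout$row_origins, layout$image_shape[1]),
       cols = axis_regions(layout$col_origins, layout$image_shape[2]))
}

#' Stitch per-tile outputs into a full-image confidence map
#'
#' Each tile output is written into the region of the image that the tile
#' owns; the owned regions partition the image, so every pixel is written by
#' exactly one tile and values are preserved bit-exactly.
#'
#' @param per_tile_outputs List of `output_tile_px` x `output_tile_px`
#'   matrices, one per row of `layout$tile_origins` (column-major tile order).
#' @param layout A [plan_tiles()] layout.
#' @return A matrix of `layout$image_shape`.
#' @export
stitch <- function(per_tile_outputs, layout) {
  stopifnot(inherits(layout, "tile_layout"))
  if (length(per_tile_outputs) != nrow(layout$tile_origins))
    stop("expected ", nrow(layout$tile_origins), " tile outputs, got ",
         length(per_tile_outputs))
  t <- layout$output_tile_px
  ok <- vapply(per_tile_outputs, function(m) is.matrix(m) && all(dim(m) == t),
               logical(1))
  if (!all(ok))
    stop("tile output ", which(!ok)[1], " does not have shape ", t, "x", t)
  reg <- tile_owned_regions(layout)
  out <- matrix(NA_real_, layout$image_shape[1], layout$image_shape[2])
  nr <- length(layout$row_origins)
  idx <- 0L
  for (cj in seq_along(layout$col_origins)) {
    for (ri in seq_len(nr)) {
      idx <- idx + 1L          # matches expand.grid (row varies fastest)
      rr <- reg$rows[[ri]]
      cc <- reg$cols[[cj]]
      o <- layout$tile_origins[idx, ]
      out[rr[1]:rr[2], cc[1]:cc[2]] <-
        per_tile_outputs[[idx]][(rr[1] - o[1]):(rr[2] - o[1]),
                                (cc[1] - o[2]):(cc[2] - o[2]), drop = FALSE]
    }
  }
  stopifnot(!anyNA(out))
  out
}

#' Shift-and-average inference plan
#'
#' Test-time ensembling: tiled inference is repeated with the tile grid
#' shifted by every offset in a square grid, and the resulting confidence maps
#' are averaged. The stride times the number of shifts per axis must equal the
#' output tile side so that the offsets are distinct modulo the tile period.
#' The default (stride 26, 5 shifts per axis, tile 130) yields 25 passes.
#'
#' @param stride_px Shift stride in pixels (default 26).
#' @param shifts_per_axis Number of shifts per axis (default 5).
#' @param output_tile_px Output tile side the plan applies to (default 130).
#' @return A `shift_plan` object with an `offsets` matrix (one (row, col)
#'   offset per pass).
#' @export
shift_plan <- function(stride_px = 26, shifts_per_axis = 5, output_tile_px = 130) {
  stopifnot(stride_px >= 1, shifts_per_axis >= 1)
  if (stride_px * shifts_per_axis != output_tile_px)
    stop("stride_px * shifts_per_axis must equal output_tile_px (",
         stride_px, " * ", shifts_per_axis, " != ", output_tile_px, "); ",
         "offsets would not be distinct modulo the tile")
  s <- as.integer((seq_len(shifts_per_axis) - 1L) * stride_px)
  offsets <- as.matrix(expand.grid(row = s, col = s, KEEP.OUT.ATTRS = FALSE))
  storage.mode(offsets) <- "integer"
  structure(list(stride_px = as.integer(stride_px),
                 shifts_per_axis = as.integer(shifts_per_axis),
                 output_tile_px = as.integer(output_tile_px),
                 offsets = offsets),
            class = "shift_plan")
}

#' Shift-and-average ensemble of a tiled-inference function
#'
#' For each offset in the plan, the tile-grid origin is translated by the
#' offset (realized by mirror-padding the image at the top-left and cropping
#' the result back), the full-image inference is run, and the per-pixel mean
#' over all passes is returned.
#'
#' @param infer Deterministic function mapping an image matrix to a
#'   confidence-map matrix of the same shape (e.g. tiled network inference).
#' @param image Image matrix.
#' @param plan A [shift_plan()].
#' @return The averaged confidence map (same shape as `image`).
#' @export
shift_average <- function(infer, image, plan = shift_plan()) {
  stopifnot(is.function(infer), is.matrix(image), inherits(plan, "shift_plan"))
  h <- nrow(image); w <- ncol(image)
  acc <- matrix(0, h, w)
  for (k in seq_len(nrow(plan$offsets))) {
    dr <- plan$offsets[k, 1]
    dc <- plan$offsets[k, 2]
    shifted <- if (dr == 0L && dc == 0L) image else
      mirror_pad(image, top = dr, left = dc)
    m <- infer(shifted)
    if (!all(dim(m) == dim(shifted)))
      stop("infer() must return a map with the shape of its input")
    acc <- acc + m[(dr + 1):(dr + h), (dc + 1):(dc + w), drop = FALSE]
  }
  acc / nrow(plan$offsets)
}
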