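#' Preprocessing configuration
#'
#' The standardization applied to every radiograph before the network, in
#' fixed order: resample to an isotropic physical resolution (default
#' 0.1 x 0.1 mm), contrast-limited adaptive histogram equalization, then
#' per-image min--max normalization to `[0, 1]`.
#'
#' CLAHE parameters are not dictated by the modelled study; the defaults
#' (8 x 8 tile grid, clip limit 0.01 of the tile pixel count, 256 histogram
#' bins over the observed intensity range) follow common practice and are
#' fully exposed here.
#'
#' @param target_spacing_mm Target isotropic pixel spacing, mm.
#' @param clahe_tile_grid Length-2 integer `(rows, cols)` tile grid, each
#'   at least 2.
#' @param clahe_clip_limit Histogram clip limit as a fraction of the tile
#'   pixel count.
#' @param clahe_bins Number of histogram bins.
#' @param interpolation Image interpolation method; only `"bilinear"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing_mm = 0.1,
                              clahe_tile_grid = c(8L, 8L),
                              clahe_clip_limit = 0.01,
                              clahe_bins = 256L,
                              interpolation = "bilinear") {
  interpolation <- match.arg(interpolation, "bilinear")
  stopifnot(target_spacing_mm > 0, length(clahe_tile_grid) == 2,
            all(clahe_tile_grid >= 2), clahe_clip_limit > 0, clahe_bins >= 2)
  structure(list(target_spacing_mm = target_spacing_mm,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_bins = as.integer(clahe_bins),
                 interpolation = interpolation),
            class = "preprocess_config")
}

#' Resample a radiograph to a target physical resolution
#'
#' The output grid has `round(size * spacing / target)` pixels per axis and
#' isotropic spacing `target_spacing_mm`; intensities are interpolated
#' bilinearly. An image already on the target grid is returned unchanged.
#' A binary mask aligned with the image can be resampled alongside; it uses
#' nearest-neighbour interpolation and stays binary.
#'
#' @param r A [radiograph()] (spacing metadata required).
#' @param target_spacing_mm Target isotropic spacing in mm.
#' @param mask Optional 0/1 matrix aligned with `r$pixels`.
#' @return The resampled radiograph; if `mask` was given, the resampled mask
#'   is attached as attribute `"mask"`.
#' @export
resample_radiograph <- function(r, target_spacing_mm = 0.1, mask = NULL) {
  stopifnot(inherits(r, "radiograph"))
  if (is.null(r$pixels)) stop("radiograph has no pixel data")
  if (any(!is.finite(r$pixel_spacing_mm)) || any(r$pixel_spacing_mm <= 0))
    stop("pixel spacing metadata is missing; required for resampling")
  insize <- dim(r$pixels)
  outsize <- as.integer(round(insize * r$pixel_spacing_mm / target_spacing_mm))
  if (any(outsize < 1)) stop("target spacing collapses the image")
  if (all(outsize == insize) && all(r$pixel_spacing_mm == target_spacing_mm)) {
    out <- r
  } else {
    px <- as.matrix(EBImage::resize(r$pixels, w = outsize[1], h = outsize[2],
                                    antialias = FALSE))
    out <- radiograph(pmax(px, 0), target_spacing_mm, r$view, r$cast, r$exam_id)
  }
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == insize))
    m <- if (all(outsize == insize)) mask else
      as.matrix(EBImage::resize(mask, w = outsize[1], h = outsize[2],
                                filter = "none"))
    attr(out, "mask") <- (m != 0) * 1L
  }
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is quantized to `bins` levels of its observed intensity range,
#' per-tile histograms are clipped at `clip_limit` (a fraction of the tile
#' pixel count) with the excess redistributed, and the per-tile mapping
#' functions are blended bilinearly between tile centers. The output spans
#' the same intensity range as the input. A constant image is returned
#' unchanged. Delegates the core algorithm to [EBImage::clahe()].
#'
#' @param image Finite numeric matrix.
#' @param tile_grid Length-2 integer `(rows, cols)` tile grid, each >= 2.
#' @param clip_limit Clip limit as a fraction of the tile pixel count.
#' @param bins Number of histogram bins (default 256).
#' @return Matrix of the same shape, spanning the input's intensity range.
#' @export
clahe_image <- function(image, tile_grid = c(8L, 8L), clip_limit = 0.01,
                        bins = 256L) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image must be finite")
  if (length(tile_grid) != 2 || any(tile_grid < 2))
    stop("tile_grid must be two integers, each at least 2")
  if (any(dim(image) < tile_grid))
    stop("tile grid finer than the image: tiles would be smaller than a pixel")
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)              # single-level histogram: identity
  x01 <- (image - lo) / (hi - lo)
  # the tiling requires dimensions divisible by the grid; mirror-pad to the
  # next multiple and crop back afterwards
  h <- nrow(x01); w <- ncol(x01)
  ph <- ceiling(h / tile_grid[1]) * tile_grid[1] - h
  pw <- ceiling(w / tile_grid[2]) * tile_grid[2] - w
  if (ph > 0 || pw > 0) x01 <- mirror_pad(x01, bottom = ph, right = pw)
  # EBImage's limit is expressed relative to the uniform bin count
  # (clip_count = limit * tile_pixels / bins), so a fraction f of the tile
  # pixel count corresponds to limit = f * bins.
  y <- EBImage::clahe(x01, nx = tile_grid[1], ny = tile_grid[2],
                      bins = bins, limit = clip_limit * bins)
  y <- as.matrix(y)[seq_len(h), seq_len(w), drop = FALSE]
  lo + y * (hi - lo)
}

#' Min--max normalize an image to `[0, 1]`
#'
#' Per-image normalization `(x - min) / (max - min)`; a constant image maps
#' to all zeros (degenerate rule).
#'
#' @param image Finite numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_intensity <- function(image) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image must be finite")
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(matrix(0, nrow(image), ncol(image)))
  (image - lo) / (hi - lo)
}

#' Full preprocessing pipeline for one radiograph
#'
#' Applies, in order: resampling to the target physical resolution, CLAHE,
#' and min--max normalization. The order is fixed; the output is always in
#' `[0, 1]`.
#'
#' @param r A [radiograph()].
#' @param config A [preprocess_config()].
#' @param mask Optional aligned 0/1 mask, resampled by nearest neighbour.
#' @return The standardized radiograph (pixels in `[0, 1]`, spacing equal to
#'   the target); a resampled mask, when given, is attached as attribute
#'   `"mask"`.
#' @export
preprocess_radiograph <- function(r, config = preprocess_config(), mask = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  rs <- resample_radiograph(r, config$target_spacing_mm, mask = mask)
  px <- clahe_image(rs$pixels, config$clahe_tile_grid,
                    config$clahe_clip_limit, config$clahe_bins)
  px <- normalize_intensity(px)
  out <- radiograph(px, rs$pixel_spacing_mm, r$view, r$cast, r$exam_id)
  attr(out, "mask") <- attr(rs, "mask")
  out
}
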