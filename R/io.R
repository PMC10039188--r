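#' Radiograph record
#'
#' A single 2-D grayscale radiograph with its physical pixel spacing, the
#' projection it was acquired in, and the cast flag. Pixel coordinates are
#' 0-based, row-major `(row, column)`; spacing is `(row_spacing, col_spacing)`
#' in millimetres.
#'
#' @param pixels Numeric matrix of nonnegative finite intensities.
#' @param pixel_spacing_mm Length-2 positive numeric, `(row, col)` spacing in
#'   mm; a scalar is recycled to both axes.
#' @param view `"postero_anterior"` or `"lateral"`, the two projections a
#'   wrist examination comprises.
#' @param cast Logical; whether a cast is present.
#' @param exam_id Identifier of the examination the radiograph belongs to.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, pixel_spacing_mm,
                       view = c("postero_anterior", "lateral"),
                       cast = FALSE, exam_id = NA_character_) {
  view <- match.arg(view)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("radiograph pixels must be finite and nonnegative")
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  if (length(pixel_spacing_mm) != 2 || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be a pair of positive reals")
  structure(list(pixels = pixels,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 view = view,
                 cast = isTRUE(cast),
                 exam_id = exam_id),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("Radiograph %s [%s]: %d x %d px @ %.3g x %.3g mm, cast=%s\n",
              x$exam_id, x$view, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$cast))
  invisible(x)
}

image_format_from_path <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.png$", lp)) return("png")
  if (grepl("\\.dcm$", lp) || grepl("\\.dicom$", lp)) return("dicom")
  stop("cannot infer image format from path: ", path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a radiograph from disk
#'
#' Supported formats are NIfTI (`.nii`/`.nii.gz`; spacing from the header
#' zooms) and PNG with a JSON sidecar (`<path>.json`; spacing and intensity
#' scale from the sidecar). Intensities are returned unchanged on the scale
#' they were written at. DICOM is recognized but not supported: no DICOM
#' reader is available to this package, and the upstream workflow converts
#' DICOM to NIfTI losslessly before analysis.
#'
#' @param path File path.
#' @param format One of `"nifti"`, `"png"`, `"dicom"`; inferred from the file
#'   extension by default.
#' @param view,cast,exam_id Metadata not carried by the pixel container,
#'   normally supplied from the dataset manifest.
#' @return A [radiograph()].
#' @export
read_image <- function(path, format = image_format_from_path(path),
                       view = c("postero_anterior", "lateral"),
                       cast = FALSE, exam_id = NA_character_) {
  view <- match.arg(view)
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- match.arg(format, c("nifti", "png", "dicom"))
  if (format == "dicom")
    stop("DICOM reading is not supported; convert to NIfTI (lossless) first")
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:2]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("NIfTI header of ", path, " has no valid pixel spacing (pixdim)")
    px <- strip_attrs(as.array(img))
    return(radiograph(px, spacing, view = view, cast = cast, exam_id = exam_id))
  }
  # PNG + sidecar
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("PNG image ", path, " has no sidecar ", sc,
         ": pixel_spacing_mm is required (needed by the resampling stage)")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$pixel_spacing_mm))
    stop("sidecar ", sc, " is missing pixel_spacing_mm")
  px01 <- png::readPNG(path)
  if (length(dim(px01)) == 3) px01 <- px01[, , 1]
  scale <- if (is.null(meta$intensity_max)) 1 else meta$intensity_max
  radiograph(px01 * scale, meta$pixel_spacing_mm,
             view = view, cast = cast, exam_id = exam_id)
}

#' Write a radiograph to disk
#'
#' NIfTI (`.nii`/`.nii.gz`) stores intensities losslessly as float64 with the
#' pixel spacing in the header and is the canonical format. PNG stores an
#' 8-bit quantization of `pixels / intensity_max` plus a JSON sidecar with the
#' spacing and scale; it is lossless only for intensities already on an 8-bit
#' grid.
#'
#' @param r A [radiograph()].
#' @param path Destination path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(r, path) {
  stopifnot(inherits(r, "radiograph"))
  format <- image_format_from_path(path)
  if (format == "dicom") stop("DICOM writing is not supported")
  if (format == "nifti") {
    img <- RNifti::asNifti(r$pixels)
    RNifti::pixdim(img) <- r$pixel_spacing_mm
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    imax <- max(r$pixels, 1)
    png::writePNG(r$pixels / imax, path)
    jsonlite::write_json(
      list(pixel_spacing_mm = r$pixel_spacing_mm, intensity_max = imax,
           view = r$view, cast = r$cast, exam_id = r$exam_id),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask Matrix of 0/1 (or logical) values.
#' @param path Destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- (mask != 0) * 1
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path `.png` path.
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "double"
  (m > 0.5) * 1L
}

#' Write a confidence map
#'
#' Confidence maps hold per-pixel fracture probabilities in `[0, 1]`. They are
#' stored as float64 NIfTI so that threshold decisions (e.g. at the 0.61
#' operating point) reproduce exactly after a round trip.
#'
#' @param map Numeric matrix with values in `[0, 1]`.
#' @param path Destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_confidence_map <- function(map, path) {
  stopifnot(is.matrix(map))
  if (any(!is.finite(map)) || any(map < 0) || any(map > 1))
    stop("confidence map values must lie in [0, 1]")
  img <- RNifti::asNifti(map)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a confidence map written by [write_confidence_map()]
#'
#' @param path `.nii` / `.nii.gz` path.
#' @return Numeric matrix.
#' @export
read_confidence_map <- function(path) {
  strip_attrs(as.array(RNifti::readNifti(path)))
}

# reduce a NIfTI-flavoured array to a bare numeric matrix
strip_attrs <- function(a) {
  d <- dim(a)
  d <- d[d > 1]
  if (length(d) != 2) stop("expected a 2-D image")
  matrix(as.numeric(a), d[1], d[2])
}
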