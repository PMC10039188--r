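#' Configuration for the synthetic wrist-radiograph simulator
#'
#' The simulator emulates two-view wrist examinations at desk scale: two
#' quasi-parallel bright bands (radius/ulna analogue) with brighter cortical
#' edges on a darker soft-tissue background, dark crack-shaped fracture lines
#' with pixel-aligned ground-truth masks, optional semi-transparent cast
#' overlays, Gaussian blur and noise. Intensities are generated on a
#' 12-bit-like scale (0--4095) so that downstream normalization is exercised
#' nontrivially.
#'
#' Defaults mirror the cohort structure of the study the package models:
#' fracture prevalence 0.7 and cast rate 0.45, with images on a 0.1 mm grid.
#'
#' @param image_height_px,image_width_px Image size in pixels.
#' @param pixel_spacing_mm Physical pixel spacing (isotropic), default 0.1 mm.
#' @param fracture_prevalence Probability that an examination is fractured.
#' @param cast_rate Probability that an examination wears a cast.
#' @param noise_sd Gaussian noise standard deviation, intensity units.
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 disables).
#' @param crack_width_px Width of the annotated fracture mask in pixels.
#' @param seed Integer seed governing dataset generation.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_height_px = 192, image_width_px = 160,
                         pixel_spacing_mm = 0.1,
                         fracture_prevalence = 0.7, cast_rate = 0.45,
                         noise_sd = 40, blur_sigma_px = 0.7,
                         crack_width_px = 3, seed = 1L) {
  cfg <- list(image_height_px = as.integer(image_height_px),
              image_width_px = as.integer(image_width_px),
              pixel_spacing_mm = pixel_spacing_mm,
              fracture_prevalence = fracture_prevalence,
              cast_rate = cast_rate,
              noise_sd = noise_sd,
              blur_sigma_px = blur_sigma_px,
              crack_width_px = crack_width_px,
              seed = as.integer(seed))
  if (cfg$image_height_px < 16 || cfg$image_width_px < 16)
    stop("image size must be at least 16 px per side")
  if (cfg$pixel_spacing_mm <= 0) stop("pixel_spacing_mm must be positive")
  if (cfg$fracture_prevalence < 0 || cfg$fracture_prevalence > 1)
    stop("fracture_prevalence must lie in [0, 1]")
  if (cfg$cast_rate < 0 || cfg$cast_rate > 1)
    stop("cast_rate must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (cfg$blur_sigma_px < 0) stop("blur_sigma_px must be nonnegative")
  if (cfg$crack_width_px <= 0) stop("crack_width_px must be positive")
  if (cfg$crack_width_px >= min(cfg$image_height_px, cfg$image_width_px))
    stop("crack_width_px larger than the image")
  structure(cfg, class = "synth_config")
}

# Distance from every pixel center to a polyline (matrix of (row, col)
# vertices), by minimizing the exact point-to-segment distance over segments.
dist_to_polyline <- function(h, w, pts) {
  py <- matrix(seq_len(h), h, w)
  px <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- matrix(Inf, h, w)
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2s <- (py - a[1])^2 + (px - a[2])^2
    } else {
      t <- ((py - a[1]) * ab[1] + (px - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      d2s <- (py - (a[1] + t * ab[1]))^2 + (px - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, d2s)
  }
  sqrt(d2)
}

# 12-bit-like intensity model, all units on the 0..4095 scale. The crack is
# a multiplicative attenuation (transmission through the lucent gap), so it
# stays visible whatever structure it crosses -- bone interior, cortex,
# overlapping bones or cast.
synth_levels <- list(tissue_base = 820, tissue_grad = 180,
                     trabecular = 1250, cortex = 1900,
                     crack_attenuation = 0.7, cast_gain = 420, max = 4095)

render_bone_band <- function(h, w, center_frac, halfwidth_frac, slope) {
  y <- seq_len(h)
  cx <- center_frac * w + slope * (y - h / 2)
  hw <- halfwidth_frac * w
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- abs(xs - matrix(cx, h, w)) / hw    # normalized distance to band center
  add <- matrix(0, h, w)
  inside <- d <= 1
  add[inside] <- synth_levels$trabecular
  shell <- d > 0.74 & d <= 1
  add[shell] <- synth_levels$trabecular + synth_levels$cortex
  list(add = add, center = cx, halfwidth = hw)
}

#' Generate one synthetic radiograph with its fracture mask
#'
#' Renders the bone/soft-tissue scene for the requested view, optionally adds
#' a dark crack-shaped fracture (lucent line) crossing the radius band, an
#' optional cast overlay, then applies Gaussian blur and noise. The mask
#' marks the dilated neighbourhood of the crack polyline (all pixels within
#' `crack_width_px / 2` of it) and is all zero for non-fracture images.
#' Deterministic: the same `config`, flags and `seed` reproduce the image and
#' mask bit-identically.
#'
#' @param config A [synth_config()].
#' @param fracture Logical; render a fracture?
#' @param cast Logical; render a cast overlay?
#' @param view `"postero_anterior"` or `"lateral"`.
#' @param seed Integer seed for this radiograph.
#' @return List with `image` (nonnegative matrix, 12-bit-like scale) and
#'   `mask` (0/1 integer matrix of the same shape).
#' @export
generate_radiograph <- function(config, fracture, cast = FALSE,
                                view = c("postero_anterior", "lateral"),
                                seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  view <- match.arg(view)
  h <- config$image_height_px
  w <- config$image_width_px
  withr::with_seed(as.integer(seed), {
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    img <- synth_levels$tissue_base +
      synth_levels$tissue_grad * xs / w +
      stats::rnorm(1, 0, 30)              # per-image exposure offset

    if (view == "postero_anterior") {
      radius <- render_bone_band(h, w, stats::runif(1, 0.34, 0.42), 0.11,
                                 stats::runif(1, -0.06, 0.06))
      ulna <- render_bone_band(h, w, stats::runif(1, 0.62, 0.70), 0.055,
                               stats::runif(1, -0.06, 0.06))
    } else {
      radius <- render_bone_band(h, w, stats::runif(1, 0.44, 0.54), 0.14,
                                 stats::runif(1, -0.06, 0.06))
      ulna <- render_bone_band(h, w, stats::runif(1, 0.56, 0.62), 0.06,
                               stats::runif(1, -0.06, 0.06))
    }
    img <- img + pmax(radius$add, ulna$add)

    mask <- matrix(0L, h, w)
    if (isTRUE(fracture)) {
      yc <- round(stats::runif(1, 0.30, 0.70) * h)
      cx <- radius$center[yc]
      hw <- radius$halfwidth
      npts <- 7L
      xpts <- seq(cx - hw - 2, cx + hw + 2, length.out = npts)
      ypts <- yc + cumsum(stats::rnorm(npts, 0, 2.2))
      ypts <- ypts - mean(ypts) + yc + stats::runif(1, -0.1, 0.1) * hw
      pts <- cbind(pmin(pmax(ypts, 2), h - 1), pmin(pmax(xpts, 2), w - 1))
      d <- dist_to_polyline(h, w, pts)
      img <- img * (1 - synth_levels$crack_attenuation * exp(-(d / 0.9)^2))
      mask[d <= config$crack_width_px / 2] <- 1L
      attr(mask, "crack_polyline") <- pts
    }

    if (isTRUE(cast)) {
      # broad semi-transparent band at a random angle
      theta <- stats::runif(1, -0.5, 0.5)
      ys <- matrix(seq_len(h), h, w)
      dline <- abs(cos(theta) * (xs - w / 2) + sin(theta) * (ys - h / 2))
      halfspan <- 0.36 * w
      profile <- pmin(1, pmax(0, (halfspan - dline) / 4))  # 4-px soft edge
      img <- img + synth_levels$cast_gain * profile
    }

    if (config$blur_sigma_px > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = config$blur_sigma_px))
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, config$noise_sd), h, w)
    img <- pmin(pmax(img, 0), synth_levels$max)
    list(image = img, mask = mask)
  })
}

#' Generate one synthetic two-view examination
#'
#' Both views are rendered independently but share the fracture and cast
#' labels; a fracture examination carries a nonempty mask in both views.
#'
#' @param config A [synth_config()].
#' @param fracture,cast Logical labels for the examination.
#' @param exam_id Identifier.
#' @param seed Integer seed; the two views use `seed` and `seed + 1`.
#' @return An object of class `synth_exam` (also an [examination()]), with
#'   `pa_mask` / `lat_mask` fields.
#' @export
generate_exam <- function(config, fracture, cast = FALSE,
                          exam_id = "exam001", seed = config$seed) {
  pa <- generate_radiograph(config, fracture, cast, "postero_anterior", seed)
  lat <- generate_radiograph(config, fracture, cast, "lateral", seed + 1L)
  ex <- examination(
    exam_id,
    radiograph(pa$image, config$pixel_spacing_mm, "postero_anterior", cast, exam_id),
    radiograph(lat$image, config$pixel_spacing_mm, "lateral", cast, exam_id),
    fracture = fracture, cast = cast)
  ex$pa_mask <- pa$mask
  ex$lat_mask <- lat$mask
  stopifnot(identical(ex$fracture, sum(pa$mask) + sum(lat$mask) > 0))
  class(ex) <- c("synth_exam", "examination")
  ex
}

#' Generate a synthetic dataset of two-view wrist examinations
#'
#' Fracture and cast labels are drawn independently per examination with the
#' configured prevalence and cast rate. When `dir` is given, images are
#' written as NIfTI (float64, spacing in the header), masks as 8-bit 0/255
#' PNG, and a manifest CSV (`exam_id, view, path, mask_path, fracture, cast`)
#' is written alongside. Identical seeds reproduce the dataset bytes.
#'
#' @param n_exams Number of examinations (>= 1).
#' @param config A [synth_config()]; `config$seed` drives all randomness.
#' @param dir Output directory, created if needed; `NULL` keeps the dataset
#'   in memory only.
#' @param keep_pixels Keep pixel arrays in the returned exams (default: only
#'   when nothing is written to disk).
#' @param render Render pixel data (`TRUE`). `render = FALSE` draws the
#'   labels and builds the manifest without rendering images (no files are
#'   written); useful for label-level work at large `n_exams`. The labels
#'   drawn are identical either way.
#' @return List of `synth_exam` objects with attribute `"manifest"` (data
#'   frame) and, when written, `"manifest_path"`.
#' @export
generate_dataset <- function(n_exams, config, dir = NULL,
                             keep_pixels = is.null(dir), render = TRUE) {
  stopifnot(inherits(config, "synth_config"), n_exams >= 1)
  n_exams <- as.integer(n_exams)
  labels <- withr::with_seed(config$seed, {
    list(fracture = stats::runif(n_exams) < config$fracture_prevalence,
         cast = stats::runif(n_exams) < config$cast_rate,
         seeds = sample.int(.Machine$integer.max %/% 4L, n_exams))
  })
  if (!isTRUE(render) && !is.null(dir))
    stop("render = FALSE cannot write image files")
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  exams <- vector("list", n_exams)
  rows <- vector("list", 2L * n_exams)
  for (i in seq_len(n_exams)) {
    id <- sprintf("exam%04d", i)
    ex <- if (isTRUE(render)) {
      generate_exam(config, labels$fracture[i], labels$cast[i],
                    exam_id = id, seed = labels$seeds[i])
    } else {
      structure(list(exam_id = id, pa = NULL, lat = NULL,
                     fracture = labels$fracture[i], cast = labels$cast[i]),
                class = c("synth_exam", "examination"))
    }
    for (k in 1:2) {
      v <- c("postero_anterior", "lateral")[k]
      img_rel <- sprintf("%s_%s.nii.gz", id, c("pa", "lat")[k])
      msk_rel <- sprintf("%s_%s_mask.png", id, c("pa", "lat")[k])
      if (!is.null(dir)) {
        write_image(if (k == 1) ex$pa else ex$lat, file.path(dir, img_rel))
        write_mask(if (k == 1) ex$pa_mask else ex$lat_mask, file.path(dir, msk_rel))
      }
      rows[[2L * (i - 1L) + k]] <- data.frame(
        exam_id = id, view = v, path = img_rel, mask_path = msk_rel,
        fracture = labels$fracture[i], cast = labels$cast[i],
        stringsAsFactors = FALSE)
    }
    if (!keep_pixels && isTRUE(render)) {
      ex$pa$pixels <- NULL
      ex$lat$pixels <- NULL
      ex$pa_mask <- NULL
      ex$lat_mask <- NULL
    }
    exams[[i]] <- ex
  }
  manifest <- do.call(rbind, rows)
  attr(exams, "manifest") <- manifest
  if (!is.null(dir)) {
    mp <- file.path(dir, "manifest.csv")
    write_manifest(manifest, mp)
    attr(exams, "manifest_path") <- mp
  }
  exams
}
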