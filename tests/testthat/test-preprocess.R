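test_that("resampling is the identity on the target grid", {
  px <- matrix(runif(50 * 50), 50)
  r <- radiograph(px, 0.1, "lateral")
  out <- resample_radiograph(r, 0.1)
  expect_identical(out$pixels, px)
})

test_that("resampling halves the spacing by doubling the grid", {
  r <- radiograph(matrix(runif(100 * 100), 100), 0.2, "postero_anterior")
  out <- resample_radiograph(r, 0.1)
  expect_equal(dim(out$pixels), c(200L, 200L))
  expect_equal(out$pixel_spacing_mm, c(0.1, 0.1))
})

test_that("bilinear interpolation reproduces a linear ramp analytically", {
  ncol_in <- 50
  vals <- seq(100, 590, by = 10)                 # linear in column index
  px <- matrix(rep(vals, each = 40), 40, ncol_in)
  r <- radiograph(px, 0.2, "lateral")
  out <- resample_radiograph(r, 0.1)$pixels
  # independent oracle: 1-D linear interpolation between pixel centers
  centers_in <- ((seq_len(ncol_in) - 1) + 0.5) * 0.2
  centers_out <- ((seq_len(ncol(out)) - 1) + 0.5) * 0.1
  interior <- centers_out >= centers_in[1] & centers_out <= centers_in[ncol_in]
  oracle <- stats::approx(centers_in, vals, xout = centers_out[interior])$y
  expect_equal(out[20, interior], oracle, tolerance = 1e-10)
})

test_that("mask resampling is nearest-neighbour and stays binary", {
  withr::with_seed(6, m <- matrix(rbinom(900, 1, 0.2), 30, 30))
  r <- radiograph(matrix(runif(900), 30), 0.2, "lateral")
  out <- resample_radiograph(r, 0.1, mask = m)
  rm <- attr(out, "mask")
  expect_equal(dim(rm), c(60L, 60L))
  expect_true(all(rm %in% c(0L, 1L)))
  # upsampling by an even factor replicates each pixel
  expect_identical(rm[seq(1, 60, 2), seq(1, 60, 2)] > 0, m > 0)
})

test_that("missing spacing fails before resampling", {
  r <- radiograph(matrix(1, 4, 4), 0.1, "lateral")
  r$pixel_spacing_mm <- c(NA_real_, NA_real_)
  expect_error(resample_radiograph(r, 0.1), "spacing")
})

test_that("CLAHE maps a constant image to itself", {
  x <- matrix(1234, 32, 32)
  expect_identical(clahe_image(x), x)
})

test_that("uncapped single-mapping CLAHE equals global histogram equalization", {
  # four identical quadrants under a 2x2 grid: every tile mapping equals the
  # global equalization mapping, and blending identical mappings is a no-op
  withr::with_seed(4, q <- matrix(runif(48 * 48, 100, 3000), 48))
  img <- rbind(cbind(q, q), cbind(q, q))
  y <- clahe_image(img, tile_grid = c(2, 2), clip_limit = 1, bins = 256)
  lo <- min(img); hi <- max(img)
  b <- pmin(floor((img - lo) / (hi - lo) * 256), 255)
  cdf <- cumsum(tabulate(as.vector(b) + 1, 256)) / length(img)
  oracle <- lo + (hi - lo) * cdf[b + 1]
  expect_lt(max(abs(y - oracle)) / (hi - lo), 2 / 256)
})

test_that("CLAHE is idempotent on a two-level image up to quantization", {
  cb <- matrix(as.double((outer(1:64, 1:64, "+")) %% 2), 64)
  a1 <- clahe_image(cb, tile_grid = c(4, 4), clip_limit = 0.01)
  a2 <- clahe_image(a1, tile_grid = c(4, 4), clip_limit = 0.01)
  expect_lt(max(abs(a2 - a1)), 3 / 256)
})

test_that("CLAHE validates its tile grid", {
  x <- matrix(runif(64), 8, 8)
  expect_error(clahe_image(x, tile_grid = c(1, 1)), "at least 2")
  expect_error(clahe_image(x, tile_grid = c(16, 16)), "finer than the image")
})

test_that("CLAHE handles dimensions not divisible by the grid", {
  withr::with_seed(13, x <- matrix(runif(130 * 130, 0, 4095), 130))
  y <- clahe_image(x, tile_grid = c(8, 8))
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
})

test_that("normalization follows the min-max rule with the degenerate case", {
  x <- matrix(c(10, 30, 30, 10), 2)
  expect_identical(normalize_intensity(x), matrix(c(0, 1, 1, 0), 2))
  expect_identical(normalize_intensity(matrix(7, 3, 3)), matrix(0, 3, 3))
  y <- normalize_intensity(matrix(c(0, 1000, 4095, 2000), 2))
  expect_identical(range(y), c(0, 1))
})

test_that("the full pipeline outputs [0, 1] at the target spacing", {
  cfg <- tiny_synth_config()
  r <- generate_radiograph(cfg, fracture = TRUE, seed = 2)
  rg <- radiograph(r$image, 0.2, "postero_anterior")
  out <- preprocess_radiograph(rg, preprocess_config(clahe_tile_grid = c(4, 4)),
                               mask = r$mask)
  expect_equal(out$pixel_spacing_mm, c(0.1, 0.1))
  expect_gte(min(out$pixels), 0)
  expect_lte(max(out$pixels), 1)
  expect_equal(dim(attr(out, "mask")), dim(out$pixels))
})
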