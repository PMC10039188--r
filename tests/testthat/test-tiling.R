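test_that("mirror padding reflects without repeating the edge", {
  m <- matrix(1:12, 3, 4)
  p <- mirror_pad(m, top = 2, left = 1)
  # rows above the image mirror rows 2 and 3; the column mirrors column 2
  expect_equal(p[3:5, 2:5], m)
  expect_equal(p[2, 2:5], m[2, ])
  expect_equal(p[1, 2:5], m[3, ])
  expect_equal(p[3:5, 1], m[, 2])
  # padding larger than the image tiles reflectively and stays finite
  big <- mirror_pad(m, top = 7, bottom = 7, left = 9, right = 9)
  expect_equal(dim(big), c(17L, 22L))
  expect_true(all(big %in% m))
})

test_that("tile plans cover the image with the expected tile counts", {
  g <- tiny_geometry()
  expect_identical(nrow(plan_tiles(c(28, 28), g, 28)$tile_origins), 1L)
  expect_identical(nrow(plan_tiles(c(56, 84), g, 28)$tile_origins), 6L)
  l <- plan_tiles(c(29, 29), g, 28)
  expect_identical(nrow(l$tile_origins), 4L)
  # brute-force coverage count over owned regions: every pixel exactly once
  reg <- wristseg:::tile_owned_regions(l)
  cover <- matrix(0L, 29, 29)
  for (rr in reg$rows) for (cc in reg$cols)
    cover[rr[1]:rr[2], cc[1]:cc[2]] <- cover[rr[1]:rr[2], cc[1]:cc[2]] + 1L
  expect_true(all(cover == 1L))
})

test_that("stitching an identity network reconstructs the image bit-exactly", {
  g <- tiny_geometry()
  withr::with_seed(11, {
    for (trial in 1:10) {
      shape <- sample(20:90, 2, replace = TRUE)
      img <- matrix(runif(prod(shape)), shape[1], shape[2])
      layout <- plan_tiles(shape, g, 28)
      expect_identical(stitch(identity_tile_outputs(img, layout), layout), img)
    }
  })
})

test_that("stitch writes each pixel from exactly one tile and checks shapes", {
  g <- tiny_geometry()
  layout <- plan_tiles(c(45, 70), g, 28)
  nt <- nrow(layout$tile_origins)
  const <- lapply(seq_len(nt), function(i) matrix(0.25, 28, 28))
  expect_true(all(stitch(const, layout) == 0.25))
  withr::with_seed(3, {
    tiles <- lapply(seq_len(nt), function(i) matrix(runif(28 * 28), 28))
    map <- stitch(tiles, layout)
    # every stitched value originates from some tile's owned block
    reg <- wristseg:::tile_owned_regions(layout)
    idx <- 0
    for (cj in seq_along(layout$col_origins)) for (ri in seq_along(layout$row_origins)) {
      idx <- idx + 1
      rr <- reg$rows[[ri]]; cc <- reg$cols[[cj]]
      o <- layout$tile_origins[idx, ]
      expect_identical(map[rr[1]:rr[2], cc[1]:cc[2]],
                       tiles[[idx]][(rr[1] - o[1]):(rr[2] - o[1]),
                                    (cc[1] - o[2]):(cc[2] - o[2]), drop = FALSE])
    }
  })
  expect_error(stitch(const[-1], layout), "expected")
  bad <- const; bad[[2]] <- matrix(0, 27, 28)
  expect_error(stitch(bad, layout), "shape")
})

test_that("the default shift plan makes 25 distinct offsets and validates stride", {
  p <- shift_plan()
  expect_identical(nrow(p$offsets), 25L)
  expect_identical(nrow(unique(p$offsets)), 25L)
  expect_setequal(unique(p$offsets[, 1]), as.integer(c(0, 26, 52, 78, 104)))
  expect_error(shift_plan(26, 4, 130), "must equal")
})

test_that("shift_average runs one pass per offset and averages a constant", {
  img <- matrix(runif(40 * 40), 40)
  plan <- shift_plan(5, 2, 10)
  calls <- 0L
  counting <- function(x) { calls <<- calls + 1L; matrix(0.3, nrow(x), ncol(x)) }
  out <- shift_average(counting, img, plan)
  expect_identical(calls, 4L)
  expect_true(all(abs(out - 0.3) < 1e-15))

  calls <- 0L
  out25 <- shift_average(function(x) { calls <<- calls + 1L; x * 0 },
                         matrix(0, 140, 140), shift_plan())
  expect_identical(calls, 25L)
})

test_that("shift_average is a no-op for a translation-equivariant stub", {
  withr::with_seed(5, img <- matrix(runif(50 * 60), 50, 60))
  single <- box_blur_reflect(img)
  avg <- shift_average(box_blur_reflect, img, shift_plan(5, 2, 10))
  expect_lt(max(abs(avg - single)), 1e-12)
})

test_that("shift_average stays within the range of the individual passes", {
  withr::with_seed(9, img <- matrix(runif(30 * 30), 30))
  passes <- list()
  stub <- function(x) {
    m <- box_blur_reflect(x)
    passes[[length(passes) + 1L]] <<- m
    m
  }
  plan <- shift_plan(3, 2, 6)
  out <- shift_average(stub, img, plan)
  lo <- min(vapply(passes, min, numeric(1)))
  hi <- max(vapply(passes, max, numeric(1)))
  expect_gte(min(out), lo - 1e-12)
  expect_lte(max(out), hi + 1e-12)
})
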