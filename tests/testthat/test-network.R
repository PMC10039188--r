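test_that("the compiled convolution matches a naive R oracle", {
  withr::with_seed(7, {
    x <- array(rnorm(12 * 11 * 3), c(12, 11, 3))
    W <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
    b <- rnorm(2)
  })
  expect_equal(wristseg:::.conv_valid_forward(x, W, b),
               naive_conv_valid(x, W, b), tolerance = 1e-12)
})

test_that("the default specification builds 25 convolution layers", {
  expect_identical(conv_layer_count(network_spec()), 25L)
  g <- network_spec()$geometry
  expect_identical(g$pool_steps, 7L)
  expect_identical(conv_layer_count(tiny_network_spec()), 6L)
})

test_that("forward output shape follows the size-propagation arithmetic", {
  spec <- tiny_network_spec()
  m <- build_model(spec, seed = 2)
  withr::with_seed(1, {
    for (inp in c(42L, 50L, 58L)) {
      out <- output_size_given_input(spec$geometry, inp)
      expect_false(is.na(out))
      tile <- matrix(runif(inp * inp), inp)
      conf <- model_confidence(m, tile)$confidence
      expect_equal(dim(conf), c(out, out))
      expect_true(all(conf > 0 & conf < 1))
    }
  })
})

test_that("infeasible tile sizes fail pointing at the size arithmetic", {
  m <- build_model(tiny_network_spec(), seed = 1)
  expect_error(model_confidence(m, matrix(0.5, 41, 41)),
               "required_input_size")
})

test_that("evaluation mode is deterministic and batch invariant", {
  m <- build_model(tiny_network_spec(), seed = 4)
  withr::with_seed(2, tile <- matrix(runif(50 * 50), 50))
  a <- model_confidence(m, tile)
  b <- model_confidence(m, tile)
  expect_identical(a$confidence, b$confidence)
  expect_null(a$aux_probability)

  xb1 <- array(tile, c(50, 50, 1, 1))
  xb8 <- array(0, c(50, 50, 1, 8))
  withr::with_seed(3, for (i in 1:8) xb8[, , 1, i] <- matrix(runif(2500), 50))
  xb8[, , 1, 5] <- tile
  r1 <- wristseg:::net_forward(m, xb1)$logits
  r8 <- wristseg:::net_forward(m, xb8)$logits
  expect_lt(max(abs(r1[, , 1, 1] - r8[, , 1, 5])), 1e-11)
})

test_that("the auxiliary head yields a patch probability but only when attached", {
  aux <- aux_head_spec(c("bottom", "dec1"), fc_hidden_layers = 2)
  m <- build_model(tiny_network_spec(), aux = aux, seed = 4)
  withr::with_seed(2, tile <- matrix(runif(50 * 50), 50))
  r <- model_confidence(m, tile, with_aux = TRUE)
  expect_true(r$aux_probability > 0 && r$aux_probability < 1)
  # prediction path never reads the head
  expect_null(model_confidence(m, tile)$aux_probability)
})

test_that("analytic gradients match finite differences", {
  g1 <- unet_geometry(1, c(1, 1), c(2))
  rt <- required_input_size(g1, 8)
  spec <- network_spec(g1, base_channels = 2, channel_cap = 4,
                       dropout_rate = 0, dropout_before_final_convs = 0)
  aux <- aux_head_spec("bottom", fc_hidden_layers = 2)
  m <- build_model(spec, aux = aux, seed = 5)
  n <- 2
  withr::with_seed(2, {
    xb <- array(runif(rt$input_px^2 * n), c(rt$input_px, rt$input_px, 1, n))
    tb <- array(rbinom(rt$actual_output_px^2 * n, 1, 0.3),
                c(rt$actual_output_px, rt$actual_output_px, n))
  })
  at <- c(1, 0)
  loss_fn <- function(model) {
    fw <- wristseg:::net_forward(model, xb, train = TRUE, with_aux = TRUE)
    ls <- wristseg:::batch_loss(fw$logits, tb, 0L,
                                aux_logits = fw$aux_logits, aux_targets = at)
    list(loss = ls$total, fw = fw, ls = ls)
  }
  r <- loss_fn(m)
  auxbw <- wristseg:::aux_backward(m, r$fw$cache$aux, r$ls$g_aux)
  grads <- wristseg:::net_backward(m, r$fw$cache, r$ls$g_logits, aux = auxbw)
  eps <- 1e-6
  withr::with_seed(3, {
    for (nm in names(grads)) {
      for (trial in 1:2) {
        i <- sample(length(m$par[[nm]]), 1)
        m2 <- m
        m2$par[[nm]][i] <- m$par[[nm]][i] + eps
        l1 <- loss_fn(m2)$loss
        m2$par[[nm]][i] <- m$par[[nm]][i] - eps
        l0 <- loss_fn(m2)$loss
        num <- (l1 - l0) / (2 * eps)
        ana <- grads[[nm]][i]
        # conv biases under batch norm have an exactly-zero gradient that
        # finite differences only recover to rounding noise
        if (abs(num) < 1e-8 && abs(ana) < 1e-8) {
          succeed()
        } else {
          expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-5)
        }
      }
    }
  })
})

test_that("tiled prediction stitches into the image shape with sane values", {
  m <- build_model(tiny_network_spec(), seed = 6)
  withr::with_seed(5, img <- matrix(runif(45 * 60), 45, 60))
  map <- predict_confidence_map(m, img, output_tile = 28)
  expect_equal(dim(map), c(45L, 60L))
  expect_true(all(map > 0 & map < 1))
})

test_that("shift-and-average inference through a model averages tiled passes", {
  m <- build_model(tiny_network_spec(), seed = 9)
  withr::with_seed(14, img <- matrix(runif(30 * 30), 30))
  plan <- shift_plan(7, 4, 28)
  avg <- predict_confidence_map(m, img, output_tile = 28, shift = plan)
  single <- predict_confidence_map(m, img, output_tile = 28)
  expect_equal(dim(avg), dim(img))
  expect_true(all(avg > 0 & avg < 1))
  # the ensemble is a genuine mean of per-offset passes: reproduce it
  acc <- matrix(0, 30, 30)
  for (k in seq_len(nrow(plan$offsets))) {
    dr <- plan$offsets[k, 1]; dc <- plan$offsets[k, 2]
    shifted <- if (dr == 0 && dc == 0) img else mirror_pad(img, top = dr, left = dc)
    mp <- predict_confidence_map(m, shifted, output_tile = 28)
    acc <- acc + mp[(dr + 1):(dr + 30), (dc + 1):(dc + 30)]
  }
  expect_equal(avg, acc / nrow(plan$offsets), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(avg, single)))
})
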