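#' Valid-padding U-Net architecture geometry
#'
#' Describes the spatial arithmetic of an encoder--decoder segmentation
#' network that uses *valid* padding: every k x k convolution shrinks each
#' spatial dimension by k - 1, every pooling halves it (and requires an even
#' size), and every upsampling doubles it. The geometry alone determines which
#' input tile sizes are feasible and what output size they produce.
#'
#' The default is the seven-pool, 25-convolution configuration used by the
#' fracture-detection model: one convolution per encoder stage (including the
#' bottleneck), two per decoder stage, and five in the top decoder stage
#' (two stage convolutions plus three final convolutions).
#'
#' @param pool_steps Number of max-pooling (and matching upsampling) steps.
#' @param convs_per_stage_down Integer vector of length `pool_steps + 1`:
#'   convolutions in each encoder stage, the last entry being the bottleneck.
#' @param convs_per_stage_up Integer vector of length `pool_steps`:
#'   convolutions in each decoder stage, ordered from the deepest stage to the
#'   top (full-resolution) stage.
#' @param kernel_size Odd convolution kernel size (default 3).
#' @return An object of class `unet_geometry`.
#' @examples
#' g <- unet_geometry()                    # 7 pools, 25 convolutions
#' classic <- unet_geometry(4, rep(2, 5), rep(2, 4))
#' output_size_given_input(classic, 572)   # 388
#' @export
unet_geometry <- function(pool_steps = 7,
                          convs_per_stage_down = NULL,
                          convs_per_stage_up = NULL,
                          kernel_size = 3) {
  stopifnot(pool_steps >= 1, kernel_size %% 2 == 1, kernel_size >= 1)
  if (is.null(convs_per_stage_down)) {
    convs_per_stage_down <- if (pool_steps == 7) rep(1L, 8L) else rep(2L, pool_steps + 1L)
  }
  if (is.null(convs_per_stage_up)) {
    convs_per_stage_up <- if (pool_steps == 7) c(rep(2L, 6L), 5L) else rep(2L, pool_steps)
  }
  convs_per_stage_down <- as.integer(convs_per_stage_down)
  convs_per_stage_up <- as.integer(convs_per_stage_up)
  if (length(convs_per_stage_down) != pool_steps + 1)
    stop("convs_per_stage_down must have length pool_steps + 1")
  if (length(convs_per_stage_up) != pool_steps)
    stop("convs_per_stage_up must have length pool_steps")
  if (any(convs_per_stage_down < 0) || any(convs_per_stage_up < 0))
    stop("convolution counts must be nonnegative")
  structure(
    list(pool_steps = as.integer(pool_steps),
         convs_per_stage_down = convs_per_stage_down,
         convs_per_stage_up = convs_per_stage_up,
         kernel_size = as.integer(kernel_size),
         padding = "valid"),
    class = "unet_geometry")
}

#' @export
print.unet_geometry <- function(x, ...) {
  cat("Valid-padding U-Net geometry\n")
  cat("  pool steps:   ", x$pool_steps, "\n")
  cat("  encoder convs:", paste(x$convs_per_stage_down, collapse = " "),
      "(last = bottleneck)\n")
  cat("  decoder convs:", paste(x$convs_per_stage_up, collapse = " "),
      "(deepest first)\n")
  cat("  kernel:       ", x$kernel_size, "x", x$kernel_size, ", valid padding\n", sep = "")
  invisible(x)
}

#' Propagate a spatial size through a valid-padding U-Net
#'
#' Simulates one spatial dimension through the network: each encoder stage
#' subtracts `(kernel - 1) * convs` then halves (requiring an even size before
#' pooling), the bottleneck subtracts its convolutions, and each decoder stage
#' doubles then subtracts. Skip connections are center-cropped and impose no
#' extra constraint.
#'
#' @param g A [unet_geometry()].
#' @param input_px Input size in pixels (scalar positive integer).
#' @return The output size, or `NA_integer_` if the size is infeasible (an
#'   intermediate size would be non-positive or odd before a pooling step).
#' @export
output_size_given_input <- function(g, input_px) {
  stopifnot(inherits(g, "unet_geometry"), length(input_px) == 1, input_px >= 1)
  shrink <- g$kernel_size - 1L
  s <- as.integer(input_px)
  p <- g$pool_steps
  for (stage in seq_len(p)) {
    s <- s - shrink * g$convs_per_stage_down[stage]
    if (s <= 0L || s %% 2L != 0L) return(NA_integer_)
    s <- s %/% 2L
  }
  s <- s - shrink * g$convs_per_stage_down[p + 1L]
  if (s <= 0L) return(NA_integer_)
  for (stage in seq_len(p)) {
    s <- 2L * s - shrink * g$convs_per_stage_up[stage]
    if (s <= 0L) return(NA_integer_)
  }
  s
}

#' Smallest feasible input size for a desired output size
#'
#' Valid padding makes the network's input necessarily larger than its output;
#' moreover only a sparse set of input sizes is feasible (evenness is required
#' before every pooling). This finds the smallest input whose propagated
#' output is feasible and at least `desired_output`; the achieved output may
#' exceed the request, in which case callers center-crop.
#'
#' @param g A [unet_geometry()].
#' @param desired_output Minimum acceptable output size in pixels.
#' @return A list with `input_px` and `actual_output_px`.
#' @export
required_input_size <- function(g, desired_output) {
  stopifnot(inherits(g, "unet_geometry"), length(desired_output) == 1,
            desired_output >= 1)
  desired_output <- as.integer(desired_output)
  shrink <- g$kernel_size - 1L
  total_convs <- sum(g$convs_per_stage_down) + sum(g$convs_per_stage_up)
  bound <- desired_output +
    shrink * total_convs * 2L^g$pool_steps + 2L^(g$pool_steps + 2L)
  for (inp in desired_output:bound) {
    out <- output_size_given_input(g, inp)
    if (!is.na(out) && out >= desired_output)
      return(list(input_px = inp, actual_output_px = out))
  }
  stop("no feasible input size found up to the search bound ", bound)
}
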