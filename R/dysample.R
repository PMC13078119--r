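# Content-aware dynamic upsampler. Instead of a fixed interpolation stencil,
# each output pixel resamples the source map at a learned position: a base
# bilinear grid plus a static offset branch (linear + channel-to-space
# rearrangement, scaled by a fixed range factor) and a dynamic branch in
# which one linear projection, squashed through a sigmoid and halved, gates
# the other. Offsets are expressed in source-pixel units; sampling is
# bilinear with border clamping, so zero offsets reproduce an exact bilinear
# resize and a constant field stays constant.

#' Dynamic upsampler specification
#'
#' @param in_channels source channel count C
#' @param scale integer upsampling factor s >= 2
#' @param groups offset groups g; channels are split into g consecutive
#'   groups sharing one (row, col) offset pair
#' @param static_range multiplier applied to the static offset branch
#' @param dynamic_gate fixed multiplier on the sigmoid-gated dynamic branch
#' @return object of class `dysample_spec`
#' @export
dysample_spec <- function(in_channels, scale = 2L, groups = 4L,
                          static_range = 0.25, dynamic_gate = 0.5) {
  stopifnot(scale >= 2L, groups >= 1L, in_channels %% groups == 0L)
  structure(list(in_channels = as.integer(in_channels), scale = as.integer(scale),
                 groups = as.integer(groups), static_range = static_range,
                 dynamic_gate = dynamic_gate),
            class = "dysample_spec")
}

#' Build a dynamic upsampler module
#' @param spec from [dysample_spec()]
#' @export
dysample <- function(spec) {
  if (is.numeric(spec)) spec <- dysample_spec(spec)
  C <- spec$in_channels
  co <- 2L * spec$groups * spec$scale^2
  mk <- function() list(w = ad_param(.winit(c(1L, 1L, C, co), C) * 1e-2),
                        b = ad_param(numeric(co)))
  p1 <- mk(); p2 <- mk(); p3 <- mk()
  new_module("dysample",
             params = list(w1 = p1$w, b1 = p1$b, w2 = p2$w, b2 = p2$b,
                           w3 = p3$w, b3 = p3$b),
             children = list(), spec = spec, co = co)
}

.check_dys_input <- function(x, spec) {
  d <- dim(vv(x))
  if (d[3] != spec$in_channels) {
    stop(sprintf("dysample expects %d channels, got %d", spec$in_channels, d[3]))
  }
  d
}

#' Static offset branch: linear projection then channel-to-space
#' rearrangement, multiplied by the static range factor.
#'
#' @param x feature map (H, W, C, N)
#' @param m module from [dysample()]
#' @return offset field (sH, sW, 2g, N) in source-pixel units
#' @export
static_offsets <- function(x, m) {
  x <- as_fmap(x)
  spec <- m$spec
  .check_dys_input(x, spec)
  lin <- ad_conv2d(x, m$params$w1, b = m$params$b1)
  ad_mul(ad_pixel_shuffle(lin, spec$scale), spec$static_range)
}

#' Dynamic offset branch: sigmoid-gated product of two linear projections
#' (gate fixed at `dynamic_gate`), then channel-to-space rearrangement.
#'
#' @inheritParams static_offsets
#' @return offset field (sH, sW, 2g, N)
#' @export
dynamic_offsets <- function(x, m) {
  x <- as_fmap(x)
  spec <- m$spec
  .check_dys_input(x, spec)
  gate <- ad_sigmoid(ad_conv2d(x, m$params$w2, b = m$params$b2))
  val <- ad_conv2d(x, m$params$w3, b = m$params$b3)
  scaled <- ad_mul(ad_mul(gate, val), spec$dynamic_gate)
  ad_pixel_shuffle(scaled, spec$scale)
}

#' Base sampling grid: each output pixel's bilinear source coordinate,
#' replicated over the offset groups.
#' @keywords internal
#' @noRd
dysample_base_grid <- function(H, W, s, g, N) {
  ys <- ((seq_len(s * H) - 0.5) / s) - 0.5
  xs <- ((seq_len(s * W) - 0.5) / s) - 0.5
  grid <- array(0, dim = c(s * H, s * W, 2L * g, N))
  for (k in seq_len(g)) {
    grid[, , 2 * k - 1, ] <- ys
    grid[, , 2 * k, ] <- rep(rep(xs, each = s * H), N)
  }
  grid
}

#' Dynamic upsampling forward pass
#'
#' Samples the input bilinearly at base-grid + static + dynamic offset
#' positions (border-clamped).
#'
#' @inheritParams static_offsets
#' @param training logical (unused; present for interface symmetry)
#' @return feature map (sH, sW, C, N)
#' @export
dysample_forward <- function(x, m, training = FALSE) {
  x <- as_fmap(x)
  spec <- m$spec
  d <- .check_dys_input(x, spec)
  off <- ad_add(static_offsets(x, m), dynamic_offsets(x, m))
  grid <- dysample_base_grid(d[1], d[2], spec$scale, spec$groups, d[4])
  pos <- ad_add(off, grid)
  ad_grid_sample(x, pos, groups = spec$groups)
}

#' @export
sd_forward.sd_dysample <- function(m, x, training = FALSE) {
  dysample_forward(x, m, training)
}

#' @export
sd_flops.sd_dysample <- function(m, H, W) {
  3 * 2 * m$spec$in_channels * m$co * H * W
}
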