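# Star-operation backbone: a four-stage hierarchical feature extractor whose
# basic block multiplies a 7x7 depthwise branch with a 1x1 pointwise branch
# element-wise and adds a residual connection. The stem and every stage entry
# are stride-2 convolutions with batch norm and a rectifier, so the four
# stages sit at strides 4/8/16/32; the last three are exported as the
# detection feature pyramid.

#' Stem parameters for the star backbone
#'
#' A 3x3, stride-2 convolution from RGB to the initial width, followed by
#' batch normalisation and a rectifier.
#'
#' @param c_init output channel count
#' @param act rectifier, `"relu6"` (default) or `"relu"`
#' @return a module usable with [stem_forward()]
#' @export
star_stem <- function(c_init = 24L, act = c("relu6", "relu")) {
  act <- match.arg(act)
  m <- mod_conv(3L, c_init, 3L, stride = 2L, act = act)
  class(m) <- c("sd_star_stem", class(m))
  m
}

#' Stride-2 downsampling block of the star backbone
#'
#' @param ci,co input/output channels
#' @param act rectifier
#' @return a module usable with [downsample_forward()]
#' @export
star_downsample <- function(ci, co, act = c("relu6", "relu")) {
  act <- match.arg(act)
  m <- mod_conv(ci, co, 3L, stride = 2L, act = act)
  class(m) <- c("sd_star_down", class(m))
  m
}

#' Star block: depthwise x pointwise multiplicative interaction
#'
#' Output is `dw7x7(x) * (W1x1 x + b) + x`: a 7x7 depthwise branch capturing
#' local spatial texture, a 1x1 pointwise branch mixing channels, merged by
#' element-wise multiplication, plus an identity shortcut. Input and output
#' shapes are identical. Zeroing the pointwise weights and bias makes the
#' block an exact identity.
#'
#' @param C channel count
#' @return star block module
#' @export
star_block <- function(C) {
  new_module("star_block",
             params = list(
               dw = ad_param(.winit(c(7L, 7L, C), 49)),
               fc = ad_param(.winit(c(1L, 1L, C, C), C)),
               fb = ad_param(numeric(C))),
             children = list(), C = C)
}

#' @export
sd_forward.sd_star_block <- function(m, x, training = FALSE) {
  xdw <- ad_dwconv2d(x, m$params$dw)
  xfc <- ad_conv2d(x, m$params$fc, b = m$params$fb)
  ad_add(ad_mul(xdw, xfc), x)
}

#' @export
sd_flops.sd_star_block <- function(m, H, W) {
  2 * 49 * m$C * H * W + 2 * m$C * m$C * H * W
}

#' Apply the stem to an image batch
#'
#' @param x array (H, W, 3, N) (a single (H, W, 3) image is promoted)
#' @param p module from [star_stem()]
#' @param training logical, batch-norm mode
#' @return feature map at half resolution
#' @export
stem_forward <- function(x, p, training = FALSE) {
  x <- as_fmap(x)
  if (dim(vv(x))[3] != 3L) {
    stop(sprintf("stem expects 3 input channels, got %d", dim(vv(x))[3]))
  }
  if (dim(vv(x))[1] < 2L || dim(vv(x))[2] < 2L) stop("stem input must be at least 2x2")
  sd_forward(p, x, training)
}

#' Apply a stride-2 downsampling block
#' @inheritParams stem_forward
#' @param p module from [star_downsample()]
#' @export
downsample_forward <- function(x, p, training = FALSE) {
  x <- as_fmap(x)
  if (dim(vv(x))[3] != p$ci) {
    stop(sprintf("downsample expects %d channels, got %d", p$ci, dim(vv(x))[3]))
  }
  sd_forward(p, x, training)
}

#' Apply a star block
#' @inheritParams stem_forward
#' @param p module from [star_block()]
#' @export
star_block_forward <- function(x, p, training = FALSE) {
  x <- as_fmap(x)
  if (dim(vv(x))[3] != p$C) {
    stop(sprintf("star block expects %d channels, got %d", p$C, dim(vv(x))[3]))
  }
  sd_forward(p, x, training)
}

#' Star backbone specification
#'
#' @param stage_widths integer(4) channel widths of the four stages
#' @param stage_depths integer(4) star blocks per stage
#' @param stem_width stem output channels
#' @param pyramid_levels which stages to export (default 2:4, strides 8/16/32)
#' @param act rectifier used in stem and downsampling blocks
#' @return an object of class `star_backbone_spec`
#' @export
star_backbone_spec <- function(stage_widths = c(32L, 48L, 96L, 160L),
                               stage_depths = c(1L, 1L, 2L, 2L),
                               stem_width = 24L,
                               pyramid_levels = 2:4,
                               act = "relu6") {
  stopifnot(length(stage_widths) == 4L, length(stage_depths) == 4L,
            all(stage_widths > 0), all(stage_depths >= 0),
            all(pyramid_levels %in% 1:4))
  structure(list(stage_widths = as.integer(stage_widths),
                 stage_depths = as.integer(stage_depths),
                 stem_width = as.integer(stem_width),
                 pyramid_levels = as.integer(pyramid_levels), act = act),
            class = "star_backbone_spec")
}

#' Build the star backbone module from a specification
#' @param spec from [star_backbone_spec()]
#' @export
star_backbone <- function(spec = star_backbone_spec()) {
  ch <- list(stem = star_stem(spec$stem_width, spec$act))
  prev <- spec$stem_width
  for (i in 1:4) {
    ch[[paste0("down", i)]] <- star_downsample(prev, spec$stage_widths[i], spec$act)
    for (j in seq_len(spec$stage_depths[i])) {
      ch[[paste0("s", i, "_", j)]] <- star_block(spec$stage_widths[i])
    }
    prev <- spec$stage_widths[i]
  }
  new_module("star_backbone", params = list(), children = ch, spec = spec)
}

#' Run the star backbone, returning the exported feature pyramid
#'
#' @param x image batch (H, W, 3, N); H and W must be divisible by 32
#' @param bb module from [star_backbone()] (a spec is accepted and built)
#' @param training logical
#' @return named list of feature maps (`p<stride>` names), strides 8/16/32
#'   for the default export levels
#' @export
backbone_forward <- function(x, bb, training = FALSE) {
  if (inherits(bb, "star_backbone_spec")) bb <- star_backbone(bb)
  x <- as_fmap(x)
  d <- dim(vv(x))
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop(sprintf("backbone input %dx%d must be divisible by 32", d[1], d[2]))
  }
  spec <- bb$spec
  y <- sd_forward(bb$children$stem, x, training)
  out <- list()
  for (i in 1:4) {
    y <- sd_forward(bb$children[[paste0("down", i)]], y, training)
    for (j in seq_len(spec$stage_depths[i])) {
      y <- sd_forward(bb$children[[paste0("s", i, "_", j)]], y, training)
    }
    if (i %in% spec$pyramid_levels) out[[paste0("p", 2^(i + 1))]] <- y
  }
  out
}

#' @export
sd_forward.sd_star_backbone <- function(m, x, training = FALSE) {
  backbone_forward(x, m, training)
}

#' @export
sd_flops.sd_star_backbone <- function(m, H, W) {
  spec <- m$spec
  f <- sd_flops(m$children$stem, H, W)
  h <- ceiling(H / 2); w <- ceiling(W / 2)
  for (i in 1:4) {
    f <- f + sd_flops(m$children[[paste0("down", i)]], h, w)
    h <- ceiling(h / 2); w <- ceiling(w / 2)
    for (j in seq_len(spec$stage_depths[i])) {
      f <- f + sd_flops(m$children[[paste0("s", i, "_", j)]], h, w)
    }
  }
  f
}

#' Promote an image or feature array to the internal (H, W, C, N) layout
#' @param x 3-D (H,W,C) or 4-D (H,W,C,N) array, or a tensor node
#' @return 4-D array (or node, passed through)
#' @export
as_fmap <- function(x) {
  if (ad_is_node(x)) return(x)
  d <- dim(x)
  if (is.null(d) || length(d) == 3L) {
    array(x, dim = c(dim(x) %||% length(x), 1L))
  } else x
}
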