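# Detector assembly: backbone -> tail fusion -> PAN neck (two top-down
# upsample+concat+fusion stages, two bottom-up downsample+concat+fusion
# stages) -> three decoupled anchor-free heads at strides 8/16/32.
#
# The three ablation switches select the backbone (plain convolutional vs
# star-operation), the neck upsampler (nearest vs dynamic) and the fusion
# block family (baseline vs SCSA-augmented). Widths and per-site block
# configurations below are the package's calibrated nano scale.

#' Calibrated nano-scale architecture table
#'
#' Channel widths, depths and per-site fusion block configuration shared by
#' all ablation variants. Values are the package's fixed calibration of the
#' nano scale; the builds differ only by the three module swaps.
#' @return a list of architecture constants
#' @export
sda_arch <- function() {
  list(
    conv_widths = c(8L, 40L, 56L, 56L, 392L),
    conv_depths = c(1L, 3L),
    conv_site3 = list(mlp_ratio = 1.5, areas = 4L, attn = FALSE),
    star = list(stem = 8L, widths = c(40L, 64L, 64L, 200L),
                depths = c(1L, 2L, 1L, 3L)),
    neck = c(n3 = 56L, n4 = 80L, n5 = 128L),
    head_width = 24L,
    tail = list(mlp_ratio = 0.5, areas = 4L, attn = TRUE),
    sites = list(
      up1 = list(mlp_ratio = 1, areas = 4L, attn = TRUE),
      up2 = list(mlp_ratio = 0, areas = 8L, attn = FALSE),
      down1 = list(mlp_ratio = 1.5, areas = 1L, attn = FALSE),
      down2 = list(mlp_ratio = 1.5, areas = 1L, attn = FALSE)),
    dysample = list(scale = 2L, groups = 4L)
  )
}

#' Detector model specification
#'
#' @param backbone `"starnet"` or `"baseline_conv"`
#' @param upsampler `"dysample"` or `"nearest"`
#' @param fusion_block `"a2c2f_scsa"` or `"a2c2f"`
#' @param num_classes number of object classes (default 6 disease classes)
#' @param input_size square input size, divisible by 32
#' @param arch architecture table, see [sda_arch()]
#' @return object of class `model_spec`
#' @export
model_spec <- function(backbone = c("starnet", "baseline_conv"),
                       upsampler = c("dysample", "nearest"),
                       fusion_block = c("a2c2f_scsa", "a2c2f"),
                       num_classes = 6L, input_size = 640L,
                       arch = sda_arch()) {
  backbone <- match.arg(backbone)
  upsampler <- match.arg(upsampler)
  fusion_block <- match.arg(fusion_block)
  stopifnot(num_classes >= 1L, input_size %% 32L == 0L)
  structure(list(backbone = backbone, upsampler = upsampler,
                 fusion_block = fusion_block, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size), arch = arch),
            class = "model_spec")
}

#' The full three-swap build
#' @param ... passed to [model_spec()]
#' @export
yolo_sda_spec <- function(...) model_spec("starnet", "dysample", "a2c2f_scsa", ...)

#' The baseline build
#' @param ... passed to [model_spec()]
#' @export
baseline_spec <- function(...) model_spec("baseline_conv", "nearest", "a2c2f", ...)

.site_a2c2f <- function(ci, co, cfg, fusion) {
  a2c2f(a2c2f_spec(ci, co, variant = fusion, mlp_ratio = cfg$mlp_ratio,
                   areas = cfg$areas, attn = cfg$attn))
}

mod_backbone_conv <- function(arch, fusion) {
  w <- arch$conv_widths; d <- arch$conv_depths
  ch <- list(
    stem = mod_conv(3L, w[1], 3L, stride = 2L),
    c2 = mod_conv(w[1], w[2], 3L, stride = 2L),
    csp2 = mod_csp(w[2], w[2], d[1]),
    c3 = mod_conv(w[2], w[3], 3L, stride = 2L),
    site3 = .site_a2c2f(w[3], w[3], arch$conv_site3, fusion),
    c4 = mod_conv(w[3], w[4], 3L, stride = 2L),
    csp4 = mod_csp(w[4], w[4], d[2]),
    c5 = mod_conv(w[4], w[5], 3L, stride = 2L))
  new_module("backbone_conv", params = list(), children = ch, widths = w)
}

#' @export
sd_forward.sd_backbone_conv <- function(m, x, training = FALSE) {
  ch <- m$children
  y <- sd_forward(ch$stem, x, training)
  y <- sd_forward(ch$csp2, sd_forward(ch$c2, y, training), training)
  p3 <- sd_forward(ch$site3, sd_forward(ch$c3, y, training), training)
  p4 <- sd_forward(ch$csp4, sd_forward(ch$c4, p3, training), training)
  p5 <- sd_forward(ch$c5, p4, training)
  list(p8 = p3, p16 = p4, p32 = p5)
}

#' @export
sd_flops.sd_backbone_conv <- function(m, H, W) {
  ch <- m$children
  sd_flops(ch$stem, H, W) + sd_flops(ch$c2, H / 2, W / 2) +
    sd_flops(ch$csp2, H / 4, W / 4) + sd_flops(ch$c3, H / 4, W / 4) +
    sd_flops(ch$site3, H / 8, W / 8) + sd_flops(ch$c4, H / 8, W / 8) +
    sd_flops(ch$csp4, H / 16, W / 16) + sd_flops(ch$c5, H / 16, W / 16)
}

mod_head <- function(ci, hw, nc) {
  ch <- list(
    box1 = mod_conv(ci, hw, 3L), box2 = mod_conv(hw, hw, 3L),
    box3 = mod_conv(hw, 4L, 1L, act = "none", bn = FALSE, bias = TRUE),
    cls1 = mod_conv(ci, hw, 3L), cls2 = mod_conv(hw, hw, 3L),
    cls3 = mod_conv(hw, nc, 1L, act = "none", bn = FALSE, bias = TRUE))
  new_module("head", params = list(), children = ch, ci = ci, hw = hw, nc = nc)
}

#' @export
sd_forward.sd_head <- function(m, x, training = FALSE) {
  ch <- m$children
  b <- sd_forward(ch$box3, sd_forward(ch$box2, sd_forward(ch$box1, x, training),
                                      training), training)
  cl <- sd_forward(ch$cls3, sd_forward(ch$cls2, sd_forward(ch$cls1, x, training),
                                       training), training)
  list(box = b, cls = cl)
}

#' @export
sd_flops.sd_head <- function(m, H, W) {
  sum(vapply(m$children, sd_flops, numeric(1), H = H, W = W))
}

#' Assemble a detector from a model specification
#'
#' @param spec from [model_spec()]
#' @param seed optional integer; when given, weight initialisation is
#'   reproducible
#' @return an `sd_network` module
#' @export
assemble <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- spec$arch
  fusion <- spec$fusion_block
  if (spec$backbone == "starnet") {
    st <- arch$star
    bb <- star_backbone(star_backbone_spec(st$widths, st$depths, st$stem))
    E <- c(st$widths[2], st$widths[3], st$widths[4])
  } else {
    bb <- mod_backbone_conv(arch, fusion)
    E <- arch$conv_widths[3:5]
  }
  n <- arch$neck
  ch <- list(backbone = bb,
             tail = .site_a2c2f(E[3], E[3], arch$tail, fusion))
  if (spec$upsampler == "dysample") {
    ds <- arch$dysample
    ch$up1_s <- dysample(dysample_spec(E[3], ds$scale, ds$groups))
    ch$up2_s <- dysample(dysample_spec(n[["n4"]], ds$scale, ds$groups))
  }
  ch$fuse_up1 <- .site_a2c2f(E[3] + E[2], n[["n4"]], arch$sites$up1, fusion)
  ch$fuse_up2 <- .site_a2c2f(n[["n4"]] + E[1], n[["n3"]], arch$sites$up2, fusion)
  ch$down1 <- mod_conv(n[["n3"]], n[["n3"]], 3L, stride = 2L)
  ch$fuse_down1 <- .site_a2c2f(n[["n3"]] + n[["n4"]], n[["n4"]],
                               arch$sites$down1, fusion)
  ch$down2 <- mod_conv(n[["n4"]], n[["n4"]], 3L, stride = 2L)
  ch$fuse_down2 <- .site_a2c2f(n[["n4"]] + E[3], n[["n5"]],
                               arch$sites$down2, fusion)
  ch$head3 <- mod_head(n[["n3"]], arch$head_width, spec$num_classes)
  ch$head4 <- mod_head(n[["n4"]], arch$head_width, spec$num_classes)
  ch$head5 <- mod_head(n[["n5"]], arch$head_width, spec$num_classes)
  new_module("network", params = list(), children = ch, spec = spec)
}

#' Raw detection forward pass
#'
#' @param model from [assemble()]
#' @param x image batch (S, S, 3, N), S divisible by 32, values in `[0, 1]`
#' @param training logical; enables batch-statistic normalisation and tape
#'   compatibility
#' @return list of per-level outputs `p8`, `p16`, `p32`, each holding `box`
#'   (H,W,4,N) raw distances and `cls` (H,W,num_classes,N) logits
#' @export
forward_detect <- function(model, x, training = FALSE) {
  x <- as_fmap(x)
  d <- dim(vv(x))
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop(sprintf("input %dx%d must be divisible by 32", d[1], d[2]))
  }
  ch <- model$children
  pyr <- sd_forward(ch$backbone, x, training)
  t5 <- sd_forward(ch$tail, pyr$p32, training)
  up <- function(z, s) {
    if (!is.null(s)) sd_forward(s, z, training) else ad_upsample_nearest(z, 2L)
  }
  u1 <- up(t5, ch$up1_s)
  f4 <- sd_forward(ch$fuse_up1, ad_concat_c(list(u1, pyr$p16)), training)
  u2 <- up(f4, ch$up2_s)
  f3 <- sd_forward(ch$fuse_up2, ad_concat_c(list(u2, pyr$p8)), training)
  d1 <- sd_forward(ch$down1, f3, training)
  f4d <- sd_forward(ch$fuse_down1, ad_concat_c(list(d1, f4)), training)
  d2 <- sd_forward(ch$down2, f4d, training)
  f5d <- sd_forward(ch$fuse_down2, ad_concat_c(list(d2, t5)), training)
  list(p8 = sd_forward(ch$head3, f3, training),
       p16 = sd_forward(ch$head4, f4d, training),
       p32 = sd_forward(ch$head5, f5d, training))
}

#' @export
sd_flops.sd_network <- function(m, H, W) {
  ch <- m$children
  r <- function(s) c(H / s, W / s)
  at <- function(mod, s) {
    if (is.null(mod)) return(0)
    z <- r(s); sd_flops(mod, z[1], z[2])
  }
  at(ch$backbone, 1) + at(ch$tail, 32) +
    at(ch$up1_s, 32) + at(ch$fuse_up1, 16) +
    at(ch$up2_s, 16) + at(ch$fuse_up2, 8) +
    at(ch$down1, 8) + at(ch$fuse_down1, 16) +
    at(ch$down2, 16) + at(ch$fuse_down2, 32) +
    at(ch$head3, 8) + at(ch$head4, 16) + at(ch$head5, 32)
}

#' Parameter / FLOP / size accounting for a build
#'
#' Parameters are the exact count of learnable array elements. FLOPs use the
#' 2-FLOPs-per-multiply-accumulate convention over convolution, linear and
#' attention matmuls at the specification's input size (normalisation and
#' activations excluded). Serialized size assumes half-precision weights.
#'
#' @param spec a [model_spec()] (or an assembled model)
#' @return object of class `complexity_report` with fields `parameters`,
#'   `flops`, `serialized_bytes` plus the rounded `params_m` / `gflops`
#' @export
complexity <- function(spec) {
  model <- if (inherits(spec, "sd_module")) spec else assemble(spec, seed = 0L)
  sp <- model$spec
  S <- sp$input_size
  p <- module_n_params(model)
  f <- sd_flops(model, S, S)
  structure(list(parameters = p, flops = f,
                 serialized_bytes = 2 * p + 1024,
                 params_m = round(p / 1e6, 1), gflops = round(f / 1e9, 1),
                 input_size = S,
                 build = paste(sp$backbone, sp$upsampler, sp$fusion_block,
                               sep = " + ")),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("%s @ %d\n  parameters: %s (%.1f M)\n  FLOPs: %.1f G\n  size (fp16): %.1f MB\n",
              x$build, x$input_size, format(x$parameters, big.mark = ","),
              x$params_m, x$gflops, x$serialized_bytes / 2^20))
  invisible(x)
}

# ---- decoding and non-maximum suppression ----------------------------------

#' IoU matrix between two sets of xyxy boxes
#' @param a,b matrices with columns x1, y1, x2, y2
#' @return nrow(a) x nrow(b) matrix of IoU values
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  inter_w <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  inter_h <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- inter_w * inter_h
  area_a <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  area_b <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  un <- outer(area_a, area_b, `+`) - inter
  ifelse(un > 0, inter / un, 0)
}

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Decode raw head outputs and run greedy per-class NMS
#'
#' Box channels are non-negative distances (softplus of the raw values,
#' in stride units) from the cell centre to the four sides. Class scores
#' are sigmoid probabilities; a detection's score is its best class.
#'
#' @param raw output of [forward_detect()]
#' @param conf_threshold minimum class score in `[0, 1]`
#' @param iou_threshold suppression threshold in `[0, 1]`
#' @param image index of the image in the batch to decode
#' @return data frame with columns x1, y1, x2, y2, score, class_id, sorted
#'   by decreasing score; no surviving same-class pair overlaps more than
#'   `iou_threshold`
#' @export
decode_and_nms <- function(raw, conf_threshold = 0.25, iou_threshold = 0.45,
                           image = 1L) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1,
            iou_threshold >= 0, iou_threshold <= 1)
  dets <- list()
  for (lv in names(raw)) {
    stride <- as.integer(sub("p", "", lv))
    bx <- vv(raw[[lv]]$box); cl <- vv(raw[[lv]]$cls)
    d <- dim(bx)
    H <- d[1]; W <- d[2]; nc <- dim(cl)[3]
    cy <- (rep(seq_len(H), times = W) - 0.5) * stride
    cx <- (rep(seq_len(W), each = H) - 0.5) * stride
    dist <- matrix(.softplus(bx[, , , image]), H * W, 4) * stride
    logits <- matrix(cl[, , , image], H * W, nc)
    prob <- 1 / (1 + exp(-logits))
    best <- max.col(prob, ties.method = "first")
    score <- prob[cbind(seq_len(H * W), best)]
    keep <- score >= conf_threshold & conf_threshold < 1
    if (!any(keep)) next
    dets[[lv]] <- data.frame(
      x1 = (cx - dist[, 1])[keep], y1 = (cy - dist[, 2])[keep],
      x2 = (cx + dist[, 3])[keep], y2 = (cy + dist[, 4])[keep],
      score = score[keep], class_id = best[keep] - 1L)
  }
  if (!length(dets)) {
    return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), score = numeric(), class_id = integer()))
  }
  .nms_frame(do.call(rbind, dets), iou_threshold)
}

# greedy per-class suppression of a detection frame, sorted by score
.nms_frame <- function(all, iou_threshold) {
  all <- all[order(-all$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(all))
  bm <- as.matrix(all[, 1:4])
  for (i in seq_len(nrow(all))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(all)) > i & all$class_id == all$class_id[i])
    if (length(later)) {
      ious <- box_iou(bm[i, , drop = FALSE], bm[later, , drop = FALSE])
      keep[later[ious[1, ] > iou_threshold]] <- FALSE
    }
  }
  out <- all[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- checkpointing ---------------------------------------------------------

module_states <- function(m) {
  out <- list()
  if (!is.null(m$state)) out <- list(m$state)
  for (ch in m$children) out <- c(out, module_states(ch))
  out
}

#' Save model weights (plus the model spec as a JSON sidecar)
#' @param model assembled network
#' @param path checkpoint file path (`.rds`); spec is written to
#'   `paste0(path, ".json")`
#' @export
save_checkpoint <- function(model, path) {
  values <- lapply(module_params(model), vv)
  states <- lapply(module_states(model),
                   function(e) list(rm = e$running_mean, rv = e$running_var))
  sp <- model$spec
  saveRDS(list(spec = sp, values = values, states = states), path)
  jsonlite::write_json(
    list(backbone = sp$backbone, upsampler = sp$upsampler,
         fusion_block = sp$fusion_block, num_classes = sp$num_classes,
         input_size = sp$input_size),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file path
#' @return assembled network with restored weights and norm statistics
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- assemble(ck$spec, seed = 0L)
  ps <- module_params(model)
  stopifnot(length(ps) == length(ck$values))
  for (i in seq_along(ps)) ps[[i]]$value <- ck$values[[i]]
  ss <- module_states(model)
  for (i in seq_along(ss)) {
    ss[[i]]$running_mean <- ck$states[[i]]$rm
    ss[[i]]$running_var <- ck$states[[i]]$rv
  }
  model
}
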