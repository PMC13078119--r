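# Spatial-channel synergistic attention (SCSA) and the fusion block that
# embeds it. The spatial pathway pools the map along each spatial axis,
# runs multi-scale (3/5/7) 1-D depthwise convolutions on the two pooled
# sequences, group-normalises each axis response and combines the two axis
# logits additively before one sigmoid - so a constant input collapses to a
# gate of exactly 0.5 everywhere. The channel pathway forms single-token
# query/key/value descriptors from pooled, group-normalised features, takes
# a row-stochastic softmax attention map over channels, and gates the
# attended vector with a sigmoid weight from a kernel-9 1-D convolution
# along the channel axis.

# ---- small broadcasting ops used by the gates ------------------------------

# (H,1,C,N) + (1,W,C,N)-style axis logit combination
.ad_axis_combine <- function(lh, lw, H, W) {
  hv <- vv(lh); wv_ <- vv(lw)
  dC <- dim(hv)[2]; N <- dim(hv)[3]
  hb <- aperm(array(hv, dim = c(H, dC, N, W)), c(1, 4, 2, 3))
  wb <- aperm(array(wv_, dim = c(W, dC, N, H)), c(4, 1, 2, 3))
  .emit(hb + wb, function(g) {
    .acc(lh, apply(g, c(1, 3, 4), sum))
    .acc(lw, apply(g, c(2, 3, 4), sum))
  })
}

# broadcast a (C,N) vector to an (H,W,C,N) map
.ad_bcast_cn <- function(v, H, W) {
  mv <- vv(v)
  C <- nrow(mv); N <- ncol(mv)
  out <- array(rep(as.vector(mv), each = H * W), dim = c(H, W, C, N))
  .emit(out, function(g) {
    .acc(v, matrix(colSums(matrix(g, nrow = H * W)), C, N))
  })
}

# elementwise product of a (C,N) matrix with a length-C parameter vector
.ad_colvec_mul <- function(m, w) {
  mv <- vv(m); wv_ <- vv(w)
  .emit(mv * wv_, function(g) {
    .acc(m, g * wv_)
    .acc(w, rowSums(g * mv))
  })
}

.ad_colvec_add <- function(m, b) {
  mv <- vv(m)
  .emit(mv + vv(b), function(g) {
    .acc(m, g)
    .acc(b, rowSums(g))
  })
}

# elementwise ops on (C,N) matrices reuse the generic elementwise nodes

# ---- SCSA ------------------------------------------------------------------

#' SCSA specification
#'
#' @param channels feature channels C
#' @param spatial_kernels 1-D depthwise kernel sizes of the multi-scale
#'   spatial gate (default 3, 5, 7; all odd)
#' @param channel_branch_kernel kernel of the 1-D convolution along the
#'   channel axis in the channel gate (default 9)
#' @param groups_for_norm group-normalisation group count (must divide C)
#' @param temperature softmax temperature of the channel attention (the
#'   printed formulation has none, so the default is 1)
#' @param pooled_1x1 if TRUE, use the degenerate fully-pooled spatial gate
#'   (a per-channel scalar) instead of the per-axis sequences
#' @export
scsa_spec <- function(channels, spatial_kernels = c(3L, 5L, 7L),
                      channel_branch_kernel = 9L, groups_for_norm = 4L,
                      temperature = 1, pooled_1x1 = FALSE) {
  stopifnot(all(spatial_kernels %% 2 == 1), channel_branch_kernel %% 2 == 1)
  if (channels %% groups_for_norm != 0) {
    stop(sprintf("SCSA: %d channels not divisible by %d norm groups",
                 channels, groups_for_norm))
  }
  structure(list(channels = as.integer(channels),
                 spatial_kernels = as.integer(spatial_kernels),
                 channel_branch_kernel = as.integer(channel_branch_kernel),
                 groups_for_norm = as.integer(groups_for_norm),
                 temperature = temperature, pooled_1x1 = pooled_1x1),
            class = "scsa_spec")
}

#' Build an SCSA module
#' @param spec [scsa_spec()] object (or a channel count)
#' @export
scsa <- function(spec) {
  if (is.numeric(spec)) spec <- scsa_spec(spec)
  C <- spec$channels
  params <- list()
  for (ax in c("h", "w")) {
    for (k in spec$spatial_kernels) {
      params[[paste0("w", k, ax)]] <- ad_param(.winit(c(k, C), k))
      params[[paste0("b", k, ax)]] <- ad_param(numeric(C))
    }
    params[[paste0("gn_", ax, "_g")]] <- ad_param(rep(1, C))
    params[[paste0("gn_", ax, "_b")]] <- ad_param(numeric(C))
  }
  params$gn_q_g <- ad_param(rep(1, C)); params$gn_q_b <- ad_param(numeric(C))
  params$gn_kv_g <- ad_param(rep(1, C)); params$gn_kv_b <- ad_param(numeric(C))
  params$gn_c_g <- ad_param(rep(1, C)); params$gn_c_b <- ad_param(numeric(C))
  params$wk <- ad_param(rep(1, C)); params$bk <- ad_param(numeric(C))
  params$wv <- ad_param(rep(1, C)); params$bv <- ad_param(numeric(C))
  params$w9 <- ad_param(.winit(spec$channel_branch_kernel,
                               spec$channel_branch_kernel))
  params$b9 <- ad_param(0)
  new_module("scsa", params = params, children = list(), spec = spec)
}

.scsa_axis_logits <- function(m, pooled, ax) {
  spec <- m$spec
  acc <- NULL
  for (k in spec$spatial_kernels) {
    f <- ad_dwconv1d(pooled, m$params[[paste0("w", k, ax)]],
                     m$params[[paste0("b", k, ax)]])
    acc <- if (is.null(acc)) f else ad_add(acc, f)
  }
  d <- dim(vv(acc))
  acc4 <- ad_reshape(acc, c(d[1], 1L, d[2], d[3]))
  gn <- ad_groupnorm(acc4, m$params[[paste0("gn_", ax, "_g")]],
                     m$params[[paste0("gn_", ax, "_b")]],
                     groups = spec$groups_for_norm)
  ad_reshape(gn, d)
}

#' Spatial pathway of SCSA
#'
#' @param x feature map (H,W,C,N)
#' @param m module from [scsa()]
#' @return list with `x` (gated map) and `weights` (the spatial gate, same
#'   shape, entries strictly in (0,1))
#' @export
spatial_attention <- function(x, m) {
  x <- as_fmap(x)
  spec <- m$spec
  d <- dim(vv(x))
  if (d[3] != spec$channels) {
    stop(sprintf("SCSA expects %d channels, got %d", spec$channels, d[3]))
  }
  if (spec$pooled_1x1) {
    pooled <- ad_mean_hw(x)                       # (C,N)
    pooled3 <- ad_reshape(pooled, c(1L, d[3], d[4]))
    acc <- NULL
    for (k in spec$spatial_kernels) {
      f <- ad_dwconv1d(pooled3, m$params[[paste0("w", k, "h")]],
                       m$params[[paste0("b", k, "h")]])
      acc <- if (is.null(acc)) f else ad_add(acc, f)
    }
    acc4 <- ad_reshape(acc, c(1L, 1L, d[3], d[4]))
    gn <- ad_groupnorm(acc4, m$params$gn_h_g, m$params$gn_h_b,
                       groups = spec$groups_for_norm)
    ws <- ad_sigmoid(.ad_bcast_cn(ad_reshape(gn, c(d[3], d[4])), d[1], d[2]))
  } else {
    ph <- ad_mean_axis(x, "W")                    # (H,C,N)
    pw <- ad_mean_axis(x, "H")                    # (W,C,N)
    lh <- .scsa_axis_logits(m, ph, "h")
    lw <- .scsa_axis_logits(m, pw, "w")
    ws <- ad_sigmoid(.ad_axis_combine(lh, lw, d[1], d[2]))
  }
  list(x = ad_mul(x, ws), weights = ws)
}

#' Channel pathway of SCSA
#'
#' Query/key/value are pooled per-channel descriptors; the attention map is
#' row-stochastic over channels; the attended vector is gated by a sigmoid
#' weight and broadcast back over space.
#'
#' @inheritParams spatial_attention
#' @return list with `x` (the channel-pathway map), `weights` (the sigmoid
#'   channel gate, a C x N matrix) and `channel_map` (per-sample C x C
#'   row-stochastic attention matrices)
#' @export
channel_attention <- function(x, m) {
  x <- as_fmap(x)
  spec <- m$spec
  d <- dim(vv(x))
  if (d[3] != spec$channels) {
    stop(sprintf("SCSA expects %d channels, got %d", spec$channels, d[3]))
  }
  pooled <- ad_mean_hw(x)                          # (C,N)
  q <- ad_mean_hw(ad_groupnorm(x, m$params$gn_q_g, m$params$gn_q_b,
                               groups = spec$groups_for_norm))
  kv_base <- ad_groupnorm_vec(pooled, m$params$gn_kv_g, m$params$gn_kv_b,
                              groups = spec$groups_for_norm)
  k <- .ad_colvec_add(.ad_colvec_mul(kv_base, m$params$wk), m$params$bk)
  v <- .ad_colvec_add(.ad_colvec_mul(kv_base, m$params$wv), m$params$bv)
  att <- ad_channel_attention(q, k, v, temp = spec$temperature)
  cg <- ad_conv1d_channels(pooled, m$params$w9, m$params$b9)
  wc <- ad_sigmoid(ad_groupnorm_vec(cg, m$params$gn_c_g, m$params$gn_c_b,
                                    groups = spec$groups_for_norm))
  gated <- ad_mul(att, wc)
  amap <- channel_attention_matrix(vv(q), vv(k), spec$temperature)
  list(x = .ad_bcast_cn(gated, d[1], d[2]), weights = vv(wc), channel_map = amap)
}

#' Full SCSA forward pass: sum of the spatial and channel pathways
#' @inheritParams spatial_attention
#' @export
scsa_forward <- function(x, m) {
  x <- as_fmap(x)
  sp <- spatial_attention(x, m)
  ch <- channel_attention(x, m)
  ad_add(sp$x, ch$x)
}

#' @export
sd_forward.sd_scsa <- function(m, x, training = FALSE) scsa_forward(x, m)

#' @export
sd_flops.sd_scsa <- function(m, H, W) {
  C <- m$spec$channels
  # the 1-D convolutions on the pooled axis sequences and channel vector
  2 * sum(m$spec$spatial_kernels) * C * (H + W) +
    2 * m$spec$channel_branch_kernel * C +
    2 * 2 * C * C   # channel attention matmuls (QK^T and AV) on pooled tokens
}

# ---- area-attention branch unit (ABlock) and the SCSA variant --------------

mod_ablock <- function(h, mlp_ratio = 2, areas = 4L, attn = TRUE) {
  ch <- list()
  params <- list()
  if (attn) {
    ch$qkv <- mod_conv(h, 3L * h, 1L, act = "none", bn = FALSE, bias = TRUE)
    params$pe_w <- ad_param(.winit(c(7L, 7L, h), 49))
    params$pe_b <- ad_param(numeric(h))
    ch$proj <- mod_conv(h, h, 1L, act = "none", bn = FALSE, bias = TRUE)
    if (mlp_ratio > 0) {
      hm <- max(1L, round(mlp_ratio * h))
      ch$mlp1 <- mod_conv(h, hm, 1L, act = "silu")
      ch$mlp2 <- mod_conv(hm, h, 1L, act = "none")
    }
  } else {
    ch$b1 <- mod_conv(h, h, 3L)
    ch$b2 <- mod_conv(h, h, 3L)
  }
  new_module("ablock", params = params, children = ch, h = h,
             mlp_ratio = mlp_ratio, areas = as.integer(areas), attn = attn)
}

.ablock_attn <- function(m, x, training) {
  h <- m$h
  qkv <- sd_forward(m$children$qkv, x, training)
  q <- ad_slice_c(qkv, seq_len(h))
  k <- ad_slice_c(qkv, h + seq_len(h))
  v <- ad_slice_c(qkv, 2L * h + seq_len(h))
  att <- ad_area_attention(q, k, v, areas = m$areas)
  pe <- ad_dwconv2d(v, m$params$pe_w, b = m$params$pe_b)
  ad_add(x, sd_forward(m$children$proj, ad_add(att, pe), training))
}

#' @export
sd_forward.sd_ablock <- function(m, x, training = FALSE) {
  if (m$attn) {
    y <- .ablock_attn(m, x, training)
    if (m$mlp_ratio > 0) {
      y2 <- sd_forward(m$children$mlp2,
                       sd_forward(m$children$mlp1, y, training), training)
      y <- ad_add(y, y2)
    }
    y
  } else {
    z <- sd_forward(m$children$b2, sd_forward(m$children$b1, x, training), training)
    ad_add(x, z)
  }
}

#' @export
sd_flops.sd_ablock <- function(m, H, W) {
  h <- m$h
  if (m$attn) {
    f <- sd_flops(m$children$qkv, H, W) + 2 * 49 * h * H * W +
      sd_flops(m$children$proj, H, W) +
      4 * (H * W)^2 * h / effective_areas(H, m$areas)
    if (m$mlp_ratio > 0) {
      f <- f + sd_flops(m$children$mlp1, H, W) + sd_flops(m$children$mlp2, H, W)
    }
    f
  } else {
    sd_flops(m$children$b1, H, W) + sd_flops(m$children$b2, H, W)
  }
}

mod_ablock_scsa <- function(h, areas = 4L, attn = TRUE, norm_groups = 4L) {
  # SCSA embedded in the branch unit, preserving the site's unit family:
  # attention sites replace the MLP with SCSA + one 1x1 convolution;
  # bottleneck sites insert SCSA between their two 3x3 convolutions.
  if (attn) {
    ch <- list(
      qkv = mod_conv(h, 3L * h, 1L, act = "none", bn = FALSE, bias = TRUE),
      proj = mod_conv(h, h, 1L, act = "none", bn = FALSE, bias = TRUE),
      att = scsa(scsa_spec(h, groups_for_norm = norm_groups)),
      cv = mod_conv(h, h, 1L, act = "none"))
    params <- list(pe_w = ad_param(.winit(c(7L, 7L, h), 49)),
                   pe_b = ad_param(numeric(h)))
  } else {
    # SCSA supplies the spatial mixing, so the closing convolution is pointwise
    ch <- list(b1 = mod_conv(h, h, 3L),
               att = scsa(scsa_spec(h, groups_for_norm = norm_groups)),
               b2 = mod_conv(h, h, 1L))
    params <- list()
  }
  new_module("ablock_scsa", params = params, children = ch, h = h,
             areas = as.integer(areas), attn = attn, mlp_ratio = 0)
}

#' @export
sd_forward.sd_ablock_scsa <- function(m, x, training = FALSE) {
  if (m$attn) {
    y <- .ablock_attn(m, x, training)
    z <- scsa_forward(y, m$children$att)
    ad_add(y, sd_forward(m$children$cv, z, training))
  } else {
    z <- sd_forward(m$children$b1, x, training)
    z <- scsa_forward(z, m$children$att)
    ad_add(x, sd_forward(m$children$b2, z, training))
  }
}

#' @export
sd_flops.sd_ablock_scsa <- function(m, H, W) {
  h <- m$h
  if (m$attn) {
    sd_flops(m$children$qkv, H, W) + 2 * 49 * h * H * W +
      sd_flops(m$children$proj, H, W) +
      4 * (H * W)^2 * h / effective_areas(H, m$areas) +
      sd_flops(m$children$att, H, W) + sd_flops(m$children$cv, H, W)
  } else {
    sd_flops(m$children$b1, H, W) + sd_flops(m$children$att, H, W) +
      sd_flops(m$children$b2, H, W)
  }
}

# ---- fusion block (branch-concat-merge with learnable branch scaling) ------

#' Fusion block specification
#'
#' @param in_channels,out_channels block input/output widths
#' @param hidden_channels branch width (default `out_channels / 2`)
#' @param variant `"a2c2f"` (baseline branch units) or `"a2c2f_scsa"`
#' @param block_depth chained branch units per branch (default 2)
#' @param mlp_ratio baseline unit MLP expansion (0 disables the MLP)
#' @param areas area-attention partitions of the baseline units
#' @param attn unit family at this site: area attention (TRUE) or plain 3x3
#'   bottlenecks (FALSE); the SCSA variant embeds SCSA into the same family
#' @export
a2c2f_spec <- function(in_channels, out_channels,
                       hidden_channels = out_channels %/% 2L,
                       variant = c("a2c2f", "a2c2f_scsa"),
                       block_depth = 2L, mlp_ratio = 2, areas = 4L,
                       attn = TRUE) {
  variant <- match.arg(variant)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 hidden_channels = as.integer(hidden_channels),
                 variant = variant, block_depth = as.integer(block_depth),
                 mlp_ratio = mlp_ratio, areas = as.integer(areas), attn = attn),
            class = "a2c2f_spec")
}

#' Build a fusion block
#' @param spec from [a2c2f_spec()]
#' @export
a2c2f <- function(spec) {
  h <- spec$hidden_channels
  mku <- function() {
    if (spec$variant == "a2c2f_scsa") mod_ablock_scsa(h, spec$areas, spec$attn)
    else mod_ablock(h, spec$mlp_ratio, spec$areas, spec$attn)
  }
  ch <- list(cv1 = mod_conv(spec$in_channels, h, 1L))
  for (br in 1:2) for (u in seq_len(spec$block_depth)) {
    ch[[paste0("br", br, "_", u)]] <- mku()
  }
  ch$cat <- mod_conv(3L * h, spec$out_channels, 1L)
  ch$out <- mod_conv(spec$out_channels, spec$out_channels, 1L)
  new_module("a2c2f",
             params = list(scale2 = ad_param(1), scale3 = ad_param(1)),
             children = ch, spec = spec)
}

#' @export
sd_forward.sd_a2c2f <- function(m, x, training = FALSE) {
  spec <- m$spec
  x1 <- sd_forward(m$children$cv1, x, training)
  run_branch <- function(br) {
    y <- x1
    for (u in seq_len(spec$block_depth)) {
      y <- sd_forward(m$children[[paste0("br", br, "_", u)]], y, training)
    }
    y
  }
  x2 <- ad_mul(run_branch(1), m$params$scale2)
  x3 <- ad_mul(run_branch(2), m$params$scale3)
  xcat <- sd_forward(m$children$cat, ad_concat_c(list(x1, x2, x3)), training)
  sd_forward(m$children$out, xcat, training)
}

#' @export
sd_flops.sd_a2c2f <- function(m, H, W) {
  sum(vapply(m$children, sd_flops, numeric(1), H = H, W = W))
}

#' Forward pass through an SCSA-augmented fusion block
#'
#' @param x feature map (H,W,C,N)
#' @param m module from [a2c2f()] with variant `"a2c2f_scsa"`
#' @param training logical
#' @export
a2c2f_scsa_forward <- function(x, m, training = FALSE) {
  stopifnot(m$spec$variant == "a2c2f_scsa")
  x <- as_fmap(x)
  if (dim(vv(x))[3] != m$spec$in_channels) {
    stop(sprintf("fusion block expects %d channels, got %d",
                 m$spec$in_channels, dim(vv(x))[3]))
  }
  sd_forward(m, x, training)
}
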