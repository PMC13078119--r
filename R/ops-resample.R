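# Spatial resampling primitives: pooling, nearest upsampling, channel-to-space
# rearrangement (pixel shuffle) and bilinear grid sampling with gradients to
# both the source map and the sampling positions.

#' Global average pool: (H,W,C,N) -> (C,N)
#' @keywords internal
#' @noRd
ad_mean_hw <- function(x) {
  xv <- vv(x); d <- dim(xv)
  m <- d[1] * d[2]
  out <- matrix(colMeans(matrix(xv, nrow = m)), d[3], d[4])
  .emit(out, function(g) {
    .acc(x, array(rep(as.vector(g), each = m) / m, dim = d))
  })
}

#' Average over one spatial axis: axis = "W" gives (H,C,N), "H" gives (W,C,N)
#' @keywords internal
#' @noRd
ad_mean_axis <- function(x, axis = c("W", "H")) {
  axis <- match.arg(axis)
  xv <- vv(x); d <- dim(xv)
  if (axis == "W") {
    out <- apply(xv, c(1, 3, 4), mean)
    .emit(array(out, dim = d[c(1, 3, 4)]), function(g) {
      ge <- aperm(array(g, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
      .acc(x, ge / d[2])
    })
  } else {
    out <- apply(xv, c(2, 3, 4), mean)
    .emit(array(out, dim = d[c(2, 3, 4)]), function(g) {
      ge <- aperm(array(g, dim = c(d[2], d[3], d[4], d[1])), c(4, 1, 2, 3))
      .acc(x, ge / d[1])
    })
  }
}

#' Nearest-neighbour upsampling by integer factor s
#' @keywords internal
#' @noRd
ad_upsample_nearest <- function(x, s = 2L) {
  xv <- vv(x); d <- dim(xv)
  hi <- rep(seq_len(d[1]), each = s)
  wi <- rep(seq_len(d[2]), each = s)
  out <- xv[hi, wi, , , drop = FALSE]
  .emit(out, function(g) {
    # sum the s x s block of output gradients feeding each input pixel
    gm <- array(g, dim = c(s, d[1], s, d[2], d[3], d[4]))
    .acc(x, array(colSums(aperm(gm, c(1, 3, 2, 4, 5, 6)), dims = 2), dim = d))
  })
}

#' Channel-to-space rearrangement (pixel shuffle).
#'
#' Input (H, W, C*s^2, N) -> output (sH, sW, C, N) with
#' `out[s*i+di, s*j+dj, c] = in[i, j, (c-1)*s^2 + di*s + dj + 1]`
#' (0-based di, dj).
#' @keywords internal
#' @noRd
ad_pixel_shuffle <- function(x, s = 2L) {
  xv <- vv(x); d <- dim(xv)
  stopifnot(d[3] %% (s * s) == 0)
  C <- d[3] %/% (s * s)
  # (H, W, s2, C, N) with channel index = c*s^2 + di*s + dj -> dj fastest
  a <- array(xv, dim = c(d[1], d[2], s, s, C, d[4]))       # [h, w, dj, di, c, n]
  out <- aperm(a, c(4, 1, 3, 2, 5, 6))                      # [di, h, dj, w, c, n]
  out <- array(out, dim = c(s * d[1], s * d[2], C, d[4]))
  .emit(out, function(g) {
    gb <- array(g, dim = c(s, d[1], s, d[2], C, d[4]))
    ga <- aperm(gb, c(2, 4, 3, 1, 5, 6))                    # [h, w, dj, di, c, n]
    .acc(x, array(ga, dim = d))
  })
}

#' Bilinear sampling of an (H,W,C,N) map at arbitrary positions.
#'
#' `pos` is (sH, sW, 2g, N): for offset group k, channels use planes
#' (2k-1, 2k) as (row, col) source coordinates in 0-based pixel units.
#' Positions are clamped to the valid range (border padding), which keeps a
#' constant field exactly constant. Gradients flow to both x and pos.
#' @keywords internal
#' @noRd
ad_grid_sample <- function(x, pos, groups = 1L) {
  xv <- vv(x); pv <- vv(pos)
  d <- dim(xv); pd <- dim(pv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  sH <- pd[1]; sW <- pd[2]
  stopifnot(pd[3] == 2 * groups, C %% groups == 0)
  cpg <- C %/% groups
  out <- array(0, dim = c(sH, sW, C, N))
  M <- sH * sW * N
  # caches for backward
  cache <- vector("list", groups)
  for (k in seq_len(groups)) {
    py <- pmin(pmax(as.vector(pv[, , 2 * k - 1, , drop = FALSE]), 0), H - 1)
    px <- pmin(pmax(as.vector(pv[, , 2 * k, , drop = FALSE]), 0), W - 1)
    inside_y <- (as.vector(pv[, , 2 * k - 1, , drop = FALSE]) > 0) &
      (as.vector(pv[, , 2 * k - 1, , drop = FALSE]) < H - 1)
    inside_x <- (as.vector(pv[, , 2 * k, , drop = FALSE]) > 0) &
      (as.vector(pv[, , 2 * k, , drop = FALSE]) < W - 1)
    y0 <- floor(py); x0 <- floor(px)
    y0 <- pmin(y0, H - 2); x0 <- pmin(x0, W - 2)  # keep y0+1, x0+1 in range (H,W >= 2)
    fy <- py - y0; fx <- px - x0
    nn <- rep(0:(N - 1), each = sH * sW)
    chan <- (k - 1) * cpg + seq_len(cpg)
    # linear index helper into x for (y, x, c, n), 0-based y/x
    base00 <- y0 + H * x0 + H * W * C * nn
    base01 <- y0 + H * (x0 + 1) + H * W * C * nn
    base10 <- (y0 + 1) + H * x0 + H * W * C * nn
    base11 <- (y0 + 1) + H * (x0 + 1) + H * W * C * nn
    w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
    w10 <- fy * (1 - fx); w11 <- fy * fx
    coff <- H * W * (chan - 1)
    for (ci in seq_len(cpg)) {
      i00 <- base00 + coff[ci] + 1; i01 <- base01 + coff[ci] + 1
      i10 <- base10 + coff[ci] + 1; i11 <- base11 + coff[ci] + 1
      val <- w00 * xv[i00] + w01 * xv[i01] + w10 * xv[i10] + w11 * xv[i11]
      out[, , chan[ci], ] <- array(val, dim = c(sH, sW, 1, N))
      if (ci == 1) {
        cache[[k]] <- list(i00 = base00 + 1, i01 = base01 + 1, i10 = base10 + 1,
                           i11 = base11 + 1, coff = coff, chan = chan,
                           w00 = w00, w01 = w01, w10 = w10, w11 = w11,
                           fy = fy, fx = fx, inside_y = inside_y, inside_x = inside_x)
      }
    }
  }
  .emit(out, function(g) {
    need_x <- ad_is_node(x); need_p <- ad_is_node(pos)
    if (need_x) dx <- numeric(length(xv))
    if (need_p) dpos <- array(0, dim = pd)
    for (k in seq_len(groups)) {
      cc <- cache[[k]]
      gy_tot <- 0; gx_tot <- 0
      for (ci in seq_along(cc$chan)) {
        gch <- as.vector(g[, , cc$chan[ci], , drop = FALSE])
        off <- cc$coff[ci]
        if (need_x) {
          for (corner in list(list(cc$i00, cc$w00), list(cc$i01, cc$w01),
                              list(cc$i10, cc$w10), list(cc$i11, cc$w11))) {
            rs <- rowsum(gch * corner[[2]], group = corner[[1]] + off)
            ii <- as.integer(rownames(rs))
            dx[ii] <- dx[ii] + rs
          }
        }
        if (need_p) {
          v00 <- xv[cc$i00 + off]; v01 <- xv[cc$i01 + off]
          v10 <- xv[cc$i10 + off]; v11 <- xv[cc$i11 + off]
          dval_dfy <- (1 - cc$fx) * (v10 - v00) + cc$fx * (v11 - v01)
          dval_dfx <- (1 - cc$fy) * (v01 - v00) + cc$fy * (v11 - v10)
          gy_tot <- gy_tot + gch * dval_dfy
          gx_tot <- gx_tot + gch * dval_dfx
        }
      }
      if (need_p) {
        dpos[, , 2 * k - 1, ] <- array(gy_tot * cc$inside_y, dim = c(sH, sW, 1, N))
        dpos[, , 2 * k, ] <- array(gx_tot * cc$inside_x, dim = c(sH, sW, 1, N))
      }
    }
    if (need_x) .acc(x, array(dx, dim = d))
    if (need_p) .acc(pos, dpos)
  })
}
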