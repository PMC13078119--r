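# Convolution primitives on (H, W, C, N) arrays.
#
# Dense convolution goes through im2col + one BLAS matmul; depthwise
# convolution uses a shift-and-accumulate sweep over kernel offsets (49
# vectorised passes for a 7x7 kernel, no patch matrix). Index matrices for
# im2col are cached per (shape, kernel, stride, pad).

.conv_cache <- new.env(parent = emptyenv())

.pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

.unpad_hw <- function(x, p, H, W) {
  if (p == 0) return(x)
  x[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
}

.im2col_idx <- function(Hp, Wp, C, N, k, stride) {
  key <- paste(Hp, Wp, C, N, k, stride, sep = "_")
  got <- .conv_cache[[key]]
  if (!is.null(got)) return(got)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  dh <- rep(0:(k - 1), times = k * C)
  dw <- rep(rep(0:(k - 1), each = k), times = C)
  cc <- rep(0:(C - 1), each = k * k)
  rowpart <- dh + Hp * dw + Hp * Wp * cc                    # length k*k*C
  ho <- rep(0:(Ho - 1), times = Wo * N)
  wo <- rep(rep(0:(Wo - 1), each = Ho), times = N)
  nn <- rep(0:(N - 1), each = Ho * Wo)
  colpart <- ho * stride + Hp * wo * stride + Hp * Wp * C * nn
  idx <- outer(rowpart, colpart, "+") + 1L
  res <- list(idx = idx, Ho = Ho, Wo = Wo)
  .conv_cache[[key]] <- res
  res
}

#' Dense 2-D convolution.
#'
#' @param x (H,W,Ci,N) input (node or array)
#' @param w (k,k,Ci,Co) kernel
#' @param b optional length-Co bias
#' @param stride,pad integers; pad defaults to k %/% 2 ("same" for stride 1)
#' @keywords internal
#' @noRd
ad_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  xv <- vv(x); wv <- vv(w)
  d <- dim(xv); kd <- dim(wv)
  k <- kd[1]
  if (is.null(pad)) pad <- k %/% 2L
  if (d[3] != kd[3]) {
    stop(sprintf("conv2d channel mismatch: input has %d channels, kernel expects %d",
                 d[3], kd[3]))
  }
  if (d[1] + 2 * pad < k || d[2] + 2 * pad < k) {
    stop(sprintf("conv2d input %dx%d smaller than kernel %d after padding %d",
                 d[1], d[2], k, pad))
  }
  Co <- kd[4]
  xp <- .pad_hw(xv, pad)
  dp <- dim(xp)
  ii <- .im2col_idx(dp[1], dp[2], d[3], d[4], k, stride)
  K <- k * k * d[3]
  cols <- matrix(xp[as.vector(ii$idx)], K, ncol(ii$idx))
  wmat <- matrix(wv, K, Co)
  y <- crossprod(wmat, cols)                                # Co x M
  out <- aperm(array(t(y), dim = c(ii$Ho, ii$Wo, d[4], Co)), c(1, 2, 4, 3))
  bv <- if (is.null(b)) NULL else vv(b)
  if (!is.null(bv)) out <- out + rep(rep(bv, each = ii$Ho * ii$Wo), d[4])
  node <- .emit(out, function(g) {
    gmat <- t(matrix(aperm(g, c(1, 2, 4, 3)), ncol = Co))    # Co x M
    if (ad_is_node(w)) .acc(w, array(cols %*% t(gmat), dim = kd))
    if (!is.null(b) && ad_is_node(b)) .acc(b, rowSums(gmat))
    if (ad_is_node(x)) {
      dcols <- wmat %*% gmat                                 # K x M
      rs <- rowsum(as.vector(dcols), group = as.vector(ii$idx))
      dxp <- array(0, dim = dp)
      dxp[as.integer(rownames(rs))] <- rs
      .acc(x, .unpad_hw(dxp, pad, d[1], d[2]))
    }
  })
  node
}

#' Depthwise 2-D convolution (one k x k filter per channel), stride 1.
#'
#' @param x (H,W,C,N); @param w (k,k,C); @param b optional length-C bias
#' @keywords internal
#' @noRd
ad_dwconv2d <- function(x, w, b = NULL, pad = NULL) {
  xv <- vv(x); wv <- vv(w)
  d <- dim(xv); k <- dim(wv)[1]
  if (is.null(pad)) pad <- k %/% 2L
  stopifnot(dim(wv)[3] == d[3])
  xp <- .pad_hw(xv, pad)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  out <- array(0, dim = d)
  for (dh in seq_len(k)) for (dw in seq_len(k)) {
    sl <- xp[dh:(dh + H - 1), dw:(dw + W - 1), , , drop = FALSE]
    wc <- rep(rep(wv[dh, dw, ], each = H * W), N)
    out <- out + sl * wc
  }
  if (!is.null(b)) out <- out + rep(rep(vv(b), each = H * W), N)
  .emit(out, function(g) {
    if (!is.null(b) && ad_is_node(b)) {
      .acc(b, colSums(matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)))
    }
    need_x <- ad_is_node(x); need_w <- ad_is_node(w)
    if (need_x) dxp <- array(0, dim = dim(xp))
    if (need_w) dwv <- array(0, dim = dim(wv))
    for (dh in seq_len(k)) for (dw in seq_len(k)) {
      if (need_w) {
        sl <- xp[dh:(dh + H - 1), dw:(dw + W - 1), , , drop = FALSE]
        dwv[dh, dw, ] <- colSums(matrix(aperm(g * sl, c(1, 2, 4, 3)), ncol = C))
      }
      if (need_x) {
        wc <- rep(rep(wv[dh, dw, ], each = H * W), N)
        dxp[dh:(dh + H - 1), dw:(dw + W - 1), , ] <-
          dxp[dh:(dh + H - 1), dw:(dw + W - 1), , , drop = FALSE] + g * wc
      }
    }
    if (need_w) .acc(w, dwv)
    if (need_x) .acc(x, .unpad_hw(dxp, pad, H, W))
  })
}

#' Depthwise 1-D convolution along the first axis of an (L, C, N) array.
#' "Same" length with replicate (edge) padding - a constant sequence maps to
#' a constant sequence, which the attention-gate invariants rely on.
#' @keywords internal
#' @noRd
ad_dwconv1d <- function(x, w, b = NULL) {
  xv <- vv(x); wv <- vv(w)
  d <- dim(xv); k <- dim(wv)[1]; p <- k %/% 2L
  stopifnot(dim(wv)[2] == d[2])
  L <- d[1]; C <- d[2]; N <- d[3]
  src <- lapply(seq_len(k), function(dk) pmin(pmax(seq_len(L) + dk - 1L - p, 1L), L))
  out <- array(0, dim = d)
  for (dk in seq_len(k)) {
    out <- out + xv[src[[dk]], , , drop = FALSE] * rep(rep(wv[dk, ], each = L), N)
  }
  if (!is.null(b)) out <- out + rep(rep(vv(b), each = L), N)
  .emit(out, function(g) {
    if (!is.null(b) && ad_is_node(b)) .acc(b, colSums(matrix(aperm(g, c(1, 3, 2)), ncol = C)))
    need_x <- ad_is_node(x); need_w <- ad_is_node(w)
    if (need_x) dx <- array(0, dim = d)
    if (need_w) dwv <- array(0, dim = dim(wv))
    for (dk in seq_len(k)) {
      sl <- xv[src[[dk]], , , drop = FALSE]
      if (need_w) dwv[dk, ] <- colSums(matrix(aperm(g * sl, c(1, 3, 2)), ncol = C))
      if (need_x) {
        tmp <- g * rep(rep(wv[dk, ], each = L), N)
        for (i in seq_len(L)) {
          dx[src[[dk]][i], , ] <- dx[src[[dk]][i], , , drop = FALSE] +
            tmp[i, , , drop = FALSE]
        }
      }
    }
    if (need_w) .acc(w, dwv)
    if (need_x) .acc(x, dx)
  })
}

#' 1-D convolution along the channel axis of a pooled (C, N) matrix,
#' single in/out channel, kernel k, replicate (edge) padding.
#' Used by the channel branch of the synergistic attention gate.
#' @keywords internal
#' @noRd
ad_conv1d_channels <- function(x, w, b = NULL) {
  xv <- vv(x); wv <- vv(w)
  C <- nrow(xv); N <- ncol(xv); k <- length(wv); p <- k %/% 2L
  src <- lapply(seq_len(k), function(dk) pmin(pmax(seq_len(C) + dk - 1L - p, 1L), C))
  out <- matrix(0, C, N)
  for (dk in seq_len(k)) out <- out + wv[dk] * xv[src[[dk]], , drop = FALSE]
  if (!is.null(b)) out <- out + vv(b)
  .emit(out, function(g) {
    if (!is.null(b) && ad_is_node(b)) .acc(b, sum(g))
    if (ad_is_node(w)) {
      gw <- vapply(seq_len(k), function(dk) sum(g * xv[src[[dk]], , drop = FALSE]),
                   numeric(1))
      .acc(w, gw)
    }
    if (ad_is_node(x)) {
      dx <- matrix(0, C, N)
      for (dk in seq_len(k)) {
        for (i in seq_len(C)) dx[src[[dk]][i], ] <- dx[src[[dk]][i], ] + wv[dk] * g[i, ]
      }
      .acc(x, dx)
    }
  })
}
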