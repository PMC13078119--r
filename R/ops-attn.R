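# Fused attention primitives with hand-derived backward passes.

#' Largest divisor of H not exceeding the configured area count
#' @keywords internal
#' @noRd
effective_areas <- function(H, areas) {
  a <- min(areas, H)
  while (H %% a != 0) a <- a - 1L
  a
}

.softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Area (regional) self-attention over an (H,W,d,N) map, single head.
#'
#' The map is partitioned into `areas` horizontal strips; attention is
#' computed independently within each strip with logits scaled by
#' 1/sqrt(d). Tokens are the strip's spatial positions.
#' @keywords internal
#' @noRd
ad_area_attention <- function(q, k, v, areas = 4L) {
  qv <- vv(q); kv <- vv(k); velo <- vv(v)
  d <- dim(qv)
  H <- d[1]; W <- d[2]; dh <- d[3]; N <- d[4]
  areas <- effective_areas(H, areas)
  hs <- H %/% areas
  t_ <- hs * W
  scale <- 1 / sqrt(dh)
  out <- array(0, dim = d)
  Acache <- vector("list", N * areas)
  for (n in seq_len(N)) for (a in seq_len(areas)) {
    rows <- (a - 1) * hs + seq_len(hs)
    Q <- matrix(qv[rows, , , n], t_, dh)
    K <- matrix(kv[rows, , , n], t_, dh)
    V <- matrix(velo[rows, , , n], t_, dh)
    A <- .softmax_rows(tcrossprod(Q, K) * scale)
    out[rows, , , n] <- array(A %*% V, dim = c(hs, W, dh))
    Acache[[(n - 1) * areas + a]] <- A
  }
  .emit(out, function(g) {
    need_q <- ad_is_node(q); need_k <- ad_is_node(k); need_v <- ad_is_node(v)
    dq <- if (need_q) array(0, dim = d)
    dk <- if (need_k) array(0, dim = d)
    dv <- if (need_v) array(0, dim = d)
    for (n in seq_len(N)) for (a in seq_len(areas)) {
      rows <- (a - 1) * hs + seq_len(hs)
      A <- Acache[[(n - 1) * areas + a]]
      dO <- matrix(g[rows, , , n], t_, dh)
      V <- matrix(velo[rows, , , n], t_, dh)
      if (need_v) dv[rows, , , n] <- array(crossprod(A, dO), dim = c(hs, W, dh))
      if (need_q || need_k) {
        dA <- tcrossprod(dO, V)
        dS <- A * (dA - rowSums(A * dA)) * scale
        if (need_q) {
          K <- matrix(kv[rows, , , n], t_, dh)
          dq[rows, , , n] <- array(dS %*% K, dim = c(hs, W, dh))
        }
        if (need_k) {
          Q <- matrix(qv[rows, , , n], t_, dh)
          dk[rows, , , n] <- array(crossprod(dS, Q), dim = c(hs, W, dh))
        }
      }
    }
    if (need_q) .acc(q, dq)
    if (need_k) .acc(k, dk)
    if (need_v) .acc(v, dv)
  })
}

#' Channel self-attention on pooled (C, N) descriptors.
#'
#' Per sample: A = softmax_rows(q k^T / temp), out = A v. Rows of A sum to 1.
#' @keywords internal
#' @noRd
ad_channel_attention <- function(q, k, v, temp = 1) {
  qv <- vv(q); kv <- vv(k); velo <- vv(v)
  C <- nrow(qv); N <- ncol(qv)
  out <- matrix(0, C, N)
  Acache <- vector("list", N)
  for (n in seq_len(N)) {
    A <- .softmax_rows(tcrossprod(qv[, n], kv[, n]) / temp)
    out[, n] <- A %*% velo[, n]
    Acache[[n]] <- A
  }
  .emit(out, function(g) {
    need_q <- ad_is_node(q); need_k <- ad_is_node(k); need_v <- ad_is_node(v)
    dq <- if (need_q) matrix(0, C, N)
    dk <- if (need_k) matrix(0, C, N)
    dv <- if (need_v) matrix(0, C, N)
    for (n in seq_len(N)) {
      A <- Acache[[n]]
      if (need_v) dv[, n] <- crossprod(A, g[, n])
      if (need_q || need_k) {
        dA <- tcrossprod(g[, n], velo[, n])
        dS <- A * (dA - rowSums(A * dA)) / temp
        if (need_q) dq[, n] <- dS %*% kv[, n]
        if (need_k) dk[, n] <- crossprod(dS, qv[, n])
      }
    }
    if (need_q) .acc(q, dq)
    if (need_k) .acc(k, dk)
    if (need_v) .acc(v, dv)
  })
}

#' Row-stochastic channel-attention matrices for inspection (no gradient).
#' @keywords internal
#' @noRd
channel_attention_matrix <- function(qv, kv, temp = 1) {
  N <- ncol(qv)
  lapply(seq_len(N), function(n) .softmax_rows(tcrossprod(qv[, n], kv[, n]) / temp))
}
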