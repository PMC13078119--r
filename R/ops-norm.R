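# Batch and group normalization with full training-mode backward passes.

#' Batch normalization over (H, W, N) per channel.
#'
#' `state` is an environment holding running_mean / running_var, updated in
#' training mode with the given momentum; eval mode normalises by the running
#' statistics (biased variance convention, matching the forward pass used at
#' train time).
#' @keywords internal
#' @noRd
ad_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- vv(x); gv <- vv(gamma); bv <- vv(beta)
  d <- dim(xv); C <- d[3]; m <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(xv, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  ym <- sweep(sweep(xhat, 2, gv, `*`), 2, bv, `+`)
  out <- aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  .emit(out, function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    if (ad_is_node(gamma)) .acc(gamma, colSums(gm * xhat))
    if (ad_is_node(beta)) .acc(beta, colSums(gm))
    if (ad_is_node(x)) {
      if (training) {
        gh <- sweep(gm, 2, gv, `*`)
        t1 <- sweep(gh, 2, colMeans(gh))
        t2 <- sweep(xhat, 2, colMeans(gh * xhat), `*`)
        dxm <- sweep(t1 - t2, 2, istd, `*`)
      } else {
        dxm <- sweep(sweep(gm, 2, gv, `*`), 2, istd, `*`)
      }
      .acc(x, aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)))
    }
  })
}

#' Group normalization of an (H,W,C,N) map: per sample, per channel group.
#' @keywords internal
#' @noRd
ad_groupnorm <- function(x, gamma, beta, groups = 4L, eps = 1e-5) {
  xv <- vv(x); gv <- vv(gamma); bv <- vv(beta)
  d <- dim(xv); C <- d[3]; N <- d[4]
  if (C %% groups != 0) {
    stop(sprintf("group norm: %d channels not divisible by %d groups", C, groups))
  }
  cg <- C %/% groups
  m <- d[1] * d[2] * cg
  # columns = (group, sample)
  xg <- matrix(xv, nrow = m)
  mu <- colMeans(xg)
  va <- colMeans(xg * xg) - mu * mu
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xg, 2, mu), 2, istd, `*`)
  xha <- array(xhat, dim = d)
  out <- xha * rep(rep(gv, each = d[1] * d[2]), N) + rep(rep(bv, each = d[1] * d[2]), N)
  .emit(out, function(g) {
    if (ad_is_node(gamma)) .acc(gamma, colSums(matrix(aperm(g * xha, c(1, 2, 4, 3)), ncol = C)))
    if (ad_is_node(beta)) .acc(beta, colSums(matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)))
    if (ad_is_node(x)) {
      gh <- matrix(g * rep(rep(gv, each = d[1] * d[2]), N), nrow = m)
      t1 <- sweep(gh, 2, colMeans(gh))
      t2 <- sweep(xhat, 2, colMeans(gh * xhat), `*`)
      .acc(x, array(sweep(t1 - t2, 2, istd, `*`), dim = d))
    }
  })
}

#' Group normalization of a pooled (C, N) matrix (spatial extent collapsed).
#' @keywords internal
#' @noRd
ad_groupnorm_vec <- function(x, gamma, beta, groups = 4L, eps = 1e-5) {
  xv <- vv(x); gv <- vv(gamma); bv <- vv(beta)
  C <- nrow(xv); N <- ncol(xv)
  if (C %% groups != 0) {
    stop(sprintf("group norm: %d channels not divisible by %d groups", C, groups))
  }
  cg <- C %/% groups
  xg <- matrix(xv, nrow = cg)
  mu <- colMeans(xg)
  va <- colMeans(xg * xg) - mu * mu
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xg, 2, mu), 2, istd, `*`)
  xhm <- matrix(xhat, C, N)
  out <- xhm * gv + bv
  .emit(out, function(g) {
    if (ad_is_node(gamma)) .acc(gamma, rowSums(g * xhm))
    if (ad_is_node(beta)) .acc(beta, rowSums(g))
    if (ad_is_node(x)) {
      gh <- matrix(g * gv, nrow = cg)
      t1 <- sweep(gh, 2, colMeans(gh))
      t2 <- sweep(xhat, 2, colMeans(gh * xhat), `*`)
      .acc(x, matrix(sweep(t1 - t2, 2, istd, `*`), C, N))
    }
  })
}
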