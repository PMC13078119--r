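# Synergistic attention: gate collapse on constant inputs, sigmoid bounds,
# row-stochastic channel attention with closed-form softmax checks, additive
# pathway decomposition, and a loop-based two-pathway oracle.

test_that("spatial gate is exactly 0.5 on constant input, so Xs = x/2", {
  m <- scsa(scsa_spec(4L))
  x <- array(2.5, dim = c(4, 4, 4, 2))
  sp <- spatial_attention(x, m)
  expect_equal(as.vector(vv(sp$weights)), rep(0.5, length(x)), tolerance = 1e-7)
  expect_equal(vv(sp$x), x * 0.5, tolerance = 1e-7)
  # channel gate likewise collapses to 0.5 on a constant field
  ch <- channel_attention(x, m)
  expect_equal(as.vector(ch$weights), rep(0.5, 8), tolerance = 1e-7)
})

test_that("spatial gate entries are strictly inside (0, 1) for random inputs", {
  set.seed(41)
  m <- scsa(scsa_spec(8L))
  sp <- spatial_attention(rmap(6, 5, 8, 2), m)
  w <- vv(sp$weights)
  expect_true(all(w > 0 & w < 1))
  expect_equal(dim(w), c(6L, 5L, 8L, 2L))
  # the degenerate fully-pooled variant is also available
  m1 <- scsa(scsa_spec(8L, pooled_1x1 = TRUE))
  sp1 <- spatial_attention(rmap(6, 5, 8, 1), m1)
  expect_equal(dim(vv(sp1$x)), c(6L, 5L, 8L, 1L))
})

test_that("channel attention rows sum to one; C = 1 attends V exactly", {
  set.seed(42)
  m <- scsa(scsa_spec(8L))
  ch <- channel_attention(rmap(4, 4, 8, 3), m)
  for (A in ch$channel_map) {
    expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-6)
  }
  # C = 1: softmax of a 1x1 matrix is [[1]]
  A1 <- channel_attention_matrix(matrix(0.7, 1, 1), matrix(-1.3, 1, 1))[[1]]
  expect_identical(A1, matrix(1, 1, 1))
})

test_that("hand-set q and k reproduce closed-form softmax rows", {
  # q = (1, 0), k = (0, ln 3): row 1 = softmax(0, ln3) = (0.25, 0.75),
  # row 2 = softmax(0, 0) = (0.5, 0.5)
  A <- channel_attention_matrix(matrix(c(1, 0), 2, 1),
                                matrix(c(0, log(3)), 2, 1))[[1]]
  expect_equal(A[1, ], c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(A[2, ], c(0.5, 0.5), tolerance = 1e-12)
})

test_that("zeroing the value projection removes the channel pathway", {
  set.seed(43)
  m <- scsa(scsa_spec(4L))
  m$params$wv$value <- numeric(4)
  m$params$bv$value <- numeric(4)
  x <- rmap(5, 5, 4, 1)
  full <- vv(scsa_forward(x, m))
  xs_only <- vv(spatial_attention(x, m)$x)
  expect_equal(full, xs_only, tolerance = 1e-12)
})

test_that("scsa_forward matches an independent loop oracle on a tiny input", {
  set.seed(44)
  C <- 4L; H <- 4L; W <- 4L
  m <- scsa(scsa_spec(C))
  # randomise every parameter so the oracle exercises all terms
  for (p in module_params(m)) p$value <- p$value + rnorm(length(p$value), 0, 0.3)
  x <- rmap(H, W, C, 1)
  got <- vv(scsa_forward(x, m))

  gn_vec <- function(v, gamma, beta, groups = 4L, eps = 1e-5) {
    cg <- length(v) / groups
    out <- numeric(length(v))
    for (g in seq_len(groups)) {
      idx <- (g - 1) * cg + seq_len(cg)
      mu <- mean(v[idx]); va <- mean(v[idx]^2) - mu^2
      out[idx] <- (v[idx] - mu) / sqrt(va + eps)
    }
    out * gamma + beta
  }
  dw1d <- function(seqm, w, b) {
    # seqm: L x C; w: k x C; replicate-padded borders
    L <- nrow(seqm); k <- nrow(w); p <- k %/% 2
    out <- matrix(0, L, ncol(seqm))
    for (c in seq_len(ncol(seqm))) for (i in seq_len(L)) {
      acc <- b[c]
      for (dk in seq_len(k)) {
        src <- min(max(i + dk - 1 - p, 1), L)
        acc <- acc + w[dk, c] * seqm[src, c]
      }
      out[i, c] <- acc
    }
    out
  }
  P <- function(nm) vv(m$params[[nm]])
  # spatial pathway
  ph <- t(sapply(seq_len(H), function(i) sapply(seq_len(C), function(c) mean(x[i, , c, 1]))))
  pw <- t(sapply(seq_len(W), function(j) sapply(seq_len(C), function(c) mean(x[, j, c, 1]))))
  lh <- dw1d(ph, P("w3h"), P("b3h")) + dw1d(ph, P("w5h"), P("b5h")) +
    dw1d(ph, P("w7h"), P("b7h"))
  lw <- dw1d(pw, P("w3w"), P("b3w")) + dw1d(pw, P("w5w"), P("b5w")) +
    dw1d(pw, P("w7w"), P("b7w"))
  # group norm over (H x group-channels) per group: flatten column-major
  gn_seq <- function(l, gamma, beta, groups = 4L, eps = 1e-5) {
    L <- nrow(l); C <- ncol(l); cg <- C / groups
    out <- l
    for (g in seq_len(groups)) {
      idx <- (g - 1) * cg + seq_len(cg)
      v <- as.vector(l[, idx])
      mu <- mean(v); va <- mean(v^2) - mu^2
      out[, idx] <- (l[, idx] - mu) / sqrt(va + eps)
    }
    sweep(sweep(out, 2, gamma, `*`), 2, beta, `+`)
  }
  lh <- gn_seq(lh, P("gn_h_g"), P("gn_h_b"))
  lw <- gn_seq(lw, P("gn_w_g"), P("gn_w_b"))
  ws <- array(0, dim = c(H, W, C))
  for (i in seq_len(H)) for (j in seq_len(W)) for (c in seq_len(C)) {
    ws[i, j, c] <- 1 / (1 + exp(-(lh[i, c] + lw[j, c])))
  }
  xs <- x[, , , 1] * ws
  # channel pathway
  pooled <- sapply(seq_len(C), function(c) mean(x[, , c, 1]))
  # q: group norm of the full map, then pooled
  xg <- x[, , , 1]
  qmap <- array(0, dim = dim(xg))
  cg <- C / 4
  for (g in seq_len(4)) {
    idx <- (g - 1) * cg + seq_len(cg)
    v <- as.vector(xg[, , idx])
    mu <- mean(v); va <- mean(v^2) - mu^2
    qmap[, , idx] <- (xg[, , idx] - mu) / sqrt(va + 1e-5)
  }
  for (c in seq_len(C)) qmap[, , c] <- qmap[, , c] * P("gn_q_g")[c] + P("gn_q_b")[c]
  q <- sapply(seq_len(C), function(c) mean(qmap[, , c]))
  kvb <- gn_vec(pooled, P("gn_kv_g"), P("gn_kv_b"))
  kk <- kvb * P("wk") + P("bk")
  vvv <- kvb * P("wv") + P("bv")
  S <- outer(q, kk)
  A <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  attn <- as.vector(A %*% vvv)
  # channel gate: kernel-9 conv along the channel axis of the pooled vector
  w9 <- P("w9"); b9 <- P("b9"); k9 <- length(w9); p9 <- k9 %/% 2
  cgate <- numeric(C)
  for (i in seq_len(C)) {
    acc <- b9
    for (dk in seq_len(k9)) {
      src <- min(max(i + dk - 1 - p9, 1), C)
      acc <- acc + w9[dk] * pooled[src]
    }
    cgate[i] <- acc
  }
  wc <- 1 / (1 + exp(-gn_vec(cgate, P("gn_c_g"), P("gn_c_b"))))
  ref <- xs
  for (c in seq_len(C)) ref[, , c] <- ref[, , c] + attn[c] * wc[c]
  expect_equal(got[, , , 1], ref, tolerance = 1e-5)
})

test_that("fusion blocks preserve spatial dims and batch equivariance", {
  set.seed(45)
  for (variant in c("a2c2f", "a2c2f_scsa")) {
    blk <- a2c2f(a2c2f_spec(8L, 8L, variant = variant))
    x <- rmap(8, 8, 8, 2)
    y <- vv(sd_forward(blk, x))
    expect_equal(dim(y), c(8L, 8L, 8L, 2L))
    # permuting batch entries permutes outputs identically
    xp <- x[, , , c(2, 1), drop = FALSE]
    yp <- vv(sd_forward(blk, xp))
    expect_equal(yp, y[, , , c(2, 1), drop = FALSE], tolerance = 1e-10)
  }
})

test_that("a2c2f_scsa_forward validates channels and changes width correctly", {
  blk <- a2c2f(a2c2f_spec(8L, 16L, variant = "a2c2f_scsa"))
  y <- a2c2f_scsa_forward(rmap(4, 4, 8), blk)
  expect_equal(dim(vv(y)), c(4L, 4L, 16L, 1L))
  expect_error(a2c2f_scsa_forward(rmap(4, 4, 4), blk), "expects 8 channels")
})

test_that("toy fusion block parameter count equals manual enumeration", {
  blk <- a2c2f(a2c2f_spec(8L, 8L, variant = "a2c2f", block_depth = 2L,
                          mlp_ratio = 2, attn = TRUE))
  h <- 4L
  convbn <- function(ci, co, k = 1) k * k * ci * co + 2 * co
  ablock <- (3 * h * h + 3 * h) +      # qkv conv with bias
    (49 * h + h) +                     # 7x7 depthwise positional conv
    (h * h + h) +                      # projection conv
    convbn(h, 2 * h) + convbn(2 * h, h)  # MLP at ratio 2
  manual <- convbn(8, h) + 4 * ablock + convbn(3 * h, 8) + convbn(8, 8) + 2
  expect_identical(module_n_params(blk), manual)
})
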