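# Independent reference implementations used as oracles: nested-loop
# convolutions, scalar star-operation arithmetic, per-pixel bilinear
# resampling, O(n^2) greedy NMS, and exhaustive PR-curve integration.
# Written as plain loops, independent of the package's vectorised paths.

oracle_conv2d <- function(x, w, b = NULL, stride = 1, pad = NULL) {
  # x: (H,W,Ci,N); w: (k,k,Ci,Co)
  d <- dim(x); kd <- dim(w); k <- kd[1]
  if (is.null(pad)) pad <- k %/% 2
  Hp <- d[1] + 2 * pad; Wp <- d[2] + 2 * pad
  xp <- array(0, dim = c(Hp, Wp, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  Ho <- (Hp - k) %/% stride + 1; Wo <- (Wp - k) %/% stride + 1
  out <- array(0, dim = c(Ho, Wo, kd[4], d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(kd[4])) {
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(d[3])) for (dy in seq_len(k)) for (dx in seq_len(k)) {
        acc <- acc + w[dy, dx, ci, co] *
          xp[(i - 1) * stride + dy, (j - 1) * stride + dx, ci, n]
      }
      out[i, j, co, n] <- acc
    }
  }
  out
}

oracle_dwconv2d <- function(x, w, b = NULL) {
  d <- dim(x); k <- dim(w)[1]; pad <- k %/% 2
  xp <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out <- array(0, dim = d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- if (is.null(b)) 0 else b[c]
      for (dy in seq_len(k)) for (dx in seq_len(k)) {
        acc <- acc + w[dy, dx, c] * xp[i + dy - 1, j + dx - 1, c, n]
      }
      out[i, j, c, n] <- acc
    }
  }
  out
}

# star block per Eqs: dw7x7 branch times (1x1 pointwise + bias), plus residual
oracle_star_block <- function(x, dw, fc, fb) {
  xdw <- oracle_dwconv2d(x, dw)
  d <- dim(x)
  xfc <- array(0, dim = d)
  for (n in seq_len(d[4])) for (co in seq_len(d[3])) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- fb[co]
      for (ci in seq_len(d[3])) acc <- acc + fc[1, 1, ci, co] * x[i, j, ci, n]
      xfc[i, j, co, n] <- acc
    }
  }
  xdw * xfc + x
}

# bilinear x s resize with the half-pixel grid convention, border clamped
oracle_bilinear_resize <- function(x, s) {
  d <- dim(x)
  out <- array(0, dim = c(s * d[1], s * d[2], d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (i in seq_len(s * d[1])) for (j in seq_len(s * d[2])) {
      sy <- min(max((i - 0.5) / s - 0.5, 0), d[1] - 1)
      sx <- min(max((j - 0.5) / s - 0.5, 0), d[2] - 1)
      y0 <- min(floor(sy), d[1] - 2); x0 <- min(floor(sx), d[2] - 2)
      fy <- sy - y0; fx <- sx - x0
      out[i, j, c, n] <-
        (1 - fy) * (1 - fx) * x[y0 + 1, x0 + 1, c, n] +
        (1 - fy) * fx * x[y0 + 1, x0 + 2, c, n] +
        fy * (1 - fx) * x[y0 + 2, x0 + 1, c, n] +
        fy * fx * x[y0 + 2, x0 + 2, c, n]
    }
  }
  out
}

oracle_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un > 0) inter / un else 0
}

oracle_nms <- function(df, iou_threshold) {
  df <- df[order(-df$score), , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in seq_len(i - 1)) {
      if (keep[j] && df$class_id[j] == df$class_id[i] &&
          oracle_iou(as.numeric(df[j, 1:4]), as.numeric(df[i, 1:4])) > iou_threshold) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  df[keep, , drop = FALSE]
}

# 101-point AP computed directly from the enumerated stepwise PR curve
oracle_ap101 <- function(flags, n_truths) {
  tp <- cumsum(flags); fp <- cumsum(!flags)
  rec <- tp / n_truths; prec <- tp / (tp + fp)
  s <- 0
  for (r in seq(0, 1, by = 0.01)) {
    pbest <- 0
    for (i in seq_along(rec)) if (rec[i] >= r) pbest <- max(pbest, max(prec[i:length(prec)]))
    s <- s + pbest
  }
  s / 101
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random tiny feature map
rmap <- function(H, W, C, N = 1, sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(H * W * C * N, 0, sd), dim = c(H, W, C, N))
}
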