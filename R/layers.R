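# Module framework: a module is a list with named parameter nodes, an
# optional state environment (batch-norm running statistics), and named
# children. Forward passes and FLOP accounting dispatch on class.

new_module <- function(type, ...) {
  m <- list(type = type, ...)
  class(m) <- c(paste0("sd_", type), "sd_module")
  m
}

#' Forward pass through a module
#' @param m module; @param x input; @param training logical
#' @keywords internal
#' @noRd
sd_forward <- function(m, x, training = FALSE) UseMethod("sd_forward")

#' Analytic FLOPs of a module applied to an H x W input (2 FLOPs per MAC;
#' convolution, linear and attention matmuls only).
#' @keywords internal
#' @noRd
sd_flops <- function(m, H, W) UseMethod("sd_flops")

#' @export
sd_flops.default <- function(m, H, W) 0

#' Collect all parameter nodes of a module tree
#' @keywords internal
#' @noRd
module_params <- function(m) {
  out <- list()
  if (!is.null(m$params)) out <- m$params
  for (ch in m$children) out <- c(out, module_params(ch))
  out
}

#' Total learnable element count of a module tree
#' @keywords internal
#' @noRd
module_n_params <- function(m) {
  sum(vapply(module_params(m), function(p) length(vv(p)), numeric(1)))
}

# deterministic weight init driven by the current RNG stream
.winit <- function(dims, fan_in) {
  s <- sqrt(2 / fan_in)
  array(stats::rnorm(prod(dims), 0, s), dim = dims)
}

.bn_state <- function(C) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(C)
  e$running_var <- rep(1, C)
  e
}

.apply_act <- function(x, act) {
  switch(act,
         silu = ad_silu(x),
         relu = ad_relu(x),
         relu6 = ad_relu6(x),
         sigmoid = ad_sigmoid(x),
         none = x,
         stop("unknown activation: ", act))
}

# ---- Conv + BN + activation ------------------------------------------------

mod_conv <- function(ci, co, k = 1L, stride = 1L, act = "silu", bn = TRUE,
                     bias = !bn) {
  params <- list(w = ad_param(.winit(c(k, k, ci, co), k * k * ci)))
  if (bias) params$b <- ad_param(numeric(co))
  if (bn) {
    params$gamma <- ad_param(rep(1, co))
    params$beta <- ad_param(numeric(co))
  }
  new_module("conv", params = params, children = list(),
             state = if (bn) .bn_state(co) else NULL,
             ci = ci, co = co, k = k, stride = stride, act = act, bn = bn,
             bias = bias)
}

#' @export
sd_forward.sd_conv <- function(m, x, training = FALSE) {
  y <- ad_conv2d(x, m$params$w, b = m$params$b, stride = m$stride)
  if (m$bn) y <- ad_batchnorm(y, m$params$gamma, m$params$beta, m$state, training)
  .apply_act(y, m$act)
}

#' @export
sd_flops.sd_conv <- function(m, H, W) {
  Ho <- ceiling(H / m$stride); Wo <- ceiling(W / m$stride)
  2 * m$k * m$k * m$ci * m$co * Ho * Wo
}

# ---- CSP bottleneck block (channel-split aggregation) ----------------------

mod_csp <- function(ci, co, n = 1L) {
  h <- co %/% 2L
  children <- list(cv1 = mod_conv(ci, 2L * h, 1L))
  for (i in seq_len(n)) {
    children[[paste0("b", i, "a")]] <- mod_conv(h, h, 3L)
    children[[paste0("b", i, "b")]] <- mod_conv(h, h, 3L)
  }
  children$cv2 <- mod_conv((2L + n) * h, co, 1L)
  new_module("csp", params = list(), children = children,
             ci = ci, co = co, h = h, n = n)
}

#' @export
sd_forward.sd_csp <- function(m, x, training = FALSE) {
  y <- sd_forward(m$children$cv1, x, training)
  a <- ad_slice_c(y, seq_len(m$h))
  b <- ad_slice_c(y, m$h + seq_len(m$h))
  parts <- list(a, b)
  cur <- b
  for (i in seq_len(m$n)) {
    z <- sd_forward(m$children[[paste0("b", i, "a")]], cur, training)
    z <- sd_forward(m$children[[paste0("b", i, "b")]], z, training)
    cur <- ad_add(z, cur)
    parts[[length(parts) + 1L]] <- cur
  }
  sd_forward(m$children$cv2, ad_concat_c(parts), training)
}

#' @export
sd_flops.sd_csp <- function(m, H, W) {
  sum(vapply(m$children, sd_flops, numeric(1), H = H, W = W))
}
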