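# Minimal CNN runtime: S3 modules holding plain R arrays, forward passes via
# im2col + BLAS. Feature maps are 4-D arrays dim (batch, channels, height,
# width); all parameters are doubles.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a feature map
#'
#' Wraps a numeric array into the canonical 4-D layout `(batch, channels,
#' height, width)` used by every network block. A 3-D array is promoted to a
#' single-image batch.
#'
#' @param x numeric array, 3-D `(C, H, W)` or 4-D `(B, C, H, W)`.
#' @return a 4-D numeric array.
#' @export
feature_map <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  stopifnot(length(dim(x)) == 4L, all(dim(x) >= 1L))
  x
}

new_module <- function(kind, params = list(), buffers = list(),
                       children = list(), meta = list()) {
  structure(list(kind = kind, params = params, buffers = buffers,
                 children = children, meta = meta),
            class = c(paste0("snet_", kind), "snet_module"))
}

#' Run a network block forward
#'
#' @param m a block built by one of the `make_*`/block constructors or
#'   [build_model()].
#' @param x feature map, 3-D `(C, H, W)` or 4-D `(B, C, H, W)` array.
#' @param ... passed to methods.
#' @return the output feature map (4-D array), except for detection heads and
#'   whole models which return a list of per-level prediction maps.
#' @export
forward <- function(m, x, ...) UseMethod("forward")

#' @export
forward.default <- function(m, x, ...)
  stop("no forward method for class ", paste(class(m), collapse = "/"))

# apply f(single image array (C,H,W)) across the batch dimension
batch_apply <- function(x, f) {
  x <- feature_map(x)
  d <- dim(x)
  first <- f(array(x[1L, , , ], d[2:4]))
  out <- array(0, c(d[1L], dim(first)))
  out[1L, , , ] <- first
  if (d[1L] > 1L) for (b in 2:d[1L]) out[b, , , ] <- f(array(x[b, , , ], d[2:4]))
  out
}

## ---- activations -----------------------------------------------------------

silu <- function(x) x / (1 + exp(-x))
hswish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6
sigmoid_ <- function(x) 1 / (1 + exp(-x))

apply_act <- function(x, act) {
  switch(act,
         silu = silu(x),
         hswish = hswish(x),
         sigmoid = sigmoid_(x),
         identity = x,
         stop("unknown activation: ", act))
}

## ---- convolution -----------------------------------------------------------

autopad <- function(k) k %/% 2L

pad_chw <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p))
  out[, (p + 1L):(p + d[2L]), (p + 1L):(p + d[3L])] <- x
  out
}

# im2col with row order (c, ky, kx), c fastest -- matches the column order of
# matrix(weight, n_out, ...) for a weight array dim (n_out, c, ky, kx)
im2col <- function(x, k, stride, pad) {
  d <- dim(x)
  xp <- pad_chw(x, pad)
  ho <- (d[2L] + 2L * pad - k) %/% stride + 1L
  wo <- (d[3L] + 2L * pad - k) %/% stride + 1L
  ih <- seq.int(1L, by = stride, length.out = ho)
  iw <- seq.int(1L, by = stride, length.out = wo)
  m <- matrix(0, d[1L] * k * k, ho * wo)
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    rows <- ((kx - 1L) * k + (ky - 1L)) * d[1L] + seq_len(d[1L])
    m[rows, ] <- matrix(xp[, ih + (ky - 1L), iw + (kx - 1L), drop = FALSE],
                        d[1L], ho * wo)
  }
  attr(m, "out_hw") <- c(ho, wo)
  m
}

conv2d_chw <- function(x, weight, bias, stride, pad, groups) {
  d <- dim(weight)                      # (c_out, c_in/g, k, k)
  c_out <- d[1L]; k <- d[3L]
  if (groups == 1L) {
    col <- im2col(x, k, stride, pad)
    hw <- attr(col, "out_hw")
    y <- matrix(weight, c_out, d[2L] * k * k) %*% col
  } else {
    cig <- d[2L]; cog <- c_out %/% groups
    hw <- NULL; y <- NULL
    for (g in seq_len(groups)) {
      xg <- x[(g - 1L) * cig + seq_len(cig), , , drop = FALSE]
      col <- im2col(xg, k, stride, pad)
      wg <- weight[(g - 1L) * cog + seq_len(cog), , , , drop = FALSE]
      yg <- matrix(wg, cog, cig * k * k) %*% col
      hw <- attr(col, "out_hw")
      y <- if (is.null(y)) yg else rbind(y, yg)
    }
  }
  if (!is.null(bias)) y <- y + as.vector(bias)
  array(y, c(c_out, hw[1L], hw[2L]))
}

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

# bare convolution leaf
conv_leaf <- function(c_in, c_out, k, stride = 1L, groups = 1L, bias = FALSE) {
  if (c_in < 1 || c_out < 1 || k < 1 || stride < 1)
    stop("conv dimensions must be positive")
  if (c_in %% groups != 0L || c_out %% groups != 0L)
    stop("groups must divide both channel counts")
  fan_in <- (c_in / groups) * k * k
  params <- list(weight = kaiming_uniform(c(c_out, c_in / groups, k, k), fan_in))
  if (bias) params$bias <- array(stats::runif(c_out, -1, 1) / sqrt(fan_in), c_out)
  new_module("conv", params = params,
             meta = list(c_in = c_in, c_out = c_out, k = k, stride = stride,
                         groups = groups, pad = autopad(k), bias = bias))
}

#' @export
forward.snet_conv <- function(m, x, ...) {
  batch_apply(x, function(xi)
    conv2d_chw(xi, m$params$weight, m$params$bias, m$meta$stride, m$meta$pad,
               m$meta$groups))
}

bn_leaf <- function(c) {
  new_module("bn",
             params = list(gamma = rep(1, c), beta = rep(0, c)),
             buffers = list(mean = rep(0, c), var = rep(1, c)),
             meta = list(c = c, eps = 1e-3))
}

#' @export
forward.snet_bn <- function(m, x, ...) {
  x <- feature_map(x)
  if (identical(getOption("sproutnet.bn_mode", "running"), "instance") &&
      prod(dim(x)[3:4]) > 1L) {
    # training-mode statistics from the map itself (used when the running
    # statistics are untrained, e.g. by the smoke trainer)
    d <- dim(x)
    mu <- apply(x, c(1L, 2L), mean)
    v <- apply(x, c(1L, 2L), function(z) stats::var(as.vector(z))) *
      (prod(d[3:4]) - 1L) / prod(d[3:4])
    out <- x
    for (b in seq_len(d[1L])) {
      scale <- m$params$gamma / sqrt(v[b, ] + m$meta$eps)
      shift <- m$params$beta - mu[b, ] * scale
      out[b, , , ] <- sweep(sweep(x[b, , , , drop = FALSE], 2L, scale, "*"),
                            2L, shift, "+")
    }
    return(out)
  }
  scale <- m$params$gamma / sqrt(m$buffers$var + m$meta$eps)
  shift <- m$params$beta - m$buffers$mean * scale
  sweep(sweep(x, 2L, scale, "*"), 2L, shift, "+")
}

## ---- pooling / upsampling --------------------------------------------------

maxpool_chw <- function(x, k, stride = 1L, pad = autopad(k)) {
  d <- dim(x)
  xp <- pad_chw(x, pad, value = -Inf)
  ho <- (d[2L] + 2L * pad - k) %/% stride + 1L
  wo <- (d[3L] + 2L * pad - k) %/% stride + 1L
  ih <- seq.int(1L, by = stride, length.out = ho)
  iw <- seq.int(1L, by = stride, length.out = wo)
  out <- array(-Inf, c(d[1L], ho, wo))
  for (ky in seq_len(k)) for (kx in seq_len(k))
    out <- pmax(out, xp[, ih + (ky - 1L), iw + (kx - 1L), drop = FALSE])
  out
}

upsample_nearest_chw <- function(x, s) {
  d <- dim(x)
  x[, rep(seq_len(d[2L]), each = s), rep(seq_len(d[3L]), each = s), drop = FALSE]
}

# bilinear interpolation on a (C,H,W) map, half-pixel centers
bilinear_chw <- function(x, ho, wo) {
  d <- dim(x)
  sy <- d[2L] / ho; sx <- d[3L] / wo
  yc <- pmin(pmax((seq_len(ho) - 0.5) * sy - 0.5, 0), d[2L] - 1)
  xc <- pmin(pmax((seq_len(wo) - 0.5) * sx - 0.5, 0), d[3L] - 1)
  y0 <- pmin(floor(yc), d[2L] - 1); y1 <- pmin(y0 + 1, d[2L] - 1)
  x0 <- pmin(floor(xc), d[3L] - 1); x1 <- pmin(x0 + 1, d[3L] - 1)
  wy <- yc - y0; wx <- xc - x0
  a <- x[, y0 + 1, x0 + 1, drop = FALSE] ; b <- x[, y0 + 1, x1 + 1, drop = FALSE]
  c_ <- x[, y1 + 1, x0 + 1, drop = FALSE]; e <- x[, y1 + 1, x1 + 1, drop = FALSE]
  wyA <- array(rep(wy, each = d[1L]), c(d[1L], ho, wo))
  wxA <- aperm(array(rep(wx, each = d[1L] * ho), c(d[1L], ho, wo)), c(1, 2, 3))
  top <- a * (1 - wxA) + b * wxA
  bot <- c_ * (1 - wxA) + e * wxA
  top * (1 - wyA) + bot * wyA
}

## ---- parameter enumeration -------------------------------------------------

#' Enumerate the learnable arrays of a block or model
#'
#' Walks the module tree and returns every learnable parameter array
#' (convolution weights/biases, batch-norm gain/shift). Fixed buffers such as
#' batch-norm running statistics and the DFL bin projection are excluded.
#'
#' @param m a block or a model from [build_model()].
#' @return named list of numeric arrays.
#' @export
module_params <- function(m) {
  if (inherits(m, "snet_model")) {
    out <- list()
    for (l in m$layers)
      out <- c(out, prefix_names(module_params(l$module), l$name))
    return(out)
  }
  stopifnot(inherits(m, "snet_module"))
  out <- m$params
  for (nm in names(m$children))
    out <- c(out, prefix_names(module_params(m$children[[nm]]), nm))
  out
}

prefix_names <- function(lst, pre) {
  if (length(lst)) names(lst) <- paste(pre, names(lst), sep = ".")
  lst
}
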