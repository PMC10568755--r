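# Analytic complexity accounting. Parameters are counted by enumerating the
# learnable arrays; FLOPs follow the convention
#   conv:   2 * H_out * W_out * (C_in/g * K^2 + 1) * C_out
# with, when `elementwise = TRUE` (the default), unfused batch norm (2 ops
# per element), activations (1/element), max-pools (k^2/element), upsampling
# and residual additions (1/element), attention re-weighting, and the CARAFE
# reassembly dot products. This is the convention under which the 2-class
# baseline at 640x640 counts 8.2 GFLOPs.

#' Count learnable parameters
#'
#' Sums the lengths of every learnable array of a block or model (see
#' [module_params()]). Batch norm contributes 2 per channel; biases are
#' counted where present; fixed buffers are not.
#'
#' @param m a block or `snet_model`.
#' @return integer-valued count.
#' @export
count_params <- function(m) {
  p <- module_params(m)
  if (!length(p)) return(0)
  sum(vapply(p, length, 0L))
}

## ---- per-block FLOP/shape tracing -----------------------------------------

# trace(module, shape=c(C,H,W)) -> list(out = shape, flops, rows = data.frame)
trace_block <- function(m, shape, elementwise = TRUE) UseMethod("trace_block")

row_df <- function(block, params, flops)
  data.frame(block = block, params = params, flops = flops,
             stringsAsFactors = FALSE)

flops_conv <- function(c_in, c_out, k, hw_out, groups = 1L)
  2 * hw_out * (c_in / groups * k^2 + 1) * c_out

#' @export
trace_block.snet_conv <- function(m, shape, elementwise = TRUE) {
  mt <- m$meta
  ho <- (shape[2L] + 2 * mt$pad - mt$k) %/% mt$stride + 1L
  wo <- (shape[3L] + 2 * mt$pad - mt$k) %/% mt$stride + 1L
  list(out = c(mt$c_out, ho, wo),
       flops = flops_conv(mt$c_in, mt$c_out, mt$k, ho * wo, mt$groups))
}

#' @export
trace_block.snet_bn <- function(m, shape, elementwise = TRUE)
  list(out = shape, flops = if (elementwise) 2 * prod(shape) else 0)

#' @export
trace_block.snet_cbs <- function(m, shape, elementwise = TRUE) {
  tc <- trace_block(m$children$conv, shape, elementwise)
  tb <- trace_block(m$children$bn, tc$out, elementwise)
  act <- if (elementwise && m$meta$act != "identity") prod(tc$out) else 0
  list(out = tc$out, flops = tc$flops + tb$flops + act)
}

#' @export
trace_block.snet_ghostconv <- function(m, shape, elementwise = TRUE) {
  t1 <- trace_block(m$children$primary, shape, elementwise)
  t2 <- trace_block(m$children$cheap, t1$out, elementwise)
  list(out = c(t1$out[1L] + t2$out[1L], t1$out[2:3]),
       flops = t1$flops + t2$flops)
}

#' @export
trace_block.snet_ghostbottleneck <- function(m, shape, elementwise = TRUE) {
  t1 <- trace_block(m$children$g1, shape, elementwise)
  t2 <- trace_block(m$children$g2, t1$out, elementwise)
  add <- if (elementwise && m$meta$shortcut) prod(shape) else 0
  list(out = t2$out, flops = t1$flops + t2$flops + add)
}

#' @export
trace_block.snet_bottleneck <- function(m, shape, elementwise = TRUE) {
  t1 <- trace_block(m$children$cv1, shape, elementwise)
  t2 <- trace_block(m$children$cv2, t1$out, elementwise)
  add <- if (elementwise && m$meta$shortcut) prod(shape) else 0
  list(out = t2$out, flops = t1$flops + t2$flops + add)
}

#' @export
trace_block.snet_c2f <- function(m, shape, elementwise = TRUE) {
  t1 <- trace_block(m$children$cv1, shape, elementwise)
  c <- m$meta$c_out %/% 2L
  f <- t1$flops
  cur <- c(c, t1$out[2:3])
  for (i in seq_len(m$meta$n)) {
    ti <- trace_block(m$children[[paste0("m", i)]], cur, elementwise)
    f <- f + ti$flops
    cur <- ti$out
  }
  t2 <- trace_block(m$children$cv2, c((2L + m$meta$n) * c, t1$out[2:3]),
                    elementwise)
  list(out = t2$out, flops = f + t2$flops)
}

#' @export
trace_block.snet_sppf <- function(m, shape, elementwise = TRUE) {
  t1 <- trace_block(m$children$cv1, shape, elementwise)
  pool <- if (elementwise) 3 * prod(t1$out) * m$meta$pool_k^2 else 0
  t2 <- trace_block(m$children$cv2, c(4L * t1$out[1L], t1$out[2:3]),
                    elementwise)
  list(out = t2$out, flops = t1$flops + pool + t2$flops)
}

#' @export
trace_block.snet_ca <- function(m, shape, elementwise = TRUE) {
  c <- m$meta$c; mid <- m$meta$mid
  h <- shape[2L]; w <- shape[3L]
  f <- 2 * (h + w) * (c * 1 + 1) * mid +          # shared 1x1 reduce
    2 * h * (mid + 1) * c + 2 * w * (mid + 1) * c # two 1x1 expands
  if (elementwise)
    f <- f + 2 * c * h * w +                       # two average pools
      2 * mid * (h + w) +                          # BN on the reduced map
      mid * (h + w) + c * (h + w) +                # h-swish + sigmoids
      2 * c * h * w                                # two gating multiplies
  list(out = shape, flops = f)
}

#' @export
trace_block.snet_carafe <- function(m, shape, elementwise = TRUE) {
  mt <- m$meta
  h <- shape[2L]; w <- shape[3L]; hw <- h * w
  f <- 2 * hw * (mt$c + 1) * mt$c_mid +
    2 * hw * (mt$c_mid * mt$k_encoder^2 + 1) * (mt$sigma^2 * mt$k_up^2)
  # reassembly: one k_up^2 dot product per channel per output position
  f <- f + 2 * mt$k_up^2 * mt$c * hw * mt$sigma^2
  if (elementwise)
    f <- f + 3 * mt$sigma^2 * mt$k_up^2 * hw       # kernel normalization
  list(out = c(mt$c, mt$sigma * h, mt$sigma * w), flops = f)
}

#' @export
trace_block.snet_pcc <- function(m, shape, elementwise = TRUE) {
  cs <- m$meta$split
  tp <- trace_block(m$children$partial, c(cs, shape[2:3]), elementwise)
  tf <- trace_block(m$children$fuse, c(m$meta$c_in, shape[2:3]), elementwise)
  list(out = tf$out, flops = tp$flops + tf$flops)
}

#' @export
trace_block.snet_upsample <- function(m, shape, elementwise = TRUE) {
  out <- c(shape[1L], shape[2L] * m$meta$scale, shape[3L] * m$meta$scale)
  list(out = out, flops = if (elementwise) prod(out) else 0)
}

#' @export
trace_block.snet_concat <- function(m, shape, elementwise = TRUE) {
  # shape is a list of input shapes
  list(out = c(sum(vapply(shape, `[`, 0, 1L)), shape[[1L]][2:3]), flops = 0)
}

#' @export
trace_block.snet_head <- function(m, shape, elementwise = TRUE) {
  f <- 0
  for (i in seq_len(3L)) {
    pre <- paste0("lv", i, ".")
    si <- shape[[i]]
    for (br in c("box", "cls")) {
      ta <- trace_block(m$children[[paste0(pre, br, "_a")]], si, elementwise)
      tb <- trace_block(m$children[[paste0(pre, br, "_b")]], ta$out, elementwise)
      tp <- trace_block(m$children[[paste0(pre, br, "_pred")]], tb$out,
                        elementwise)
      f <- f + ta$flops + tb$flops + tp$flops
    }
  }
  list(out = shape, flops = f)
}

## ---- model-level accounting ------------------------------------------------

trace_model <- function(m, input_size, elementwise = TRUE) {
  shapes <- list(); prev <- c(3L, input_size, input_size)
  rows <- list()
  for (l in m$layers) {
    inp <- if (identical(l$from, "prev")) prev
           else if (length(l$from) == 1L) shapes[[l$from]]
           else lapply(l$from, function(nm) shapes[[nm]])
    tr <- trace_block(l$module, inp, elementwise)
    rows[[length(rows) + 1L]] <-
      row_df(l$name, count_params(l$module), tr$flops)
    prev <- tr$out
    shapes[[l$name]] <- prev
  }
  do.call(rbind, rows)
}

#' Count FLOPs
#'
#' Analytic floating-point-operation count of a block or model at a given
#' input resolution, under the convention described above (2 x
#' multiply-accumulates with the bias term, at each convolution's own output
#' resolution; grouped convolutions divided by their group count). With
#' `elementwise = FALSE` only the convolution term is counted.
#'
#' @param m a block or `snet_model`.
#' @param input_h,input_w input resolution in pixels. For a bare block this
#'   is the resolution of its input map; `channels` must then be supplied.
#' @param channels input channel count (blocks only; models are 3).
#' @param elementwise include non-convolution elementwise operations.
#' @return total FLOPs (numeric).
#' @export
count_flops <- function(m, input_h = 640L, input_w = input_h, channels = NULL,
                        elementwise = TRUE) {
  if (inherits(m, "snet_model")) {
    if (input_h != input_w)
      return(sum(trace_model_rect(m, input_h, input_w, elementwise)$flops))
    return(sum(trace_model(m, input_h, elementwise)$flops))
  }
  if (is.null(channels)) channels <- m$meta$c_in %||% m$meta$c
  if (is.null(channels)) stop("count_flops: supply `channels` for this block")
  trace_block(m, c(channels, input_h, input_w), elementwise)$flops
}

# non-square variant (kept separate: the square path is the common one)
trace_model_rect <- function(m, h, w, elementwise = TRUE) {
  shapes <- list(); prev <- c(3L, h, w)
  rows <- list()
  for (l in m$layers) {
    inp <- if (identical(l$from, "prev")) prev
           else if (length(l$from) == 1L) shapes[[l$from]]
           else lapply(l$from, function(nm) shapes[[nm]])
    tr <- trace_block(l$module, inp, elementwise)
    rows[[length(rows) + 1L]] <- row_df(l$name, count_params(l$module), tr$flops)
    prev <- tr$out
    shapes[[l$name]] <- prev
  }
  do.call(rbind, rows)
}

#' Per-layer complexity report
#'
#' @param model an `snet_model`.
#' @param input_size square input resolution in pixels.
#' @param elementwise include elementwise operations in FLOPs.
#' @return a `complexity_report`: data frame of per-layer parameter and FLOP
#'   counts with totals in attributes (`total_params`, `total_flops`).
#' @export
complexity_report <- function(model, input_size = 640L, elementwise = TRUE) {
  stopifnot(inherits(model, "snet_model"))
  df <- trace_model(model, input_size, elementwise)
  structure(df, class = c("complexity_report", "data.frame"),
            total_params = sum(df$params), total_flops = sum(df$flops),
            input_size = input_size)
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("complexity at %dx%d\n", attr(x, "input_size"),
              attr(x, "input_size")))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("total: %s params (%s M), %.4g FLOPs (%s G)\n",
              format(attr(x, "total_params"), big.mark = ","),
              params_m(attr(x, "total_params")),
              attr(x, "total_flops"), flops_g(attr(x, "total_flops"))))
  invisible(x)
}

#' Format totals the way the tables print them
#'
#' `params_m()` reports millions of parameters truncated (not rounded) to
#' `digits` decimals; `flops_g()` reports GFLOPs rounded to one decimal.
#'
#' @param n a raw count.
#' @param digits decimals to keep.
#' @return character scalar.
#' @export
params_m <- function(n, digits = 2L) {
  sprintf(paste0("%.", digits, "f"), trunc(n / 1e6 * 10^digits) / 10^digits)
}

#' @rdname params_m
#' @export
flops_g <- function(n, digits = 1L) sprintf(paste0("%.", digits, "f"), n / 1e9)

#' Write the layer table as TSV
#'
#' @param report a [complexity_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_layer_table <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- closed-form ratios ----------------------------------------------------

#' Partial-convolution FLOP ratio
#'
#' Closed-form ratio of PCC FLOPs to those of a dense `k`x`k` convolution on
#' the same map: `1/r^2 + 1/k^2`. At `k = 3`, `r = 4` this is 25/144, inside
#' the 1/6 to 1/5 band.
#'
#' @param k partial-convolution kernel size.
#' @param r channel split ratio.
#' @return the ratio (numeric scalar).
#' @export
pconv_ratio <- function(k, r) {
  if (any(c(k, r) <= 0)) stop("pconv_ratio: k and r must be positive")
  1 / r^2 + 1 / k^2
}

#' Depthwise (grouped) convolution FLOP ratio
#'
#' Ratio of DBS FLOPs to the equivalent dense convolution on the weight
#' term: `1/gcd(c_in, c_out)`.
#'
#' @param c_in,c_out channel counts.
#' @return the ratio (numeric scalar).
#' @export
dwconv_ratio <- function(c_in, c_out) {
  if (c_in < 1 || c_out < 1) stop("dwconv_ratio: channels must be positive")
  1 / gcd2(c_in, c_out)
}
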