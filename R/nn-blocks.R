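# The YOLOv8-Peas building blocks. Every constructor returns an S3 module
# whose learnable arrays are initialized Kaiming-style from the current RNG
# state, so a model build is reproducible under set.seed().

## ---- CBS / DBS -------------------------------------------------------------

#' Convolution + batch norm + SiLU (CBS)
#'
#' The standard convolutional unit: a `k`x`k` convolution (no bias; the shift
#' is folded into batch normalization), batch normalization, and a SiLU
#' activation. Spatial size is divided by `s` (same padding).
#'
#' @param c_in,c_out input/output channel counts.
#' @param k kernel size.
#' @param s stride (1 or 2 in this architecture).
#' @param act activation: `"silu"` (default) or `"identity"`.
#' @return a network block; run it with [forward()].
#' @examples
#' b <- make_cbs(3, 16, 3, 2)
#' dim(forward(b, array(0, c(1, 3, 8, 8))))  # 1 16 4 4
#' @export
make_cbs <- function(c_in, c_out, k = 1L, s = 1L, act = "silu") {
  if (c_in < 1 || c_out < 1 || k < 1 || s < 1)
    stop("make_cbs: dimensions must be positive")
  new_module("cbs",
             children = list(conv = conv_leaf(c_in, c_out, k, s),
                             bn = bn_leaf(c_out)),
             meta = list(c_in = c_in, c_out = c_out, k = k, stride = s,
                         act = act))
}

#' @export
forward.snet_cbs <- function(m, x, ...) {
  apply_act(forward(m$children$bn, forward(m$children$conv, x)), m$meta$act)
}

#' Depthwise (grouped) convolution + batch norm + SiLU (DBS)
#'
#' A lighter drop-in for [make_cbs()]: the convolution is grouped with
#' `M = gcd(c_in, c_out)` groups, so its weight count is `k^2 (c_in/M) c_out`
#' and its FLOPs are about `1/M` of the equivalent dense convolution.
#'
#' @inheritParams make_cbs
#' @return a network block.
#' @examples
#' length(module_params(make_dbs(64, 128, 3, 2))$conv.weight)  # 1152
#' @export
make_dbs <- function(c_in, c_out, k = 1L, s = 1L, act = "silu") {
  if (c_in < 1 || c_out < 1) stop("make_dbs: dimensions must be positive")
  m <- gcd2(c_in, c_out)
  new_module("cbs",
             children = list(conv = conv_leaf(c_in, c_out, k, s, groups = m),
                             bn = bn_leaf(c_out)),
             meta = list(c_in = c_in, c_out = c_out, k = k, stride = s,
                         act = act, groups = m, dbs = TRUE))
}

gcd2 <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

## ---- Ghost blocks ----------------------------------------------------------

#' Ghost convolution
#'
#' Produces half its output channels with a primary `k`x`k` convolution and
#' the other half with a cheap linear transform of that primary output, then
#' concatenates the two halves. The cheap transform is a `cheap_k` x `cheap_k`
#' convolution on the `c_out/2` primary channels: pointwise (1x1, dense) by
#' default, or depthwise (the GhostNet convention) when
#' `cheap_depthwise = TRUE`.
#'
#' @inheritParams make_cbs
#' @param act logical; apply the SiLU nonlinearity after each half.
#' @param cheap_k kernel size of the cheap transform.
#' @param cheap_depthwise use a depthwise cheap transform.
#' @return a network block.
#' @examples
#' g <- ghost_conv(16, 32, 1, act = TRUE, cheap_k = 5, cheap_depthwise = TRUE)
#' sum(lengths(module_params(g))) - 2 * 32  # 656 convolution weights
#' @export
ghost_conv <- function(c_in, c_out, k = 1L, act = TRUE, cheap_k = 1L,
                       cheap_depthwise = FALSE) {
  if (c_out %% 2L != 0L) stop("ghost_conv: c_out must be even")
  ch <- c_out %/% 2L
  a <- if (isTRUE(act)) "silu" else "identity"
  new_module("ghostconv",
             children = list(
               primary = make_cbs(c_in, ch, k, 1L, act = a),
               cheap = new_module("cbs",
                 children = list(
                   conv = conv_leaf(ch, ch, cheap_k, 1L,
                                    groups = if (cheap_depthwise) ch else 1L),
                   bn = bn_leaf(ch)),
                 meta = list(c_in = ch, c_out = ch, k = cheap_k, stride = 1L,
                             act = a,
                             groups = if (cheap_depthwise) ch else 1L))),
             meta = list(c_in = c_in, c_out = c_out, k = k, act = act))
}

#' @export
forward.snet_ghostconv <- function(m, x, ...) {
  y1 <- forward(m$children$primary, x)
  y2 <- forward(m$children$cheap, y1)
  cat_channels(y1, y2)
}

cat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[2L], 0L)
  out <- array(0, c(d[1L], sum(cs), d[3L], d[4L]))
  at <- 0L
  for (x in xs) {
    out[, at + seq_len(dim(x)[2L]), , ] <- x
    at <- at + dim(x)[2L]
  }
  out
}

#' Ghost bottleneck
#'
#' Two stacked ghost convolutions on `c` channels (the second without
#' activation) with an optional residual connection. This is the unit that
#' replaces the plain two-convolution bottleneck inside C2f to form C2f-Ghost.
#'
#' @param c channel count (even).
#' @param shortcut add the input back to the output.
#' @param cheap_k,cheap_depthwise cheap-transform settings, see
#'   [ghost_conv()].
#' @return a network block; output shape equals input shape.
#' @export
ghost_bottleneck <- function(c, shortcut = TRUE, cheap_k = 1L,
                             cheap_depthwise = FALSE) {
  if (c %% 2L != 0L) stop("ghost_bottleneck: c must be even")
  new_module("ghostbottleneck",
             children = list(
               g1 = ghost_conv(c, c, 1L, TRUE, cheap_k, cheap_depthwise),
               g2 = ghost_conv(c, c, 1L, FALSE, cheap_k, cheap_depthwise)),
             meta = list(c = c, shortcut = isTRUE(shortcut)))
}

#' @export
forward.snet_ghostbottleneck <- function(m, x, ...) {
  x <- feature_map(x)
  y <- forward(m$children$g2, forward(m$children$g1, x))
  if (m$meta$shortcut) {
    if (!identical(dim(x), dim(y)))
      stop("ghost_bottleneck: shortcut shape mismatch")
    y <- y + x
  }
  y
}

# plain two-conv bottleneck (baseline C2f)
bottleneck_std <- function(c, shortcut = TRUE) {
  new_module("bottleneck",
             children = list(cv1 = make_cbs(c, c, 3L, 1L),
                             cv2 = make_cbs(c, c, 3L, 1L)),
             meta = list(c = c, shortcut = isTRUE(shortcut)))
}

#' @export
forward.snet_bottleneck <- function(m, x, ...) {
  x <- feature_map(x)
  y <- forward(m$children$cv2, forward(m$children$cv1, x))
  if (m$meta$shortcut) y <- y + x
  y
}

#' C2f stage (with plain or ghost bottlenecks)
#'
#' The standard split-transform-concatenate stage: a 1x1 convolution expands
#' to `c_out` channels, which are split in half; `n` bottlenecks run on the
#' second half, every intermediate map is concatenated, and a final 1x1
#' convolution fuses back to `c_out`. `c2f_ghost()` is the same topology with
#' each bottleneck replaced by [ghost_bottleneck()].
#'
#' @inheritParams make_cbs
#' @param n number of stacked bottlenecks.
#' @param shortcut residual connections inside the bottlenecks.
#' @param ghost use ghost bottlenecks.
#' @param ... passed to [ghost_bottleneck()].
#' @return a network block.
#' @export
c2f <- function(c_in, c_out, n = 1L, shortcut = FALSE, ghost = FALSE, ...) {
  if (c_out %% 2L != 0L) stop("c2f: c_out must be even")
  if (n < 1L) stop("c2f: n must be >= 1")
  c <- c_out %/% 2L
  btls <- lapply(seq_len(n), function(i)
    if (ghost) ghost_bottleneck(c, shortcut, ...) else bottleneck_std(c, shortcut))
  names(btls) <- paste0("m", seq_len(n))
  new_module("c2f",
             children = c(list(cv1 = make_cbs(c_in, c_out, 1L, 1L)), btls,
                          list(cv2 = make_cbs((2L + n) * c, c_out, 1L, 1L))),
             meta = list(c_in = c_in, c_out = c_out, n = n, ghost = ghost))
}

#' @rdname c2f
#' @export
c2f_ghost <- function(c_in, c_out, n = 1L, shortcut = FALSE, ...)
  c2f(c_in, c_out, n, shortcut, ghost = TRUE, ...)

#' @export
forward.snet_c2f <- function(m, x, ...) {
  y <- forward(m$children$cv1, x)
  c <- m$meta$c_out %/% 2L
  parts <- list(y[, seq_len(c), , , drop = FALSE],
                y[, c + seq_len(c), , , drop = FALSE])
  for (i in seq_len(m$meta$n))
    parts[[length(parts) + 1L]] <-
      forward(m$children[[paste0("m", i)]], parts[[length(parts)]])
  forward(m$children$cv2, do.call(cat_channels, parts))
}

## ---- SPPF ------------------------------------------------------------------

#' Spatial pyramid pooling, fast variant
#'
#' 1x1 reduce to `c_in/2` channels, three chained max-pools of kernel
#' `pool_k` (stride 1, same padding), concatenation of the four maps, and a
#' 1x1 expansion to `c_out`. Chaining the pools reproduces the receptive
#' fields of single larger pools at lower cost.
#'
#' @inheritParams make_cbs
#' @param pool_k odd pooling kernel (default 5).
#' @return a network block; spatial size is unchanged.
#' @export
sppf <- function(c_in, c_out, pool_k = 5L) {
  if (pool_k %% 2L == 0L) stop("sppf: pool_k must be odd")
  ch <- c_in %/% 2L
  new_module("sppf",
             children = list(cv1 = make_cbs(c_in, ch, 1L, 1L),
                             cv2 = make_cbs(ch * 4L, c_out, 1L, 1L)),
             meta = list(c_in = c_in, c_out = c_out, pool_k = pool_k))
}

#' @export
forward.snet_sppf <- function(m, x, ...) {
  y <- forward(m$children$cv1, x)
  k <- m$meta$pool_k
  p1 <- batch_apply(y, function(z) maxpool_chw(z, k))
  p2 <- batch_apply(p1, function(z) maxpool_chw(z, k))
  p3 <- batch_apply(p2, function(z) maxpool_chw(z, k))
  forward(m$children$cv2, cat_channels(y, p1, p2, p3))
}

## ---- Coordinate attention --------------------------------------------------

#' Coordinate attention
#'
#' Channel attention factorized into two axis-wise encodings: per-channel
#' average pooling with kernels (H,1) and (1,W), concatenation along the
#' pooled axis, a shared 1x1 reduction (+ BN + h-swish) to
#' `max(8, c/reduction)` channels, then two 1x1 expansions with sigmoid
#' gates. The input is re-weighted by both positional attention maps, so the
#' output keeps the input shape.
#'
#' @param c channel count.
#' @param reduction channel reduction ratio (mid channels floor at 8).
#' @return a network block.
#' @export
coord_attention <- function(c, reduction = 32L) {
  mid <- max(8L, c %/% reduction)
  new_module("ca",
             children = list(
               conv1 = conv_leaf(c, mid, 1L, bias = TRUE),
               bn1 = bn_leaf(mid),
               conv_h = conv_leaf(mid, c, 1L, bias = TRUE),
               conv_w = conv_leaf(mid, c, 1L, bias = TRUE)),
             meta = list(c = c, mid = mid, reduction = reduction))
}

#' @export
forward.snet_ca <- function(m, x, ...) {
  x <- feature_map(x)
  d <- dim(x)
  batch_apply(x, function(xi) {
    h <- d[3L]; w <- d[4L]
    ph <- apply(xi, c(1L, 2L), mean)                   # (C,H) pooled over W
    pw <- apply(xi, c(1L, 3L), mean)                   # (C,W) pooled over H
    cc <- array(cbind(ph, pw), c(d[2L], h + w, 1L))    # concat along pooled axis
    y <- forward(m$children$bn1,
                 feature_map(conv2d_chw(cc, m$children$conv1$params$weight,
                                        m$children$conv1$params$bias, 1L, 0L, 1L)))
    y <- hswish(array(y, dim(y)[2:4]))
    yh <- y[, seq_len(h), 1L, drop = FALSE]
    yw <- y[, h + seq_len(w), 1L, drop = FALSE]
    ah <- sigmoid_(conv2d_chw(yh, m$children$conv_h$params$weight,
                              m$children$conv_h$params$bias, 1L, 0L, 1L))[, , 1L]
    aw <- sigmoid_(conv2d_chw(yw, m$children$conv_w$params$weight,
                              m$children$conv_w$params$bias, 1L, 0L, 1L))[, , 1L]
    ah <- array(ah, c(d[2L], h))                        # (C,H)
    aw <- array(aw, c(d[2L], w))                        # (C,W)
    out <- xi
    for (ci in seq_len(d[2L]))
      out[ci, , ] <- xi[ci, , ] * outer(ah[ci, ], aw[ci, ])
    out
  })
}

## ---- CARAFE ----------------------------------------------------------------

#' CARAFE content-aware upsampling
#'
#' Predicts a normalized `k_up` x `k_up` reassembly kernel for every output
#' position from the local content: a 1x1 channel compressor to `c_mid`, a
#' `k_encoder` x `k_encoder` content encoder to `sigma^2 k_up^2` channels,
#' pixel-shuffle of those channels over the `sigma H x sigma W` grid, and
#' per-position kernel normalization (softmax by default). Each output value
#' is the dot product of its kernel with the `k_up` x `k_up` source
#' neighborhood of the corresponding low-resolution position.
#'
#' @param c channel count of the map being upsampled.
#' @param sigma integer upsampling ratio (>= 2).
#' @param k_up odd reassembly kernel size.
#' @param k_encoder odd encoder kernel size.
#' @param c_mid compressed channel count.
#' @param normalizer `"softmax"` (kernels sum to one) or `"sigmoid"`.
#' @return a network block; output is `(B, c, sigma*H, sigma*W)`.
#' @export
carafe <- function(c, sigma = 2L, k_up = 3L, k_encoder = 5L, c_mid = 64L,
                   normalizer = c("softmax", "sigmoid")) {
  normalizer <- match.arg(normalizer)
  if (k_up %% 2L == 0L || k_encoder %% 2L == 0L)
    stop("carafe: kernel sizes must be odd")
  if (sigma < 2L) stop("carafe: sigma must be >= 2")
  new_module("carafe",
             children = list(
               compressor = conv_leaf(c, c_mid, 1L, bias = TRUE),
               encoder = conv_leaf(c_mid, sigma^2 * k_up^2, k_encoder,
                                   bias = TRUE)),
             meta = list(c = c, sigma = sigma, k_up = k_up,
                         k_encoder = k_encoder, c_mid = c_mid,
                         normalizer = normalizer))
}

#' @export
forward.snet_carafe <- function(m, x, ...) {
  s <- m$meta$sigma; ku <- m$meta$k_up; r <- ku %/% 2L
  batch_apply(x, function(xi) {
    d <- dim(xi); h <- d[2L]; w <- d[3L]
    z <- conv2d_chw(xi, m$children$compressor$params$weight,
                    m$children$compressor$params$bias, 1L, 0L, 1L)
    kmap <- conv2d_chw(z, m$children$encoder$params$weight,
                       m$children$encoder$params$bias, 1L,
                       autopad(m$meta$k_encoder), 1L)   # (s^2*ku^2, H, W)
    # kernel normalization per output position
    kern <- array(kmap, c(ku * ku, s * s, h, w))
    if (m$meta$normalizer == "softmax") {
      kern <- exp(sweep(kern, c(2, 3, 4), apply(kern, c(2, 3, 4), max), "-"))
      kern <- sweep(kern, c(2, 3, 4), apply(kern, c(2, 3, 4), sum), "/")
    } else {
      kern <- sigmoid_(kern)
    }
    xp <- pad_chw(xi, r)
    out <- array(0, c(d[1L], s * h, s * w))
    for (sy in seq_len(s)) for (sx in seq_len(s)) {
      sub <- (sx - 1L) * s + sy                         # pixel-shuffle order
      acc <- array(0, c(d[1L], h, w))
      idx <- 0L
      for (kx in seq_len(ku)) for (ky in seq_len(ku)) {
        idx <- idx + 1L
        wgt <- kern[idx, sub, , , drop = TRUE]
        nb <- xp[, (ky - 1L) + seq_len(h), (kx - 1L) + seq_len(w), drop = FALSE]
        acc <- acc + sweep(nb, c(2L, 3L), array(wgt, c(h, w)), "*")
      }
      out[, seq.int(sy, by = s, length.out = h),
          seq.int(sx, by = s, length.out = w)] <- acc
    }
    out
  })
}

## ---- PCC -------------------------------------------------------------------

#' Partial-convolution block (PCC)
#'
#' Splits the input channels, runs a `k`x`k` CBS on a `1/r` slice, splices
#' the result back onto the untouched `1 - 1/r` slice, and fuses with a 1x1
#' CBS. When `c_out` differs from `c_in` the fusion convolution performs the
#' channel change. FLOPs relative to a dense `k`x`k` convolution follow
#' `1/r^2 + 1/k^2` ([pconv_ratio()]).
#'
#' @param c_in,c_out channel counts; `r` must divide `c_in`.
#' @param r channel split ratio (the convolved slice is `c_in/r` wide).
#' @param k kernel of the partial convolution.
#' @return a network block.
#' @export
pcc <- function(c_in, c_out = c_in, r = 4L, k = 3L) {
  if (c_in %% r != 0L)
    stop("pcc: r must divide the input channel count")
  cs <- c_in %/% r
  new_module("pcc",
             children = list(partial = make_cbs(cs, cs, k, 1L),
                             fuse = make_cbs(c_in, c_out, 1L, 1L)),
             meta = list(c_in = c_in, c_out = c_out, r = r, k = k, split = cs))
}

#' @export
forward.snet_pcc <- function(m, x, ...) {
  x <- feature_map(x)
  cs <- m$meta$split
  c_in <- m$meta$c_in
  x1 <- x[, seq_len(c_in - cs), , , drop = FALSE]
  x2 <- x[, c_in - cs + seq_len(cs), , , drop = FALSE]
  forward(m$children$fuse, cat_channels(x1, forward(m$children$partial, x2)))
}

## ---- detection heads -------------------------------------------------------

head_branch_std <- function(c_in, c_mid) {
  list(a = make_cbs(c_in, c_mid, 3L, 1L), b = make_cbs(c_mid, c_mid, 3L, 1L))
}

head_branch_pcc <- function(c_in, c_mid, r, k) {
  list(a = pcc(c_in, c_mid, r, k), b = pcc(c_mid, c_mid, r, k))
}

make_head <- function(per_level_channels, num_classes, reg_max, kind,
                      pcc_ratio = 4L, pcc_kernel = 3L) {
  if (length(per_level_channels) != 3L)
    stop("detection head expects three input levels (strides 8/16/32)")
  c2 <- max(16L, per_level_channels[1L] %/% 4L, reg_max * 4L)
  c3 <- max(per_level_channels[1L], min(num_classes, 100L))
  if (kind == "pdetect") c3 <- c2       # PCC branches share the 64-wide trunk
  levels <- lapply(per_level_channels, function(x) {
    br <- function(cm) if (kind == "pdetect")
      head_branch_pcc(x, cm, pcc_ratio, pcc_kernel) else head_branch_std(x, cm)
    box <- br(c2); cls <- br(c3)
    list(box_a = box$a, box_b = box$b,
         box_pred = conv_leaf(c2, 4L * reg_max, 1L, bias = TRUE),
         cls_a = cls$a, cls_b = cls$b,
         cls_pred = conv_leaf(c3, num_classes, 1L, bias = TRUE))
  })
  children <- list()
  for (i in seq_along(levels))
    children <- c(children, prefix_list(levels[[i]], paste0("lv", i)))
  new_module("head", children = children,
             buffers = list(dfl_bins = 0:(reg_max - 1L)),
             meta = list(ch = per_level_channels, nc = num_classes,
                         reg_max = reg_max, kind = kind))
}

prefix_list <- function(lst, pre) {
  names(lst) <- paste(pre, names(lst), sep = ".")
  lst
}

#' Decoupled anchor-free detection heads
#'
#' `detect_head()` is the standard decoupled head: per level, separate box
#' and class branches of two 3x3 CBS each, finished by 1x1 prediction
#' convolutions (`4*reg_max` distribution-focal box channels; `num_classes`
#' class logits). `pdetect_head()` replaces each branch's stacked 3x3 CBS
#' pair with [pcc()] modules, which is what makes the head light.
#'
#' @param per_level_channels integer vector of three input channel counts
#'   (strides 8, 16, 32).
#' @param num_classes number of object classes.
#' @param reg_max number of distribution-focal bins per box side.
#' @param pcc_ratio,pcc_kernel PCC settings (PDetect only).
#' @return a head block; its [forward()] returns a list of three prediction
#'   maps with `4*reg_max + num_classes` channels.
#' @export
detect_head <- function(per_level_channels = c(64L, 128L, 256L),
                        num_classes = 2L, reg_max = 16L)
  make_head(per_level_channels, num_classes, reg_max, "detect")

#' @rdname detect_head
#' @export
pdetect_head <- function(per_level_channels = c(64L, 128L, 256L),
                         num_classes = 2L, reg_max = 16L, pcc_ratio = 4L,
                         pcc_kernel = 3L)
  make_head(per_level_channels, num_classes, reg_max, "pdetect",
            pcc_ratio, pcc_kernel)

#' @export
forward.snet_head <- function(m, x, ...) {
  stopifnot(is.list(x), length(x) == 3L)
  lapply(seq_len(3L), function(i) {
    xi <- feature_map(x[[i]])
    pre <- paste0("lv", i, ".")
    box <- forward(m$children[[paste0(pre, "box_b")]],
                   forward(m$children[[paste0(pre, "box_a")]], xi))
    box <- forward(m$children[[paste0(pre, "box_pred")]], box)
    cls <- forward(m$children[[paste0(pre, "cls_b")]],
                   forward(m$children[[paste0(pre, "cls_a")]], xi))
    cls <- forward(m$children[[paste0(pre, "cls_pred")]], cls)
    cat_channels(box, cls)
  })
}

## ---- plumbing blocks -------------------------------------------------------

upsample_block <- function(scale = 2L, mode = "nearest")
  new_module("upsample", meta = list(scale = scale, mode = mode))

#' @export
forward.snet_upsample <- function(m, x, ...) {
  batch_apply(x, function(xi) {
    if (m$meta$mode == "nearest") upsample_nearest_chw(xi, m$meta$scale)
    else bilinear_chw(xi, dim(xi)[2L] * m$meta$scale, dim(xi)[3L] * m$meta$scale)
  })
}

concat_block <- function() new_module("concat", meta = list())

#' @export
forward.snet_concat <- function(m, x, ...) do.call(cat_channels, x)
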