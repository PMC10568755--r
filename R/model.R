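# Model configuration and whole-detector assembly (backbone, PAN-FPN neck,
# detection head), mirroring the -n scale layer plan.

#' Model configuration
#'
#' Collects every architectural choice that determines the detector graph
#' and its parameter count. `yolov8n_config()` is the unmodified baseline at
#' the -n scale (plain C2f, CBS everywhere, nearest upsampling, standard
#' decoupled head, no attention); `yolov8_peas_config()` is the full
#' lightweight configuration (C2f-Ghost, DBS on the calibrated downsample
#' set, CARAFE upsampling, PDetect head, coordinate attention after the
#' first C2f-Ghost stage).
#'
#' @param num_classes number of object classes (2: not_sprout / sprout).
#' @param input_size nominal square input size in pixels.
#' @param width_multiple,depth_multiple channel/depth scale factors of the
#'   -n model scale.
#' @param use_ghost replace every C2f bottleneck with a ghost bottleneck.
#' @param ghost_cheap_kernel,ghost_cheap_depthwise cheap-transform settings
#'   of the ghost convolutions (pointwise 1x1 by default).
#' @param dbs_placement character vector of downsample identifiers whose CBS
#'   becomes DBS; any of `"stem"`, `"p2"`, `"p3"`, `"p4"`, `"p5"`,
#'   `"n_d1"`, `"n_d2"`.
#' @param use_carafe use CARAFE for both neck upsamples.
#' @param carafe_k_up,carafe_k_encoder,carafe_sigma,carafe_mid_channels
#'   CARAFE settings, see [carafe()].
#' @param kernel_normalizer CARAFE kernel normalizer (`"softmax"` or
#'   `"sigmoid"`).
#' @param use_pdetect use the PCC-based PDetect head.
#' @param pcc_ratio,pcc_kernel PCC settings, see [pcc()].
#' @param use_ca insert coordinate attention after the first C2f stage.
#' @param ca_reduction coordinate-attention reduction ratio.
#' @param reg_max distribution-focal bins per box side.
#' @param upsample_mode `"nearest"` or `"bilinear"` when CARAFE is off.
#' @param seed RNG seed used by [build_model()] for weight initialization.
#' @return a `snet_config` list.
#' @export
model_config <- function(num_classes = 2L, input_size = 640L,
                         width_multiple = 0.25, depth_multiple = 0.33,
                         use_ghost = FALSE, ghost_cheap_kernel = 1L,
                         ghost_cheap_depthwise = FALSE,
                         dbs_placement = character(),
                         use_carafe = FALSE, carafe_k_up = 3L,
                         carafe_k_encoder = 5L, carafe_sigma = 2L,
                         carafe_mid_channels = 64L,
                         kernel_normalizer = "softmax",
                         use_pdetect = FALSE, pcc_ratio = 4L, pcc_kernel = 3L,
                         use_ca = FALSE, ca_reduction = 32L,
                         reg_max = 16L, upsample_mode = "nearest",
                         seed = 7L) {
  if (carafe_k_up %% 2L == 0L || carafe_k_encoder %% 2L == 0L)
    stop("model_config: CARAFE kernels must be odd")
  if (carafe_sigma < 2L) stop("model_config: carafe_sigma must be >= 2")
  bad <- setdiff(dbs_placement, c("stem", "p2", "p3", "p4", "p5", "n_d1", "n_d2"))
  if (length(bad)) stop("model_config: unknown dbs_placement id(s): ",
                        paste(bad, collapse = ", "))
  rm(bad)
  structure(as.list(environment()), class = "snet_config")
}

#' @rdname model_config
#' @export
yolov8n_config <- function(num_classes = 2L, ...)
  model_config(num_classes = num_classes, ...)

#' @rdname model_config
#' @export
yolov8_peas_config <- function(num_classes = 2L, ...)
  model_config(num_classes = num_classes, use_ghost = TRUE,
               dbs_placement = c("p3", "p4", "p5", "n_d1", "n_d2"),
               use_carafe = TRUE, use_pdetect = TRUE, use_ca = TRUE, ...)

make_divisible <- function(x, div = 8L) max(div, as.integer(round(x / div) * div))

scaled_channels <- function(cfg) {
  base <- c(64L, 128L, 256L, 512L, 1024L)
  vapply(base, function(b) make_divisible(b * cfg$width_multiple), 0L)
}

scaled_depth <- function(cfg, n) max(1L, as.integer(round(n * cfg$depth_multiple)))

#' Build the detector
#'
#' Assembles the full graph from a [model_config()]: CBS/DBS stem and
#' downsamples plus C2f(-Ghost) stages and SPPF in the backbone (with
#' optional coordinate attention after the first stage), a PAN-FPN neck
#' whose two upsamples are nearest/bilinear or CARAFE, and the standard or
#' PDetect head. The build is deterministic given `config$seed`.
#'
#' @param config a `snet_config` from [model_config()].
#' @return an object of class `snet_model`; run it with [forward()] on a
#'   `(B, 3, H, W)` array (H, W divisible by 32) to obtain three prediction
#'   maps at strides 8/16/32.
#' @examples
#' \donttest{
#' m <- build_model(yolov8_peas_config())
#' count_params(m)
#' }
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "snet_config"))
  set.seed(config$seed)
  ch <- scaled_channels(config)          # 16 32 64 128 256 at width 0.25
  c1 <- ch[1L]; c2 <- ch[2L]; c3 <- ch[3L]; c4 <- ch[4L]; c5 <- ch[5L]
  cfg <- config

  cbs_or_dbs <- function(id, c_in, c_out) {
    if (id %in% cfg$dbs_placement) make_dbs(c_in, c_out, 3L, 2L)
    else make_cbs(c_in, c_out, 3L, 2L)
  }
  stage <- function(c_in, c_out, n, shortcut)
    c2f(c_in, c_out, scaled_depth(cfg, n), shortcut, ghost = cfg$use_ghost,
        cheap_k = cfg$ghost_cheap_kernel,
        cheap_depthwise = cfg$ghost_cheap_depthwise)
  upsampler <- function(c) {
    if (cfg$use_carafe)
      carafe(c, cfg$carafe_sigma, cfg$carafe_k_up, cfg$carafe_k_encoder,
             cfg$carafe_mid_channels, cfg$kernel_normalizer)
    else upsample_block(2L, cfg$upsample_mode)
  }

  layers <- list()
  add <- function(name, module, from = "prev") {
    layers[[length(layers) + 1L]] <<- list(name = name, module = module,
                                           from = from)
  }

  add("stem",   cbs_or_dbs("stem", 3L, c1))
  add("down_p2", cbs_or_dbs("p2", c1, c2))
  add("stage_p2", stage(c2, c2, 3L, TRUE))
  if (cfg$use_ca) add("ca", coord_attention(c2, cfg$ca_reduction))
  add("down_p3", cbs_or_dbs("p3", c2, c3))
  add("stage_p3", stage(c3, c3, 6L, TRUE))
  add("down_p4", cbs_or_dbs("p4", c3, c4))
  add("stage_p4", stage(c4, c4, 6L, TRUE))
  add("down_p5", cbs_or_dbs("p5", c4, c5))
  add("stage_p5", stage(c5, c5, 3L, TRUE))
  add("sppf", sppf(c5, c5))
  add("up1", upsampler(c5))
  add("cat1", concat_block(), from = c("up1", "stage_p4"))
  add("neck_t1", stage(c5 + c4, c4, 3L, FALSE))
  add("up2", upsampler(c4))
  add("cat2", concat_block(), from = c("up2", "stage_p3"))
  add("neck_t2", stage(c4 + c3, c3, 3L, FALSE))        # P3 out (stride 8)
  add("n_down1", cbs_or_dbs("n_d1", c3, c3))
  add("cat3", concat_block(), from = c("n_down1", "neck_t1"))
  add("neck_b1", stage(c3 + c4, c4, 3L, FALSE))        # P4 out (stride 16)
  add("n_down2", cbs_or_dbs("n_d2", c4, c4))
  add("cat4", concat_block(), from = c("n_down2", "sppf"))
  add("neck_b2", stage(c4 + c5, c5, 3L, FALSE))        # P5 out (stride 32)
  head_ch <- c(c3, c4, c5)
  head <- if (cfg$use_pdetect)
    pdetect_head(head_ch, cfg$num_classes, cfg$reg_max, cfg$pcc_ratio,
                 cfg$pcc_kernel)
  else detect_head(head_ch, cfg$num_classes, cfg$reg_max)
  add("head", head, from = c("neck_t2", "neck_b1", "neck_b2"))

  structure(list(layers = layers, config = config, strides = c(8L, 16L, 32L)),
            class = "snet_model")
}

#' @export
forward.snet_model <- function(m, x, ...) {
  if (!is.null(m$bn_mode)) {
    old <- options(sproutnet.bn_mode = m$bn_mode)
    on.exit(options(old))
  }
  x <- feature_map(x)
  if (dim(x)[2L] != 3L) stop("model input must have 3 channels")
  if (any(dim(x)[3:4] %% 32L != 0L))
    stop("model input height/width must be divisible by 32")
  outs <- list()
  prev <- x
  for (l in m$layers) {
    inp <- if (identical(l$from, "prev")) prev
           else if (length(l$from) == 1L) outs[[l$from]]
           else lapply(l$from, function(nm) outs[[nm]])
    prev <- forward(l$module, inp)
    outs[[l$name]] <- prev
  }
  outs[["head"]]
}

#' @export
print.snet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<snet_model> %s, %d classes, %d layers, %s parameters\n",
              if (cfg$use_ghost || cfg$use_pdetect) "YOLOv8-Peas-style" else "YOLOv8-n baseline",
              cfg$num_classes, length(x$layers),
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

# Frozen-feature cache for the smoke trainer. For the PDetect head the
# trainable slice is the last two layers of each branch (the 1x1 fuse
# convolution of the second PCC block and the final prediction
# convolution), so what is cached is the fuse input -- the concatenation of
# the untouched channel slice and the frozen 3x3 partial-convolution
# output. For the standard head only the final prediction convolution is
# trained and the cached map is the branch output itself.
head_features <- function(m, x) {
  if (!is.null(m$bn_mode)) {
    old <- options(sproutnet.bn_mode = m$bn_mode)
    on.exit(options(old))
  }
  x <- feature_map(x)
  outs <- list(); prev <- x
  for (l in m$layers) {
    if (l$name == "head") break
    inp <- if (identical(l$from, "prev")) prev
           else if (length(l$from) == 1L) outs[[l$from]]
           else lapply(l$from, function(nm) outs[[nm]])
    prev <- forward(l$module, inp)
    outs[[l$name]] <- prev
  }
  head <- m$layers[[length(m$layers)]]$module
  deep <- identical(head$meta$kind, "pdetect")
  feats <- list(outs[["neck_t2"]], outs[["neck_b1"]], outs[["neck_b2"]])
  lapply(seq_len(3L), function(i) {
    xi <- feature_map(feats[[i]])
    pre <- paste0("lv", i, ".")
    one_branch <- function(br) {
      a_out <- forward(head$children[[paste0(pre, br, "_a")]], xi)
      blk <- head$children[[paste0(pre, br, "_b")]]
      if (!deep) {
        f <- forward(blk, a_out)
        d <- dim(f)
        return(list(X = matrix(f[1L, , , ], d[2L], d[3L] * d[4L]),
                    hw = d[3:4]))
      }
      cs <- blk$meta$split; c_in <- blk$meta$c_in
      x1 <- a_out[, seq_len(c_in - cs), , , drop = FALSE]
      x2 <- a_out[, c_in - cs + seq_len(cs), , , drop = FALSE]
      xb <- cat_channels(x1, forward(blk$children$partial, x2))
      d <- dim(xb)
      list(X = matrix(xb[1L, , , ], d[2L], d[3L] * d[4L]), hw = d[3:4])
    }
    list(box = one_branch("box"), cls = one_branch("cls"), deep = deep)
  })
}
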