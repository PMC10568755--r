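# Label-preserving augmentation: the image transform and the matching
# coordinate mapping for its bounding boxes, plus the dataset-doubling
# policy. Images are numeric arrays (H, W, 3) with values in [0, 255].

AUG_METHODS <- c("brightness", "hflip", "vflip", "scale", "gauss_noise")

#' Augmentation specification
#'
#' Exactly one method per spec. `brightness` multiplies all pixels by
#' `brightness_factor` (boxes unchanged); `hflip`/`vflip` mirror the image
#' (box corners mapped to `W - x2, W - x1` / `H - y2, H - y1`); `scale`
#' resizes the whole image by `scale_s` (all coordinates multiplied by
#' `s`); `gauss_noise` adds i.i.d. N(0, sigma^2) pixel noise (geometry
#' unchanged by default; see `jitter_sigma`).
#'
#' @param method one of `"brightness"`, `"hflip"`, `"vflip"`, `"scale"`,
#'   `"gauss_noise"`.
#' @param brightness_factor multiplicative gain.
#' @param scale_s scale factor `s > 0` (`s < 1` shrinks, `s > 1` enlarges).
#' @param noise_sigma noise standard deviation in intensity units.
#' @param jitter_sigma optional box-coordinate jitter s.d. for the noise
#'   method (0 disables; ground truth is then preserved exactly).
#' @param seed integer seed for the stochastic methods.
#' @return an `augment_spec` list.
#' @export
augment_spec <- function(method, brightness_factor = 1, scale_s = 1,
                         noise_sigma = 10, jitter_sigma = 0, seed = 1L) {
  method <- match.arg(method, AUG_METHODS)
  if (scale_s <= 0) stop("augment_spec: scale_s must be > 0")
  structure(list(method = method, brightness_factor = brightness_factor,
                 scale_s = scale_s, noise_sigma = noise_sigma,
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "augment_spec")
}

#' Transform an image
#'
#' @param image numeric array (H, W, 3), values in `[0, 255]`.
#' @param spec an [augment_spec()].
#' @return the transformed image array.
#' @export
transform_image <- function(image, spec) {
  stopifnot(inherits(spec, "augment_spec"))
  if (is.null(dim(image)) || length(dim(image)) != 3L || any(dim(image) == 0L))
    stop("transform_image: image must be a non-empty (H, W, 3) array")
  switch(spec$method,
    brightness = clamp255(image * spec$brightness_factor),
    hflip = image[, rev(seq_len(dim(image)[2L])), , drop = FALSE],
    vflip = image[rev(seq_len(dim(image)[1L])), , , drop = FALSE],
    scale = {
      H <- dim(image)[1L]; W <- dim(image)[2L]
      resize_image(image, floor(spec$scale_s * H), floor(spec$scale_s * W))
    },
    gauss_noise = {
      set.seed(spec$seed)
      clamp255(image + stats::rnorm(length(image), 0, spec$noise_sigma))
    })
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Bilinear image resize
#'
#' @param image numeric array (H, W, C).
#' @param out_h,out_w target size in pixels.
#' @return the resized array.
#' @export
resize_image <- function(image, out_h, out_w) {
  d <- dim(image)
  chw <- aperm(image, c(3L, 1L, 2L))
  out <- bilinear_chw(chw, out_h, out_w)
  aperm(out, c(2L, 3L, 1L))
}

#' Transform bounding-box labels
#'
#' Applies the coordinate mapping that matches [transform_image()] for the
#' same spec, re-normalizes corner order, and clips to the output frame
#' (degenerate boxes are dropped with a warning).
#'
#' @param labels a [box_labels()] data frame, valid in a `W` x `H` image.
#' @param spec an [augment_spec()].
#' @param W,H source image size in pixels.
#' @return transformed [box_labels()].
#' @export
transform_labels <- function(labels, spec, W, H) {
  stopifnot(inherits(spec, "augment_spec"))
  out <- labels
  outW <- W; outH <- H
  if (nrow(labels)) {
    switch(spec$method,
      brightness = NULL,
      hflip = {
        out$x1 <- W - labels$x2
        out$x2 <- W - labels$x1
      },
      vflip = {
        out$y1 <- H - labels$y2
        out$y2 <- H - labels$y1
      },
      scale = {
        s <- spec$scale_s
        out$x1 <- s * labels$x1; out$y1 <- s * labels$y1
        out$x2 <- s * labels$x2; out$y2 <- s * labels$y2
      },
      gauss_noise = if (spec$jitter_sigma > 0) {
        set.seed(spec$seed + 1L)
        dx <- stats::rnorm(nrow(labels), 0, spec$jitter_sigma)
        dy <- stats::rnorm(nrow(labels), 0, spec$jitter_sigma)
        out$x1 <- labels$x1 + dx; out$x2 <- labels$x2 + dx
        out$y1 <- labels$y1 + dy; out$y2 <- labels$y2 + dy
      })
  }
  if (spec$method == "scale") { outW <- floor(spec$scale_s * W); outH <- floor(spec$scale_s * H) }
  # re-normalize corner order, then clip to the output frame
  if (nrow(out)) {
    xlo <- pmin(out$x1, out$x2); xhi <- pmax(out$x1, out$x2)
    ylo <- pmin(out$y1, out$y2); yhi <- pmax(out$y1, out$y2)
    out$x1 <- xlo; out$x2 <- xhi; out$y1 <- ylo; out$y2 <- yhi
  }
  clip_boxes(as_box_labels(out), outW, outH)
}

#' Double a dataset by augmentation
#'
#' Emits exactly one augmented copy per original image (so `n` inputs give
#' `2n` outputs), with the method sampled per image from `policy` under
#' `seed` and labels co-transformed via [transform_labels()]. The returned
#' manifest records the source id, method and parameters of every copy.
#'
#' @param dataset list of items, each a list with `id`, `image`
#'   (H x W x 3 array) and `labels` ([box_labels()]).
#' @param policy character vector of methods to sample from (a subset of
#'   `r paste(AUG_METHODS, collapse = ", ")`).
#' @param seed integer seed.
#' @param brightness_range,scale_range parameter ranges sampled uniformly.
#' @param noise_sigma Gaussian noise s.d.
#' @return list with `items` (originals followed by augmented copies) and
#'   `manifest` (data frame).
#' @export
augment_dataset <- function(dataset, policy = AUG_METHODS, seed = 1L,
                            brightness_range = c(0.6, 1.4),
                            scale_range = c(0.7, 1.3), noise_sigma = 10) {
  if (!length(dataset)) stop("augment_dataset: empty dataset")
  policy <- match.arg(policy, AUG_METHODS, several.ok = TRUE)
  set.seed(seed)
  n <- length(dataset)
  methods <- sample(policy, n, replace = TRUE)
  bf <- stats::runif(n, brightness_range[1L], brightness_range[2L])
  sc <- stats::runif(n, scale_range[1L], scale_range[2L])
  sub_seeds <- sample.int(.Machine$integer.max, n)
  out <- vector("list", 2L * n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    it <- dataset[[i]]
    spec <- augment_spec(methods[i], brightness_factor = bf[i],
                         scale_s = sc[i], noise_sigma = noise_sigma,
                         seed = sub_seeds[i])
    H <- dim(it$image)[1L]; W <- dim(it$image)[2L]
    out[[i]] <- it
    out[[n + i]] <- list(id = paste0(it$id, "_aug"),
                         image = transform_image(it$image, spec),
                         labels = transform_labels(it$labels, spec, W, H),
                         source = it$id, spec = spec)
    man[[i]] <- data.frame(
      id = paste0(it$id, "_aug"), source = it$id, method = methods[i],
      brightness_factor = if (methods[i] == "brightness") bf[i] else NA,
      scale_s = if (methods[i] == "scale") sc[i] else NA,
      noise_sigma = if (methods[i] == "gauss_noise") noise_sigma else NA,
      seed = sub_seeds[i], stringsAsFactors = FALSE)
  }
  list(items = out, manifest = do.call(rbind, man))
}
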