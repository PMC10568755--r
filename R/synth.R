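# Synthetic seed-plate generator: a grid of roughly elliptical seeds on a
# paper-like background, sprouts drawn as curved strokes whose length
# relative to the seed determines the class (germinated once germ length
# reaches half the seed length), root-like clutter, and brightness
# variation. Appearance is chosen for controllability, not realism.

#' Synthetic plate specification
#'
#' @param grid integer vector `c(rows, cols)` of seed positions (the default
#'   6 x 6 gives the 36-seed plate layout used in germination trials).
#' @param img_size square image size in pixels.
#' @param seed_axes range of the seed ellipse semi-major axis, pixels.
#' @param sprout_prob_by_day per-day germination hazard: probability that a
#'   still-ungerminated seed germinates on each day. Recycled/truncated to
#'   the simulated horizon.
#' @param sprout_len_ratio range of germ length / seed length on the
#'   germination day (must start at or above the 0.5 criterion).
#' @param growth_per_day range of the daily increment of that ratio after
#'   germination.
#' @param clutter_density number of root-like clutter curves per image.
#' @param brightness_jitter per-day global brightness factor range.
#' @param seed integer RNG seed.
#' @return a `plate_spec` list.
#' @export
plate_spec <- function(grid = c(6L, 6L), img_size = 320L,
                       seed_axes = NULL,
                       sprout_prob_by_day = c(0, 0.4, 0.35, 0.3, 0.2),
                       sprout_len_ratio = c(0.55, 0.75),
                       growth_per_day = c(0.15, 0.3),
                       clutter_density = 6L,
                       brightness_jitter = c(0.92, 1.08),
                       seed = 1L) {
  stopifnot(length(grid) == 2L, all(grid >= 1L))
  if (prod(grid) > 126L)
    stop("plate_spec: more than 126 seeds per plate is out of scale")
  if (any(sprout_prob_by_day < 0) || any(sprout_prob_by_day > 1))
    stop("plate_spec: probabilities must be in [0, 1]")
  if (sprout_len_ratio[1L] < 0.5)
    stop("plate_spec: sprout_len_ratio must start at or above the 0.5 criterion")
  cell <- img_size / max(grid)
  if (is.null(seed_axes)) seed_axes <- c(0.16, 0.22) * cell
  if (2 * max(seed_axes) > cell)
    stop("plate_spec: grid too dense for the seed size")
  structure(list(grid = as.integer(grid), img_size = as.integer(img_size),
                 seed_axes = seed_axes,
                 sprout_prob_by_day = sprout_prob_by_day,
                 sprout_len_ratio = sprout_len_ratio,
                 growth_per_day = growth_per_day,
                 clutter_density = as.integer(clutter_density),
                 brightness_jitter = brightness_jitter,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

#' Generate a per-day synthetic plate image series with ground truth
#'
#' One image per day. Seeds keep their position across days; germs grow
#' monotonically and a seed's label flips to `sprout` on exactly the day its
#' germ length crosses half the seed length. Bounding boxes enclose the seed
#' plus the visible germ. Deterministic under `spec$seed`.
#'
#' @param spec a [plate_spec()].
#' @param n_days number of days (>= 1).
#' @return list with `images` (list of (H, W, 3) arrays), `labels` (list of
#'   [box_labels()], one per day), `events` (data frame: seed id, grid cell,
#'   germination day, `NA` if never), and `layout` (data frame of seed
#'   centers, used by [series_from_detections()]).
#' @export
generate_plate_series <- function(spec, n_days = 5L) {
  stopifnot(inherits(spec, "plate_spec"), n_days >= 1L)
  set.seed(spec$seed)
  sz <- spec$img_size
  rows <- spec$grid[1L]; cols <- spec$grid[2L]
  cell_h <- sz / rows; cell_w <- sz / cols
  n <- rows * cols

  haz <- rep_len(spec$sprout_prob_by_day, n_days)
  seeds <- vector("list", n)
  ev_day <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% cols + 1L; cl <- (i - 1L) %% cols + 1L
    a <- stats::runif(1, spec$seed_axes[1L], spec$seed_axes[2L])
    b <- a * stats::runif(1, 0.72, 0.9)
    cx <- (cl - 0.5) * cell_w + stats::runif(1, -0.08, 0.08) * cell_w
    cy <- (r - 0.5) * cell_h + stats::runif(1, -0.08, 0.08) * cell_h
    day <- NA_integer_
    for (t in seq_len(n_days)) if (stats::runif(1) < haz[t]) { day <- t; break }
    ev_day[i] <- day
    seeds[[i]] <- list(
      id = i, row = r, col = cl, cx = cx, cy = cy, a = a, b = b,
      angle = stats::runif(1, 0, pi),
      germ_dir = stats::runif(1, 0, 2 * pi),
      germ_bend = stats::runif(1, -0.6, 0.6),
      r0 = stats::runif(1, spec$sprout_len_ratio[1L], spec$sprout_len_ratio[2L]),
      growth = stats::runif(1, spec$growth_per_day[1L], spec$growth_per_day[2L]),
      nub = stats::runif(1, 0.15, 0.35),
      day = day)
  }

  clutter <- lapply(seq_len(spec$clutter_density), function(j) {
    p0 <- stats::runif(2, 0, sz)
    p2 <- stats::runif(2, 0, sz)
    p1 <- (p0 + p2) / 2 + stats::rnorm(2, 0, sz / 6)
    list(p0 = p0, p1 = p1, p2 = p2)
  })
  bright <- stats::runif(n_days, spec$brightness_jitter[1L],
                         spec$brightness_jitter[2L])
  # smooth paper texture, fixed across days
  texture <- smooth_noise(sz, seed = spec$seed + 1L)

  images <- vector("list", n_days)
  labels <- vector("list", n_days)
  for (t in seq_len(n_days)) {
    img <- array(rep(150 + 14 * texture, 3L), c(sz, sz, 3L))
    img[, , 1] <- img[, , 1] * 1.02
    img[, , 3] <- img[, , 3] * 0.96
    for (cu in clutter) img <- draw_stroke(img, cu$p0, cu$p1, cu$p2,
                                           width = 1.2,
                                           col = c(104, 88, 70))
    lab <- list()
    for (s in seeds) {
      ratio <- germ_ratio(s, t)
      seed_len <- 2 * s$a
      img <- draw_ellipse(img, s$cx, s$cy, s$a, s$b, s$angle,
                          col = c(212, 192, 138))
      gbox <- NULL
      if (ratio > 0) {
        glen <- ratio * seed_len
        g <- germ_points(s, glen)
        img <- draw_stroke(img, g$p0, g$p1, g$p2, width = 2,
                           col = c(252, 248, 200))
        gbox <- g$bbox
      }
      bb <- ellipse_bbox(s)
      if (!is.null(gbox))
        bb <- c(min(bb[1L], gbox[1L]), min(bb[2L], gbox[2L]),
                max(bb[3L], gbox[3L]), max(bb[4L], gbox[4L]))
      bb <- pmin(pmax(bb, 0), sz)
      lab[[length(lab) + 1L]] <- data.frame(
        cls = if (ratio >= 0.5) "sprout" else "not_sprout",
        x1 = bb[1L], y1 = bb[2L], x2 = bb[3L], y2 = bb[4L],
        stringsAsFactors = FALSE)
    }
    images[[t]] <- clamp255(img * bright[t])
    labels[[t]] <- as_box_labels(do.call(rbind, lab))
  }

  layout <- do.call(rbind, lapply(seeds, function(s)
    data.frame(seed_id = s$id, row = s$row, col = s$col, cx = s$cx, cy = s$cy)))
  events <- data.frame(seed_id = seq_len(n),
                       row = layout$row, col = layout$col,
                       day = ev_day)
  list(images = images, labels = labels, events = events, layout = layout,
       spec = spec)
}

# germ length / seed length on day t: 0 before the pre-emergence nub, a
# sub-criterion nub the day before germination, then >= 0.5 growing linearly
germ_ratio <- function(s, t) {
  if (is.na(s$day)) return(0)
  if (t >= s$day) return(s$r0 + s$growth * (t - s$day))
  if (t == s$day - 1L) return(s$nub)
  0
}

smooth_noise <- function(sz, seed) {
  set.seed(seed)
  coarse <- matrix(stats::rnorm(16 * 16), 16, 16)
  idx <- pmin(pmax(ceiling(seq_len(sz) / sz * 16), 1L), 16L)
  fine <- coarse[idx, idx]
  fine + matrix(stats::rnorm(sz * sz, 0, 0.35), sz, sz)
}

ellipse_bbox <- function(s) {
  # axis-aligned bbox of a rotated ellipse
  ux <- sqrt((s$a * cos(s$angle))^2 + (s$b * sin(s$angle))^2)
  uy <- sqrt((s$a * sin(s$angle))^2 + (s$b * cos(s$angle))^2)
  c(s$cx - ux, s$cy - uy, s$cx + ux, s$cy + uy)
}

draw_ellipse <- function(img, cx, cy, a, b, angle, col) {
  sz <- dim(img)[1L]
  rr <- max(a, b) + 1
  xs <- max(1L, floor(cx - rr)):min(sz, ceiling(cx + rr))
  ys <- max(1L, floor(cy - rr)):min(sz, ceiling(cy + rr))
  if (!length(xs) || !length(ys)) return(img)
  gx <- outer(rep(1, length(ys)), xs - 0.5) - cx
  gy <- outer(ys - 0.5, rep(1, length(xs))) - cy
  xr <- gx * cos(angle) + gy * sin(angle)
  yr <- -gx * sin(angle) + gy * cos(angle)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  if (!any(inside)) return(img)
  speckle <- matrix(stats::runif(length(inside), 0.88, 1.08),
                    nrow(inside), ncol(inside))
  for (ch in 1:3) {
    sl <- img[ys, xs, ch]
    sl[inside] <- col[ch] * speckle[inside]
    img[ys, xs, ch] <- sl
  }
  img
}

# quadratic Bezier control points for a germ anchored at the seed edge
germ_points <- function(s, glen) {
  dir <- s$germ_dir
  edge <- c(s$cx + s$a * cos(dir) * 0.9, s$cy + s$a * sin(dir) * 0.9)
  tip <- edge + glen * c(cos(dir), sin(dir))
  normal <- c(-sin(dir), cos(dir))
  mid <- (edge + tip) / 2 + s$germ_bend * glen * normal / 2
  pts <- bezier_pts(edge, mid, tip)
  list(p0 = edge, p1 = mid, p2 = tip,
       bbox = c(min(pts[, 1L]), min(pts[, 2L]), max(pts[, 1L]), max(pts[, 2L])))
}

bezier_pts <- function(p0, p1, p2, n = 40L) {
  tt <- seq(0, 1, length.out = n)
  cbind((1 - tt)^2 * p0[1L] + 2 * (1 - tt) * tt * p1[1L] + tt^2 * p2[1L],
        (1 - tt)^2 * p0[2L] + 2 * (1 - tt) * tt * p1[2L] + tt^2 * p2[2L])
}

draw_stroke <- function(img, p0, p1, p2, width, col) {
  sz <- dim(img)[1L]
  pts <- bezier_pts(p0, p1, p2, n = max(12L, ceiling(4 * sum(abs(p2 - p0)))))
  px <- unique(data.frame(x = round(pts[, 1L]), y = round(pts[, 2L])))
  w <- ceiling(width)
  off <- expand.grid(dx = -w:w, dy = -w:w)
  off <- off[off$dx^2 + off$dy^2 <= width^2 + 0.5, ]
  for (i in seq_len(nrow(px))) {
    xs <- px$x[i] + off$dx; ys <- px$y[i] + off$dy
    ok <- xs >= 1 & xs <= sz & ys >= 1 & ys <= sz
    if (!any(ok)) next
    for (ch in 1:3)
      img[cbind(ys[ok], xs[ok], ch)] <- col[ch]
  }
  img
}

#' Write a synthetic image as PNG
#'
#' @param image numeric array (H, W, 3) in `[0, 255]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read an image file into the (H, W, 3) array convention
#'
#' @param path PNG file.
#' @return numeric array (H, W, 3), values in `[0, 255]`.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  x[, , 1:3, drop = FALSE] * 255
}
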