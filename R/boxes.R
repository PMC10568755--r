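# Bounding-box labels. Coordinates are 0-based pixel corners in the image
# frame (x right, y down), half-open on the far edge: 0 <= x1 < x2 <= W.

SNET_CLASSES <- c("not_sprout", "sprout")

#' Bounding-box labels
#'
#' One row per annotated seed: class (`not_sprout`/`sprout`) and corner
#' coordinates `(x1, y1)` top-left, `(x2, y2)` bottom-right, 0-based pixels.
#'
#' @param cls character vector of class names (or integer ids 0/1).
#' @param x1,y1,x2,y2 numeric corner coordinates.
#' @return a `box_labels` data frame.
#' @export
box_labels <- function(cls = character(), x1 = numeric(), y1 = numeric(),
                       x2 = numeric(), y2 = numeric()) {
  if (is.numeric(cls)) cls <- SNET_CLASSES[cls + 1L]
  stopifnot(all(cls %in% SNET_CLASSES),
            length(cls) == length(x1), length(x1) == length(y1),
            length(y1) == length(x2), length(x2) == length(y2))
  if (any(x1 >= x2) || any(y1 >= y2))
    stop("box_labels: corners must satisfy x1 < x2 and y1 < y2")
  structure(data.frame(cls = cls, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                       stringsAsFactors = FALSE),
            class = c("box_labels", "data.frame"))
}

as_box_labels <- function(df) {
  structure(as.data.frame(df), class = c("box_labels", "data.frame"))
}

empty_boxes <- function() box_labels()

#' Pairwise intersection-over-union of two box sets
#'
#' @param a,b `box_labels` (or data frames with `x1,y1,x2,y2`).
#' @return a `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
box_iou <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  ix1 <- outer(a$x1, b$x1, pmax); iy1 <- outer(a$y1, b$y1, pmax)
  ix2 <- outer(a$x2, b$x2, pmin); iy2 <- outer(a$y2, b$y2, pmin)
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  aa <- (a$x2 - a$x1) * (a$y2 - a$y1)
  ab <- (b$x2 - b$x1) * (b$y2 - b$y1)
  inter / (outer(aa, ab, "+") - inter)
}

# normalized center format (class cx cy w h) <-> corner format
boxes_to_yolo <- function(boxes, W, H) {
  data.frame(cls = match(boxes$cls, SNET_CLASSES) - 1L,
             cx = (boxes$x1 + boxes$x2) / 2 / W,
             cy = (boxes$y1 + boxes$y2) / 2 / H,
             w = (boxes$x2 - boxes$x1) / W,
             h = (boxes$y2 - boxes$y1) / H)
}

yolo_to_boxes <- function(df, W, H) {
  box_labels(cls = SNET_CLASSES[df$cls + 1L],
             x1 = (df$cx - df$w / 2) * W, y1 = (df$cy - df$h / 2) * H,
             x2 = (df$cx + df$w / 2) * W, y2 = (df$cy + df$h / 2) * H)
}

clip_boxes <- function(boxes, W, H, warn = TRUE) {
  if (!nrow(boxes)) return(boxes)
  boxes$x1 <- pmin(pmax(boxes$x1, 0), W); boxes$x2 <- pmin(pmax(boxes$x2, 0), W)
  boxes$y1 <- pmin(pmax(boxes$y1, 0), H); boxes$y2 <- pmin(pmax(boxes$y2, 0), H)
  keep <- boxes$x2 - boxes$x1 > 0 & boxes$y2 - boxes$y1 > 0
  if (any(!keep) && warn)
    warning(sum(!keep), " degenerate box(es) dropped after transform")
  as_box_labels(boxes[keep, , drop = FALSE])
}
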