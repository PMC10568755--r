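# Annotation readers/writers: Pascal-VOC XML (the LabelImg dialect) and YOLO
# txt (class cx cy w h, normalized to the image size).

#' Read bounding-box labels
#'
#' @param path annotation file.
#' @param dialect `"voc_xml"` or `"yolo_txt"`.
#' @param W,H image size in pixels (required for `yolo_txt`, whose
#'   coordinates are normalized; read from the file for `voc_xml`).
#' @return a [box_labels()] data frame; empty files give zero rows.
#' @export
read_labels <- function(path, dialect = c("voc_xml", "yolo_txt"),
                        W = NULL, H = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_labels: no such file: ", path)
  if (dialect == "voc_xml") read_voc_xml(path) else read_yolo_txt(path, W, H)
}

#' Write bounding-box labels
#'
#' @param labels a [box_labels()] data frame.
#' @param path output file.
#' @param dialect `"voc_xml"` or `"yolo_txt"`.
#' @param W,H image size in pixels.
#' @param image_name image filename recorded in the VOC header.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, dialect = c("voc_xml", "yolo_txt"),
                         W, H, image_name = "image.png") {
  dialect <- match.arg(dialect)
  if (dialect == "voc_xml") write_voc_xml(labels, path, W, H, image_name)
  else write_yolo_txt(labels, path, W, H)
  invisible(path)
}

read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("read_labels: malformed XML in ",
                                           path, ": ", conditionMessage(e)))
  objs <- xml2::xml_find_all(doc, ".//object")
  if (!length(objs)) return(empty_boxes())
  get_num <- function(o, q) {
    node <- xml2::xml_find_first(o, q)
    if (is.na(node))
      stop("read_labels: missing <", q, "> element in ", path)
    as.numeric(xml2::xml_text(node))
  }
  box_labels(
    cls = vapply(objs, function(o)
      xml2::xml_text(xml2::xml_find_first(o, ".//name")), ""),
    x1 = vapply(objs, get_num, 0, ".//bndbox/xmin"),
    y1 = vapply(objs, get_num, 0, ".//bndbox/ymin"),
    x2 = vapply(objs, get_num, 0, ".//bndbox/xmax"),
    y2 = vapply(objs, get_num, 0, ".//bndbox/ymax"))
}

write_voc_xml <- function(labels, path, W, H, image_name) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", image_name)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(W))
  xml2::xml_add_child(size, "height", as.character(H))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(labels))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", labels$cls[i])
    xml2::xml_add_child(o, "difficult", "0")
    b <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(b, "xmin", format(labels$x1[i], scientific = FALSE))
    xml2::xml_add_child(b, "ymin", format(labels$y1[i], scientific = FALSE))
    xml2::xml_add_child(b, "xmax", format(labels$x2[i], scientific = FALSE))
    xml2::xml_add_child(b, "ymax", format(labels$y2[i], scientific = FALSE))
  }
  xml2::write_xml(doc, path)
}

read_yolo_txt <- function(path, W, H) {
  if (is.null(W) || is.null(H))
    stop("read_labels: yolo_txt needs the image size (W, H)")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 5L)
  if (length(bad))
    stop("read_labels: line ", bad[1L], " of ", path,
         " has fewer than 5 fields")
  num <- lapply(parts, function(p) suppressWarnings(as.numeric(p[1:5])))
  bad <- which(vapply(num, function(v) any(is.na(v)), TRUE))
  if (length(bad))
    stop("read_labels: line ", bad[1L], " of ", path, " is not numeric")
  df <- do.call(rbind, num)
  yolo_to_boxes(data.frame(cls = as.integer(df[, 1L]), cx = df[, 2L],
                           cy = df[, 3L], w = df[, 4L], h = df[, 5L]), W, H)
}

write_yolo_txt <- function(labels, path, W, H, conf = NULL) {
  y <- boxes_to_yolo(labels, W, H)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", y$cls, y$cx, y$cy, y$w, y$h)
  if (!is.null(conf)) lines <- paste(lines, sprintf("%.4f", conf))
  writeLines(lines, path)
}

#' Split items into train/validation/test manifests
#'
#' Deterministic random split at the given ratios (3:1:1 by default), using
#' largest-remainder rounding so the sizes are exact. With `by` supplied
#' (e.g. a plate identifier per item), all items sharing a value are kept in
#' the same split, which avoids temporal leakage across a plate's day
#' series.
#'
#' @param items character vector (or anything indexable) of item ids.
#' @param ratios numeric vector of three weights, normalized internally.
#' @param seed integer RNG seed.
#' @param by optional grouping vector, same length as `items`.
#' @return named list of three vectors: `train`, `val`, `test`.
#' @export
split_dataset <- function(items, ratios = c(3, 1, 1), seed = 1L, by = NULL) {
  stopifnot(length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  n <- length(items)
  units <- if (is.null(by)) seq_len(n) else match(by, unique(by))
  nu <- length(unique(units))
  if (nu < sum(ratios > 0)) stop("split_dataset: fewer items than splits")
  p <- ratios / sum(ratios)
  # largest-remainder apportioning of the units
  quota <- nu * p
  sizes <- floor(quota)
  rem <- order(quota - sizes, decreasing = TRUE)
  short <- nu - sum(sizes)
  if (short > 0) sizes[rem[seq_len(short)]] <- sizes[rem[seq_len(short)]] + 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample(unique(units))
  grp <- rep(3L, nu)
  grp[perm[seq_len(sizes[1L])]] <- 1L
  if (sizes[2L] > 0) grp[perm[sizes[1L] + seq_len(sizes[2L])]] <- 2L
  assign_split <- grp[units]
  list(train = items[assign_split == 1L],
       val = items[assign_split == 2L],
       test = items[assign_split == 3L])
}
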