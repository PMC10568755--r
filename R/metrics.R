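# Detection evaluation: greedy matching, precision/recall, all-point
# interpolated AP, mAP@0.5, and class-wise non-maximum suppression.

#' Detection records
#'
#' @param cls character vector of class names.
#' @param x1,y1,x2,y2 box corners, pixels.
#' @param conf confidence scores in `[0, 1]`.
#' @return a `detections` data frame.
#' @export
detection_records <- function(cls = character(), x1 = numeric(),
                              y1 = numeric(), x2 = numeric(), y2 = numeric(),
                              conf = numeric()) {
  if (length(conf) && (any(conf < 0) || any(conf > 1)))
    stop("detection_records: conf must be in [0, 1]")
  structure(data.frame(cls = cls, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                       conf = conf, stringsAsFactors = FALSE),
            class = c("detections", "data.frame"))
}

#' Match predictions to ground truth and tally TP/FP/FN
#'
#' Greedy confidence-descending one-to-one matching within each class at
#' IoU >= `iou_thr`. Unmatched predictions are false positives, unmatched
#' truths false negatives.
#'
#' @param predictions a [detection_records()] data frame.
#' @param truths a [box_labels()] data frame.
#' @param iou_thr IoU threshold in (0, 1).
#' @return list with `tp`, `fp`, `fn` and `outcomes` (per-prediction logical
#'   TP flags in confidence order, with class and confidence, for PR
#'   curves).
#' @export
match_and_count <- function(predictions, truths, iou_thr = 0.5) {
  stopifnot(iou_thr > 0, iou_thr < 1)
  if (!nrow(predictions))
    return(list(tp = 0L, fp = 0L, fn = nrow(truths),
                outcomes = data.frame(cls = character(), conf = numeric(),
                                      tp = logical())))
  ord <- order(-predictions$conf)
  preds <- predictions[ord, , drop = FALSE]
  used <- rep(FALSE, nrow(truths))
  tp_flag <- rep(FALSE, nrow(preds))
  if (nrow(truths)) {
    iou <- box_iou(preds, truths)
    for (i in seq_len(nrow(preds))) {
      cand <- which(!used & truths$cls == preds$cls[i] &
                      iou[i, ] >= iou_thr)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        tp_flag[i] <- TRUE
      }
    }
  }
  list(tp = sum(tp_flag), fp = sum(!tp_flag), fn = sum(!used),
       outcomes = data.frame(cls = preds$cls, conf = preds$conf, tp = tp_flag,
                             stringsAsFactors = FALSE))
}

#' Precision and recall from tallies
#'
#' `0/0` is defined as 0 (an empty prediction set early in training has
#' precision 0, not NaN); a message notes when that rule fires.
#'
#' @param tallies list with `tp`, `fp`, `fn` (from [match_and_count()]).
#' @return named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(tallies) {
  tp <- tallies$tp; fp <- tallies$fp; fn <- tallies$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0 || tp + fn == 0)
    message("precision_recall: 0/0 defined as 0")
  c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Average precision by all-point interpolation
#'
#' Integrates the precision envelope over recall from the ranked outcome
#' list of one class.
#'
#' @param tp_flags logical vector of per-prediction outcomes, already in
#'   descending-confidence order.
#' @param n_truth number of ground-truth boxes of the class.
#' @return AP in `[0, 1]`.
#' @export
ap <- function(tp_flags, n_truth) {
  if (n_truth == 0L) return(0)
  if (!length(tp_flags)) return(0)
  tp_cum <- cumsum(tp_flags)
  fp_cum <- cumsum(!tp_flags)
  recall <- tp_cum / n_truth
  precision <- tp_cum / (tp_cum + fp_cum)
  # precision envelope (non-increasing from the right), then integrate
  r <- c(0, recall, 1)
  p <- c(0, precision, 0)
  for (i in (length(p) - 1L):1L) p[i] <- max(p[i], p[i + 1L])
  idx <- which(r[-1L] != r[-length(r)])
  sum((r[idx + 1L] - r[idx]) * p[idx + 1L])
}

#' Evaluate detections over a dataset: AP per class and mAP@0.5
#'
#' @param predictions list of [detection_records()], one per image.
#' @param truths list of [box_labels()], one per image (same order).
#' @param iou_thr IoU threshold.
#' @return list with `ap_per_class`, `map50`, `precision`, `recall`,
#'   `pr_curves` (per-class ranked PR point lists).
#' @export
evaluate_detections <- function(predictions, truths, iou_thr = 0.5) {
  stopifnot(length(predictions) == length(truths))
  outs <- list(); tp <- fp <- fn <- 0L
  for (i in seq_along(predictions)) {
    mc <- match_and_count(predictions[[i]], truths[[i]], iou_thr)
    outs[[i]] <- mc$outcomes
    tp <- tp + mc$tp; fp <- fp + mc$fp; fn <- fn + mc$fn
  }
  all_out <- do.call(rbind, outs)
  n_truth <- table(factor(unlist(lapply(truths, function(t) t$cls)),
                          levels = SNET_CLASSES))
  ap_per_class <- stats::setNames(numeric(length(SNET_CLASSES)), SNET_CLASSES)
  pr_curves <- list()
  for (cl in SNET_CLASSES) {
    sub <- all_out[all_out$cls == cl, , drop = FALSE]
    sub <- sub[order(-sub$conf), , drop = FALSE]
    ap_per_class[cl] <- ap(sub$tp, as.integer(n_truth[cl]))
    tp_cum <- cumsum(sub$tp); fp_cum <- cumsum(!sub$tp)
    pr_curves[[cl]] <- data.frame(
      conf = sub$conf,
      recall = if (n_truth[cl] > 0) tp_cum / as.integer(n_truth[cl]) else 0 * tp_cum,
      precision = ifelse(tp_cum + fp_cum > 0, tp_cum / (tp_cum + fp_cum), 0))
  }
  present <- as.integer(n_truth) > 0
  pr <- suppressMessages(precision_recall(list(tp = tp, fp = fp, fn = fn)))
  list(ap_per_class = ap_per_class,
       map50 = if (any(present)) mean(ap_per_class[present]) else 0,
       precision = pr[["precision"]], recall = pr[["recall"]],
       pr_curves = pr_curves)
}

#' Mean average precision over classes
#'
#' @param per_class numeric vector of per-class AP values.
#' @return their unweighted mean.
#' @export
map50 <- function(per_class) mean(per_class)

#' Class-wise greedy non-maximum suppression
#'
#' @param detections a [detection_records()] data frame.
#' @param iou_thr suppression IoU threshold (0.65 by default, the value
#'   used for evaluation here).
#' @return the surviving detections, confidence-sorted.
#' @export
nms <- function(detections, iou_thr = 0.65) {
  if (!nrow(detections)) return(detections)
  keep_all <- list()
  for (cl in unique(detections$cls)) {
    d <- detections[detections$cls == cl, , drop = FALSE]
    d <- d[order(-d$conf), , drop = FALSE]
    keep <- logical(nrow(d))
    alive <- rep(TRUE, nrow(d))
    iou <- box_iou(d, d)
    for (i in seq_len(nrow(d))) {
      if (!alive[i]) next
      keep[i] <- TRUE
      alive[iou[i, ] > iou_thr] <- FALSE
      alive[i] <- FALSE
    }
    keep_all[[cl]] <- d[keep, , drop = FALSE]
  }
  out <- do.call(rbind, keep_all)
  out <- out[order(-out$conf), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("detections", "data.frame"))
}
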