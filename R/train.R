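# Desk-scale training and inference. The detector is anchor-free: each
# feature-map cell predicts a discrete distribution over reg_max bins for
# the four box-side distances (distribution focal representation) plus
# per-class logits. The smoke trainer optimizes the final 1x1 prediction
# convolutions on frozen backbone/neck/branch features (a linear probe)
# with the composite BCE + CIoU + DFL loss and the Adam update -- enough to
# verify end-to-end learning at desk scale without a full backprop engine.

## ---- decoding --------------------------------------------------------------

# anchor centers of an (h, w) grid at a given stride, 0-based pixel frame
anchor_centers <- function(h, w, stride) {
  gx <- (seq_len(w) - 0.5) * stride
  gy <- (seq_len(h) - 0.5) * stride
  list(cx = rep(gx, each = h), cy = rep(gy, times = w))  # column-major order
}

dfl_expect <- function(logits, reg_max) {
  # logits: (4*reg_max, n) -> expected distances (4, n)
  bins <- 0:(reg_max - 1L)
  out <- matrix(0, 4L, ncol(logits))
  for (s in 1:4) {
    z <- logits[(s - 1L) * reg_max + seq_len(reg_max), , drop = FALSE]
    z <- exp(sweep(z, 2L, apply(z, 2L, max), "-"))
    p <- sweep(z, 2L, colSums(z), "/")
    out[s, ] <- colSums(p * bins)
  }
  out
}

#' Decode raw prediction maps into detection records
#'
#' Converts the three per-level prediction maps (distribution-focal box
#' logits + class logits) of a single image into boxes with class
#' confidences, then applies class-wise NMS.
#'
#' @param preds list of three `(1, 4*reg_max + nc, H, W)` arrays from
#'   [forward()] on a model.
#' @param strides integer vector of level strides (8, 16, 32).
#' @param num_classes,reg_max head layout.
#' @param conf_thr minimum class confidence.
#' @param iou_thr NMS threshold.
#' @return a [detection_records()] data frame.
#' @export
decode_predictions <- function(preds, strides = c(8L, 16L, 32L),
                               num_classes = 2L, reg_max = 16L,
                               conf_thr = 0.25, iou_thr = 0.65) {
  rows <- list()
  for (i in seq_along(preds)) {
    p4 <- feature_map(preds[[i]])
    d <- dim(p4)[2:4]
    p <- array(p4[1L, , , ], d)
    h <- d[2L]; w <- d[3L]
    flat <- matrix(p, d[1L], h * w)
    dist <- dfl_expect(flat[seq_len(4L * reg_max), , drop = FALSE], reg_max)
    cls <- sigmoid_(flat[4L * reg_max + seq_len(num_classes), , drop = FALSE])
    an <- anchor_centers(h, w, strides[i])
    x1 <- an$cx - dist[1L, ] * strides[i]
    y1 <- an$cy - dist[2L, ] * strides[i]
    x2 <- an$cx + dist[3L, ] * strides[i]
    y2 <- an$cy + dist[4L, ] * strides[i]
    for (ci in seq_len(num_classes)) {
      keep <- which(cls[ci, ] >= conf_thr & x2 > x1 & y2 > y1)
      if (length(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          cls = SNET_CLASSES[ci], x1 = x1[keep], y1 = y1[keep],
          x2 = x2[keep], y2 = y2[keep], conf = cls[ci, keep],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(detection_records())
  out <- do.call(rbind, rows)
  nms(structure(out, class = c("detections", "data.frame")), iou_thr)
}

#' Run the detector on one image
#'
#' @param model an `snet_model`.
#' @param image numeric array (H, W, 3) in `[0, 255]`; resized to `imgsz`.
#' @param imgsz square inference size (divisible by 32).
#' @param conf_thr,iou_thr decoding thresholds.
#' @return [detection_records()] in the original image frame.
#' @export
detect_objects <- function(model, image, imgsz = 96L, conf_thr = 0.25,
                           iou_thr = 0.65) {
  H <- dim(image)[1L]; W <- dim(image)[2L]
  x <- resize_image(image, imgsz, imgsz) / 255
  x4 <- array(aperm(x, c(3L, 1L, 2L)), c(1L, 3L, imgsz, imgsz))
  preds <- forward(model, x4)
  det <- decode_predictions(preds, model$strides,
                            model$config$num_classes,
                            model$config$reg_max, conf_thr, iou_thr)
  if (nrow(det)) {
    det$x1 <- det$x1 / imgsz * W; det$x2 <- det$x2 / imgsz * W
    det$y1 <- det$y1 / imgsz * H; det$y2 <- det$y2 / imgsz * H
  }
  det
}

## ---- target assignment -----------------------------------------------------

# center-region assigner: at the size-matched level, every cell whose
# center lies inside a ground-truth box is a positive for that box and
# regresses its own anchor-relative edge distances; duplicate decoded boxes
# are later merged by NMS
assign_targets <- function(truths, imgsz, strides = c(8L, 16L, 32L)) {
  if (!nrow(truths)) return(NULL)
  md <- pmax(truths$x2 - truths$x1, truths$y2 - truths$y1)
  rows <- list()
  for (i in seq_len(nrow(truths))) {
    l <- if (md[i] < 4 * strides[1L]) 1L else if (md[i] < 4 * strides[2L]) 2L else 3L
    s <- strides[l]
    ncell <- imgsz %/% s
    gxs <- floor(truths$x1[i] / s):floor((truths$x2[i] - 1e-9) / s)
    gys <- floor(truths$y1[i] / s):floor((truths$y2[i] - 1e-9) / s)
    gxs <- gxs[gxs >= 0 & gxs < ncell]; gys <- gys[gys >= 0 & gys < ncell]
    # center sampling: positives are cells whose center falls in the middle
    # 60% of the box, which keeps decoded duplicates near-identical so NMS
    # merges them
    shr <- 0.3
    bw <- truths$x2[i] - truths$x1[i]; bh <- truths$y2[i] - truths$y1[i]
    sx1 <- truths$x1[i] + shr * bw; sx2 <- truths$x2[i] - shr * bw
    sy1 <- truths$y1[i] + shr * bh; sy2 <- truths$y2[i] - shr * bh
    ctr_gx <- floor((truths$x1[i] + bw / 2) / s)
    ctr_gy <- floor((truths$y1[i] + bh / 2) / s)
    for (gx in gxs) for (gy in gys) {
      cx <- (gx + 0.5) * s; cy <- (gy + 0.5) * s
      if ((cx <= sx1 || cx >= sx2 || cy <= sy1 || cy >= sy2) &&
          !(gx == ctr_gx && gy == ctr_gy)) next
      rows[[length(rows) + 1L]] <- data.frame(
        level = l, gx = gx, gy = gy,
        cls = match(truths$cls[i], SNET_CLASSES),
        x1 = truths$x1[i], y1 = truths$y1[i],
        x2 = truths$x2[i], y2 = truths$y2[i])
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  # drop duplicate anchor claims (first, i.e. arbitrary-but-stable, wins)
  key <- paste(out$level, out$gx, out$gy)
  out[!duplicated(key), , drop = FALSE]
}

## ---- CIoU ------------------------------------------------------------------

ciou <- function(a, b) {
  # a, b: c(x1, y1, x2, y2)
  iw <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  ih <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- iw * ih
  aa <- (a[3L] - a[1L]) * (a[4L] - a[2L])
  ab <- (b[3L] - b[1L]) * (b[4L] - b[2L])
  iou <- inter / (aa + ab - inter + 1e-9)
  cw <- max(a[3L], b[3L]) - min(a[1L], b[1L])
  chh <- max(a[4L], b[4L]) - min(a[2L], b[2L])
  c2 <- cw^2 + chh^2 + 1e-9
  rho2 <- ((a[1L] + a[3L]) - (b[1L] + b[3L]))^2 / 4 +
    ((a[2L] + a[4L]) - (b[2L] + b[4L]))^2 / 4
  wa <- a[3L] - a[1L]; ha <- a[4L] - a[2L]
  wb <- b[3L] - b[1L]; hb <- b[4L] - b[2L]
  v <- 4 / pi^2 * (atan(wb / (hb + 1e-9)) - atan(wa / (ha + 1e-9)))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - alpha * v
}

## ---- loss + analytic gradients for the prediction layer --------------------

softmax_cols <- function(z) {
  z <- exp(sweep(z, 2L, apply(z, 2L, max), "-"))
  sweep(z, 2L, colSums(z), "/")
}

# loss and gradients w.r.t. the box/cls prediction logits of one level
level_loss_grads <- function(box_logits, cls_logits, targets, stride, imgsz,
                             reg_max, num_classes,
                             w_box = 7.5, w_cls = 0.5, w_dfl = 1.5,
                             pos_weight = 10, ignore = NULL) {
  h <- dim(box_logits)[2L]; w <- dim(box_logits)[3L]
  bl <- matrix(box_logits, dim(box_logits)[1L], h * w)
  cl <- matrix(cls_logits, dim(cls_logits)[1L], h * w)
  an <- anchor_centers(h, w, stride)
  tgt_cls <- matrix(0, num_classes, h * w)
  gb <- matrix(0, nrow(bl), ncol(bl))
  loss_box <- 0; loss_dfl <- 0; n_pos <- 0L
  bins <- 0:(reg_max - 1L)
  if (!is.null(targets) && nrow(targets)) {
    for (k in seq_len(nrow(targets))) {
      t <- targets[k, ]
      idx <- t$gy + 1L + t$gx * h          # column-major cell index
      tgt_cls[t$cls, idx] <- 1
      n_pos <- n_pos + 1L
      cx <- an$cx[idx]; cy <- an$cy[idx]
      dtrue <- c(cx - t$x1, cy - t$y1, t$x2 - cx, t$y2 - cy) / stride
      dtrue <- pmin(pmax(dtrue, 0), reg_max - 1 - 1e-3)
      z <- matrix(bl[, idx], reg_max, 4L)
      p <- apply(z, 2L, function(col) {
        e <- exp(col - max(col)); e / sum(e)
      })
      dpred <- colSums(p * bins)
      pred_box <- c(cx - dpred[1L] * stride, cy - dpred[2L] * stride,
                    cx + dpred[3L] * stride, cy + dpred[4L] * stride)
      tbox <- c(t$x1, t$y1, t$x2, t$y2)
      lc <- 1 - ciou(pred_box, tbox)
      loss_box <- loss_box + lc
      # d(ciou loss)/d(distance) by central differences
      dld <- numeric(4L)
      eps <- 1e-3
      for (s in 1:4) {
        dp <- dpred; dp[s] <- dpred[s] + eps
        bp <- c(cx - dp[1L] * stride, cy - dp[2L] * stride,
                cx + dp[3L] * stride, cy + dp[4L] * stride)
        dm <- dpred; dm[s] <- dpred[s] - eps
        bm <- c(cx - dm[1L] * stride, cy - dm[2L] * stride,
                cx + dm[3L] * stride, cy + dm[4L] * stride)
        dld[s] <- ((1 - ciou(bp, tbox)) - (1 - ciou(bm, tbox))) / (2 * eps)
      }
      # DFL: soft two-hot cross entropy per side
      lo <- floor(dtrue); hi <- lo + 1
      wlo <- hi - dtrue; whi <- dtrue - lo
      gz <- matrix(0, reg_max, 4L)
      for (s in 1:4) {
        tdist <- numeric(reg_max)
        tdist[lo[s] + 1L] <- wlo[s]
        if (hi[s] + 1L <= reg_max) tdist[hi[s] + 1L] <- whi[s]
        loss_dfl <- loss_dfl - sum(tdist * log(p[, s] + 1e-12))
        gz[, s] <- w_dfl * (p[, s] * sum(tdist) - tdist) +
          w_box * dld[s] * p[, s] * (bins - dpred[s])
      }
      gb[, idx] <- as.vector(gz)
    }
  }
  pc <- sigmoid_(cl)
  # weighted BCE: positives are rare (a handful of seed cells against a few
  # hundred background anchors), so the positive term is up-weighted;
  # in-box anchors that are not the assigned positive carry no loss
  wmask <- matrix(1, num_classes, h * w)
  if (!is.null(ignore)) wmask[, ignore] <- 0
  wmask[tgt_cls == 1] <- 1
  loss_cls <- -sum(wmask * (pos_weight * tgt_cls * log(pc + 1e-12) +
                              (1 - tgt_cls) * log(1 - pc + 1e-12)))
  gc <- w_cls * wmask *
    (pos_weight * tgt_cls * (pc - 1) + (1 - tgt_cls) * pc)
  list(loss_box = loss_box, loss_dfl = loss_dfl, loss_cls = loss_cls,
       n_pos = n_pos, grad_box = gb, grad_cls = gc * 1)
}

## ---- checkpointing ---------------------------------------------------------

#' Save / load a training checkpoint
#'
#' The checkpoint holds the model configuration, every learnable array, and
#' (optionally) the optimizer state, so training can resume exactly.
#'
#' @param model an `snet_model`.
#' @param path file path.
#' @param optimizer optional [adam_init()] state.
#' @return `path` invisibly; `load_checkpoint()` returns a list with
#'   `model` and `optimizer`.
#' @export
save_checkpoint <- function(model, path, optimizer = NULL) {
  saveRDS(list(config = model$config, params = module_params(model),
               optimizer = optimizer), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  model <- set_model_params(model, ck$params)
  list(model = model, optimizer = ck$optimizer)
}

# write a flat named parameter list back into the module tree
set_model_params <- function(model, flat) {
  for (li in seq_along(model$layers)) {
    nm <- model$layers[[li]]$name
    pre <- paste0(nm, ".")
    sub <- flat[startsWith(names(flat), pre)]
    if (!length(sub)) next
    names(sub) <- substring(names(sub), nchar(pre) + 1L)
    model$layers[[li]]$module <- set_module_params(model$layers[[li]]$module, sub)
  }
  model
}

set_module_params <- function(m, flat) {
  for (p in names(m$params)) {
    if (p %in% names(flat)) m$params[[p]] <- flat[[p]]
  }
  for (ch in names(m$children)) {
    pre <- paste0(ch, ".")
    sub <- flat[startsWith(names(flat), pre)]
    if (!length(sub)) next
    names(sub) <- substring(names(sub), nchar(pre) + 1L)
    m$children[[ch]] <- set_module_params(m$children[[ch]], sub)
  }
  m
}

## ---- the smoke trainer -----------------------------------------------------

#' Desk-scale smoke training
#'
#' Trains the final 1x1 prediction convolutions of the detection head on
#' frozen features (a linear probe over the randomly initialized
#' backbone/neck/branches) with the standard composite detection loss --
#' binary cross-entropy for the classes, complete-IoU for the decoded
#' boxes, and distribution-focal loss for the box-side bins -- optimized by
#' [adam_step()] with a linear (optionally cosine) learning-rate decay.
#' This is not meant to reach deployment accuracy; it verifies that the
#' whole pipeline (generator, model, loss, optimizer, decoder, metrics)
#' learns: validation mAP@0.5 after training should beat the untrained
#' head.
#'
#' @param model an `snet_model` (its head layout defines the predictions).
#' @param train_items,val_items lists of items with `image` (H x W x 3) and
#'   `labels` ([box_labels()]), e.g. flattened from
#'   [generate_plate_series()].
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr0,lrf initial and final learning rate.
#' @param weight_decay L2 coefficient added to the gradients.
#' @param imgsz square training size (divisible by 32).
#' @param schedule `"linear"` or `"cosine"` decay from `lr0` to `lrf`.
#' @param seed shuffling seed.
#' @param checkpoint optional path; when set, the trained model and
#'   optimizer state are saved there.
#' @param quiet suppress per-epoch messages.
#' @return list with `model` (head updated), `history` (per-epoch data
#'   frame: loss components and validation mAP), `eval_before`,
#'   `eval_after` (validation [evaluate_detections()] results), and
#'   `optimizer` (final Adam state).
#' @export
smoke_train <- function(model, train_items, val_items = NULL, epochs = 10L,
                        batch_size = 8L, lr0 = 1e-2, lrf = 1e-4,
                        weight_decay = 1e-4, imgsz = 96L,
                        schedule = c("linear", "cosine"), seed = 1L,
                        checkpoint = NULL, quiet = FALSE) {
  schedule <- match.arg(schedule)
  if (!length(train_items)) stop("smoke_train: empty dataset")
  # the backbone is frozen with untrained BN statistics, so features are
  # extracted under training-mode (per-map) normalization
  model$bn_mode <- "instance"
  reg_max <- model$config$reg_max
  nc <- model$config$num_classes

  prep <- function(items) lapply(items, function(it) {
    H <- dim(it$image)[1L]; W <- dim(it$image)[2L]
    x <- resize_image(it$image, imgsz, imgsz) / 255
    lab <- it$labels
    if (nrow(lab)) {
      lab$x1 <- lab$x1 / W * imgsz; lab$x2 <- lab$x2 / W * imgsz
      lab$y1 <- lab$y1 / H * imgsz; lab$y2 <- lab$y2 / H * imgsz
    }
    feats <- head_features(model, array(aperm(x, c(3L, 1L, 2L)),
                                        c(1L, 3L, imgsz, imgsz)))
    list(feats = feats, labels = lab,
         targets = assign_targets(lab, imgsz, model$strides))
  })
  if (!quiet) message("caching frozen features for ", length(train_items),
                      " training images ...")
  tr <- prep(train_items)
  va <- if (length(val_items)) prep(val_items) else NULL

  # trainable parameters: the final 1x1 prediction convs, plus (for the
  # PDetect head) the 1x1 fuse conv of each branch's second PCC block
  head_idx <- length(model$layers)
  head <- model$layers[[head_idx]]$module
  deep <- identical(head$meta$kind, "pdetect")
  branches <- as.vector(outer(paste0("lv", 1:3), c("box", "cls"),
                              paste, sep = "."))
  params <- list()
  for (br in branches) {
    parts <- strsplit(br, ".", fixed = TRUE)[[1L]]
    pred <- head$children[[paste(parts[1L], paste0(parts[2L], "_pred"),
                                 sep = ".")]]
    params[[paste0(br, ".pred.weight")]] <- pred$params$weight
    params[[paste0(br, ".pred.bias")]] <- pred$params$bias
    if (deep) {
      blk <- head$children[[paste(parts[1L], paste0(parts[2L], "_b"),
                                  sep = ".")]]
      params[[paste0(br, ".fuse.weight")]] <-
        blk$children$fuse$children$conv$params$weight
    }
  }
  opt <- adam_init(params, eta = lr0)
  bn_eps <- 1e-3

  silu_grad <- function(x) {
    s <- sigmoid_(x)
    s * (1 + x * (1 - s))
  }

  # forward through the trainable slice of one branch; keeps intermediates
  branch_forward <- function(feat, lv, brn, pars) {
    key <- paste0("lv", lv, ".", brn)
    X <- feat$X
    if (deep) {
      wf <- pars[[paste0(key, ".fuse.weight")]]
      z1 <- matrix(wf, dim(wf)[1L], dim(wf)[2L]) %*% X
      mu <- rowMeans(z1)
      sdv <- sqrt(rowMeans(z1^2) - mu^2 + bn_eps)
      z2 <- (z1 - mu) / sdv
      f <- silu(z2)
    } else {
      z1 <- NULL; z2 <- NULL; sdv <- NULL
      f <- X
    }
    wp <- pars[[paste0(key, ".pred.weight")]]
    bp <- pars[[paste0(key, ".pred.bias")]]
    wpm <- matrix(wp, dim(wp)[1L], dim(wp)[2L])
    list(out = array(wpm %*% f + as.vector(bp),
                     c(dim(wp)[1L], feat$hw)),
         f = f, z2 = z2, sdv = sdv, X = X, wpm = wpm, key = key)
  }

  # gradients of the trainable slice given dL/d(prediction logits)
  branch_backward <- function(bf, G, grads) {
    grads[[paste0(bf$key, ".pred.weight")]] <-
      grads[[paste0(bf$key, ".pred.weight")]] +
      array(G %*% t(bf$f), dim(grads[[paste0(bf$key, ".pred.weight")]]))
    grads[[paste0(bf$key, ".pred.bias")]] <-
      grads[[paste0(bf$key, ".pred.bias")]] + rowSums(G)
    if (deep) {
      dF <- t(bf$wpm) %*% G
      dz2 <- dF * silu_grad(bf$z2)
      # exact instance-norm backward (gamma = 1, beta = 0)
      dz1 <- (dz2 - rowMeans(dz2) - bf$z2 * rowMeans(dz2 * bf$z2)) / bf$sdv
      grads[[paste0(bf$key, ".fuse.weight")]] <-
        grads[[paste0(bf$key, ".fuse.weight")]] +
        array(dz1 %*% t(bf$X), dim(grads[[paste0(bf$key, ".fuse.weight")]]))
    }
    grads
  }

  predict_level <- function(item, lv, pars) {
    bx <- branch_forward(item$feats[[lv]]$box, lv, "box", pars)
    cx <- branch_forward(item$feats[[lv]]$cls, lv, "cls", pars)
    list(box = bx$out, cls = cx$out, bx = bx, cx = cx,
         hw = item$feats[[lv]]$box$hw)
  }

  eval_on <- function(items, pars) {
    preds <- lapply(items, function(it) {
      maps <- lapply(1:3, function(lv) {
        pl <- predict_level(it, lv, pars)
        nb <- dim(pl$box)[1L]; ncl <- dim(pl$cls)[1L]
        arr <- array(0, c(nb + ncl, pl$hw))
        arr[seq_len(nb), , ] <- pl$box
        arr[nb + seq_len(ncl), , ] <- pl$cls
        feature_map(arr)
      })
      # maps are (1, C, H, W) after feature_map of (C,H,W)
      decode_predictions(maps, model$strides, nc, reg_max,
                         conf_thr = 0.05, iou_thr = 0.65)
    })
    evaluate_detections(preds, lapply(items, `[[`, "labels"))
  }

  eval_before <- if (!is.null(va)) eval_on(va, params) else NULL
  history <- list()
  n <- length(tr)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    frac <- if (epochs == 1L) 1 else (ep - 1) / (epochs - 1)
    lr <- if (schedule == "linear") lr0 + (lrf - lr0) * frac
          else lrf + (lr0 - lrf) * (1 + cos(pi * frac)) / 2
    ord <- sample.int(n)
    ep_loss <- c(box = 0, cls = 0, dfl = 0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      grads <- lapply(params, function(p) { p[] <- 0; p })
      for (ii in idx) {
        it <- tr[[ii]]
        for (lv in 1:3) {
          pl <- predict_level(it, lv, params)
          tg <- it$targets
          tg <- if (!is.null(tg)) tg[tg$level == lv, , drop = FALSE] else NULL
          lg <- level_loss_grads(pl$box, pl$cls, tg, model$strides[lv],
                                 imgsz, reg_max, nc)
          ep_loss <- ep_loss +
            c(lg$loss_box, lg$loss_cls, lg$loss_dfl) / length(idx)
          grads <- branch_backward(pl$bx, lg$grad_box, grads)
          grads <- branch_backward(pl$cx, lg$grad_cls, grads)
        }
      }
      for (nm in names(grads))
        grads[[nm]] <- grads[[nm]] / length(idx) + weight_decay * params[[nm]]
      st <- adam_step(opt, grads, params, eta = lr)
      params <- st$params; opt <- st$state
    }
    history[[ep]] <- data.frame(epoch = ep, lr = lr,
                                loss_box = ep_loss[["box"]],
                                loss_cls = ep_loss[["cls"]],
                                loss_dfl = ep_loss[["dfl"]])
    if (!quiet) message(sprintf(
      "epoch %d/%d lr %.2e box %.3f cls %.3f dfl %.3f", ep, epochs, lr,
      ep_loss[["box"]], ep_loss[["cls"]], ep_loss[["dfl"]]))
  }
  eval_after <- if (!is.null(va)) eval_on(va, params) else NULL

  # write the trained parameters back into the head
  for (br in branches) {
    parts <- strsplit(br, ".", fixed = TRUE)[[1L]]
    pred_nm <- paste(parts[1L], paste0(parts[2L], "_pred"), sep = ".")
    head$children[[pred_nm]]$params$weight <- params[[paste0(br, ".pred.weight")]]
    head$children[[pred_nm]]$params$bias <- params[[paste0(br, ".pred.bias")]]
    if (deep) {
      blk_nm <- paste(parts[1L], paste0(parts[2L], "_b"), sep = ".")
      head$children[[blk_nm]]$children$fuse$children$conv$params$weight <-
        params[[paste0(br, ".fuse.weight")]]
    }
  }
  model$layers[[head_idx]]$module <- head
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint, opt)
  list(model = model, history = do.call(rbind, history),
       eval_before = eval_before, eval_after = eval_after, optimizer = opt)
}
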