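# Adam, matching, PR/AP/mAP, NMS, decoding, loss gradients, checkpointing.

test_that("adam_step equals an independent reference to 1e-12", {
  theta <- c(a = 0.5, b = -1.5)
  g <- c(1, -2)
  st <- adam_init(list(p = theta), eta = 0.1)
  pars <- list(p = theta)
  for (i in 1:3) {
    out <- adam_step(st, list(p = g), pars)
    pars <- out$params; st <- out$state
  }
  ref <- reference_adam(theta, list(g, g, g), eta = 0.1)
  expect_equal(pars$p, ref, tolerance = 1e-12)
  expect_identical(st$t, 3L)
})

test_that("adam bias correction: first step moves by -eta sign(g)", {
  st <- adam_init(list(p = c(0, 0)), eta = 0.1, eps = 0)
  out <- adam_step(st, list(p = c(3, -0.01)), list(p = c(0, 0)))
  # mhat = g and vhat = g^2 exactly at t = 1, so the update is -eta sign(g)
  expect_equal(out$params$p, c(-0.1, 0.1), tolerance = 1e-12)
  # constant gradient keeps per-step updates at -eta sign(g) as eps -> 0
  pars <- list(p = 5); st <- adam_init(list(p = 5), eta = 0.01, eps = 0)
  for (i in 1:20) {
    out <- adam_step(st, list(p = 2), pars); pars <- out$params; st <- out$state
  }
  expect_equal(pars$p, 5 - 20 * 0.01, tolerance = 1e-6)
  expect_error(adam_step(st, list(p = c(1, 2)), pars), "shape")
})

test_that("match_and_count: exact cases and dual-route greedy agreement", {
  t1 <- box_labels("sprout", 0, 0, 10, 10)
  p_same <- detection_records("sprout", 0, 0, 10, 10, 0.9)
  mc <- match_and_count(p_same, t1)
  expect_identical(c(mc$tp, mc$fp, mc$fn), c(1L, 0L, 0L))
  mc0 <- match_and_count(p_same, box_labels())
  expect_identical(c(mc0$tp, mc0$fp, mc0$fn), c(0L, 1L, 0L))
  # two overlapping predictions on one truth: higher confidence wins
  p2 <- detection_records(c("sprout", "sprout"), c(0, 1), c(0, 1),
                          c(10, 11), c(10, 11), c(0.6, 0.8))
  mc2 <- match_and_count(p2, t1)
  expect_identical(c(mc2$tp, mc2$fp), c(1L, 1L))
  expect_true(mc2$outcomes$tp[1] && !mc2$outcomes$tp[2])
  expect_equal(mc2$outcomes$conf[1], 0.8)
  # random <= 6-box instances against an independent implementation
  set.seed(21)
  for (rep in 1:25) {
    np <- sample(0:6, 1); nt <- sample(1:6, 1)
    mk <- function(n) {
      x <- runif(n, 0, 40); y <- runif(n, 0, 40)
      data.frame(cls = sample(c("sprout", "not_sprout"), n, replace = TRUE),
                 x1 = x, y1 = y, x2 = x + runif(n, 4, 20),
                 y2 = y + runif(n, 4, 20), conf = runif(n),
                 stringsAsFactors = FALSE)
    }
    preds <- mk(np); truths <- mk(nt); truths$conf <- NULL
    got <- match_and_count(preds, truths, 0.4)
    ref <- reference_greedy_match(preds, truths, 0.4)
    expect_identical(c(got$tp, got$fp, got$fn), c(ref$tp, ref$fp, ref$fn))
  }
})

test_that("precision/recall ratios and the 0/0 convention", {
  pr <- precision_recall(list(tp = 8, fp = 2, fn = 0))
  expect_equal(pr[["precision"]], 0.8)
  expect_equal(pr[["recall"]], 1)
  expect_message(pr0 <- precision_recall(list(tp = 0, fp = 0, fn = 3)),
                 "0/0")
  expect_equal(pr0[["precision"]], 0)
})

test_that("AP: hand example, perfection, and duplication invariance", {
  # ranked outcomes [TP, FP, TP] against 2 truths: all-point interpolation
  # gives 0.5 * 1 + 0.5 * (2/3)
  expect_equal(ap(c(TRUE, FALSE, TRUE), 2), 0.5 + 0.5 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(ap(c(TRUE, TRUE), 2), 1)
  expect_equal(ap(logical(0), 2), 0)
  expect_equal(map50(c(0.8, 0.6)), 0.7)

  set.seed(22)
  truths <- box_labels(rep("sprout", 3), c(0, 20, 40), c(0, 0, 0),
                       c(10, 30, 50), c(10, 10, 10))
  preds <- detection_records(rep("sprout", 4), c(0, 20, 40, 60), c(0, 0, 0, 0),
                             c(10, 30, 50, 70), c(10, 10, 10, 10),
                             c(0.9, 0.8, 0.3, 0.5))
  e1 <- evaluate_detections(list(preds), list(truths))
  e2 <- evaluate_detections(list(preds, preds), list(truths, truths))
  expect_equal(e1$ap_per_class[["sprout"]], e2$ap_per_class[["sprout"]],
               tolerance = 1e-12)
  # perfect predictions give mAP exactly 1; empty predictions exactly 0
  perfect <- detection_records(truths$cls, truths$x1, truths$y1, truths$x2,
                               truths$y2, rep(1, 3))
  ep <- evaluate_detections(list(perfect), list(truths))
  expect_equal(ep$map50, 1)
  ee <- evaluate_detections(list(detection_records()), list(truths))
  expect_equal(ee$map50, 0)
})

test_that("nms matches a brute-force suppression oracle", {
  brute_nms <- function(d, thr) {
    keep <- integer()
    alive <- order(-d$conf)
    while (length(alive)) {
      i <- alive[1]
      keep <- c(keep, i)
      ious <- box_iou(d[i, , drop = FALSE], d[alive, , drop = FALSE])[1, ]
      alive <- alive[ious <= thr]
    }
    sort(keep)
  }
  two <- detection_records(c("sprout", "sprout"), c(0, 0), c(0, 0),
                           c(10, 10), c(10, 10), c(0.9, 0.8))
  out <- nms(two, 0.65)
  expect_identical(nrow(out), 1L)
  expect_equal(out$conf, 0.9)
  disj <- detection_records(c("sprout", "sprout"), c(0, 20), c(0, 0),
                            c(10, 30), c(10, 10), c(0.9, 0.8))
  expect_identical(nrow(nms(disj, 0.65)), 2L)
  set.seed(23)
  for (rep in 1:20) {
    n <- 5
    x <- runif(n, 0, 20); y <- runif(n, 0, 20)
    d <- detection_records(rep("sprout", n), x, y, x + runif(n, 5, 15),
                           y + runif(n, 5, 15), runif(n))
    got <- nms(d, 0.5)
    ref <- d[brute_nms(d, 0.5), , drop = FALSE]
    expect_identical(sort(got$conf), sort(ref$conf))
  }
})

test_that("decoding inverts a hand-built prediction map", {
  # place one box on a 2x2 stride-8 grid: cell (1,1), center (12, 12),
  # distances (1, 1, 0.5, 0.5) in stride units -> box (4, 4, 16, 16)
  reg_max <- 16
  m <- array(-20, c(1, 4 * reg_max + 2, 2, 2))
  enc <- function(d) { z <- rep(-20, reg_max)
    lo <- floor(d); z[lo + 1] <- log(1 - (d - lo) + 1e-9) + 20
    if (d > lo) z[lo + 2] <- log(d - lo) + 20
    z }
  m[1, 1:16, 2, 2] <- enc(1); m[1, 17:32, 2, 2] <- enc(1)
  m[1, 33:48, 2, 2] <- enc(0.5); m[1, 49:64, 2, 2] <- enc(0.5)
  m[1, 65, 2, 2] <- 8                      # not_sprout logit
  det <- decode_predictions(list(m,
                                 array(-20, c(1, 66, 1, 1)),
                                 array(-20, c(1, 66, 1, 1))),
                            strides = c(8, 16, 32), conf_thr = 0.25)
  expect_identical(nrow(det), 1L)
  expect_equal(as.numeric(det[1, 2:5]), c(4, 4, 16, 16), tolerance = 1e-3)
  expect_identical(det$cls, "not_sprout")
})

test_that("loss gradients match finite differences of the weighted loss", {
  set.seed(24)
  reg_max <- 8; nc <- 2; h <- 4
  box <- array(rnorm(4 * reg_max * h * h, sd = 0.5), c(4 * reg_max, h, h))
  cls <- array(rnorm(nc * h * h, sd = 0.5), c(nc, h, h))
  tg <- data.frame(level = 1, gx = c(1, 2), gy = c(1, 3), cls = c(1, 2),
                   x1 = c(9, 17), y1 = c(10, 26), x2 = c(16, 26),
                   y2 = c(17, 33))
  llg <- sproutnet:::level_loss_grads
  base <- llg(box, cls, tg, 8, 32, reg_max, nc)
  wloss <- function(b, c_) {
    l <- llg(b, c_, tg, 8, 32, reg_max, nc)
    7.5 * l$loss_box + 1.5 * l$loss_dfl + 0.5 * l$loss_cls
  }
  eps <- 1e-5
  for (probe in list(c(3, 2, 2), c(20, 2, 2), c(28, 4, 3))) {
    bp <- box; bp[probe[1], probe[2], probe[3]] <- bp[probe[1], probe[2], probe[3]] + eps
    bm <- box; bm[probe[1], probe[2], probe[3]] <- bm[probe[1], probe[2], probe[3]] - eps
    num <- (wloss(bp, cls) - wloss(bm, cls)) / (2 * eps)
    idx <- probe[2] + (probe[3] - 1) * h
    expect_equal(base$grad_box[probe[1], idx], num, tolerance = 1e-3)
  }
  for (probe in list(c(1, 2, 2), c(2, 1, 4))) {
    cp <- cls; cp[probe[1], probe[2], probe[3]] <- cp[probe[1], probe[2], probe[3]] + eps
    cm <- cls; cm[probe[1], probe[2], probe[3]] <- cm[probe[1], probe[2], probe[3]] - eps
    num <- (wloss(box, cp) - wloss(box, cm)) / (2 * eps)
    idx <- probe[2] + (probe[3] - 1) * h
    expect_equal(base$grad_cls[probe[1], idx], num, tolerance = 1e-6)
  }
})

test_that("smoke training improves validation mAP and checkpoints resume", {
  set.seed(25)
  train <- do.call(c, lapply(1:10, plate_items))    # 50 images
  val <- do.call(c, lapply(101:104, plate_items))   # 20 images
  model <- build_model(yolov8_peas_config())
  ck <- tempfile(fileext = ".rds")
  res <- smoke_train(model, train, val, epochs = 10, quiet = TRUE,
                     checkpoint = ck)
  expect_true(all(is.finite(as.matrix(res$history[, 3:5]))))
  expect_gt(res$eval_after$map50, res$eval_before$map50)
  # loss decreases over training
  expect_lt(sum(res$history[nrow(res$history), 3:5]),
            sum(res$history[1, 3:5]))
  # checkpoint restores parameters and optimizer state exactly
  back <- load_checkpoint(ck)
  expect_equal(module_params(back$model), module_params(res$model),
               tolerance = 1e-15)
  expect_identical(back$optimizer$t, res$optimizer$t)
  expect_equal(back$optimizer$m, res$optimizer$m, tolerance = 1e-15)
  expect_error(smoke_train(model, list()), "empty")
})
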