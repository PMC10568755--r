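# Shared fixtures: models are expensive to build, so the configurations the
# tests keep coming back to are built once and cached here.

.model_cache <- new.env(parent = emptyenv())

cached_model <- function(key, config_fn) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- build_model(config_fn)
  .model_cache[[key]]
}

baseline_model <- function()
  cached_model("baseline", yolov8n_config())

peas_model <- function()
  cached_model("peas", yolov8_peas_config())

ghost_model <- function()
  cached_model("ghost", model_config(use_ghost = TRUE))

# flatten a plate series into per-image items for training/eval
plate_items <- function(seed, grid = c(2L, 2L), img_size = 96L, n_days = 5L,
                        ...) {
  s <- generate_plate_series(
    plate_spec(grid = grid, img_size = img_size, clutter_density = 0L,
               seed_axes = c(12.5, 14.5), sprout_len_ratio = c(0.55, 0.65),
               growth_per_day = c(0.08, 0.15), seed = seed, ...), n_days)
  lapply(seq_len(n_days), function(t)
    list(id = paste0("p", seed, "d", t), image = s$images[[t]],
         labels = s$labels[[t]]))
}

# independent greedy matcher used as a dual-route oracle for match_and_count
reference_greedy_match <- function(preds, truths, thr) {
  ord <- order(preds$conf, decreasing = TRUE)
  used <- rep(FALSE, nrow(truths))
  tp <- 0L
  for (i in ord) {
    best <- 0; best_j <- 0L
    for (j in seq_len(nrow(truths))) {
      if (used[j] || truths$cls[j] != preds$cls[i]) next
      iou <- box_iou(preds[i, , drop = FALSE], truths[j, , drop = FALSE])[1, 1]
      if (iou >= thr && iou > best) { best <- iou; best_j <- j }
    }
    if (best_j > 0L) { used[best_j] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nrow(preds) - tp, fn = sum(!used))
}

# zero every learnable array of a module (children included), leaving
# buffers and metadata untouched
zero_params <- function(m) {
  m$params <- lapply(m$params, function(p) { p[] <- 0; p })
  m$children <- lapply(m$children, zero_params)
  m
}

# independent step-by-step reference of the moment/bias-correction update
reference_adam <- function(theta, grads_seq, eta, b1 = 0.937, b2 = 0.999,
                           eps = 1e-8) {
  m <- v <- 0 * theta
  for (t in seq_along(grads_seq)) {
    g <- grads_seq[[t]]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    theta <- theta - eta * mhat / (sqrt(vhat) + eps)
  }
  theta
}

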