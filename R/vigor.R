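# Germination-vigor statistics: germination rate (cumulative percentage of
# seeds germinated by day t) and germination index (sum over days of newly
# germinated seeds divided by day number, which weights early germination
# more), plus cross-day seed tracking from detections and condition/
# genotype comparison reports.

#' Germination rate
#'
#' `100 * Nt / N`: the cumulative percentage of seeds germinated by day t.
#'
#' @param Nt number of seeds germinated by day t (cumulative).
#' @param N total number of seeds tested (> 0).
#' @return percentage in `[0, 100]`.
#' @export
germination_rate <- function(Nt, N) {
  if (any(N <= 0)) stop("germination_rate: N must be > 0")
  if (any(Nt < 0) || any(Nt > N))
    stop("germination_rate: need 0 <= Nt <= N")
  100 * Nt / N
}

#' Germination index
#'
#' `sum_t Gt / Dt` where `Gt` is the number of seeds newly germinated on
#' day `Dt` (1-based). Earlier germination contributes more.
#'
#' @param Gt_by_day numeric vector of per-day new germinations; element `t`
#'   is day `t`.
#' @param days optional day indices (defaults to `seq_along(Gt_by_day)`);
#'   must be >= 1.
#' @return the index (numeric scalar).
#' @export
germination_index <- function(Gt_by_day, days = seq_along(Gt_by_day)) {
  if (any(days < 1)) stop("germination_index: days are 1-based (no day 0)")
  if (any(Gt_by_day < 0)) stop("germination_index: Gt must be >= 0")
  sum(Gt_by_day / days)
}

#' Germination series
#'
#' Per-day cumulative (`Nt`) and incremental (`Gt`) germination counts for
#' one plate/genotype/condition.
#'
#' @param plate,genotype,condition identifying labels.
#' @param N total seeds on the plate.
#' @param Nt cumulative germinated count per day (non-decreasing, <= N).
#' @return a `germination_series` list with derived `Gt`.
#' @export
germination_series <- function(plate, genotype, condition, N, Nt) {
  if (any(diff(Nt) < 0)) stop("germination_series: Nt must be non-decreasing")
  if (any(Nt > N) || any(Nt < 0)) stop("germination_series: need 0 <= Nt <= N")
  Gt <- diff(c(0, Nt))
  structure(list(plate = plate, genotype = genotype, condition = condition,
                 N = N, day = seq_along(Nt), Nt = Nt, Gt = Gt),
            class = "germination_series")
}

#' Build a germination series from per-day detections
#'
#' Assigns each detection to the nearest plate-layout cell by box centroid
#' (seeds are stationary in the incubator). A seed's germination day is the
#' first day its assigned detection has class `sprout`; monotonicity is
#' enforced, so later `not_sprout` detections on a germinated seed are
#' treated as detector noise (a warning is raised). When two detections
#' claim the same cell on one day, the higher-confidence one wins.
#'
#' @param detections_by_day list of [detection_records()] (or
#'   [box_labels()] with a `conf` column defaulting to 1), one per day.
#' @param layout data frame with `seed_id`, `cx`, `cy` (e.g. from
#'   [generate_plate_series()]).
#' @param plate,genotype,condition labels stored on the series.
#' @param max_dist maximum centroid-to-cell distance for an assignment, in
#'   pixels (`Inf` accepts all).
#' @return a [germination_series()].
#' @export
series_from_detections <- function(detections_by_day, layout,
                                   plate = "plate1", genotype = "gt1",
                                   condition = "CK", max_dist = Inf) {
  n_seeds <- nrow(layout)
  n_days <- length(detections_by_day)
  germ_day <- rep(NA_integer_, n_seeds)
  flip_warned <- FALSE
  for (t in seq_len(n_days)) {
    det <- detections_by_day[[t]]
    if (is.null(det) || !nrow(det)) next
    if (is.null(det$conf)) det$conf <- rep(1, nrow(det))
    cx <- (det$x1 + det$x2) / 2
    cy <- (det$y1 + det$y2) / 2
    dist <- outer(cx, layout$cx, "-")^2 + outer(cy, layout$cy, "-")^2
    cell <- apply(dist, 1L, which.min)
    dmin <- sqrt(dist[cbind(seq_along(cell), cell)])
    ok <- dmin <= max_dist
    # resolve multi-claims: keep the higher-confidence detection per cell
    keep <- rep(TRUE, nrow(det))
    for (cl in unique(cell[ok])) {
      claim <- which(ok & cell == cl)
      if (length(claim) > 1L) {
        best <- claim[which.max(det$conf[claim])]
        keep[setdiff(claim, best)] <- FALSE
        message("day ", t, ": ", length(claim) - 1L,
                " extra detection(s) on one cell dropped")
      }
    }
    for (i in which(ok & keep)) {
      sid <- layout$seed_id[cell[i]]
      if (det$cls[i] == "sprout") {
        if (is.na(germ_day[sid])) germ_day[sid] <- t
      } else if (!is.na(germ_day[sid]) && germ_day[sid] < t && !flip_warned) {
        warning("sprout -> not_sprout flip treated as detector noise ",
                "(monotonicity enforced)")
        flip_warned <- TRUE
      }
    }
  }
  Nt <- vapply(seq_len(n_days),
               function(t) sum(!is.na(germ_day) & germ_day <= t), 0L)
  s <- germination_series(plate, genotype, condition, n_seeds, Nt)
  s$germ_day <- germ_day
  s
}

#' Compare control and stress conditions
#'
#' For every genotype with both a control and a stress series (replicates
#' averaged), reports the final-day germination rate and germination index
#' under each condition and the percent decrease `100 (CK - S) / CK`;
#' pooled rows aggregate across genotypes. Genotypes lacking a condition
#' are skipped with a warning.
#'
#' @param series list of [germination_series()].
#' @param control,stress condition labels to compare.
#' @return list with `per_genotype` and `pooled` data frames, plus
#'   `per_day` (mean cumulative rate per genotype, condition and day).
#' @export
compare_conditions <- function(series, control = "CK", stress = "S1") {
  stopifnot(length(series) > 0)
  meta <- data.frame(
    genotype = vapply(series, `[[`, "", "genotype"),
    condition = vapply(series, `[[`, "", "condition"),
    stringsAsFactors = FALSE)
  gts <- unique(meta$genotype)
  rows <- list(); per_day <- list()
  for (g in gts) {
    ck <- series[meta$genotype == g & meta$condition == control]
    st <- series[meta$genotype == g & meta$condition == stress]
    if (!length(ck) || !length(st)) {
      warning("genotype ", g, " lacks a ", control, "/", stress,
              " pair; skipped")
      next
    }
    summ <- function(ss) {
      rate <- mean(vapply(ss, function(s)
        germination_rate(s$Nt[length(s$Nt)], s$N), 0))
      gi <- mean(vapply(ss, function(s) germination_index(s$Gt, s$day), 0))
      c(rate = rate, gi = gi)
    }
    a <- summ(ck); b <- summ(st)
    rows[[g]] <- data.frame(
      genotype = g,
      rate_ck = a[["rate"]], rate_s = b[["rate"]],
      rate_decrease_pct = if (a[["rate"]] > 0)
        100 * (a[["rate"]] - b[["rate"]]) / a[["rate"]] else NA_real_,
      gi_ck = a[["gi"]], gi_s = b[["gi"]],
      gi_decrease_pct = if (a[["gi"]] > 0)
        100 * (a[["gi"]] - b[["gi"]]) / a[["gi"]] else NA_real_,
      stringsAsFactors = FALSE)
    for (cond in c(control, stress)) {
      ss <- series[meta$genotype == g & meta$condition == cond]
      if (!length(ss)) next
      nd <- length(ss[[1L]]$Nt)
      rates <- sapply(ss, function(s) germination_rate(s$Nt, s$N))
      per_day[[paste(g, cond)]] <- data.frame(
        genotype = g, condition = cond, day = seq_len(nd),
        rate = rowMeans(matrix(rates, nrow = nd)))
    }
  }
  per_genotype <- do.call(rbind, rows)
  pooled <- NULL
  if (!is.null(per_genotype) && nrow(per_genotype)) {
    rate_ck <- mean(per_genotype$rate_ck); rate_s <- mean(per_genotype$rate_s)
    gi_ck <- mean(per_genotype$gi_ck); gi_s <- mean(per_genotype$gi_s)
    pooled <- data.frame(
      rate_ck = rate_ck, rate_s = rate_s,
      rate_decrease_pct = 100 * (rate_ck - rate_s) / rate_ck,
      gi_ck = gi_ck, gi_s = gi_s,
      gi_decrease_pct = 100 * (gi_ck - gi_s) / gi_ck)
  }
  list(per_genotype = per_genotype, pooled = pooled,
       per_day = do.call(rbind, per_day))
}

#' Bar-chart export of a condition comparison
#'
#' Writes a two-panel PNG (final germination rate; germination index) per
#' genotype and condition.
#'
#' @param cmp result of [compare_conditions()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_vigor_comparison <- function(cmp, path) {
  pg <- cmp$per_genotype
  grDevices::png(path, width = 900, height = 420)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
  m <- t(as.matrix(pg[, c("rate_ck", "rate_s")]))
  graphics::barplot(m, beside = TRUE, names.arg = pg$genotype, las = 2,
                    col = c("steelblue", "tan3"),
                    ylab = "germination rate (%)",
                    legend.text = c("CK", "stress"))
  m2 <- t(as.matrix(pg[, c("gi_ck", "gi_s")]))
  graphics::barplot(m2, beside = TRUE, names.arg = pg$genotype, las = 2,
                    col = c("steelblue", "tan3"),
                    ylab = "germination index",
                    legend.text = c("CK", "stress"))
  invisible(path)
}
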