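# Germination rate / index, detection-to-series tracking, condition reports.

test_that("germination rate is the exact cumulative percentage", {
  expect_equal(germination_rate(0, 36), 0)
  expect_equal(germination_rate(36, 36), 100)
  expect_equal(germination_rate(9, 36), 25)
  expect_error(germination_rate(5, 0), "N must be > 0")
  expect_error(germination_rate(40, 36), "Nt <= N")
})

test_that("germination index: hand sum, monotone day-shift, bounds", {
  expect_equal(germination_index(rep(0, 5)), 0)
  expect_equal(germination_index(c(0, 3, 4, 2, 0)), 3 / 2 + 4 / 3 + 2 / 4,
               tolerance = 1e-12)
  # shifting all germinations one day later strictly decreases the index
  g <- c(0, 3, 4, 2, 0)
  shifted <- c(0, 0, 3, 4, 2)
  expect_lt(germination_index(shifted), germination_index(g))
  expect_error(germination_index(c(1, 2), days = c(0, 1)), "1-based")
  # index <= N and >= N_final / D_final
  set.seed(31)
  for (i in 1:20) {
    gt <- rpois(5, 2)
    gi <- germination_index(gt)
    expect_lte(gi, sum(gt))
    expect_gte(gi, sum(gt) / 5)
  }
})

test_that("series invariants: Nt monotone, Gt consistent", {
  s <- germination_series("p1", "g1", "CK", 36, c(0, 5, 12, 20, 28))
  expect_equal(s$Gt, c(0, 5, 7, 8, 8))
  expect_equal(sum(s$Gt), s$Nt[5])
  expect_error(germination_series("p", "g", "CK", 36, c(5, 3)),
               "non-decreasing")
  expect_error(germination_series("p", "g", "CK", 10, c(5, 12)), "Nt <= N")
})

test_that("series_from_detections recovers generator ground truth exactly", {
  s <- generate_plate_series(plate_spec(grid = c(3, 3), img_size = 96,
                                        seed = 32), 5)
  det_days <- lapply(s$labels, function(l)
    detection_records(l$cls, l$x1, l$y1, l$x2, l$y2, rep(1, nrow(l))))
  sr <- series_from_detections(det_days, s$layout)
  truth_nt <- vapply(1:5, function(t)
    sum(!is.na(s$events$day) & s$events$day <= t), 0L)
  expect_identical(sr$Nt, truth_nt)
  expect_equal(sr$Gt, diff(c(0L, truth_nt)), ignore_attr = TRUE)
  expect_identical(sr$germ_day, s$events$day)
  # zero detections -> all-zero series
  empty <- lapply(1:5, function(t) detection_records())
  s0 <- series_from_detections(empty, s$layout)
  expect_true(all(s0$Nt == 0))
})

test_that("monotonicity rule: sprout -> not_sprout flips count from first day", {
  layout <- data.frame(seed_id = 1, cx = 10, cy = 10)
  mk <- function(cls) detection_records(cls, 5, 5, 15, 15, 0.9)
  days <- list(mk("sprout"), mk("not_sprout"), mk("sprout"))
  expect_warning(sr <- series_from_detections(days, layout), "noise")
  expect_identical(sr$Nt, c(1L, 1L, 1L))
  # two detections claiming one cell: higher confidence wins
  two <- detection_records(c("sprout", "not_sprout"), c(5, 6), c(5, 6),
                           c(15, 16), c(15, 16), c(0.4, 0.9))
  expect_message(sr2 <- series_from_detections(list(two), layout), "dropped")
  expect_identical(sr2$Nt, 0L)   # the not_sprout detection won
})

test_that("compare_conditions: formula cases, pooling, permutation invariance", {
  mk <- function(g, cond, nt, plate = "p") {
    germination_series(plate, g, cond, 100, nt)
  }
  # identical series give a 0% decrease
  same <- compare_conditions(list(mk("g1", "CK", c(10, 40, 80)),
                                  mk("g1", "S1", c(10, 40, 80))))
  expect_equal(same$per_genotype$rate_decrease_pct, 0)
  expect_equal(same$per_genotype$gi_decrease_pct, 0)
  # CK 80% vs stress 40% is a 50% decrease
  half <- compare_conditions(list(mk("g1", "CK", c(0, 0, 80)),
                                  mk("g1", "S1", c(0, 0, 40))))
  expect_equal(half$per_genotype$rate_decrease_pct, 50)
  # pooled decrease equals a spreadsheet-style hand computation
  ser <- list(mk("g1", "CK", c(20, 60, 90)), mk("g1", "S1", c(0, 30, 60)),
              mk("g2", "CK", c(10, 50, 70)), mk("g2", "S1", c(0, 20, 35)))
  cmp <- compare_conditions(ser)
  rate_ck <- mean(c(90, 70)); rate_s <- mean(c(60, 35))
  expect_equal(cmp$pooled$rate_decrease_pct,
               100 * (rate_ck - rate_s) / rate_ck, tolerance = 1e-12)
  gi_ck <- mean(c(20 / 1 + 40 / 2 + 30 / 3, 10 / 1 + 40 / 2 + 20 / 3))
  gi_s <- mean(c(0 + 30 / 2 + 30 / 3, 0 + 20 / 2 + 15 / 3))
  expect_equal(cmp$pooled$gi_decrease_pct, 100 * (gi_ck - gi_s) / gi_ck,
               tolerance = 1e-12)
  # replicate order does not matter
  rep1 <- list(mk("g1", "CK", c(10, 40, 80), "a"),
               mk("g1", "CK", c(20, 50, 90), "b"),
               mk("g1", "S1", c(0, 20, 40), "a"),
               mk("g1", "S1", c(10, 30, 50), "b"))
  cmp1 <- compare_conditions(rep1)
  cmp2 <- compare_conditions(rep1[c(2, 4, 1, 3)])
  expect_equal(cmp1$per_genotype, cmp2$per_genotype, tolerance = 1e-12)
  # missing pair is skipped with a warning
  expect_warning(solo <- compare_conditions(list(mk("g3", "CK", c(1, 2, 3)))),
                 "skipped")
  expect_null(solo$per_genotype)
})

test_that("vigor bar-chart export writes a PNG", {
  mk <- function(g, cond, nt) germination_series("p", g, cond, 100, nt)
  cmp <- compare_conditions(list(mk("g1", "CK", c(10, 80)),
                                 mk("g1", "S1", c(0, 40))))
  tmp <- tempfile(fileext = ".png")
  plot_vigor_comparison(cmp, tmp)
  expect_true(file.exists(tmp) && file.size(tmp) > 0)
})
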