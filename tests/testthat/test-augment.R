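# Image-and-label co-transformation algebra and the doubling policy.

toy_image <- function(h = 40, w = 60) {
  array(stats::runif(h * w * 3, 0, 255), c(h, w, 3))
}

test_that("label mappings match the per-method coordinate formulas", {
  b <- box_labels("sprout", 100, 200, 300, 400)
  # horizontal flip at W = 2448: x -> (W - x2, W - x1)
  hf <- transform_labels(box_labels("sprout", 100, 10, 300, 20),
                         augment_spec("hflip"), 2448, 2048)
  expect_equal(c(hf$x1, hf$x2), c(2148, 2348))
  expect_equal(c(hf$y1, hf$y2), c(10, 20))
  # vertical flip at H = 2048: y -> (H - y2, H - y1)
  vf <- transform_labels(box_labels("sprout", 5, 0, 10, 100),
                         augment_spec("vflip"), 2448, 2048)
  expect_equal(c(vf$y1, vf$y2), c(1948, 2048))
  # scale s = 0.5 multiplies every coordinate
  sc <- transform_labels(b, augment_spec("scale", scale_s = 0.5), 2448, 2048)
  expect_equal(as.numeric(sc[1, 2:5]), c(50, 100, 150, 200))
  # brightness and (default) gaussian noise leave geometry untouched
  for (m in c("brightness", "gauss_noise"))
    expect_equal(as.numeric(transform_labels(b, augment_spec(m),
                                             2448, 2048)[1, 2:5]),
                 c(100, 200, 300, 400))
})

test_that("flips are involutions on image and labels; scale inverts to 1 px", {
  set.seed(5)
  img <- toy_image()
  lab <- box_labels(c("sprout", "not_sprout"), c(3, 20), c(5, 11),
                    c(12, 40), c(15, 30))
  for (m in c("hflip", "vflip")) {
    sp <- augment_spec(m)
    expect_identical(transform_image(transform_image(img, sp), sp), img)
    twice <- transform_labels(transform_labels(lab, sp, 60, 40), sp, 60, 40)
    expect_equal(as.matrix(twice[, 2:5]), as.matrix(lab[, 2:5]),
                 ignore_attr = TRUE)
  }
  up <- augment_spec("scale", scale_s = 2)
  down <- augment_spec("scale", scale_s = 0.5)
  back <- transform_labels(transform_labels(lab, up, 60, 40), down, 120, 80)
  expect_lt(max(abs(as.matrix(back[, 2:5]) - as.matrix(lab[, 2:5]))), 1)
  # areas scale by s^2 exactly before clipping
  s2 <- transform_labels(lab, augment_spec("scale", scale_s = 1.5), 60, 40)
  a0 <- (lab$x2 - lab$x1) * (lab$y2 - lab$y1)
  expect_equal((s2$x2 - s2$x1) * (s2$y2 - s2$y1), a0 * 1.5^2)
})

test_that("image operators behave: identity gain, clamping, resize, noise", {
  set.seed(6)
  img <- toy_image()
  expect_identical(transform_image(img, augment_spec("brightness",
                                                     brightness_factor = 1)),
                   img)
  bright <- transform_image(img, augment_spec("brightness",
                                              brightness_factor = 3))
  expect_lte(max(bright), 255)
  sc <- transform_image(img, augment_spec("scale", scale_s = 0.5))
  expect_identical(dim(sc), c(20L, 30L, 3L))
  n1 <- transform_image(img, augment_spec("gauss_noise", seed = 9))
  n2 <- transform_image(img, augment_spec("gauss_noise", seed = 9))
  expect_identical(n1, n2)
  expect_false(identical(n1, img))
  expect_error(transform_image(array(0, c(0, 4, 3)), augment_spec("hflip")),
               "empty")
})

test_that("degenerate boxes after clipping are dropped with a warning", {
  lab <- box_labels(c("sprout", "sprout"), c(5, 58), c(5, 5), c(10, 60),
                    c(10, 10))
  sp <- augment_spec("scale", scale_s = 0.5)
  # an odd-width frame shrinks to floor(0.5 * 59) = 29, so a box at the far
  # edge collapses after clipping and is dropped
  lab2 <- box_labels("sprout", 58.5, 5, 59, 10)
  expect_warning(out <- transform_labels(lab2, sp, 59, 40), "degenerate")
  expect_identical(nrow(out), 0L)
  expect_true(nrow(suppressWarnings(transform_labels(lab, sp, 60, 40))) <= 2)
})

test_that("augment_dataset doubles the set deterministically with a manifest", {
  set.seed(7)
  items <- lapply(1:10, function(i)
    list(id = paste0("img", i), image = toy_image(24, 24),
         labels = box_labels("sprout", 2, 2, 12, 12)))
  a1 <- augment_dataset(items, seed = 3)
  a2 <- augment_dataset(items, seed = 3)
  expect_length(a1$items, 20)
  expect_identical(a1$manifest, a2$manifest)
  expect_identical(a1$manifest$source, paste0("img", 1:10))
  # labels of every augmented copy remain valid boxes in their frame
  for (it in a1$items[11:20]) {
    H <- dim(it$image)[1]; W <- dim(it$image)[2]
    if (nrow(it$labels)) {
      expect_true(all(it$labels$x1 < it$labels$x2))
      expect_true(all(it$labels$x2 <= W + 1e-9))
      expect_true(all(it$labels$y2 <= H + 1e-9))
    }
  }
  expect_error(augment_dataset(list()), "empty")
})

test_that("flipped label files round-trip through the yolo dialect", {
  set.seed(8)
  lab <- box_labels(c("sprout", "not_sprout"), c(10, 30), c(5, 12),
                    c(20, 50), c(15, 30))
  sp <- augment_spec("hflip")
  flipped <- transform_labels(lab, sp, 64, 64)
  tmp <- tempfile(fileext = ".txt")
  write_labels(flipped, tmp, "yolo_txt", 64, 64)
  reread <- read_labels(tmp, "yolo_txt", W = 64, H = 64)
  unflipped <- transform_labels(reread, sp, 64, 64)
  expect_lt(max(abs(as.matrix(unflipped[, 2:5]) - as.matrix(lab[, 2:5]))), 1)
})
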