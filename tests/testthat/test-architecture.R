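# Network blocks: shape contracts, enumerated weight counts, and the
# behavioral identities each block must satisfy.

params_of <- function(m) sum(vapply(module_params(m), length, 0L))
conv_weights_of <- function(m) {
  p <- module_params(m)
  sum(vapply(p[grepl("weight", names(p))], length, 0L))
}

test_that("CBS stride arithmetic and enumerated weight count", {
  set.seed(1)
  b <- make_cbs(3, 16, 3, 2)
  out <- forward(b, array(rnorm(3 * 64 * 64), c(1, 3, 64, 64)))
  expect_identical(dim(out), c(1L, 16L, 32L, 32L))
  expect_equal(conv_weights_of(b), 3 * 9 * 16)          # 432
  expect_equal(params_of(b), 432 + 32)                  # + BN
  b1 <- make_cbs(16, 16, 1, 1)
  x <- array(rnorm(16 * 8 * 8), c(1, 16, 8, 8))
  expect_identical(dim(forward(b1, x)), dim(x))
  expect_error(make_cbs(0, 16, 3, 1), "positive")
})

test_that("DBS groups by gcd and counts k^2 (c_in/M) c_out weights", {
  set.seed(1)
  d <- make_dbs(64, 128, 3, 2)
  expect_equal(conv_weights_of(d), 9 * (64 / 64) * 128)   # 1152
  d2 <- make_dbs(64, 64, 3, 1)
  expect_equal(conv_weights_of(d2), 9 * 64)               # 576, pure depthwise
  x <- array(rnorm(64 * 8 * 8), c(1, 64, 8, 8))
  expect_identical(dim(forward(d2, x)), dim(x))
  # grouped forward equals per-group dense convolution
  c_in <- 4L; groups <- 2L
  g <- sproutnet:::conv_leaf(c_in, 4L, 3L, 1L, groups = groups)
  xi <- array(rnorm(c_in * 6 * 6), c(c_in, 6, 6))
  yg <- sproutnet:::conv2d_chw(xi, g$params$weight, NULL, 1L, 1L, groups)
  for (grp in 1:2) {
    wd <- g$params$weight[(grp - 1) * 2 + 1:2, , , , drop = FALSE]
    yd <- sproutnet:::conv2d_chw(xi[(grp - 1) * 2 + 1:2, , , drop = FALSE],
                                 wd, NULL, 1L, 1L, 1L)
    expect_equal(yg[(grp - 1) * 2 + 1:2, , ], yd[, , ], tolerance = 1e-12)
  }
})

test_that("GhostConv: two-stage structure, shapes, concatenation order", {
  set.seed(1)
  # depthwise-5x5 cheap variant: 16*16 primary + 25*16 cheap conv weights
  g <- ghost_conv(16, 32, 1, act = TRUE, cheap_k = 5, cheap_depthwise = TRUE)
  expect_equal(conv_weights_of(g), 256 + 400)
  x <- array(rnorm(16 * 8 * 8), c(1, 16, 8, 8))
  out <- forward(g, x)
  expect_identical(dim(out), c(1L, 32L, 8L, 8L))
  # first half of the output is the primary branch itself
  prim <- forward(g$children$primary, x)
  expect_equal(out[, 1:16, , ], prim[, , , ], tolerance = 1e-12)
  expect_error(ghost_conv(16, 31), "even")
})

test_that("Ghost bottleneck: residual identity and frozen weight count", {
  set.seed(1)
  gb <- ghost_bottleneck(32, shortcut = TRUE)
  x <- array(rnorm(32 * 16 * 16), c(1, 32, 16, 16))
  expect_identical(dim(forward(gb, x)), dim(x))
  # zeroed weights + shortcut -> identity
  gb0 <- zero_params(gb)
  expect_equal(forward(gb0, x), x, tolerance = 1e-12)
  # enumerated parameter count: two GhostConv(c -> c) with pointwise cheap
  # transform is 1.5 c^2 weights + 4 c batch-norm terms
  expect_equal(params_of(gb), 1.5 * 32^2 + 4 * 32)
  # spec'd half-width variant still has the documented c -> c/2 -> c shape
  g1 <- ghost_conv(32, 16, 1)
  expect_identical(dim(forward(g1, x)), c(1L, 16L, 16L, 16L))
})

test_that("C2f and C2f-Ghost: topology, shapes, parameter ordering", {
  set.seed(1)
  cg <- c2f_ghost(32, 32, n = 1)
  x <- array(rnorm(32 * 16 * 16), c(1, 32, 16, 16))
  expect_identical(dim(forward(cg, x)), dim(x))
  # frozen-by-enumeration regression value for the ghost stage
  expect_equal(params_of(cg),
               params_of(make_cbs(32, 32, 1)) +      # cv1
                 params_of(make_cbs(48, 32, 1)) +    # cv2 on (2+n) c
                 params_of(ghost_bottleneck(16)))
  # ghost substitution strictly reduces parameters at equal topology
  cstd <- c2f(32, 32, n = 1)
  expect_lt(params_of(cg), params_of(cstd))
})

test_that("SPPF: shape preservation, constants, chained-pool receptive field", {
  set.seed(1)
  s <- sppf(64, 64)
  x <- array(rnorm(64 * 10 * 10), c(1, 64, 10, 10))
  expect_identical(dim(forward(s, x)), dim(x))
  # pooling a monotone ramp twice with k=5 equals pooling once with k=9
  ramp <- array(seq_len(30), c(1, 30, 1))
  p55 <- sproutnet:::maxpool_chw(sproutnet:::maxpool_chw(ramp, 5), 5)
  p9 <- sproutnet:::maxpool_chw(ramp, 9)
  expect_equal(p55, p9)
  # constant input stays constant per channel through max pooling
  xc <- array(rep(c(1, 2), times = 25), c(2, 5, 5))
  pc <- sproutnet:::maxpool_chw(xc, 5)
  expect_true(all(pc[1, , ] == 1) && all(pc[2, , ] == 2))
})

test_that("coordinate attention: shape, constant maps, sigmoid saturation", {
  set.seed(1)
  ca <- coord_attention(32, 32)
  x <- array(rnorm(32 * 8 * 8), c(1, 32, 8, 8))
  expect_identical(dim(forward(ca, x)), dim(x))
  # spatially constant input -> spatially proportional output per channel
  xc <- array(rep(rnorm(32), times = 64), c(1, 32, 8, 8))
  oc <- forward(ca, xc)
  ratio <- oc / xc
  for (ch in which(abs(xc[1, , 1, 1]) > 1e-6))
    expect_lt(max(ratio[1, ch, , ]) - min(ratio[1, ch, , ]), 1e-9)
  # driving the gate logits high saturates attention at 1 (output = input)
  ca_sat <- ca
  for (nm in c("conv_h", "conv_w")) {
    ca_sat$children[[nm]]$params$weight[] <- 0
    ca_sat$children[[nm]]$params$bias[] <- 50
  }
  expect_equal(forward(ca_sat, x), x, tolerance = 1e-8)
})

test_that("CARAFE: channel conversion, upsampled shape, uniform-kernel mean", {
  set.seed(1)
  cf <- carafe(64, sigma = 2, k_up = 3, k_encoder = 5)
  expect_equal(dim(cf$children$encoder$params$weight)[1], 2^2 * 3^2)  # 36
  x <- array(rnorm(64 * 8 * 8), c(1, 64, 8, 8))
  expect_identical(dim(forward(cf, x)), c(1L, 64L, 16L, 16L))
  expect_error(carafe(64, k_up = 4), "odd")

  # constant encoder output -> softmax gives a uniform 1/k^2 kernel, so each
  # output pixel is the mean of its 3x3 source neighborhood (brute force on
  # a 5x5 integer image)
  cf1 <- carafe(1, sigma = 2, k_up = 3, k_encoder = 5, c_mid = 4)
  cf1$children$encoder$params$weight[] <- 0
  cf1$children$encoder$params$bias[] <- 0
  img <- array(matrix(1:25, 5, 5), c(1, 1, 5, 5))
  out <- forward(cf1, img)
  pad <- matrix(0, 7, 7); pad[2:6, 2:6] <- img[1, 1, , ]
  for (i in 1:5) for (j in 1:5) {
    nb <- pad[i:(i + 2), j:(j + 2)]
    m <- sum(nb) / 9
    for (dy in 0:1) for (dx in 0:1)
      expect_equal(out[1, 1, 2 * i - 1 + dy, 2 * j - 1 + dx], m,
                   tolerance = 1e-9)
  }
})

test_that("CARAFE softmax kernels sum to one and reproduce constant maps", {
  set.seed(2)
  cf <- carafe(8, sigma = 2, k_up = 3, k_encoder = 3, c_mid = 8)
  xc <- array(rep(rnorm(8), times = 36), c(1, 8, 6, 6))
  out <- forward(cf, xc)
  # interior positions see a full neighborhood: value reproduced exactly
  expect_equal(out[, , 3:10, 3:10, drop = FALSE],
               array(rep(xc[1, , 1, 1], times = 64), c(1, 8, 8, 8)),
               tolerance = 1e-5)
  # sigmoid normalizer breaks the sum-to-one property
  cfs <- carafe(8, sigma = 2, k_up = 3, k_encoder = 3, c_mid = 8,
                normalizer = "sigmoid")
  outs <- forward(cfs, xc)
  expect_false(isTRUE(all.equal(outs[, , 3:10, 3:10, drop = FALSE],
                                array(rep(xc[1, , 1, 1], times = 64),
                                      c(1, 8, 8, 8)), tolerance = 1e-3)))
})

test_that("PCC: split-convolve-fuse structure and degenerate r = 1", {
  set.seed(1)
  p <- pcc(64, 64, r = 4, k = 3)
  expect_equal(conv_weights_of(p), 9 * 16 * 16 + 64 * 64)   # 2304 + 4096
  x <- array(rnorm(64 * 8 * 8), c(1, 64, 8, 8))
  expect_identical(dim(forward(p, x)), dim(x))
  expect_error(pcc(63, 63, r = 4), "divide")
  # r = 1 degenerates to CBS(k) on all channels followed by CBS(1)
  p1 <- pcc(16, 16, r = 1, k = 3)
  x16 <- array(rnorm(16 * 6 * 6), c(1, 16, 6, 6))
  y1 <- forward(p1, x16)
  y_ref <- forward(p1$children$fuse, forward(p1$children$partial, x16))
  expect_equal(y1, y_ref, tolerance = 1e-12)
})

test_that("detection heads: level contract and PDetect parameter saving", {
  set.seed(1)
  hd <- detect_head(c(64, 128, 256), num_classes = 2)
  pd <- pdetect_head(c(64, 128, 256), num_classes = 2)
  xs <- list(array(rnorm(64 * 8 * 8), c(1, 64, 8, 8)),
             array(rnorm(128 * 4 * 4), c(1, 128, 4, 4)),
             array(rnorm(256 * 2 * 2), c(1, 256, 2, 2)))
  for (h in list(hd, pd)) {
    out <- forward(h, xs)
    expect_identical(vapply(out, function(o) dim(o)[2], 0),
                     rep(4 * 16 + 2, 3))
    expect_identical(vapply(out, function(o) dim(o)[3], 0), c(8, 4, 2))
  }
  expect_lt(params_of(pd), params_of(hd))
  # frozen enumeration value of the calibrated PDetect head
  expect_equal(params_of(pd), 207558)
  expect_error(detect_head(c(64, 128)), "three")
})

test_that("whole-model forward, determinism, batch handling", {
  m <- peas_model()
  x <- array(rnorm(3 * 64 * 64), c(1, 3, 64, 64))
  out <- forward(m, x)
  expect_length(out, 3)
  expect_identical(vapply(out, function(o) dim(o)[3], 0), c(8, 4, 2))
  expect_true(all(vapply(out, function(o) all(is.finite(o)), TRUE)))
  # identical seeds give identical weights; normalizer toggle is param-free
  m2 <- build_model(yolov8_peas_config())
  expect_identical(module_params(m), module_params(m2))
  m3 <- build_model(yolov8_peas_config(kernel_normalizer = "sigmoid"))
  expect_equal(count_params(m3), count_params(m))
  # batch permutation commutes with the forward pass
  set.seed(9)
  xb <- array(rnorm(2 * 3 * 64 * 64), c(2, 3, 64, 64))
  cbs <- make_cbs(3, 8, 3, 2)
  yb <- forward(cbs, xb)
  yswap <- forward(cbs, xb[2:1, , , , drop = FALSE])
  expect_equal(yb[1, , , ], yswap[2, , , ], tolerance = 1e-12)
  expect_error(forward(m, array(0, c(1, 3, 50, 50))), "divisible")
})
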