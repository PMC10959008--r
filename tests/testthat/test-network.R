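# Architecture contracts: encoder stage arithmetic, Upception block shapes,
# fusion, end-to-end resolution identity, determinism, and checkpoints.

test_that("encoder stage arithmetic matches the residual-backbone plan", {
  enc <- build_encoder(18, 3)
  f <- encoder_features(enc, array(0, c(224, 224, 3)))
  expect_equal(dim(f$s4), c(7, 7, 512))
  expect_equal(dim(f$s1), c(56, 56, 64))
  enc50 <- build_encoder(50, 1)
  f50 <- encoder_features(enc50, array(0, c(64, 64, 1)))
  expect_equal(dim(f50$s4), c(2, 2, 2048))     # bottleneck expansion x4
  expect_error(build_encoder(18, 2), class = "rifseg_invalid_config")
  expect_error(build_encoder(27, 3), class = "rifseg_invalid_config")
})

test_that("Upception block A preserves shape, including minimal maps", {
  for (d in list(c(16, 16, 64), c(1, 1, 1), c(8, 4, 3))) {
    x <- array(rnorm(prod(d)), d)
    expect_equal(dim(upception_a(x)), d)
  }
  # zeroed convolutions pass the input straight through the residual sum
  x <- array(0, c(4, 4, 2))
  expect_true(all(upception_a(x) == 0))
})

test_that("Upception block B halves channels and doubles resolution", {
  b <- upception_b(array(rnorm(16 * 16 * 512), c(16, 16, 512)))
  expect_equal(dim(b), c(32, 32, 256))
  for (d in list(c(2, 2, 512), c(8, 8, 32), c(3, 5, 4))) {
    x <- array(rnorm(prod(d)), d)
    out <- upception_b(x)
    expect_equal(dim(out), c(2 * d[1], 2 * d[2], d[3] / 2))
  }
  expect_error(upception_b(array(0, c(4, 4, 3))),
               class = "rifseg_shape_error")
})

test_that("fusion is elementwise summation with strict shape agreement", {
  f <- array(rnorm(8 * 8 * 64), c(8, 8, 64))
  expect_equal(fuse(f, array(0, dim(f))), f)
  expect_equal(fuse(f, f), 2 * f)
  err <- tryCatch(fuse(f, array(0, c(8, 4, 64))), error = identity)
  expect_s3_class(err, "rifseg_shape_error")
  expect_match(conditionMessage(err), "8x8x64")
  expect_match(conditionMessage(err), "8x4x64")
})

test_that("shape ledger: encoder/decoder stage shapes follow the layer table", {
  # symbolic contract c x h x w -> c/2 x 2h x 2w per decoder stage, traced
  # programmatically for both block families
  for (depth in c(18, 50)) {
    for (hw in c(64, 96)) {
      net <- rifseg_net(network_spec(depth, c(hw, hw)), seed = 1)
      cexp <- if (depth == 50) 4L else 1L
      widths <- c(64, 128, 256, 512) * cexp
      x <- array(rnorm(hw * hw * 3), c(hw, hw, 3))
      f <- encoder_features(net$enc_rgb, x)
      for (s in 1:4) {
        expect_equal(dim(f[[s]]), c(hw / 2^(s + 1), hw / 2^(s + 1), widths[s]))
      }
      # five decoder stages: channels halve, resolution doubles, ending at
      # the input resolution with C4/32 channels
      ch <- widths[4]
      res <- hw / 32
      z <- f$s4
      for (k in 1:5) {
        z <- rifseg:::upc_b_forward(net$dec$stages[[k]]$b, z)
        ch <- ch / 2
        res <- res * 2
        expect_equal(dim(z), c(res, res, ch))
      }
      expect_equal(res, hw)
    }
  }
})

test_that("forward pass restores input resolution with values in [0, 1]", {
  sc <- tiny_scene(seed = 2)
  net <- rifseg_net(network_spec(18, c(64, 64)), seed = 1)
  p <- rifseg_forward(net, sc$rgb, sc$ir)
  expect_equal(dim(p), c(64, 64))
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
  # repeated evaluation is deterministic
  expect_identical(p, rifseg_forward(net, sc$rgb, sc$ir))
  # mismatched pair is rejected
  expect_error(rifseg_forward(net, sc$rgb, sc$ir[1:32, 1:32]),
               class = "rifseg_shape_error")
})

test_that("binarize thresholds inclusively", {
  p <- matrix(c(0.5, 0.2, 0.9, 0.7), 2)
  expect_equal(binarize(p, 0.5), matrix(c(1L, 0L, 1L, 1L), 2))
  expect_equal(binarize(matrix(0, 3, 3), 0.5), matrix(0L, 3, 3))
  expect_equal(binarize(matrix(0.7, 2, 2), 0.9), matrix(0L, 2, 2))
})

test_that("network spec validates depth, size and pretrained flag", {
  expect_error(network_spec(20), class = "rifseg_invalid_config")
  expect_error(network_spec(18, c(50, 64)), class = "rifseg_invalid_config")
  expect_error(network_spec(18, c(64, 64), pretrained = TRUE),
               class = "rifseg_invalid_config")
})

test_that("a single optimization step decreases the training loss", {
  sc <- tiny_scene(seed = 4)
  net <- rifseg_net(network_spec(18, c(64, 64)), seed = 3)
  delta <- training_step_delta(net, sc, lr = 1e-4)
  expect_lt(delta["after"], delta["before"])
})

test_that("checkpoints round-trip weights, normalization and predictions", {
  sc <- tiny_scene(seed = 6)
  net <- rifseg_net(network_spec(18, c(64, 64)), seed = 2)
  train_rifseg(net, list(sc), steps = 2, lr = 1e-3, seed = 1)
  p1 <- predict(net, sc)
  path <- tempfile(fileext = ".rds")
  save_rifseg(net, path)
  net2 <- load_rifseg(path, seed = 99)
  expect_equal(predict(net2, sc), p1, tolerance = 1e-12)
  expect_equal(net2$meta$trained_steps, 2L)
  suppressWarnings(expect_error(load_rifseg(tempfile()), "cannot open"))
})
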