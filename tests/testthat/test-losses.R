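# Loss functions: window statistics, SSIM selection loss, total variation,
# and the combined training objective, each against independent oracles.

test_that("window_mean is the arithmetic mean and rejects empty windows", {
  expect_equal(window_mean(matrix(c(1, 5, 3, 7), 2)), 4)
  expect_equal(window_mean(matrix(0.5, 3, 3)), 0.5)
  expect_equal(window_mean(matrix(c(0, 0, 0, 1), 2)), 0.25)
  expect_error(window_mean(numeric(0)), class = "rifseg_invalid_input")
})

test_that("ssim_window matches the closed-form oracle and self-similarity", {
  cfg <- ssim_config()
  x <- matrix(runif(9), 3)
  expect_equal(ssim_window(x, x, cfg), 1, tolerance = 1e-12)
  xc <- matrix(0.7, 3, 3)                    # constant window, stabilized
  expect_equal(ssim_window(xc, xc, cfg), 1, tolerance = 1e-12)
  set.seed(31)
  for (k in 1:5) {
    a <- matrix(runif(9), 3)
    b <- matrix(runif(9), 3)
    expect_equal(ssim_window(a, b, cfg), oracle_ssim(a, b, cfg$C1, cfg$C2),
                 tolerance = 1e-10)
  }
  expect_error(ssim_window(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "rifseg_shape_error")
})

test_that("l_ssim is zero when the output equals a source everywhere", {
  set.seed(7)
  IA <- matrix(runif(16 * 16), 16)
  IB <- matrix(runif(16 * 16), 16)
  cfg <- ssim_config(window = c(8, 8))
  expect_equal(as.numeric(l_ssim(fusion_triple(IA, IA, IA), cfg)), 0,
               tolerance = 1e-12)
  # the per-window max selects the matching source even when I_B differs
  expect_equal(as.numeric(l_ssim(fusion_triple(IA, IB, IA), cfg)), 0,
               tolerance = 1e-12)
  expect_error(l_ssim(fusion_triple(IA[1:4, 1:4], IB[1:4, 1:4],
                                    IA[1:4, 1:4]), cfg),
               class = "rifseg_shape_error")
})

test_that("sliding-window l_ssim equals the naive double-loop oracle", {
  set.seed(13)
  for (case in list(list(hw = c(16, 16), win = c(8, 8), stride = 8),
                    list(hw = c(24, 20), win = c(7, 5), stride = 3),
                    list(hw = c(32, 32), win = c(11, 11), stride = 11),
                    list(hw = c(32, 32), win = c(9, 9), stride = 4))) {
    IA <- matrix(runif(prod(case$hw)), case$hw[1])
    IB <- matrix(runif(prod(case$hw)), case$hw[1])
    IF_ <- matrix(runif(prod(case$hw)), case$hw[1])
    cfg <- ssim_config(window = case$win, stride = case$stride)
    got <- l_ssim(fusion_triple(IA, IB, IF_), cfg)
    expect_equal(as.numeric(got),
                 oracle_l_ssim(IA, IB, IF_, case$win[1], case$win[2],
                               case$stride, cfg$C1, cfg$C2),
                 tolerance = 1e-10)
    expect_gte(as.numeric(got), 0)
  }
})

test_that("l_tv matches enumeration and is shift/sign invariant", {
  IA <- matrix(c(0, 1, 1, 0), 2)              # residual [[0,1],[1,0]]
  expect_equal(l_tv(IA, matrix(0, 2, 2)), 4)
  set.seed(17)
  A <- matrix(runif(30), 5)
  F1 <- matrix(runif(30), 5)
  expect_equal(l_tv(A, F1), oracle_l_tv(A, F1), tolerance = 1e-12)
  expect_equal(l_tv(A, A), 0)
  expect_equal(l_tv(A, A + 0.37), 0, tolerance = 1e-12)       # constant shift
  # global sign swap of the residual: l_tv(A, F) with R -> -R
  expect_equal(l_tv(A, F1), l_tv(F1, A), tolerance = 1e-12)
  expect_error(l_tv(A, matrix(0, 2, 2)), class = "rifseg_shape_error")
})

test_that("combined_loss is linear in phi with slope l_ssim", {
  set.seed(19)
  IA <- matrix(runif(16 * 16), 16)
  IB <- matrix(runif(16 * 16), 16)
  IF_ <- matrix(runif(16 * 16), 16)
  tr <- fusion_triple(IA, IB, IF_)
  cfg <- ssim_config(window = c(8, 8))
  ls <- as.numeric(l_ssim(tr, cfg))
  c0 <- combined_loss(tr, cfg, loss_weights(phi = 0))
  c5 <- combined_loss(tr, cfg, loss_weights(phi = 5))
  expect_equal(as.numeric(c0), l_tv(IA, IF_))
  expect_equal((as.numeric(c5) - as.numeric(c0)) / 5, ls, tolerance = 1e-10)
  # both components exactly zero on the degenerate triple
  z <- combined_loss(fusion_triple(IA, IA, IA), cfg, loss_weights(phi = 3))
  expect_equal(as.numeric(z), 0, tolerance = 1e-12)
})

test_that("training_loss adds a mean BCE term and reduces to the fusion loss", {
  set.seed(23)
  IA <- matrix(runif(16 * 16), 16)
  truth <- matrix(rbinom(256, 1, 0.4), 16)
  cfg <- ssim_config(window = c(8, 8))
  # perfect prediction and degenerate triple: everything vanishes
  tl <- training_loss(truth, truth, fusion_triple(IA, IA, IA), cfg,
                      loss_weights(phi = 7, lambda_sup = 3))
  expect_equal(as.numeric(tl), 0, tolerance = 1e-5)
  # lambda_sup = 0 recovers the combined fusion loss exactly
  IF_ <- matrix(runif(256), 16)
  w0 <- loss_weights(phi = 2, lambda_sup = 0)
  expect_equal(as.numeric(training_loss(IF_, truth,
                                        fusion_triple(IA, IA, IF_), cfg, w0)),
               as.numeric(combined_loss(fusion_triple(IA, IA, IF_), cfg, w0)),
               tolerance = 1e-12)
  # uniform 0.5 prediction: BCE term is ln 2 per pixel
  p <- matrix(0.5, 16, 16)
  tl2 <- training_loss(p, truth, fusion_triple(IA, IA, IA), cfg,
                       loss_weights(phi = 0, lambda_sup = 1))
  expect_equal(attr(tl2, "bce"), log(2), tolerance = 1e-9)
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(29)
  IA <- matrix(runif(12 * 12), 12)
  IB <- matrix(runif(12 * 12), 12)
  IF_ <- matrix(runif(12 * 12), 12)
  cfg <- ssim_config(window = c(6, 6), stride = 3)
  tr <- fusion_triple(IA, IB, IF_)
  g <- rifseg:::l_ssim_grad(tr, cfg)
  gt <- rifseg:::l_tv_grad(IA, IF_)
  eps <- 1e-6
  idx <- sample(length(IF_), 25)
  for (i in idx) {
    f1 <- IF_; f1[i] <- f1[i] + eps
    f2 <- IF_; f2[i] <- f2[i] - eps
    num_s <- (as.numeric(l_ssim(fusion_triple(IA, IB, f1), cfg)) -
                as.numeric(l_ssim(fusion_triple(IA, IB, f2), cfg))) / (2 * eps)
    num_t <- (l_tv(IA, f1) - l_tv(IA, f2)) / (2 * eps)
    expect_equal(g[i], num_s, tolerance = 1e-5)
    expect_equal(gt[i], num_t, tolerance = 1e-5)
  }
})

test_that("auto-balance puts the two fusion terms at the same level", {
  set.seed(37)
  IA <- matrix(runif(32 * 32), 32)
  IB <- matrix(runif(32 * 32), 32)
  IF_ <- matrix(runif(32 * 32), 32)
  tr <- fusion_triple(IA, IB, IF_)
  cfg <- ssim_config(window = c(8, 8), stride = 8)
  w <- auto_balance_weights(tr, cfg)
  expect_equal(w$phi * as.numeric(l_ssim(tr, cfg)), l_tv(IA, IF_),
               tolerance = 1e-9)
})
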