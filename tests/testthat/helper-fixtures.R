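# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_scene <- function(seed = 1, h = 64, w = 64, n_leaves = 4) {
  generate_scene(scene_config(height = h, width = w, n_leaves = n_leaves,
                              leaf_size_range = c(14, 30), seed = seed))
}

# Independent SSIM oracle: the closed form recomputed from raw sums, no
# shared code with ssim_window().
oracle_ssim <- function(x, y, C1, C2) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  mx <- sx / n; my <- sy / n
  vx <- sum(x^2) / n - mx^2
  vy <- sum(y^2) / n - my^2
  cxy <- sum(x * y) / n - mx * my
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Naive double-loop oracle for the windowed source-selection loss.
oracle_l_ssim <- function(IA, IB, IF_, m, n, stride, C1, C2) {
  scores <- c()
  r <- 1
  while (r + m - 1 <= nrow(IA)) {
    cc <- 1
    while (cc + n - 1 <= ncol(IA)) {
      xa <- IA[r:(r + m - 1), cc:(cc + n - 1)]
      xb <- IB[r:(r + m - 1), cc:(cc + n - 1)]
      xf <- IF_[r:(r + m - 1), cc:(cc + n - 1)]
      scores <- c(scores, max(oracle_ssim(xa, xf, C1, C2),
                              oracle_ssim(xb, xf, C1, C2)))
      cc <- cc + stride
    }
    r <- r + stride
  }
  1 - mean(scores)
}

# Pixel-enumeration oracle for the total-variation sum.
oracle_l_tv <- function(IA, IF_) {
  R <- IA - IF_
  acc <- 0
  for (i in seq_len(nrow(R))) {
    for (j in seq_len(ncol(R))) {
      if (j + 1 <= ncol(R)) acc <- acc + (R[i, j + 1] - R[i, j])^2
      if (i + 1 <= nrow(R)) acc <- acc + (R[i + 1, j] - R[i, j])^2
    }
  }
  acc
}

# Axis-aligned filled rectangle mask.
rect_mask <- function(h, w, r0, c0, rh, rw) {
  m <- matrix(0L, h, w)
  m[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- 1L
  m
}

# Rasterize a rotated filled rectangle of side lengths a x b.
rot_rect_mask <- function(h, w, cx, cy, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), w), h, w) - cy
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  matrix(as.integer(abs(u) <= a / 2 & abs(v) <= b / 2), h, w)
}

logistic_cover <- function(t, K, r, t0) K / (1 + exp(-r * (t - t0)))
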