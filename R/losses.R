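# Training objectives: windowed structural-similarity source-selection loss,
# total-variation loss on the RGB-minus-output residual, their weighted
# combination, and the supervised cross-entropy term used during training.

#' SSIM loss configuration
#'
#' Sliding-window geometry and stability constants for the structural
#' similarity computation. The default non-overlapping 11x11 window makes
#' the window count `N` well defined; the constants are the standard
#' stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic range `L`.
#'
#' @param window Length-2 window size `(m, n)` in pixels, each `>= 2`.
#' @param stride Window stride in pixels (`>= 1`); defaults to the window
#'   height (non-overlapping tiling).
#' @param L Dynamic range of the images (1 for `[0, 1]` intensities).
#' @param C1,C2 Stability constants; computed from `L` when `NULL`.
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(window = c(11, 11), stride = NULL, L = 1,
                        C1 = NULL, C2 = NULL) {
  if (length(window) != 2L || any(window < 2)) {
    stop_rifseg("window must be two sizes >= 2", "rifseg_invalid_config")
  }
  stride <- stride %||% window[1]
  check_number(stride, "stride", lower = 1)
  check_number(L, "L", lower = 1e-12)
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 L = L,
                 C1 = C1 %||% (0.01 * L)^2, C2 = C2 %||% (0.03 * L)^2),
            class = "ssim_config")
}

#' Loss weights
#'
#' @param phi Balance factor multiplying the SSIM loss so that it and the
#'   total-variation term are of comparable magnitude (`>= 0`).
#' @param lambda_sup Weight of the supervised cross-entropy term (`>= 0`).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(phi = 10, lambda_sup = 1) {
  check_number(phi, "phi", lower = 0)
  check_number(lambda_sup, "lambda_sup", lower = 0)
  structure(list(phi = phi, lambda_sup = lambda_sup), class = "loss_weights")
}

#' Bundle the three images entering the fusion losses
#'
#' `I_A` is the grayscale (luminance) view of the RGB image, `I_B` the
#' infrared image, and `I_F` the network output on the same intensity scale.
#'
#' @param I_A,I_B,I_F Matrices of identical dimensions on a common scale.
#' @param L Common dynamic range.
#' @return An object of class `fusion_triple`.
#' @export
fusion_triple <- function(I_A, I_B, I_F, L = 1) {
  if (!identical(dim(I_A), dim(I_B)) || !identical(dim(I_A), dim(I_F))) {
    stop_rifseg("I_A, I_B and I_F must have identical dimensions",
                "rifseg_shape_error")
  }
  structure(list(I_A = I_A, I_B = I_B, I_F = I_F, L = L),
            class = "fusion_triple")
}

#' Luminance of an RGB image (ITU-R 601 weights)
#'
#' @param rgb `H x W x 3` array; values in `[0, 255]` are rescaled to
#'   `[0, 1]` first.
#' @return `H x W` matrix in `[0, 1]`.
#' @export
luminance <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (max(rgb, na.rm = TRUE) > 1.5) rgb <- rgb / 255
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Mean intensity of a pixel window
#'
#' @param patch Non-empty numeric matrix or vector of window pixels.
#' @return Arithmetic mean of the pixel values.
#' @export
window_mean <- function(patch) {
  if (length(patch) == 0L) {
    stop_rifseg("window is empty", "rifseg_invalid_input")
  }
  mean(patch)
}

#' Structural similarity of two equally sized windows
#'
#' Combines luminance, contrast and structure through the usual closed form
#' on window means, variances and covariance, stabilized by `C1`, `C2`.
#'
#' @param x,y Windows of identical shape.
#' @param cfg An [ssim_config()] supplying `C1`, `C2`.
#' @return SSIM index in `[-1, 1]`.
#' @export
ssim_window <- function(x, y, cfg = ssim_config()) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y))) {
    stop_rifseg("windows must have identical shape", "rifseg_shape_error")
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + cfg$C1) * (2 * cxy + cfg$C2)) /
    ((mx^2 + my^2 + cfg$C1) * (vx + vy + cfg$C2))
}

window_origins <- function(H, W, cfg) {
  m <- cfg$window[1]; n <- cfg$window[2]; s <- cfg$stride
  if (H < m || W < n) {
    stop_rifseg("image is smaller than the SSIM window", "rifseg_shape_error")
  }
  list(rows = seq(1L, H - m + 1L, by = s), cols = seq(1L, W - n + 1L, by = s))
}

#' Windowed SSIM source-selection loss
#'
#' For every sliding window, the structural similarity of the output to the
#' RGB luminance and to the infrared image are both computed and the larger
#' of the two is kept (the output should resemble whichever source carries
#' more local structure); the loss is one minus the mean selected score over
#' all `N` windows, hence in `[0, 2]` and zero exactly when every window's
#' best similarity is 1.
#'
#' @param t A [fusion_triple()].
#' @param cfg An [ssim_config()].
#' @return Scalar loss with attribute `n_windows`.
#' @export
l_ssim <- function(t, cfg = ssim_config()) {
  stopifnot(inherits(t, "fusion_triple"))
  org <- window_origins(nrow(t$I_A), ncol(t$I_A), cfg)
  m <- cfg$window[1]; n <- cfg$window[2]
  total <- 0
  N <- 0L
  for (r in org$rows) {
    for (cc in org$cols) {
      ri <- r:(r + m - 1L); ci <- cc:(cc + n - 1L)
      f <- t$I_F[ri, ci]
      s <- max(ssim_window(t$I_A[ri, ci], f, cfg),
               ssim_window(t$I_B[ri, ci], f, cfg))
      total <- total + s
      N <- N + 1L
    }
  }
  structure(1 - total / N, n_windows = N)
}

# Gradient of l_ssim with respect to I_F (subgradient through the per-window
# max: only the selected source contributes).
l_ssim_grad <- function(t, cfg = ssim_config()) {
  org <- window_origins(nrow(t$I_A), ncol(t$I_A), cfg)
  m <- cfg$window[1]; n <- cfg$window[2]
  npx <- m * n
  g <- matrix(0, nrow(t$I_A), ncol(t$I_A))
  N <- length(org$rows) * length(org$cols)
  for (r in org$rows) {
    for (cc in org$cols) {
      ri <- r:(r + m - 1L); ci <- cc:(cc + n - 1L)
      f <- t$I_F[ri, ci]
      sa <- ssim_window(t$I_A[ri, ci], f, cfg)
      sb <- ssim_window(t$I_B[ri, ci], f, cfg)
      x <- if (sa >= sb) t$I_A[ri, ci] else t$I_B[ri, ci]
      mx <- mean(x); my <- mean(f)
      xc <- x - mx; fc <- f - my
      vx <- mean(xc^2); vy <- mean(fc^2)
      cxy <- mean(xc * fc)
      A1 <- 2 * mx * my + cfg$C1; A2 <- 2 * cxy + cfg$C2
      B1 <- mx^2 + my^2 + cfg$C1; B2 <- vx + vy + cfg$C2
      # dSSIM/df_i via the quotient rule on (A1 A2)/(B1 B2)
      dA1 <- 2 * mx / npx
      dA2 <- 2 * xc / npx
      dB1 <- 2 * my / npx
      dB2 <- 2 * fc / npx
      dssim <- ((dA1 * A2 + A1 * dA2) * B1 * B2 -
                  A1 * A2 * (dB1 * B2 + B1 * dB2)) / (B1 * B2)^2
      g[ri, ci] <- g[ri, ci] - dssim / N
    }
  }
  g
}

#' Total-variation loss on the residual image
#'
#' The residual `R = I_A - I_F` is formed and its squared horizontal and
#' vertical forward differences are summed over all pixel pairs where the
#' neighbor exists (no wraparound). Adding a constant to `I_F` leaves the
#' loss unchanged.
#'
#' @param I_A,I_F Matrices of identical dimensions.
#' @return Scalar loss (a sum, not a mean).
#' @export
l_tv <- function(I_A, I_F) {
  if (!identical(dim(I_A), dim(I_F))) {
    stop_rifseg("I_A and I_F must have identical dimensions",
                "rifseg_shape_error")
  }
  R <- I_A - I_F
  dh <- R[, -1, drop = FALSE] - R[, -ncol(R), drop = FALSE]
  dv <- R[-1, , drop = FALSE] - R[-nrow(R), , drop = FALSE]
  sum(dh^2) + sum(dv^2)
}

# Gradient of l_tv with respect to I_F. With L = sum over forward
# differences of R and R = I_A - I_F, dL/dF = -dL/dR.
l_tv_grad <- function(I_A, I_F) {
  R <- I_A - I_F
  H <- nrow(R); W <- ncol(R)
  dR <- matrix(0, H, W)
  dh <- R[, -1, drop = FALSE] - R[, -W, drop = FALSE]
  dv <- R[-1, , drop = FALSE] - R[-H, , drop = FALSE]
  dR[, -W] <- dR[, -W] - 2 * dh
  dR[, -1] <- dR[, -1] + 2 * dh
  dR[-H, ] <- dR[-H, ] - 2 * dv
  dR[-1, ] <- dR[-1, ] + 2 * dv
  -dR
}

#' Combined fusion loss
#'
#' `phi * L_SSIM + L_TV`; both components are returned as attributes for
#' per-component logging.
#'
#' @param t A [fusion_triple()].
#' @param cfg An [ssim_config()].
#' @param w A [loss_weights()].
#' @return Scalar loss with attributes `l_ssim` and `l_tv`.
#' @export
combined_loss <- function(t, cfg = ssim_config(), w = loss_weights()) {
  ls <- as.numeric(l_ssim(t, cfg))
  lt <- l_tv(t$I_A, t$I_F)
  structure(w$phi * ls + lt, l_ssim = ls, l_tv = lt)
}

# Per-pixel mean binary cross-entropy of a probability map against a 0/1
# mask, clamped for numerical safety.
bce_mean <- function(p, truth, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Full training loss
#'
#' `lambda_sup * BCE(p, truth) + phi * L_SSIM + L_TV`, where the binary
#' cross-entropy is the per-pixel mean and the network output plays the role
#' of `I_F` in the fusion terms. With `lambda_sup = 0` this reduces exactly
#' to [combined_loss()].
#'
#' @param p Probability map (matrix in `[0, 1]`).
#' @param truth 0/1 ground-truth mask of the same dimensions.
#' @param t A [fusion_triple()] whose `I_F` is the network output.
#' @param cfg An [ssim_config()].
#' @param w A [loss_weights()].
#' @return Scalar loss with attributes `bce`, `l_ssim`, `l_tv`.
#' @export
training_loss <- function(p, truth, t, cfg = ssim_config(),
                          w = loss_weights()) {
  if (!identical(dim(p), dim(truth))) {
    stop_rifseg("prediction and truth must have identical dimensions",
                "rifseg_shape_error")
  }
  bce <- bce_mean(p, truth)
  comb <- combined_loss(t, cfg, w)
  structure(w$lambda_sup * bce + as.numeric(comb),
            bce = bce, l_ssim = attr(comb, "l_ssim"),
            l_tv = attr(comb, "l_tv"))
}

#' Set the SSIM balance factor from initial component magnitudes
#'
#' Auto-balance mode: computes both loss components on a reference triple and
#' returns weights whose `phi` equates their orders of magnitude
#' (`phi = L_TV / L_SSIM`).
#'
#' @param t A [fusion_triple()] representative of initialization.
#' @param cfg An [ssim_config()].
#' @param lambda_sup Supervised weight carried through.
#' @return A [loss_weights()].
#' @export
auto_balance_weights <- function(t, cfg = ssim_config(), lambda_sup = 1) {
  ls <- as.numeric(l_ssim(t, cfg))
  lt <- l_tv(t$I_A, t$I_F)
  phi <- if (ls > 1e-9) lt / ls else 1
  loss_weights(phi = phi, lambda_sup = lambda_sup)
}
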