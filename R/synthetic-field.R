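# Synthetic field scenes and growth trajectories.
#
# The generator emulates the statistical structure of nadir plot imagery:
# leaf-shaped green foreground (superellipses spanning the oval-to-lanceolate
# continuum) over low-frequency textured soil, with a correlated infrared
# channel in which canopy and soil differ by a fixed contrast offset, plus
# logistic canopy-cover trajectories on a thermal-time axis.

#' Scene generator configuration
#'
#' Describes one synthetic plot scene: image geometry, leaf population, and
#' the infrared contrast between canopy and soil. Height and width must be
#' divisible by 32 so that the five 2x downsamplings of the segmentation
#' encoder are exact.
#'
#' @param height,width Image dimensions in pixels; each `>= 64` and divisible
#'   by 32.
#' @param n_leaves Number of leaves to draw (`>= 0`).
#' @param leaf_axis_ratio_mean,leaf_axis_ratio_sd Mean and SD of the leaf
#'   long/short axis ratio (dimensionless, mean `>= 1`).
#' @param leaf_size_range Length-2 range of leaf long-axis diameters, pixels.
#' @param ir_contrast Offset in `[0, 1]` between canopy and soil infrared
#'   intensity, applied before noise.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (intensity units on the `[0, 1]` scale).
#' @param squareness_range Range of the superellipse squareness exponent;
#'   values near 2 give ellipses, larger values boxier leaves.
#' @param seed Integer seed making the scene a pure function of this config.
#' @return An object of class `scene_config`.
#' @seealso [generate_scene()]
#' @export
scene_config <- function(height = 96, width = 96, n_leaves = 8,
                         leaf_axis_ratio_mean = 2, leaf_axis_ratio_sd = 0.2,
                         leaf_size_range = c(16, 34), ir_contrast = 0.3,
                         noise_sd = 0.02, squareness_range = c(1.5, 3),
                         seed = 1L) {
  check_number(height, "height", lower = 64)
  check_number(width, "width", lower = 64)
  if (height %% 32 != 0 || width %% 32 != 0) {
    stop_rifseg("height and width must be divisible by 32 (five exact 2x downsamplings)",
                "rifseg_invalid_config")
  }
  check_number(n_leaves, "n_leaves", lower = 0)
  check_number(leaf_axis_ratio_mean, "leaf_axis_ratio_mean", lower = 1)
  check_number(leaf_axis_ratio_sd, "leaf_axis_ratio_sd", lower = 0)
  if (length(leaf_size_range) != 2L || any(leaf_size_range <= 0) ||
      diff(leaf_size_range) < 0) {
    stop_rifseg("leaf_size_range must be an increasing positive length-2 range",
                "rifseg_invalid_config")
  }
  if (max(leaf_size_range) > min(height, width)) {
    stop_rifseg("leaf size range exceeds image dimensions",
                "rifseg_invalid_config")
  }
  check_number(ir_contrast, "ir_contrast", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_leaves = as.integer(n_leaves),
                 leaf_axis_ratio_mean = leaf_axis_ratio_mean,
                 leaf_axis_ratio_sd = leaf_axis_ratio_sd,
                 leaf_size_range = leaf_size_range,
                 ir_contrast = ir_contrast, noise_sd = noise_sd,
                 squareness_range = squareness_range,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Low-frequency soil texture: coarse Gaussian grid upsampled bilinearly.
soil_texture <- function(h, w, cell = 12) {
  gh <- max(2L, ceiling(h / cell) + 1L)
  gw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(rnorm(gh * gw), gh, gw)
  yi <- (seq_len(h) - 1) / (h - 1) * (gh - 1) + 1
  xi <- (seq_len(w) - 1) / (w - 1) * (gw - 1) + 1
  y0 <- pmin(floor(yi), gh - 1); x0 <- pmin(floor(xi), gw - 1)
  fy <- yi - y0; fx <- xi - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fy <- rep(fy, w); fx <- rep(fx, each = h)
  v <- a * (1 - fy) * (1 - fx) + b * fy * (1 - fx) +
    cc * (1 - fy) * fx + d * fy * fx
  matrix(v, h, w)
}

# Superellipse membership |u/a|^n + |v/b|^n <= 1 in rotated leaf coordinates.
superellipse_mask <- function(h, w, cx, cy, a, b, angle, n) {
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), w), h, w) - cy
  u <- cos(angle) * x + sin(angle) * y
  v <- -sin(angle) * x + cos(angle) * y
  (abs(u / a)^n + abs(v / b)^n) <= 1
}

#' Generate one synthetic RGB + infrared canopy scene
#'
#' Draws `n_leaves` superellipse leaves (sampled axis ratio, size, rotation,
#' position, squareness) on textured soil. The returned instance masks store
#' each leaf's full, un-occluded shape; the scene mask is their union. The
#' infrared channel equals the soil intensity field plus `ir_contrast` under
#' the canopy, before noise. Deterministic in `cfg` (including `cfg$seed`).
#'
#' @param cfg A [scene_config()].
#' @return A list of class `rifseg_scene` with elements `rgb` (H x W x 3
#'   array in `[0, 255]`), `ir` (H x W matrix in `[0, 1]`), `mask` (H x W
#'   0/1 integer matrix, canopy = 1), `instances` (list of 0/1 matrices, one
#'   per leaf, possibly overlapping), `labelmap` (H x W integer matrix,
#'   0 = background, later leaves painted over earlier ones), and `leaf_truth`
#'   (data frame of the sampled per-leaf geometry).
#' @examples
#' sc <- generate_scene(scene_config(n_leaves = 3, seed = 7))
#' mean(sc$mask)  # ground-truth canopy cover
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width
    soil <- soil_texture(h, w)
    soil01 <- (soil - min(soil)) / max(1e-12, diff(range(soil)))

    instances <- list()
    truth <- vector("list", cfg$n_leaves)
    mask <- matrix(0L, h, w)
    labelmap <- matrix(0L, h, w)
    if (cfg$n_leaves > 0) {
      for (i in seq_len(cfg$n_leaves)) {
        len <- runif(1, cfg$leaf_size_range[1], cfg$leaf_size_range[2])
        ratio <- max(1, rnorm(1, cfg$leaf_axis_ratio_mean, cfg$leaf_axis_ratio_sd))
        a <- len / 2
        b <- a / ratio
        angle <- runif(1, 0, pi)
        nexp <- runif(1, cfg$squareness_range[1], cfg$squareness_range[2])
        cx <- runif(1, a + 1, w - a)
        cy <- runif(1, a + 1, h - a)
        m <- superellipse_mask(h, w, cx, cy, a, b, angle, nexp)
        instances[[i]] <- matrix(as.integer(m), h, w)
        mask[m] <- 1L
        labelmap[m] <- i
        truth[[i]] <- data.frame(leaf_id = i, cx = cx, cy = cy,
                                 semi_major = a, semi_minor = b,
                                 axis_ratio = ratio, angle = angle,
                                 squareness = nexp)
      }
    }

    # RGB in [0,1] first: brown soil with texture, green canopy with
    # per-leaf tone jitter, then pixel noise.
    r <- 0.45 + 0.10 * (soil01 - 0.5)
    g <- 0.35 + 0.08 * (soil01 - 0.5)
    b2 <- 0.24 + 0.06 * (soil01 - 0.5)
    if (cfg$n_leaves > 0) {
      for (i in seq_along(instances)) {
        tone <- rnorm(1, 0, 0.03)
        sel <- labelmap == i
        r[sel] <- 0.20 + tone
        g[sel] <- 0.48 + tone + 0.04 * (soil01[sel] - 0.5)
        b2[sel] <- 0.16 + tone
      }
    }
    rgb01 <- array(c(r, g, b2), dim = c(h, w, 3))
    if (cfg$noise_sd > 0) {
      rgb01 <- rgb01 + array(rnorm(length(rgb01), 0, cfg$noise_sd), dim = dim(rgb01))
    }
    rgb01 <- pmin(pmax(rgb01, 0), 1)

    ir <- 0.35 + 0.08 * (soil01 - 0.5)
    ir[mask == 1L] <- ir[mask == 1L] + cfg$ir_contrast
    if (cfg$noise_sd > 0) ir <- ir + matrix(rnorm(h * w, 0, cfg$noise_sd), h, w)
    ir <- pmin(pmax(ir, 0), 1)

    structure(list(rgb = rgb01 * 255, ir = ir, mask = mask,
                   instances = instances, labelmap = labelmap,
                   leaf_truth = if (cfg$n_leaves > 0) do.call(rbind, truth)
                                else data.frame(),
                   config = cfg),
              class = "rifseg_scene")
  })
}

#' Logistic growth-curve parameters
#'
#' Parameters of the sigmoid ("S"-shaped) canopy-cover trajectory
#' `cover(t) = K / (1 + exp(-r (t - t0)))` on the cumulative thermal-time
#' axis, sampled at `sample_times` with additive Gaussian noise.
#'
#' @param K Asymptotic cover fraction in `(0, 1]`.
#' @param r Growth rate per degree-day (`> 0`).
#' @param t0 Inflection thermal time in degree-days (`> 0`).
#' @param noise_sd SD of additive cover-fraction noise (`>= 0`).
#' @param sample_times Strictly increasing non-negative thermal times
#'   (degree-days) at which cover is observed.
#' @param seed Integer seed.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(K = 0.9, r = 0.01, t0 = 800, noise_sd = 0.02,
                          sample_times = seq(100, 1660, by = 120),
                          seed = 1L) {
  check_number(K, "K", lower = 1e-9, upper = 1)
  check_number(r, "r", lower = 1e-12)
  check_number(t0, "t0", lower = 1e-12)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (length(sample_times) < 1L || any(sample_times < 0) ||
      any(diff(sample_times) <= 0)) {
    stop_rifseg("sample_times must be non-negative and strictly increasing",
                "rifseg_invalid_config")
  }
  structure(list(K = K, r = r, t0 = t0, noise_sd = noise_sd,
                 sample_times = sample_times, seed = as.integer(seed)),
            class = "growth_params")
}

#' Simulate a canopy-cover time series
#'
#' Evaluates the logistic trajectory at the configured thermal times, adds
#' Gaussian noise, and clips to `[0, 1]`.
#'
#' @param p A [growth_params()].
#' @param genotype_id Optional identifier carried into the output.
#' @return A data frame of class `thermal_series` with columns
#'   `genotype_id`, `thermal_time_Cd`, `canopy_cover`.
#' @examples
#' gs <- generate_growth_series(growth_params(K = 1, noise_sd = 0, t0 = 800))
#' @export
generate_growth_series <- function(p, genotype_id = "g1") {
  stopifnot(inherits(p, "growth_params"))
  with_seed(p$seed, {
    mu <- p$K / (1 + exp(-p$r * (p$sample_times - p$t0)))
    cover <- mu
    if (p$noise_sd > 0) cover <- cover + rnorm(length(mu), 0, p$noise_sd)
    cover <- pmin(pmax(cover, 0), 1)
    structure(data.frame(genotype_id = genotype_id,
                         thermal_time_Cd = p$sample_times,
                         canopy_cover = cover),
              class = c("thermal_series", "data.frame"))
  })
}

# Class-specific parameter distributions. Oval-leaf (OLT) genotypes have low
# axis ratios and faster canopy development with greater final cover;
# lanceolate (LLT) genotypes the reverse. Ratio draws are truncated to
# class-specific supports separated by a clear gap (means >4 pooled SD
# apart), so major classes are recoverable by design for any seed.
.class_presets <- list(
  OLT = list(ratio_mean = 1.6, ratio_sd = 0.15, ratio_rng = c(1.0, 2.05),
             K_mean = 0.93, K_sd = 0.03,
             r_mean = 0.011, r_sd = 0.0012, t0_mean = 750, t0_sd = 55),
  LLT = list(ratio_mean = 3.0, ratio_sd = 0.30, ratio_rng = c(2.45, 4.0),
             K_mean = 0.84, K_sd = 0.05,
             r_mean = 0.009, r_sd = 0.0012, t0_mean = 900, t0_sd = 70)
)

#' Generate a synthetic genotype panel
#'
#' Draws per-genotype growth parameters and a leaf axis ratio from
#' class-specific distributions: the oval leaf type (OLT) has low axis ratio
#' and faster canopy development, the lanceolate leaf type (LLT) high axis
#' ratio and slower development. Class counts follow `class_mix` by largest
#' remainder, so the counts are exact, not stochastic.
#'
#' @param n_genotypes Number of genotypes (`>=` number of classes).
#' @param class_mix Named proportions summing to 1; defaults to the
#'   29/71 OLT/LLT split of a 200-genotype panel.
#' @param sample_times Thermal times passed to every genotype's
#'   [growth_params()].
#' @param noise_sd Cover noise SD for each genotype's series.
#' @param seed Integer seed.
#' @return A data frame with one row per genotype: `genotype_id`, `class`,
#'   `leaf_axis_ratio`, `K`, `r`, `t0`, plus a `params` list-column of
#'   [growth_params()] objects.
#' @examples
#' pop <- generate_population(20, seed = 3)
#' table(pop$class)
#' @export
generate_population <- function(n_genotypes,
                                class_mix = c(OLT = 0.29, LLT = 0.71),
                                sample_times = seq(100, 1660, by = 120),
                                noise_sd = 0.02, seed = 1L) {
  if (is.null(names(class_mix))) {
    names(class_mix) <- names(.class_presets)[seq_along(class_mix)]
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop_rifseg("class_mix proportions must sum to 1", "rifseg_invalid_config")
  }
  if (n_genotypes < length(class_mix)) {
    stop_rifseg("n_genotypes must be at least the number of classes",
                "rifseg_invalid_config")
  }
  # Largest-remainder apportionment: exact counts for exact mixes.
  raw <- n_genotypes * class_mix
  cnt <- floor(raw)
  left <- n_genotypes - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  with_seed(seed, {
    rows <- list()
    gid <- 0L
    for (cl in names(cnt)) {
      preset <- .class_presets[[cl]]
      if (is.null(preset)) preset <- .class_presets[[1L]]
      for (i in seq_len(cnt[[cl]])) {
        gid <- gid + 1L
        ratio <- min(preset$ratio_rng[2],
                     max(preset$ratio_rng[1],
                         rnorm(1, preset$ratio_mean, preset$ratio_sd)))
        K <- min(1, max(0.3, rnorm(1, preset$K_mean, preset$K_sd)))
        r <- max(1e-4, rnorm(1, preset$r_mean, preset$r_sd))
        t0 <- max(50, rnorm(1, preset$t0_mean, preset$t0_sd))
        rows[[gid]] <- data.frame(genotype_id = sprintf("G%03d", gid),
                                  class = cl, leaf_axis_ratio = ratio,
                                  K = K, r = r, t0 = t0)
      }
    }
    out <- do.call(rbind, rows)
    out$params <- lapply(seq_len(nrow(out)), function(i) {
      growth_params(K = out$K[i], r = out$r[i], t0 = out$t0[i],
                    noise_sd = noise_sd, sample_times = sample_times,
                    seed = seed + i)
    })
    out
  })
}
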