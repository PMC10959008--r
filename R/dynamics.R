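# Canopy-cover growth curves on the cumulative thermal-time axis:
# penalized-spline additive model per genotype, prediction at arbitrary
# thermal times, inversion for time-to-cover traits, and the five
# canopy-development traits with group summaries.

#' Canopy-cover fraction of a binary mask
#'
#' @param mask 0/1 matrix; canopy = 1.
#' @return Canopy pixels / total pixels, in `[0, 1]`.
#' @export
canopy_cover <- function(mask) {
  if (length(mask) == 0) {
    stop_rifseg("mask is empty", "rifseg_invalid_input")
  }
  sum(mask != 0) / length(mask)
}

#' Thermal-time accumulation configuration
#'
#' @param base Base temperature in deg C below which no thermal time
#'   accrues; default 10 (a common soybean growing-degree-day convention).
#' @param cutoff Optional upper cutoff in deg C at which daily mean
#'   temperatures are capped; `NULL` for none.
#' @return Object of class `thermal_time_config`.
#' @export
thermal_time_config <- function(base = 10, cutoff = NULL) {
  check_number(base, "base")
  if (!is.null(cutoff)) {
    check_number(cutoff, "cutoff")
    if (cutoff <= base) {
      stop_rifseg("cutoff must exceed the base temperature",
                  "rifseg_invalid_config")
    }
  }
  structure(list(base = base, cutoff = cutoff), class = "thermal_time_config")
}

#' Cumulative thermal time from daily mean temperatures
#'
#' Running sum of `max(0, min(T, cutoff) - base)` per day, in degree-days.
#'
#' @param temps Numeric vector of daily mean temperatures (deg C).
#' @param cfg A [thermal_time_config()].
#' @return Numeric vector of the same length (degree-days).
#' @examples
#' cumulative_thermal_time(c(20, 25), thermal_time_config(base = 10))
#' @export
cumulative_thermal_time <- function(temps, cfg = thermal_time_config()) {
  if (!is.numeric(temps) || any(!is.finite(temps))) {
    stop_rifseg("temps must be finite numbers", "rifseg_invalid_input")
  }
  t <- temps
  if (!is.null(cfg$cutoff)) t <- pmin(t, cfg$cutoff)
  cumsum(pmax(0, t - cfg$base))
}

#' Fit a smooth canopy-cover growth curve
#'
#' Penalized B-spline additive model (identity link) of cover on thermal
#' time. The smoothing parameter is chosen by generalized cross-validation
#' over a fixed log-spaced grid of 11 penalties, which keeps per-genotype
#' fits deterministic and cheap. Predictions are clipped to `[0, 1]`.
#'
#' @param thermal_time Thermal times in degree-days (strictly increasing,
#'   `>= 5` points), or a data frame with columns `thermal_time_Cd` and
#'   `canopy_cover` (e.g. a [generate_growth_series()] result).
#' @param cover Cover fractions in `[0, 1]` (ignored when a data frame is
#'   given).
#' @param k Spline basis dimension; defaults to `min(13, n - 1)` — generous
#'   for a 14-point series so that the penalty, not the basis, controls
#'   smoothness (a basis-limited fit cannot follow the logistic toe).
#' @param sp_grid Smoothing-parameter grid searched by GCV.
#' @return Object of class `canopy_gam` with `print`, `summary`, `predict`,
#'   `plot`, `residuals`, `fitted` and `coef` methods.
#' @examples
#' gs <- generate_growth_series(growth_params(noise_sd = 0.01, seed = 2))
#' fit <- fit_growth_curve(gs)
#' predict(fit, c(500, 1000, 1500))
#' @export
fit_growth_curve <- function(thermal_time, cover = NULL, k = NULL,
                             sp_grid = 10^seq(-4, 6, length.out = 11)) {
  if (is.data.frame(thermal_time)) {
    cover <- thermal_time$canopy_cover
    thermal_time <- thermal_time$thermal_time_Cd
  }
  n <- length(thermal_time)
  if (n < 5) {
    stop_rifseg("at least 5 time points are required for spline fitting",
                "rifseg_invalid_input")
  }
  if (any(diff(thermal_time) <= 0)) {
    stop_rifseg("thermal_time must be strictly increasing",
                "rifseg_invalid_input")
  }
  if (length(cover) != n || any(cover < -1e-9) || any(cover > 1 + 1e-9)) {
    stop_rifseg("cover must match thermal_time and lie in [0, 1]",
                "rifseg_invalid_input")
  }
  k <- k %||% max(4L, min(13L, n - 1L))
  dat <- data.frame(tt = thermal_time, cc = cover)
  if (sd(cover) < 1e-12) {
    # perfectly flat series: the smooth is a constant
    fit <- mgcv::gam(cc ~ 1, data = dat)
    best_sp <- Inf
  } else {
    fits <- lapply(sp_grid, function(sp) {
      mgcv::gam(cc ~ s(tt, k = k, bs = "ps"), data = dat, sp = sp)
    })
    gcv <- vapply(fits, function(f) f$gcv.ubre, numeric(1))
    fit <- fits[[which.min(gcv)]]
    best_sp <- sp_grid[which.min(gcv)]
  }
  structure(list(gam = fit, domain = range(thermal_time), k = k,
                 sp = best_sp, data = dat,
                 sigma_resid = sd(dat$cc - as.numeric(fitted(fit)))),
            class = "canopy_gam")
}

#' Predict canopy cover at given thermal times
#'
#' @param object A [fit_growth_curve()] object.
#' @param thermal_time Thermal times (degree-days) at which to predict.
#' @param warn_extrapolation Warn when a query lies outside the fit domain.
#' @param ... Unused.
#' @return Cover predictions clipped to `[0, 1]`; queries outside the
#'   domain are flagged by the logical attribute `extrapolated`.
#' @export
predict.canopy_gam <- function(object, thermal_time,
                               warn_extrapolation = TRUE, ...) {
  outside <- thermal_time < object$domain[1] | thermal_time > object$domain[2]
  if (warn_extrapolation && any(outside)) {
    warning(sprintf("%d prediction point(s) outside the fit domain [%g, %g]",
                    sum(outside), object$domain[1], object$domain[2]))
  }
  p <- as.numeric(predict(object$gam,
                          newdata = data.frame(tt = thermal_time)))
  structure(pmin(pmax(p, 0), 1), extrapolated = outside)
}

#' @rdname predict.canopy_gam
#' @param fit A [fit_growth_curve()] object.
#' @param tt Thermal times.
#' @export
predict_cc <- function(fit, tt) {
  as.numeric(predict(fit, tt, warn_extrapolation = FALSE))
}

#' @export
print.canopy_gam <- function(x, ...) {
  cat(sprintf("<canopy_gam> penalized-spline growth curve, k = %d, sp = %g\n",
              x$k, x$sp))
  cat(sprintf("  %d points on [%g, %g] degree-days; residual SD %.4f\n",
              nrow(x$data), x$domain[1], x$domain[2], x$sigma_resid))
  invisible(x)
}

#' @export
summary.canopy_gam <- function(object, ...) summary(object$gam, ...)

#' @export
residuals.canopy_gam <- function(object, ...) {
  object$data$cc - as.numeric(fitted(object$gam))
}

#' @export
fitted.canopy_gam <- function(object, ...) {
  pmin(pmax(as.numeric(fitted(object$gam)), 0), 1)
}

#' @export
coef.canopy_gam <- function(object, ...) coef(object$gam)

#' @export
plot.canopy_gam <- function(x, ...) {
  grid <- seq(x$domain[1], x$domain[2], length.out = 200)
  plot(x$data$tt, x$data$cc, xlab = "cumulative thermal time (degree-days)",
       ylab = "canopy cover", ylim = c(0, 1), ...)
  lines(grid, predict_cc(x, grid), col = "forestgreen", lwd = 2)
  invisible(x)
}

#' Smallest thermal time at which the fitted curve reaches a target cover
#'
#' Dense-grid scan over the fit domain followed by bisection refinement to
#' 0.1 degree-day resolution; returns the smallest thermal time whose
#' prediction meets or exceeds the target, or a "not reached" value (`NA`
#' with attribute `reached = FALSE`) when the curve never attains it.
#'
#' @param fit A [fit_growth_curve()] object.
#' @param target Cover fraction in `(0, 1)`.
#' @param resolution Refinement resolution in degree-days.
#' @return Thermal time in degree-days, or `NA` (attribute
#'   `reached = FALSE`) when the target is not attained.
#' @export
invert_tt <- function(fit, target, resolution = 0.1) {
  check_number(target, "target", lower = 1e-9, upper = 1 - 1e-9)
  lo <- fit$domain[1]; hi <- fit$domain[2]
  grid <- seq(lo, hi, length.out = 2048L)
  pred <- predict_cc(fit, grid)
  hit <- which(pred >= target)
  if (length(hit) == 0) {
    return(structure(NA_real_, reached = FALSE))
  }
  i <- hit[1]
  if (i == 1L) return(structure(grid[1], reached = TRUE))
  a <- grid[i - 1L]; b <- grid[i]
  while (b - a > resolution) {
    mid <- (a + b) / 2
    if (predict_cc(fit, mid) >= target) b <- mid else a <- mid
  }
  structure(b, reached = TRUE)
}

#' Extract the five canopy-development traits from a fitted curve
#'
#' Cover at 500, 1000 and 1500 accumulated degree-days (via
#' [predict_cc()]) and the accumulated thermal time to 30% and 50% cover
#' (via [invert_tt()]). Queries outside the fit domain are still answered
#' but flagged in the `extrapolated` attribute; unattained cover targets are
#' explicit `NA` ("not reached"), never imputed.
#'
#' @param fit A [fit_growth_curve()] object.
#' @param cc_times Thermal times for the cover traits.
#' @param tt_targets Cover targets for the time traits.
#' @return One-row data frame `CC_500TT`, `CC_1000TT`, `CC_1500TT`,
#'   `TT_30CC`, `TT_50CC` with attribute `extrapolated`.
#' @export
extract_traits <- function(fit, cc_times = c(500, 1000, 1500),
                           tt_targets = c(0.30, 0.50)) {
  cc <- predict_cc(fit, cc_times)
  tts <- lapply(tt_targets, function(tg) invert_tt(fit, tg))
  out <- data.frame(CC_500TT = cc[1], CC_1000TT = cc[2], CC_1500TT = cc[3],
                    TT_30CC = as.numeric(tts[[1]]),
                    TT_50CC = as.numeric(tts[[2]]))
  attr(out, "extrapolated") <-
    cc_times < fit$domain[1] | cc_times > fit$domain[2]
  out
}

#' Fit growth curves and extract traits for a whole panel
#'
#' @param series Data frame with columns `genotype_id`, `thermal_time_Cd`,
#'   `canopy_cover` (multiple genotypes stacked).
#' @param ... Passed to [fit_growth_curve()].
#' @return Data frame of traits, one row per genotype.
#' @export
traits_for_population <- function(series, ...) {
  ids <- unique(series$genotype_id)
  rows <- lapply(ids, function(id) {
    s <- series[series$genotype_id == id, ]
    fit <- fit_growth_curve(s$thermal_time_Cd, s$canopy_cover, ...)
    cbind(data.frame(genotype_id = id), extract_traits(fit))
  })
  do.call(rbind, rows)
}

#' Quartile summaries of traits by group
#'
#' Per group and trait: min, Q1, median, Q3, max, and n; "not reached"
#' values are excluded from the quantiles and counted separately.
#'
#' @param traits Data frame from [traits_for_population()] (or any data
#'   frame of numeric trait columns).
#' @param groups Group label per row.
#' @param trait_cols Trait columns to summarize.
#' @return Data frame: `group`, `trait`, `min`, `q1`, `median`, `q3`,
#'   `max`, `n`, `n_not_reached`.
#' @export
group_summary <- function(traits, groups,
                          trait_cols = c("CC_500TT", "CC_1000TT",
                                         "CC_1500TT", "TT_30CC", "TT_50CC")) {
  stopifnot(nrow(traits) == length(groups))
  if (any(table(groups) == 0)) {
    stop_rifseg("every group must contain at least one genotype",
                "rifseg_invalid_input")
  }
  rows <- list()
  for (g in sort(unique(groups))) {
    sub <- traits[groups == g, , drop = FALSE]
    for (tr in trait_cols) {
      v <- sub[[tr]]
      nr <- sum(is.na(v))
      v <- v[!is.na(v)]
      q <- if (length(v) > 0) quantile(v, c(0, 0.25, 0.5, 0.75, 1),
                                       names = FALSE)
           else rep(NA_real_, 5)
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, trait = tr, min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5],
                   n = length(v), n_not_reached = nr)
    }
  }
  do.call(rbind, rows)
}
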