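# Growth-curve modelling on the thermal-time axis: cover computation,
# degree-day accumulation, spline fits against known logistic truth, trait
# extraction and group summaries.

test_that("canopy_cover is the canopy pixel fraction", {
  expect_equal(canopy_cover(matrix(1L, 5, 5)), 1)
  m <- matrix(0L, 10, 10); m[1:5, 1:5] <- 1L
  expect_equal(canopy_cover(m), 0.25)
  sc <- tiny_scene(seed = 12)
  expect_equal(canopy_cover(sc$mask), sum(sc$mask) / length(sc$mask))
  expect_error(canopy_cover(matrix(numeric(0), 0, 0)),
               class = "rifseg_invalid_input")
})

test_that("thermal time accumulates capped excess over the base", {
  expect_equal(cumulative_thermal_time(c(20, 25), thermal_time_config(10)),
               c(10, 25))
  expect_equal(cumulative_thermal_time(c(5, 8, 9), thermal_time_config(10)),
               c(0, 0, 0))
  expect_equal(cumulative_thermal_time(c(14, 25), thermal_time_config(0)),
               c(14, 39))
  cfg <- thermal_time_config(10, cutoff = 30)
  expect_equal(cumulative_thermal_time(c(35, 20), cfg), c(20, 30))
  expect_error(thermal_time_config(10, cutoff = 5),
               class = "rifseg_invalid_config")
  expect_error(cumulative_thermal_time(c(1, NA)),
               class = "rifseg_invalid_input")
})

test_that("noise-free logistic samples are fitted within 0.02 cover", {
  p <- growth_params(K = 0.9, r = 0.01, t0 = 800, noise_sd = 0)
  gs <- generate_growth_series(p)
  expect_equal(nrow(gs), 14)
  fit <- fit_growth_curve(gs)
  grid <- seq(min(gs$thermal_time_Cd), max(gs$thermal_time_Cd), by = 20)
  expect_lt(max(abs(predict_cc(fit, grid) -
                      logistic_cover(grid, 0.9, 0.01, 800))), 0.02)
  expect_lt(fit$sigma_resid, 0.01)
})

test_that("degenerate fits behave: flat series, too few points, bad axis", {
  flat <- fit_growth_curve(seq(100, 900, by = 100), rep(0.5, 9))
  expect_equal(predict_cc(flat, c(200, 500, 800)), rep(0.5, 3),
               tolerance = 1e-9)
  expect_error(fit_growth_curve(c(1, 2, 3), c(0.1, 0.2, 0.3)),
               class = "rifseg_invalid_input")
  expect_error(fit_growth_curve(c(1, 2, 2, 3, 4), rep(0.2, 5)),
               class = "rifseg_invalid_input")
  expect_error(fit_growth_curve(1:5, c(0.1, 0.2, 0.3, 0.4, 1.4)),
               class = "rifseg_invalid_input")
})

test_that("predictions interpolate samples, clip to [0,1], and flag extrapolation", {
  p <- growth_params(K = 1, r = 0.01, t0 = 800, noise_sd = 0)
  fit <- fit_growth_curve(generate_growth_series(p))
  expect_equal(predict_cc(fit, 800), 0.5, tolerance = 0.02)
  at_samples <- predict_cc(fit, p$sample_times)
  expect_lt(max(abs(at_samples -
                      logistic_cover(p$sample_times, 1, 0.01, 800))), 0.02)
  grid <- seq(fit$domain[1], fit$domain[2], length.out = 100)
  expect_true(all(predict_cc(fit, grid) >= 0 & predict_cc(fit, grid) <= 1))
  expect_warning(predict(fit, 5000), "outside the fit domain")
})

test_that("invert_tt finds the first crossing of a target cover", {
  fit <- fit_growth_curve(generate_growth_series(
    growth_params(K = 1, r = 0.01, t0 = 800, noise_sd = 0)))
  expect_equal(as.numeric(invert_tt(fit, 0.5)), 800, tolerance = 5 / 800)
  # closed form: t = t0 - ln(7/3)/r for 30% of a K = 1 logistic
  expect_equal(as.numeric(invert_tt(fit, 0.3)), 800 - log(7 / 3) / 0.01,
               tolerance = 5 / 715)
  low <- fit_growth_curve(generate_growth_series(
    growth_params(K = 0.6, r = 0.01, t0 = 700, noise_sd = 0)))
  nr <- invert_tt(low, 0.9)
  expect_true(is.na(nr))
  expect_false(attr(nr, "reached"))
})

test_that("predict/invert are mutually consistent", {
  fit <- fit_growth_curve(generate_growth_series(
    growth_params(K = 0.95, r = 0.012, t0 = 750, noise_sd = 0.01, seed = 3)))
  for (target in c(0.2, 0.3, 0.5, 0.7)) {
    tt <- invert_tt(fit, target)
    if (!is.na(tt)) {
      expect_gte(predict_cc(fit, as.numeric(tt)), target - 1e-3)
    }
  }
})

test_that("the five traits follow the closed form of the generating curve", {
  fit <- fit_growth_curve(generate_growth_series(
    growth_params(K = 1, r = 0.01, t0 = 800, noise_sd = 0)))
  tr <- extract_traits(fit)
  expect_equal(tr$CC_500TT, 1 / (1 + exp(3)), tolerance = 0.02 / 0.047)
  expect_equal(tr$TT_50CC, 800, tolerance = 5 / 800)
  expect_equal(tr$CC_1000TT, 1 / (1 + exp(-2)), tolerance = 0.02 / 0.88)
  expect_lte(tr$TT_30CC, tr$TT_50CC)    # monotone curve ordering
  # flat series at 0.4: 30% reached immediately, 50% never
  flat <- fit_growth_curve(seq(100, 1500, length.out = 10), rep(0.4, 10))
  trf <- extract_traits(flat)
  expect_equal(trf$TT_30CC, flat$domain[1])
  expect_true(is.na(trf$TT_50CC))
})

test_that("trait extraction is invariant to consistent time-axis rescaling", {
  p <- growth_params(K = 0.9, r = 0.01, t0 = 800, noise_sd = 0)
  gs <- generate_growth_series(p)
  fit1 <- fit_growth_curve(gs)
  gs2 <- gs; gs2$thermal_time_Cd <- gs2$thermal_time_Cd * 2
  fit2 <- fit_growth_curve(gs2)
  expect_equal(predict_cc(fit2, 1600), predict_cc(fit1, 800),
               tolerance = 1e-6)
  expect_equal(as.numeric(invert_tt(fit2, 0.3)) / 2,
               as.numeric(invert_tt(fit1, 0.3)), tolerance = 1e-2)
})

test_that("group summaries quantify class differences in development", {
  # one-genotype group: all five summaries collapse onto its value
  tr1 <- data.frame(genotype_id = "g1", CC_500TT = 0.2, CC_1000TT = 0.6,
                    CC_1500TT = 0.9, TT_30CC = 600, TT_50CC = 820)
  gs <- group_summary(tr1, "solo")
  expect_true(all(gs$min == gs$max))
  expect_equal(gs$median, unlist(tr1[, -1], use.names = FALSE))
  # identical groups give identical summaries
  tr2 <- rbind(tr1, tr1); tr2$genotype_id <- c("a", "b")
  gs2 <- group_summary(tr2, c("x", "y"))
  expect_equal(gs2$median[gs2$group == "x"], gs2$median[gs2$group == "y"])
  # synthetic panel: oval leaf type develops faster at 500 degree-days
  pop <- generate_population(24, c(OLT = 0.5, LLT = 0.5), noise_sd = 0.01,
                             seed = 6)
  series <- do.call(rbind, lapply(seq_len(nrow(pop)), function(i) {
    generate_growth_series(pop$params[[i]], pop$genotype_id[i])
  }))
  traits <- traits_for_population(series)
  gsum <- group_summary(traits, pop$class)
  med <- gsum[gsum$trait == "CC_500TT", ]
  expect_gt(med$median[med$group == "OLT"], med$median[med$group == "LLT"])
})
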