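# Leaf morphometrics: canopy masking, instance extraction, minimum-area
# rotated rectangles, aspect ratios, and the two-stage classification.

test_that("mask_canopy zeroes exactly the background", {
  rgb <- array(runif(8 * 8 * 3, 0.2, 1), c(8, 8, 3))
  expect_equal(mask_canopy(rgb, matrix(1L, 8, 8)), rgb)
  expect_true(all(mask_canopy(rgb, matrix(0L, 8, 8)) == 0))
  chk <- matrix(rep_len(c(0L, 1L), 64), 8)
  masked <- mask_canopy(rgb, chk)
  expect_equal(sum(masked[, , 1] > 0), sum(chk))
  expect_error(mask_canopy(rgb, matrix(1L, 4, 4)),
               class = "rifseg_shape_error")
})

test_that("extract_instances honours labels and the incomplete-leaf filter", {
  lm <- matrix(0L, 20, 20)
  lm[2:11, 2:11] <- 1L
  lm[14:19, 14:19] <- 2L
  inst <- extract_instances(lm, min_area = 10)
  expect_length(inst, 2)
  expect_equal(vapply(inst, function(i) i$label, numeric(1)), c(1, 2))
  expect_length(extract_instances(matrix(0L, 5, 5)), 0)
  blob <- matrix(0L, 10, 10); blob[1, 1:3] <- 1L
  expect_length(extract_instances(blob, min_area = 10), 0)
})

test_that("minimum-area rectangle recovers axis-aligned side lengths", {
  m <- rect_mask(40, 40, 10, 5, 10, 20)       # 10 x 20 block
  r <- min_area_rectangle(m)
  expect_equal(sort(c(r$width, r$height)), c(10, 20), tolerance = 0.5 / 10)
  expect_equal(aspect_ratio(r), 2, tolerance = 0.06)
  # single pixel degenerates to a unit square
  px <- matrix(0L, 5, 5); px[3, 3] <- 1L
  rp <- min_area_rectangle(px)
  expect_equal(sort(c(rp$width, rp$height)), c(1, 1))
  expect_equal(aspect_ratio(rp), 1)
  expect_error(min_area_rectangle(matrix(0L, 4, 4)),
               class = "rifseg_invalid_input")
})

test_that("rectangle side lengths are rotation invariant within a pixel", {
  base <- c(30, 14)
  for (ang in c(0, 17, 30, 45, 78)) {
    m <- rot_rect_mask(80, 80, 40, 40, base[1], base[2], ang)
    r <- min_area_rectangle(m)
    sides <- sort(c(r$width, r$height))
    expect_equal(sides, sort(base), tolerance = 1 / min(base))
  }
})

test_that("rectangle area never exceeds the axis-aligned bounding box", {
  set.seed(41)
  for (k in 1:10) {
    m <- rot_rect_mask(60, 60, runif(1, 20, 40), runif(1, 20, 40),
                       runif(1, 8, 25), runif(1, 4, 12), runif(1, 0, 180))
    idx <- which(m == 1, arr.ind = TRUE)
    bbox <- (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
    expect_lte(min_area_rectangle(m)$area, bbox + 1e-9)
  }
})

test_that("synthetic superellipse leaves round-trip their axis ratio", {
  # lone leaf with a known 2.5 long/short ratio, arbitrary rotation; the
  # short axis is kept above ~20 px so half-pixel boundary uncertainty
  # stays below the 5% recovery tolerance
  for (ang in c(0.3, 1.1, 2.2)) {
    m <- rifseg:::superellipse_mask(160, 160, 80, 80, 60, 24, ang, 2)
    inst <- matrix(as.integer(m), 160, 160)
    r <- min_area_rectangle(inst)
    expect_equal(aspect_ratio(r), 2.5, tolerance = 0.05)
  }
})

test_that("aspect_ratio validates its input", {
  expect_equal(aspect_ratio(list(width = 20, height = 10)), 2)
  expect_equal(aspect_ratio(list(width = 10, height = 10)), 1)
  expect_error(aspect_ratio(list(width = 0, height = 3)),
               class = "rifseg_invalid_input")
})

test_that("genotype summaries enforce the 5-10 leaf rule", {
  expect_error(genotype_morphology("g1", c(1.2, 1.3)),
               class = "rifseg_invalid_input")
  gm <- genotype_morphology("g2", seq(1, 2, length.out = 12))
  expect_length(gm$leaf_ratios, 10)
  gm5 <- genotype_morphology("g3", rep(1.5, 5))
  expect_equal(gm5$mean_ratio, 1.5)
})

test_that("two-stage classification separates well-separated ratio clusters", {
  df <- data.frame(genotype_id = paste0("g", 1:4),
                   mean_ratio = c(1.2, 1.3, 2.8, 3.0))
  out <- classify_population(df, seed = 1)
  expect_equal(out$major_class, c("OLT", "OLT", "LLT", "LLT"))
  # label assignment is invariant to row order
  out2 <- classify_population(df[c(3, 1, 4, 2), ], seed = 1)
  m <- match(out$genotype_id, out2$genotype_id)
  expect_equal(out$major_class, out2$major_class[m])
  # degenerate: identical ratios
  expect_error(classify_population(
    data.frame(genotype_id = paste0("g", 1:4), mean_ratio = rep(2, 4))),
    class = "rifseg_degenerate_input")
  expect_error(classify_population(df[1:3, ]),
               class = "rifseg_invalid_input")
})

test_that("generator round-trip recovers major classes perfectly", {
  pop <- generate_population(40, c(OLT = 0.4, LLT = 0.6), seed = 5)
  df <- data.frame(genotype_id = pop$genotype_id,
                   mean_ratio = pop$leaf_axis_ratio)
  out <- classify_population(df, seed = 2)
  expect_equal(out$major_class, pop$class)
  expect_true(all(out$subclass %in% c("A", "B")))
  # subclass A has the lower ratios within each major class
  for (cl in c("OLT", "LLT")) {
    a <- out$mean_ratio[out$major_class == cl & out$subclass == "A"]
    b <- out$mean_ratio[out$major_class == cl & out$subclass == "B"]
    expect_lt(max(a), min(b))
  }
})

test_that("connected-component labelling agrees with the imaging library", {
  skip_if_not_installed("EBImage")
  sc <- tiny_scene(seed = 8, n_leaves = 5)
  lab_eb <- label_mask(sc$mask, method = "ebimage")
  lab_own <- label_mask(sc$mask, method = "builtin")
  # same partition up to label permutation
  expect_equal(max(lab_eb), max(lab_own))
  tab <- table(lab_own[lab_own > 0], lab_eb[lab_eb > 0])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})
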