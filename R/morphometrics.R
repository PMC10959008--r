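# Per-leaf morphometrics: instance extraction, minimum-area rotated
# rectangles (rotating calipers over the convex hull of pixel squares),
# aspect ratios, per-genotype summaries, and the two-stage leaf-type
# classification (oval vs. lanceolate, then A/B subclasses).

#' Mask an RGB image with a binary canopy mask
#'
#' Background pixels are set to 0 in every channel; canopy pixels are
#' unchanged.
#'
#' @param rgb `H x W x 3` array.
#' @param mask `H x W` 0/1 mask of the same spatial dimensions.
#' @return Masked array.
#' @export
mask_canopy <- function(rgb, mask) {
  if (!identical(dim(rgb)[1:2], dim(mask)[1:2])) {
    stop_rifseg("image and mask dimensions differ", "rifseg_shape_error")
  }
  out <- rgb
  bg <- mask == 0
  for (c in seq_len(dim(rgb)[3])) {
    ch <- out[, , c]
    ch[bg] <- 0
    out[, , c] <- ch
  }
  out
}

#' Label connected components of a binary mask
#'
#' Adapter producing an indexed label map when no externally supplied
#' instance map (e.g. from a promptable segmentation model) is available.
#' Uses `EBImage::bwlabel` when installed, otherwise the package's built-in
#' 4-connectivity labeller.
#'
#' @param mask 0/1 matrix.
#' @param method `"auto"`, `"ebimage"`, or `"builtin"`.
#' @return Integer matrix; 0 is background, components are 1..k.
#' @export
label_mask <- function(mask, method = c("auto", "ebimage", "builtin")) {
  method <- match.arg(method)
  use_eb <- method == "ebimage" ||
    (method == "auto" && requireNamespace("EBImage", quietly = TRUE))
  if (use_eb) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_rifseg("EBImage is not installed", "rifseg_missing_dependency")
    }
    lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask)))
    return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  }
  cpp_label_components(matrix(as.integer(mask != 0), nrow(mask)))
}

#' Extract leaf instances from an indexed label map
#'
#' One instance per distinct positive label; instances smaller than
#' `min_area` pixels are discarded as incomplete leaves.
#'
#' @param labelmap Integer matrix, 0 = background.
#' @param min_area Minimum pixel count for a complete leaf.
#' @return List of `leaf_instance` objects, each with `label`, `mask`,
#'   `area`, `rect` (see [min_area_rectangle()]) and `aspect_ratio`.
#' @export
extract_instances <- function(labelmap, min_area = 50) {
  labs <- sort(unique(labelmap[labelmap > 0]))
  out <- list()
  for (l in labs) {
    m <- matrix(as.integer(labelmap == l), nrow(labelmap), ncol(labelmap))
    area <- sum(m)
    if (area < min_area) next
    rect <- min_area_rectangle(m)
    out[[length(out) + 1L]] <-
      structure(list(label = l, mask = m, area = area, rect = rect,
                     aspect_ratio = aspect_ratio(rect)),
                class = "leaf_instance")
  }
  out
}

# Convex hull of the pixel squares: hull of pixel centers, then the four
# half-pixel corner offsets of each hull vertex (Minkowski sum with the unit
# square), hulled again. Guarantees the rectangle encloses full pixels, so an
# axis-aligned w x h filled rectangle measures exactly w x h.
pixel_hull <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_rifseg("mask has no foreground pixels", "rifseg_invalid_input")
  }
  pts <- cbind(x = idx[, 2], y = idx[, 1])
  h <- grDevices::chull(pts)
  pts <- pts[h, , drop = FALSE]
  corners <- rbind(cbind(pts[, 1] - 0.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] + 0.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] - 0.5, pts[, 2] + 0.5),
                   cbind(pts[, 1] + 0.5, pts[, 2] + 0.5))
  h2 <- grDevices::chull(corners)
  corners[h2, , drop = FALSE]
}

#' Minimum-area enclosing rotated rectangle of a leaf mask
#'
#' Rotating calipers over the convex hull of the instance's pixel squares:
#' the minimum-area rectangle has a side collinear with a hull edge, so each
#' edge direction is tested and the smallest-area bounding box kept. Ties
#' are broken by the smallest angle in `[0, 90)` degrees.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return List of class `min_rect`: `center` (x, y), `width`, `height`
#'   (side lengths in pixels), `angle` (degrees in `[0, 90)`), `area`.
#' @examples
#' m <- matrix(0L, 30, 40); m[10:19, 5:24] <- 1L  # 10 x 20 block
#' min_area_rectangle(m)[c("width", "height")]
#' @export
min_area_rectangle <- function(mask) {
  pts <- pixel_hull(mask)
  n <- nrow(pts)
  best <- NULL
  angles_done <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    theta <- atan2(e[2], e[1]) %% (pi / 2)   # box repeats every 90 degrees
    if (any(abs(angles_done - theta) < 1e-12)) next
    angles_done <- c(angles_done, theta)
    ct <- cos(theta); st <- sin(theta)
    u <- pts[, 1] * ct + pts[, 2] * st
    v <- -pts[, 1] * st + pts[, 2] * ct
    du <- diff(range(u)); dv <- diff(range(v))
    area <- du * dv
    if (is.null(best) || area < best$area - 1e-9 ||
        (abs(area - best$area) <= 1e-9 && theta < best$theta)) {
      cu <- mean(range(u)); cv <- mean(range(v))
      best <- list(area = area, theta = theta, width = du, height = dv,
                   center = c(x = cu * ct - cv * st, y = cu * st + cv * ct))
    }
  }
  structure(list(center = best$center, width = best$width,
                 height = best$height, angle = best$theta * 180 / pi,
                 area = best$area),
            class = "min_rect")
}

#' Aspect ratio of a rectangle
#'
#' Long side over short side, always `>= 1`.
#'
#' @param rect A [min_area_rectangle()] result, or any list with `width`
#'   and `height`.
#' @return Scalar `>= 1`.
#' @export
aspect_ratio <- function(rect) {
  w <- rect$width; h <- rect$height
  if (is.null(w) || is.null(h) || w <= 0 || h <= 0) {
    stop_rifseg("rectangle sides must be positive", "rifseg_invalid_input")
  }
  max(w, h) / min(w, h)
}

#' Summarize leaf aspect ratios for one genotype
#'
#' Five to ten complete leaves are used per genotype: fewer than five is an
#' error; if more are supplied, the `max_leaves` largest instances are kept.
#' The per-genotype value is the mean ratio.
#'
#' @param genotype_id Identifier.
#' @param instances List of `leaf_instance` objects ([extract_instances()]),
#'   or a numeric vector of aspect ratios.
#' @param min_leaves,max_leaves Bounds on the number of leaves used.
#' @return Object of class `genotype_morphology`: list with `genotype_id`,
#'   `leaf_ratios`, `mean_ratio`.
#' @export
genotype_morphology <- function(genotype_id, instances, min_leaves = 5,
                                max_leaves = 10) {
  if (is.numeric(instances)) {
    ratios <- instances
  } else {
    areas <- vapply(instances, function(i) i$area, numeric(1))
    if (length(instances) > max_leaves) {
      instances <- instances[order(areas, decreasing = TRUE)[seq_len(max_leaves)]]
    }
    ratios <- vapply(instances, function(i) i$aspect_ratio, numeric(1))
  }
  if (length(ratios) > max_leaves) ratios <- ratios[seq_len(max_leaves)]
  if (length(ratios) < min_leaves) {
    stop_rifseg(sprintf("genotype %s has %d complete leaves; at least %d are required",
                        genotype_id, length(ratios), min_leaves),
                "rifseg_invalid_input")
  }
  structure(list(genotype_id = genotype_id, leaf_ratios = ratios,
                 mean_ratio = mean(ratios)),
            class = "genotype_morphology")
}

# Deterministic 1-D two-cluster split (k-means with multiple restarts;
# two points split trivially, which kmeans() refuses to do).
split_two <- function(x, seed) {
  if (length(x) == 2L) {
    return(ifelse(seq_along(x) == which.min(x), "low", "high"))
  }
  km <- with_seed(seed, kmeans(x, centers = 2, nstart = 10))
  low <- which.min(km$centers)
  ifelse(km$cluster == low, "low", "high")
}

#' Two-stage leaf-type classification of a genotype panel
#'
#' Stage 1 partitions mean aspect ratios into two clusters: the cluster with
#' the smaller centroid is the oval leaf type (OLT), the other the
#' lanceolate leaf type (LLT). Stage 2 repeats the split within each major
#' class, labelling the lower-ratio cluster subclass A and the higher B.
#'
#' @param records List of [genotype_morphology()] objects, or a data frame
#'   with columns `genotype_id` and `mean_ratio`.
#' @param seed Integer seed for the k-means restarts.
#' @return Data frame: `genotype_id`, `mean_ratio`, `major_class`
#'   (`"OLT"`/`"LLT"`), `subclass` (`"A"`/`"B"`).
#' @export
classify_population <- function(records, seed = 1L) {
  if (is.data.frame(records)) {
    df <- records[, c("genotype_id", "mean_ratio")]
  } else {
    df <- do.call(rbind, lapply(records, function(r) {
      data.frame(genotype_id = r$genotype_id, mean_ratio = r$mean_ratio)
    }))
  }
  if (nrow(df) < 4) {
    stop_rifseg("at least 4 genotypes are required for the two-stage classification",
                "rifseg_invalid_input")
  }
  if (sd(df$mean_ratio) < 1e-9) {
    stop_rifseg("all mean ratios are identical; no cluster structure to recover",
                "rifseg_degenerate_input")
  }
  major <- split_two(df$mean_ratio, seed)
  df$major_class <- ifelse(major == "low", "OLT", "LLT")
  df$subclass <- NA_character_
  for (cl in c("OLT", "LLT")) {
    sel <- df$major_class == cl
    if (sum(sel) < 2 || sd(df$mean_ratio[sel]) < 1e-9) {
      df$subclass[sel] <- "A"
      if (sum(sel) > 0) {
        warning(sprintf("class %s has no internal spread; all assigned subclass A",
                        cl))
      }
      next
    }
    sub <- split_two(df$mean_ratio[sel], seed + 1L)
    df$subclass[sel] <- ifelse(sub == "low", "A", "B")
  }
  rownames(df) <- NULL
  df
}

#' Per-leaf morphometrics table for a scene
#'
#' Convenience wrapper running [extract_instances()] on a label map and
#' tabulating rectangle geometry and aspect ratio per leaf.
#'
#' @param labelmap Indexed label raster.
#' @param genotype_id Identifier column value.
#' @param min_area Passed to [extract_instances()].
#' @return Data frame: `genotype_id`, `leaf_id`, `width`, `height`, `angle`,
#'   `area_px`, `aspect_ratio`.
#' @export
leaf_table <- function(labelmap, genotype_id = "g1", min_area = 50) {
  inst <- extract_instances(labelmap, min_area = min_area)
  if (length(inst) == 0) {
    return(data.frame(genotype_id = character(0), leaf_id = integer(0),
                      width = numeric(0), height = numeric(0),
                      angle = numeric(0), area_px = numeric(0),
                      aspect_ratio = numeric(0)))
  }
  do.call(rbind, lapply(inst, function(i) {
    data.frame(genotype_id = genotype_id, leaf_id = i$label,
               width = i$rect$width, height = i$rect$height,
               angle = i$rect$angle, area_px = i$area,
               aspect_ratio = i$aspect_ratio)
  }))
}
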