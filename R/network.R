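# The dual-encoder fusion segmentation network.
#
# Two ResNet-style encoders (3-channel RGB, 1-channel infrared) reduce the
# input by a factor of 32; their feature maps are fused by elementwise
# summation; a symmetric decoder of Upception blocks restores the input
# resolution; a sigmoid head yields a per-pixel canopy probability map.

.resnet_plan <- list(
  `18` = list(block = "basic", counts = c(2, 2, 2, 2), expansion = 1L),
  `34` = list(block = "basic", counts = c(3, 4, 6, 3), expansion = 1L),
  `50` = list(block = "bottleneck", counts = c(3, 4, 6, 3), expansion = 4L),
  `101` = list(block = "bottleneck", counts = c(3, 4, 23, 3), expansion = 4L),
  `152` = list(block = "bottleneck", counts = c(3, 8, 36, 3), expansion = 4L)
)

make_basic_block <- function(cin, cout, stride) {
  down <- if (stride != 1L || cin != cout) {
    list(ly_conv(1, 1, cin, cout, stride = stride, pad = 0), ly_bn(cout))
  } else NULL
  list(kind = "res_basic",
       main = list(ly_conv(3, 3, cin, cout, stride = stride, pad = 1),
                   ly_bn(cout), ly_lrelu(),
                   ly_conv(3, 3, cout, cout, stride = 1, pad = 1),
                   ly_bn(cout)),
       down = down, act_out = ly_lrelu())
}

make_bottleneck_block <- function(cin, cmid, cout, stride) {
  down <- if (stride != 1L || cin != cout) {
    list(ly_conv(1, 1, cin, cout, stride = stride, pad = 0), ly_bn(cout))
  } else NULL
  list(kind = "res_basic",   # same forward/backward pattern as basic
       main = list(ly_conv(1, 1, cin, cmid, stride = 1, pad = 0),
                   ly_bn(cmid), ly_lrelu(),
                   ly_conv(3, 3, cmid, cmid, stride = stride, pad = 1),
                   ly_bn(cmid), ly_lrelu(),
                   ly_conv(1, 1, cmid, cout, stride = 1, pad = 0),
                   ly_bn(cout)),
       down = down, act_out = ly_lrelu())
}

residual_forward <- function(blk, x, train = FALSE) {
  y <- seq_forward(blk$main, x, train)
  idn <- if (is.null(blk$down)) x else seq_forward(blk$down, x, train)
  layer_forward(blk$act_out, y + idn, train)
}

residual_backward <- function(blk, dy) {
  d <- layer_backward(blk$act_out, dy)
  dmain <- seq_backward(blk$main, d)
  dskip <- if (is.null(blk$down)) d else seq_backward(blk$down, d)
  dmain + dskip
}

stage_forward <- function(blocks, x, train = FALSE) {
  for (b in blocks) x <- residual_forward(b, x, train)
  x
}

stage_backward <- function(blocks, dy) {
  for (b in rev(blocks)) dy <- residual_backward(b, dy)
  dy
}

#' Build a ResNet-style encoder
#'
#' The encoder is the standard residual backbone with classification parts
#' removed: an initial block (7x7 stride-2 convolution, batch normalization,
#' leaky ReLU), a 3x3 stride-2 max pool, and four residual stages; the
#' average-pool and fully connected layers are absent, so the output stride
#' is 32. The infrared encoder differs from the RGB encoder only in the
#' number of input channels of the first convolution.
#'
#' @param depth Backbone depth, one of 18, 34, 50, 101, 152.
#' @param in_channels 3 (RGB) or 1 (infrared).
#' @return An object of class `rifseg_encoder`.
#' @examples
#' enc <- build_encoder(18, 3)
#' dim(encoder_features(enc, array(rnorm(3 * 64 * 64), c(64, 64, 3)))$s4)
#' @export
build_encoder <- function(depth, in_channels) {
  plan <- .resnet_plan[[as.character(depth)]]
  if (is.null(plan)) {
    stop_rifseg("backbone depth must be one of 18, 34, 50, 101, 152",
                "rifseg_invalid_config")
  }
  if (!in_channels %in% c(1L, 3L)) {
    stop_rifseg("in_channels must be 1 (infrared) or 3 (RGB)",
                "rifseg_invalid_config")
  }
  widths <- c(64L, 128L, 256L, 512L)
  stages <- vector("list", 4L)
  cin <- 64L
  for (s in 1:4) {
    blocks <- vector("list", plan$counts[s])
    stride <- if (s == 1L) 1L else 2L
    cout <- widths[s] * plan$expansion
    for (b in seq_len(plan$counts[s])) {
      blocks[[b]] <- if (plan$block == "basic") {
        make_basic_block(cin, widths[s], if (b == 1L) stride else 1L)
      } else {
        make_bottleneck_block(cin, widths[s], cout, if (b == 1L) stride else 1L)
      }
      cin <- cout
    }
    stages[[s]] <- blocks
  }
  structure(list(depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 expansion = plan$expansion,
                 init = list(ly_conv(7, 7, in_channels, 64L, stride = 2,
                                     pad = 3),
                             ly_bn(64L), ly_lrelu()),
                 pool = ly_maxpool(3, 2, 1),
                 stages = stages),
            class = "rifseg_encoder")
}

#' Run an encoder and return its four stage outputs
#'
#' @param enc A [build_encoder()] object.
#' @param x Input array `H x W x C` with `C` matching the encoder.
#' @param train Logical; keep caches and use batch statistics for BN.
#' @return List with elements `s1`..`s4` (output strides 4, 8, 16, 32).
#' @export
encoder_features <- function(enc, x, train = FALSE) {
  if (length(dim(x)) != 3L || dim(x)[3] != enc$in_channels) {
    stop_rifseg(sprintf("encoder expects H x W x %d input", enc$in_channels),
                "rifseg_shape_error")
  }
  x <- seq_forward(enc$init, x, train)
  x <- layer_forward(enc$pool, x, train)
  s1 <- stage_forward(enc$stages[[1]], x, train)
  s2 <- stage_forward(enc$stages[[2]], s1, train)
  s3 <- stage_forward(enc$stages[[3]], s2, train)
  s4 <- stage_forward(enc$stages[[4]], s3, train)
  list(s1 = s1, s2 = s2, s3 = s3, s4 = s4)
}

# Backward through an encoder; d1..d3 are optional extra gradients injected
# at the corresponding stage outputs (per-stage fusion).
encoder_backward <- function(enc, d4, d3 = NULL, d2 = NULL, d1 = NULL) {
  d <- stage_backward(enc$stages[[4]], d4)
  if (!is.null(d3)) d <- d + d3
  d <- stage_backward(enc$stages[[3]], d)
  if (!is.null(d2)) d <- d + d2
  d <- stage_backward(enc$stages[[2]], d)
  if (!is.null(d1)) d <- d + d1
  d <- stage_backward(enc$stages[[1]], d)
  d <- layer_backward(enc$pool, d)
  seq_backward(enc$init, d)
  invisible(NULL)
}

# ---- Upception blocks -------------------------------------------------------

make_upception_a <- function(c) {
  list(kind = "upc_a",
       path = list(ly_conv(1, 1, c, c, stride = 1, pad = 0), ly_bn(c),
                   ly_lrelu(),
                   ly_conv(3, 3, c, c, stride = 1, pad = 1), ly_bn(c),
                   ly_lrelu(),
                   ly_conv(3, 3, c, c, stride = 1, pad = 1), ly_bn(c)),
       act_out = ly_lrelu())
}

# Variant B halves channels and doubles resolution. The published layer table
# lists TransConv 1 with stride 2 / padding 1 and TransConv 2 with stride 3 /
# padding 0 (kernel 2x2 each); under the standard transposed-convolution size
# formula those give 2h-2 and 3h-1, contradicting the table's own
# c/2 x 2h x 2w output column. The output-size contract wins: both transposed
# convolutions here use kernel 2, stride 2, padding 0, which maps h -> 2h.
make_upception_b <- function(c) {
  ch <- c %/% 2L
  list(kind = "upc_b",
       main = list(ly_conv(1, 1, c, ch, stride = 1, pad = 0), ly_bn(ch),
                   ly_lrelu(),
                   ly_conv(3, 3, ch, ch, stride = 1, pad = 1), ly_bn(ch),
                   ly_lrelu(),
                   ly_convT(2, 2, ch, ch, stride = 2, pad = 0), ly_bn(ch)),
       skip = list(ly_convT(2, 2, c, ch, stride = 2, pad = 0), ly_bn(ch)),
       act_out = ly_lrelu())
}

upc_a_forward <- function(blk, x, train = FALSE) {
  y <- seq_forward(blk$path, x, train)
  layer_forward(blk$act_out, y + x, train)
}

upc_a_backward <- function(blk, dy) {
  d <- layer_backward(blk$act_out, dy)
  seq_backward(blk$path, d) + d
}

upc_b_forward <- function(blk, x, train = FALSE) {
  y <- seq_forward(blk$main, x, train)
  s <- seq_forward(blk$skip, x, train)
  layer_forward(blk$act_out, y + s, train)
}

upc_b_backward <- function(blk, dy) {
  d <- layer_backward(blk$act_out, dy)
  seq_backward(blk$main, d) + seq_backward(blk$skip, d)
}

#' Apply an Upception block of variant A (shape-preserving)
#'
#' Variant A passes the input through three convolutions (kernels 1x1, 3x3,
#' 3x3, all shape-preserving) and adds the input back elementwise; channels
#' and resolution are unchanged.
#'
#' @param f Feature map, `C x H x W` given as an `H x W x C` array.
#' @param block Optionally a block built by a previous call (returned as
#'   attribute `block`); a fresh randomly initialised block is built
#'   otherwise.
#' @return Array of the same shape, with the block as attribute `block`.
#' @export
upception_a <- function(f, block = NULL) {
  stopifnot(length(dim(f)) == 3L)
  if (is.null(block)) block <- make_upception_a(dim(f)[3])
  out <- upc_a_forward(block, f, train = FALSE)
  attr(out, "block") <- block
  out
}

#' Apply an Upception block of variant B (upsampling)
#'
#' Variant B halves the channel count and doubles the spatial resolution:
#' a 1x1 convolution halving channels, a shape-preserving 3x3 convolution and
#' a 2x resolution transposed convolution on the main path, plus a transposed
#' convolution on the skip path that matches the main path's output shape
#' before elementwise summation.
#'
#' @inheritParams upception_a
#' @return Array of shape `2H x 2W x C/2`, with the block as attribute
#'   `block`.
#' @export
upception_b <- function(f, block = NULL) {
  stopifnot(length(dim(f)) == 3L)
  if (dim(f)[3] %% 2L != 0L) {
    stop_rifseg("Upception block B requires an even channel count",
                "rifseg_shape_error")
  }
  if (is.null(block)) block <- make_upception_b(dim(f)[3])
  out <- upc_b_forward(block, f, train = FALSE)
  attr(out, "block") <- block
  out
}

#' Fuse two feature maps by elementwise summation
#'
#' @param rgb_f,ir_f Feature maps of identical shape.
#' @return Their elementwise sum; the shape is unchanged by fusion.
#' @export
fuse <- function(rgb_f, ir_f) {
  if (!identical(dim(rgb_f), dim(ir_f))) {
    stop_rifseg(sprintf("cannot fuse feature maps of shapes (%s) and (%s)",
                        paste(dim(rgb_f), collapse = "x"),
                        paste(dim(ir_f), collapse = "x")),
                "rifseg_shape_error")
  }
  rgb_f + ir_f
}

# ---- Network assembly -------------------------------------------------------

#' Network specification
#'
#' @param backbone_depth Encoder depth: 18, 34, 50, 101 or 152.
#' @param input_size Length-2 `(H, W)`; each divisible by 32.
#' @param pretrained Logical; pretrained encoder weights are not bundled with
#'   the package, so only `FALSE` (random initialisation) is accepted.
#' @param fusion `"multi"` (default) sums the fused RGB+IR encoder features
#'   into the decoder at every matching scale; `"late"` fuses only at the
#'   deepest stage.
#' @param threshold Probability threshold used by [binarize()] defaults.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(backbone_depth = 18, input_size = c(96, 96),
                         pretrained = FALSE, fusion = c("multi", "late"),
                         threshold = 0.5) {
  if (is.null(.resnet_plan[[as.character(backbone_depth)]])) {
    stop_rifseg("backbone depth must be one of 18, 34, 50, 101, 152",
                "rifseg_invalid_config")
  }
  if (length(input_size) != 2L || any(input_size < 32) ||
      any(input_size %% 32 != 0)) {
    stop_rifseg("input_size must be two dimensions divisible by 32",
                "rifseg_invalid_config")
  }
  if (isTRUE(pretrained)) {
    stop_rifseg("pretrained encoder weights are not bundled; use pretrained = FALSE",
                "rifseg_invalid_config")
  }
  fusion <- match.arg(fusion)
  check_number(threshold, "threshold", lower = 1e-9, upper = 1 - 1e-9)
  structure(list(backbone_depth = as.integer(backbone_depth),
                 input_size = as.integer(input_size),
                 pretrained = FALSE, fusion = fusion, threshold = threshold),
            class = "network_spec")
}

#' Construct the fusion segmentation network
#'
#' Assembles the two encoders, the fusion stage, and the decoder: an
#' Upception-A block on the fused deepest features, then five Upception-B
#' stages (each doubling resolution and halving channels, mirroring the five
#' 2x reductions of the encoder) with Upception-A refinement between them,
#' and a 1x1 convolution + sigmoid head. With `fusion = "multi"` the fused
#' encoder features are additionally summed into the decoder at the three
#' scales where decoder and encoder shapes coincide.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for Kaiming-uniform weight initialisation.
#' @return An object of class `rifseg_net`.
#' @examples
#' net <- rifseg_net(network_spec(18, c(64, 64)), seed = 1)
#' net
#' @export
rifseg_net <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(seed, {
    enc_rgb <- build_encoder(spec$backbone_depth, 3L)
    enc_ir <- build_encoder(spec$backbone_depth, 1L)
    c4 <- 512L * enc_rgb$expansion
    stages <- vector("list", 5L)
    ch <- c4
    for (k in 1:5) {
      stages[[k]] <- list(b = make_upception_b(ch),
                          a = if (k < 5L) make_upception_a(ch %/% 2L) else NULL)
      ch <- ch %/% 2L
    }
    meta <- new.env(parent = emptyenv())
    meta$trained_steps <- 0L
    meta$loss_log <- NULL
    net <- structure(list(spec = spec, enc_rgb = enc_rgb, enc_ir = enc_ir,
                          dec = list(fuse_a = make_upception_a(c4),
                                     stages = stages,
                                     head = ly_conv(1, 1, ch, 1L, stride = 1,
                                                    pad = 0, bias = TRUE)),
                          norm = list(mean_rgb = rep(0.5, 3),
                                      sd_rgb = rep(0.25, 3),
                                      mean_ir = 0.5, sd_ir = 0.25),
                          meta = meta),
                     class = "rifseg_net")
    net
  })
}

net_layers <- function(net) {
  collect_layers(list(net$enc_rgb$init, net$enc_rgb$pool, net$enc_rgb$stages,
                      net$enc_ir$init, net$enc_ir$pool, net$enc_ir$stages,
                      net$dec))
}

normalize_inputs <- function(net, rgb, ir) {
  rgb01 <- rgb / 255
  for (c in 1:3) {
    rgb01[, , c] <- (rgb01[, , c] - net$norm$mean_rgb[c]) / net$norm$sd_rgb[c]
  }
  ir_n <- (ir - net$norm$mean_ir) / net$norm$sd_ir
  list(rgb = rgb01, ir = array(ir_n, c(dim(ir)[1], dim(ir)[2], 1L)))
}

check_input_dims <- function(net, rgb, ir) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop_rifseg("rgb must be an H x W x 3 array", "rifseg_shape_error")
  }
  if (is.matrix(ir)) ir <- array(ir, c(dim(ir), 1L))
  if (!identical(dim(rgb)[1:2], dim(ir)[1:2])) {
    stop_rifseg("rgb and infrared images must be co-registered (same H x W)",
                "rifseg_shape_error")
  }
  if (any(dim(rgb)[1:2] %% 32 != 0)) {
    stop_rifseg("input dimensions must be divisible by 32", "rifseg_shape_error")
  }
  invisible(NULL)
}

# Full forward pass. Returns the probability map; with train = TRUE the
# per-layer caches needed by rifseg_backward() are retained and the logits
# attached as an attribute.
rifseg_forward_impl <- function(net, rgb, ir, train = FALSE) {
  check_input_dims(net, rgb, ir)
  xs <- normalize_inputs(net, rgb, ir)
  er <- encoder_features(net$enc_rgb, xs$rgb, train)
  ei <- encoder_features(net$enc_ir, xs$ir, train)
  x <- fuse(er$s4, ei$s4)
  x <- upc_a_forward(net$dec$fuse_a, x, train)
  multi <- net$spec$fusion == "multi"
  skips <- list(er$s3 + ei$s3, er$s2 + ei$s2, er$s1 + ei$s1)
  for (k in 1:5) {
    st <- net$dec$stages[[k]]
    x <- upc_b_forward(st$b, x, train)
    if (multi && k <= 3L) x <- x + skips[[k]]
    if (!is.null(st$a)) x <- upc_a_forward(st$a, x, train)
  }
  logits <- layer_forward(net$dec$head, x, train)
  prob <- 1 / (1 + exp(-logits[, , 1]))
  if (train) attr(prob, "logits") <- logits[, , 1]
  prob
}

# Backward pass from d(loss)/d(logits); accumulates gradients in the layers.
rifseg_backward <- function(net, dlogits) {
  d <- layer_backward(net$dec$head, array(dlogits, c(dim(dlogits), 1L)))
  multi <- net$spec$fusion == "multi"
  denc <- list(NULL, NULL, NULL)   # extra gradients for encoder stages 3,2,1
  for (k in 5:1) {
    st <- net$dec$stages[[k]]
    if (!is.null(st$a)) d <- upc_a_backward(st$a, d)
    if (multi && k <= 3L) denc[[k]] <- d
    d <- upc_b_backward(st$b, d)
  }
  d4 <- upc_a_backward(net$dec$fuse_a, d)
  # fusion sums route identical gradients to both encoders
  encoder_backward(net$enc_rgb, d4, denc[[1]], denc[[2]], denc[[3]])
  encoder_backward(net$enc_ir, d4, denc[[1]], denc[[2]], denc[[3]])
  invisible(NULL)
}

#' Segment one RGB + infrared pair
#'
#' Runs the full network in evaluation mode (batch-norm running statistics)
#' and returns the canopy probability map at the input resolution.
#'
#' @param net A [rifseg_net()].
#' @param rgb `H x W x 3` array in `[0, 255]`.
#' @param ir `H x W` infrared matrix in `[0, 1]`.
#' @return `H x W` matrix of probabilities in `[0, 1]`.
#' @export
rifseg_forward <- function(net, rgb, ir) {
  stopifnot(inherits(net, "rifseg_net"))
  rifseg_forward_impl(net, rgb, ir, train = FALSE)
}

#' Threshold a probability map into a binary canopy mask
#'
#' Pixels with probability greater than or equal to the threshold are canopy
#' (the boundary is inclusive).
#'
#' @param p Probability map (matrix in `[0, 1]`).
#' @param threshold Scalar in `(0, 1)`; default 0.5.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(p, threshold = 0.5) {
  check_number(threshold, "threshold", lower = 1e-12, upper = 1 - 1e-12)
  m <- matrix(as.integer(p >= threshold), nrow(p), ncol(p))
  m
}

#' @describeIn rifseg_net Predict canopy probability or mask for a scene or
#'   an RGB/IR pair.
#' @param object A `rifseg_net`.
#' @param rgb,ir Image pair; alternatively pass a `rifseg_scene` as `rgb`.
#' @param type `"prob"` for the probability map, `"mask"` for the binarized
#'   mask at the spec threshold.
#' @param threshold Overrides the spec threshold for `type = "mask"`.
#' @param ... Unused.
#' @export
predict.rifseg_net <- function(object, rgb, ir = NULL,
                               type = c("prob", "mask"),
                               threshold = NULL, ...) {
  type <- match.arg(type)
  if (inherits(rgb, "rifseg_scene")) {
    ir <- rgb$ir
    rgb <- rgb$rgb
  }
  p <- rifseg_forward(object, rgb, ir)
  if (type == "prob") return(p)
  binarize(p, threshold %||% object$spec$threshold)
}

#' @export
print.rifseg_net <- function(x, ...) {
  n_par <- sum(vapply(net_layers(x), function(ly) {
    sum(vapply(param_names(ly), function(p) length(ly[[p]]), numeric(1)))
  }, numeric(1)))
  cat(sprintf("<rifseg_net> backbone ResNet-%d, fusion '%s', %s parameters\n",
              x$spec$backbone_depth, x$spec$fusion,
              format(n_par, big.mark = ",")))
  cat(sprintf("  input %dx%d, threshold %.2f, trained steps: %d\n",
              x$spec$input_size[1], x$spec$input_size[2], x$spec$threshold,
              x$meta$trained_steps))
  invisible(x)
}
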