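# Layer primitives for the segmentation network.
#
# Each layer is an environment (class "rif_layer") holding its parameters,
# gradient accumulators, optimiser state, and the forward cache of the most
# recent sample. Mutation-in-place keeps training free of large list copies;
# the network trains one image per step (batch size 1), so a single cache per
# layer suffices. Feature maps are H x W x C arrays of doubles.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- "rif_layer"
  e
}

# Kaiming-uniform fan-in initialisation with leaky-ReLU gain.
kaiming_uniform <- function(n, fan_in, slope = 0.01) {
  gain <- sqrt(2 / (1 + slope^2))
  bound <- gain * sqrt(3 / fan_in)
  runif(n, -bound, bound)
}

ly_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L, bias = FALSE) {
  fan_in <- kh * kw * cin
  w <- matrix(kaiming_uniform(fan_in * cout, fan_in), fan_in, cout)
  b <- if (bias) numeric(cout) else NULL
  new_layer("conv", kh = as.integer(kh), kw = as.integer(kw),
            cin = as.integer(cin), cout = as.integer(cout),
            stride = as.integer(stride), pad = as.integer(pad),
            w = w, b = b)
}

ly_convT <- function(kh, kw, cin, cout, stride = 2L, pad = 0L, bias = FALSE) {
  fan_in <- kh * kw * cin            # per output unit, pre-stride
  w <- matrix(kaiming_uniform(kh * kw * cout * cin, fan_in),
              kh * kw * cout, cin)
  b <- if (bias) numeric(cout) else NULL
  new_layer("convT", kh = as.integer(kh), kw = as.integer(kw),
            cin = as.integer(cin), cout = as.integer(cout),
            stride = as.integer(stride), pad = as.integer(pad),
            w = w, b = b)
}

ly_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", c = as.integer(c), momentum = momentum, eps = eps,
            gamma = rep(1, c), beta = numeric(c),
            running_mean = numeric(c), running_var = rep(1, c))
}

ly_lrelu <- function(slope = 0.01) new_layer("lrelu", slope = slope)

ly_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

layer_forward <- function(ly, x, train = FALSE) {
  switch(ly$type,
    conv = {
      y <- cpp_conv2d_fw(x, ly$w, ly$b %||% numeric(0),
                         ly$kh, ly$kw, ly$stride, ly$pad)
      if (train) ly$cache_x <- x
      y
    },
    convT = {
      y <- cpp_convT_fw(x, ly$w, ly$b %||% numeric(0),
                        ly$kh, ly$kw, ly$stride, ly$pad, ly$cout)
      if (train) ly$cache_x <- x
      y
    },
    bn = {
      # Normalization over the sample's own H x W extent in training AND
      # inference: with one image per step the batch degenerates to the
      # instance, and reusing the same statistics at test time keeps the two
      # modes identical (averaged running statistics are still tracked for
      # diagnostics and checkpoints).
      d <- dim(x)
      n <- d[1] * d[2]
      xm <- x
      dim(xm) <- c(n, d[3])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc * xc)
      invstd <- 1 / sqrt(v + ly$eps)
      xhat <- sweep(xc, 2, invstd, `*`)
      if (train) {
        ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
        ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * v
        ly$cache_xhat <- xhat
        ly$cache_invstd <- invstd
      }
      y <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
      dim(y) <- d
      y
    },
    lrelu = {
      neg <- x < 0
      if (train) ly$cache_neg <- neg
      x[neg] <- x[neg] * ly$slope
      x
    },
    maxpool = {
      r <- cpp_maxpool_fw(x, ly$k, ly$stride, ly$pad)
      if (train) {
        ly$cache_argmax <- r$argmax
        ly$cache_dim <- dim(x)
      }
      r$y
    },
    stop("unknown layer type: ", ly$type))
}

layer_backward <- function(ly, dy) {
  switch(ly$type,
    conv = {
      r <- cpp_conv2d_bw(ly$cache_x, ly$w, dy, ly$kh, ly$kw,
                         ly$stride, ly$pad, TRUE, !is.null(ly$b))
      ly$gw <- if (is.null(ly$gw)) r$dw else ly$gw + r$dw
      if (!is.null(ly$b)) {
        ly$gb <- if (is.null(ly$gb)) as.numeric(r$db) else ly$gb + as.numeric(r$db)
      }
      r$dx
    },
    convT = {
      r <- cpp_convT_bw(ly$cache_x, ly$w, dy, ly$kh, ly$kw,
                        ly$stride, ly$pad, TRUE, !is.null(ly$b))
      ly$gw <- if (is.null(ly$gw)) r$dw else ly$gw + r$dw
      if (!is.null(ly$b)) {
        ly$gb <- if (is.null(ly$gb)) as.numeric(r$db) else ly$gb + as.numeric(r$db)
      }
      r$dx
    },
    bn = {
      d <- dim(dy)
      n <- d[1] * d[2]
      dym <- dy
      dim(dym) <- c(n, d[3])
      xhat <- ly$cache_xhat
      dgamma <- colSums(dym * xhat)
      dbeta <- colSums(dym)
      ly$ggamma <- if (is.null(ly$ggamma)) dgamma else ly$ggamma + dgamma
      ly$gbeta <- if (is.null(ly$gbeta)) dbeta else ly$gbeta + dbeta
      # dx = invstd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
      dxhat <- sweep(dym, 2, ly$gamma, `*`)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- sweep(sweep(n * dxhat, 2, s1) - sweep(xhat, 2, s2, `*`),
                  2, ly$cache_invstd / n, `*`)
      dim(dx) <- d
      dx
    },
    lrelu = {
      dy[ly$cache_neg] <- dy[ly$cache_neg] * ly$slope
      dy
    },
    maxpool = {
      d <- ly$cache_dim
      cpp_maxpool_bw(dy, ly$cache_argmax, d[1], d[2], d[3])
    },
    stop("unknown layer type: ", ly$type))
}

seq_forward <- function(layers, x, train = FALSE) {
  for (ly in layers) x <- layer_forward(ly, x, train)
  x
}

seq_backward <- function(layers, dy) {
  for (ly in rev(layers)) dy <- layer_backward(ly, dy)
  dy
}

# Recursively collect all rif_layer environments under a (nested) list.
collect_layers <- function(x) {
  if (inherits(x, "rif_layer")) return(list(x))
  if (is.list(x)) return(unlist(lapply(x, collect_layers), recursive = FALSE))
  list()
}

param_names <- function(ly) {
  switch(ly$type,
    conv = ,
    convT = c("w", if (!is.null(ly$b)) "b"),
    bn = c("gamma", "beta"),
    character(0))
}

grad_name <- function(p) {
  c(w = "gw", b = "gb", gamma = "ggamma", beta = "gbeta")[[p]]
}

zero_grads <- function(layers) {
  for (ly in layers) {
    for (g in c("gw", "gb", "ggamma", "gbeta")) {
      if (!is.null(ly[[g]])) ly[[g]] <- NULL
    }
  }
  invisible(NULL)
}

clear_caches <- function(layers) {
  for (ly in layers) {
    for (cn in grep("^cache_", ls(ly), value = TRUE)) rm(list = cn, envir = ly)
  }
  invisible(NULL)
}

# One Adam step over every parameter of every layer, in place.
adam_step <- function(layers, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t = 1L) {
  for (ly in layers) {
    for (p in param_names(ly)) {
      g <- ly[[grad_name(p)]]
      if (is.null(g)) next
      ms <- paste0("adam_m_", p)
      vs <- paste0("adam_v_", p)
      if (is.null(ly[[ms]])) {
        ly[[ms]] <- ly[[p]] * 0
        ly[[vs]] <- ly[[p]] * 0
      }
      cpp_adam_step(ly[[p]], g, ly[[ms]], ly[[vs]], lr, beta1, beta2, eps, t)
    }
  }
  invisible(NULL)
}

# Flat named list of parameter values (copies), for checkpointing.
export_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (p in param_names(ly)) out[[sprintf("L%04d.%s", i, p)]] <- ly[[p]]
    if (ly$type == "bn") {
      out[[sprintf("L%04d.running_mean", i)]] <- ly$running_mean
      out[[sprintf("L%04d.running_var", i)]] <- ly$running_var
    }
  }
  out
}

import_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (p in c(param_names(ly),
                if (ly$type == "bn") c("running_mean", "running_var"))) {
      key <- sprintf("L%04d.%s", i, p)
      if (is.null(params[[key]])) {
        stop_rifseg(sprintf("checkpoint is missing parameter %s", key),
                    "rifseg_checkpoint_error")
      }
      val <- params[[key]]
      if (!identical(dim(ly[[p]]), dim(val)) ||
          length(ly[[p]]) != length(val)) {
        stop_rifseg(sprintf("checkpoint parameter %s has the wrong shape", key),
                    "rifseg_checkpoint_error")
      }
      ly[[p]] <- val
    }
  }
  invisible(NULL)
}
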