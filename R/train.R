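# Single-image-per-step training of the fusion segmentation network (the
# reference training regime uses batch size 1), with Adam updates and
# per-component loss logging.

# d(total loss)/d(logits) for one sample; the network output plays I_F.
training_grad_logits <- function(p, truth, triple, cfg, w) {
  n <- length(p)
  g <- w$lambda_sup * (p - truth) / n
  if (w$phi > 0) {
    g <- g + w$phi * l_ssim_grad(triple, cfg) * p * (1 - p)
  }
  g + l_tv_grad(triple$I_A, triple$I_F) * p * (1 - p)
}

# Per-channel standardization statistics from the training split.
input_norm_stats <- function(scenes) {
  rs <- sapply(scenes, function(s) apply(s$rgb / 255, 3, mean))
  r2 <- sapply(scenes, function(s) apply(s$rgb / 255, 3, sd))
  list(mean_rgb = rowMeans(rs), sd_rgb = pmax(rowMeans(r2), 1e-3),
       mean_ir = mean(vapply(scenes, function(s) mean(s$ir), numeric(1))),
       sd_ir = max(mean(vapply(scenes, function(s) sd(s$ir), numeric(1))),
                   1e-3))
}

#' Train the fusion segmentation network
#'
#' Runs `steps` optimization steps, one scene per step (cycling through the
#' training set in order), minimizing
#' `lambda_sup * BCE + phi * L_SSIM + L_TV` with Adam. The default
#' `lambda_sup` equals the pixel count so that the supervised term is a
#' pixel-wise sum on the same summation convention as the total-variation
#' term; `phi` keeps the SSIM term at a comparable order of magnitude.
#' Input standardization statistics are computed from the training scenes
#' and stored in the network.
#'
#' @param net A [rifseg_net()]; its weights are updated in place and the
#'   (same) network is returned.
#' @param scenes List of `rifseg_scene` objects (or lists with elements
#'   `rgb`, `ir`, `mask`).
#' @param steps Number of optimization steps.
#' @param lr Adam learning rate.
#' @param cfg An [ssim_config()] for the SSIM term.
#' @param weights A [loss_weights()]; defaults to `phi = 10` and
#'   `lambda_sup = H * W`.
#' @param seed Integer seed (ordering-independent reproducibility of any
#'   stochastic part of the run).
#' @param verbose Print a progress line every 25 steps.
#' @return The trained network, invisibly; the per-step component losses are
#'   available as `net$meta$loss_log`.
#' @export
train_rifseg <- function(net, scenes, steps = 200, lr = 1e-3,
                         cfg = ssim_config(), weights = NULL,
                         seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "rifseg_net"), length(scenes) >= 1)
  hw <- dim(scenes[[1]]$rgb)[1:2]
  weights <- weights %||% loss_weights(phi = 10, lambda_sup = prod(hw))
  net$norm <- input_norm_stats(scenes)
  layers <- net_layers(net)
  log <- vector("list", steps)
  with_seed(seed, {
    for (step in seq_len(steps)) {
      sc <- scenes[[(step - 1L) %% length(scenes) + 1L]]
      p <- rifseg_forward_impl(net, sc$rgb, sc$ir, train = TRUE)
      triple <- fusion_triple(luminance(sc$rgb), sc$ir, unclass_prob(p))
      loss <- training_loss(unclass_prob(p), sc$mask, triple, cfg, weights)
      dlog <- training_grad_logits(unclass_prob(p), sc$mask, triple, cfg,
                                   weights)
      zero_grads(layers)
      rifseg_backward(net, dlog)
      net$meta$trained_steps <- net$meta$trained_steps + 1L
      adam_step(layers, lr = lr, t = net$meta$trained_steps)
      log[[step]] <- data.frame(step = net$meta$trained_steps,
                                total = as.numeric(loss),
                                bce = attr(loss, "bce"),
                                l_ssim = attr(loss, "l_ssim"),
                                l_tv = attr(loss, "l_tv"))
      if (verbose && step %% 25 == 0) {
        message(sprintf("step %4d  total %.4f  bce %.4f", step,
                        as.numeric(loss), attr(loss, "bce")))
      }
    }
  })
  clear_caches(layers)
  net$meta$loss_log <- rbind(net$meta$loss_log, do.call(rbind, log))
  invisible(net)
}

unclass_prob <- function(p) {
  attr(p, "logits") <- NULL
  p
}

#' One training step's loss before and after an update
#'
#' Convenience for smoke-checking gradient flow: performs a single Adam step
#' on one scene and reports the training loss before and after.
#'
#' @param net A [rifseg_net()].
#' @param scene One `rifseg_scene`.
#' @param lr Learning rate.
#' @param cfg,weights Loss configuration as in [train_rifseg()].
#' @return Named numeric vector `c(before = , after = )`.
#' @export
training_step_delta <- function(net, scene, lr = 1e-4, cfg = ssim_config(),
                                weights = NULL) {
  hw <- dim(scene$rgb)[1:2]
  weights <- weights %||% loss_weights(phi = 10, lambda_sup = prod(hw))
  net$norm <- input_norm_stats(list(scene))
  layers <- net_layers(net)
  eval_loss <- function() {
    p <- rifseg_forward_impl(net, scene$rgb, scene$ir, train = TRUE)
    triple <- fusion_triple(luminance(scene$rgb), scene$ir, unclass_prob(p))
    list(p = p, triple = triple,
         loss = training_loss(unclass_prob(p), scene$mask, triple, cfg,
                              weights))
  }
  e1 <- eval_loss()
  dlog <- training_grad_logits(unclass_prob(e1$p), scene$mask, e1$triple,
                               cfg, weights)
  zero_grads(layers)
  rifseg_backward(net, dlog)
  net$meta$trained_steps <- net$meta$trained_steps + 1L
  adam_step(layers, lr = lr, t = net$meta$trained_steps)
  e2 <- eval_loss()
  clear_caches(layers)
  c(before = as.numeric(e1$loss), after = as.numeric(e2$loss))
}

#' Save / load a trained network checkpoint
#'
#' Single-file versioned checkpoint holding the spec, normalization
#' statistics, every parameter and batch-norm running statistic, and the
#' training step counter.
#'
#' @param net A [rifseg_net()].
#' @param path File path.
#' @return `save_rifseg` returns `path` invisibly; `load_rifseg` returns the
#'   restored network.
#' @export
save_rifseg <- function(net, path) {
  stopifnot(inherits(net, "rifseg_net"))
  layers <- net_layers(net)
  saveRDS(list(format = "rifseg_checkpoint", version = 1L,
               spec = net$spec, norm = net$norm,
               trained_steps = net$meta$trained_steps,
               params = export_params(layers)),
          path)
  invisible(path)
}

#' @rdname save_rifseg
#' @param seed Seed used to rebuild the layer graph before weights are
#'   restored (any value; the weights are overwritten).
#' @export
load_rifseg <- function(path, seed = 1L) {
  ck <- readRDS(path)
  if (!identical(ck$format, "rifseg_checkpoint")) {
    stop_rifseg("not a rifseg checkpoint file", "rifseg_checkpoint_error")
  }
  net <- rifseg_net(ck$spec, seed = seed)
  import_params(net_layers(net), ck$params)
  net$norm <- ck$norm
  net$meta$trained_steps <- ck$trained_steps
  net
}
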