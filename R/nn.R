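# Minimal convolutional network engine.
#
# Layers are environments holding parameters, gradient accumulators and
# forward caches; tensors are plain R arrays [H, W, C] so they interoperate
# with the image code without copying conventions around. The heavy kernels
# (im2col convolution, depthwise convolution, pooling, upsampling) live in
# src/convops.cpp. Everything is deterministic given the R RNG state: layer
# construction draws initial weights with rnorm() in a fixed order.

`%||%` <- function(a, b) if (is.null(a)) b else a


nn_conv <- function(kh, kw, cin, cout, stride = 1L, pad = kh %/% 2L,
                    dil = 1L, gain = 2, act = c("none", "relu")) {
  act <- match.arg(act)
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$kh <- as.integer(kh); e$kw <- as.integer(kw)
  e$cin <- as.integer(cin); e$cout <- as.integer(cout)
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$dil <- as.integer(dil); e$relu <- as.integer(act == "relu")
  sd <- sqrt(gain / (kh * kw * cin))
  e$W <- matrix(stats::rnorm(kh * kw * cin * cout, sd = sd),
                nrow = kh * kw * cin, ncol = cout)
  e$b <- numeric(cout)
  e$gW <- e$W * 0; e$gb <- e$b * 0
  e
}

nn_dwconv <- function(k, channels, dil = 1L, gain = 2) {
  e <- new.env(parent = emptyenv())
  e$type <- "dwconv"
  e$k <- as.integer(k); e$dil <- as.integer(dil)
  e$pad <- as.integer((k %/% 2L) * dil)
  sd <- sqrt(gain / (k * k))
  e$W <- array(stats::rnorm(k * k * channels, sd = sd), dim = c(k, k, channels))
  e$b <- numeric(channels)
  e$gW <- e$W * 0; e$gb <- e$b * 0
  e
}

nn_linear <- function(nin, nout) {
  e <- new.env(parent = emptyenv())
  e$type <- "linear"
  e$W <- matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  e$b <- numeric(nout)
  e$gW <- e$W * 0; e$gb <- e$b * 0
  e
}

nn_state <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e
}

layer_fwd <- function(l, x) {
  switch(l$type,
    conv = {
      l$x <- x
      y <- .cpp_conv_fwd(x, l$W, l$b, l$kh, l$kw, l$stride, l$pad, l$dil,
                         l$relu)
      if (l$relu) l$y <- y
      y
    },
    dwconv = {
      l$x <- x
      .cpp_dwconv_fwd(x, l$W, l$b, l$pad, l$dil)
    },
    linear = {
      l$x <- as.numeric(x)
      drop(l$x %*% l$W) + l$b
    },
    relu = {
      l$y <- .cpp_relu_fwd(x)
      l$y
    },
    maxpool2 = {
      r <- .cpp_maxpool2_fwd(x)
      l$idx <- r$idx; l$H <- dim(x)[1]; l$W_in <- dim(x)[2]
      r$y
    },
    upsample2 = .cpp_upsample_fwd(x, 2L),
    stop("unknown layer type: ", l$type)
  )
}

layer_bwd <- function(l, g) {
  switch(l$type,
    conv = {
      r <- .cpp_conv_bwd(l$x, l$W, g, l$kh, l$kw, l$stride, l$pad, l$dil,
                         if (l$relu) l$y else NULL)
      l$gW <- l$gW + r$gw; l$gb <- l$gb + as.numeric(r$gb)
      r$gx
    },
    dwconv = {
      r <- .cpp_dwconv_bwd(l$x, l$W, g, l$pad, l$dil)
      l$gW <- l$gW + r$gw; l$gb <- l$gb + as.numeric(r$gb)
      r$gx
    },
    linear = {
      g <- as.numeric(g)
      l$gW <- l$gW + outer(l$x, g)
      l$gb <- l$gb + g
      drop(l$W %*% g)
    },
    relu = .cpp_relu_bwd(l$y, g),
    maxpool2 = .cpp_maxpool2_bwd(l$idx, g, l$H, l$W_in),
    upsample2 = .cpp_upsample_bwd(g, 2L),
    stop("unknown layer type: ", l$type)
  )
}

param_layers <- function(layers) {
  Filter(function(l) l$type %in% c("conv", "dwconv", "linear"), layers)
}

zero_grads <- function(layers) {
  for (l in param_layers(layers)) {
    l$gW <- l$gW * 0
    l$gb <- l$gb * 0
  }
  invisible(NULL)
}

n_params <- function(layers) {
  sum(vapply(param_layers(layers),
             function(l) length(l$W) + length(l$b), numeric(1)))
}

# Decoupled weight decay (AdamW); wd = 0 gives plain Adam. Gradients are
# averaged over the minibatch by the caller before the step.
adam_step <- function(layers, lr, t, wd = 0, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in param_layers(layers)) {
    if (is.null(l$mW)) {
      l$mW <- l$gW * 0; l$vW <- l$gW * 0
      l$mb <- l$gb * 0; l$vb <- l$gb * 0
    }
    l$mW <- beta1 * l$mW + (1 - beta1) * l$gW
    l$vW <- beta2 * l$vW + (1 - beta2) * l$gW^2
    l$mb <- beta1 * l$mb + (1 - beta1) * l$gb
    l$vb <- beta2 * l$vb + (1 - beta2) * l$gb^2
    mh <- l$mW / (1 - beta1^t); vh <- l$vW / (1 - beta2^t)
    l$W <- l$W - lr * (mh / (sqrt(vh) + eps) + wd * l$W)
    mh <- l$mb / (1 - beta1^t); vh <- l$vb / (1 - beta2^t)
    l$b <- l$b - lr * mh / (sqrt(vh) + eps)
  }
  invisible(NULL)
}

cosine_lr <- function(lr0, epoch, n_epochs, lr_min = 1e-6) {
  lr_min <- min(lr_min, lr0)  # lr0 = 0 must stay exactly 0
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max(1, n_epochs - 1)))
}

# Serialize / restore trainable parameters (environments don't survive
# plain saveRDS round-trips meaningfully for our purposes).
nn_weights <- function(layers) {
  lapply(param_layers(layers), function(l) list(W = l$W, b = l$b))
}

nn_set_weights <- function(layers, weights) {
  pl <- param_layers(layers)
  stopifnot(length(pl) == length(weights))
  for (i in seq_along(pl)) {
    stopifnot(identical(dim(pl[[i]]$W), dim(weights[[i]]$W) %||% dim(pl[[i]]$W)))
    pl[[i]]$W <- weights[[i]]$W
    pl[[i]]$b <- weights[[i]]$b
  }
  invisible(NULL)
}
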