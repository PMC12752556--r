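# Compact pyramid-fusion encoder-decoder for nuclear segmentation.
#
# The network is a U-shaped encoder-decoder with skip connections. With
# pyramid fusion enabled, the decoder's output at every scale is upsampled
# to full resolution, concatenated, and fused by a 1x1 projection before
# the per-pixel foreground head - a feature-pyramid reading that keeps the
# parameter budget far below a DeepLab-v1-style reference (see
# [deeplab_reference_params()]). Training uses pixel-wise binary
# cross-entropy plus Dice loss with equal weights.

#' Segmentation network configuration
#'
#' @param depth number of encoder stages (>= 2).
#' @param base_width channels at stage 1 (>= 4); stage i uses
#'   `base_width * 2^(i-1)`.
#' @param pyramid_fusion fuse decoder outputs across scales before the
#'   foreground head.
#' @param input_size input raster side in pixels; must be divisible by
#'   `2^depth`.
#' @return object of class `seg_net_config`.
#' @export
seg_net_config <- function(depth = 3L, base_width = 8L,
                           pyramid_fusion = TRUE, input_size = 128L) {
  if (depth < 2) stop("depth must be at least 2", call. = FALSE)
  if (base_width < 4) stop("base_width must be at least 4", call. = FALSE)
  if (input_size %% (2^depth) != 0)
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 pyramid_fusion = isTRUE(pyramid_fusion),
                 input_size = as.integer(input_size)),
            class = "seg_net_config")
}

#' The "tiny" desk-scale segmentation preset
#' @return a [seg_net_config()] with depth 3, base width 8, input 128.
#' @export
seg_net_tiny <- function() seg_net_config(3L, 8L, TRUE, 128L)

#' Build the segmentation network
#'
#' @param config a [seg_net_config()].
#' @param init_seed seed for weight initialisation; two builds with the same
#'   config and seed produce identical parameters.
#' @return object of class `seg_net` with elements `config`, `layers` and
#'   `n_params`.
#' @export
build_seg_net <- function(config, init_seed = 0L) {
  stopifnot(inherits(config, "seg_net_config"))
  d <- config$depth
  ch <- config$base_width * 2^(0:(d - 1))
  with_seed(init_seed, {
    L <- list()
    prev <- 3L
    for (i in 1:d) {
      L[[paste0("enc", i, "a")]] <- nn_conv(3, 3, prev, ch[i], act = "relu")
      L[[paste0("enc", i, "b")]] <- nn_conv(3, 3, ch[i], ch[i], act = "relu")
      if (i < d) L[[paste0("pool", i)]] <- nn_state("maxpool2")
      prev <- ch[i]
    }
    for (j in (d - 1):1) {
      L[[paste0("up", j)]] <- nn_state("upsample2")
      cin <- ch[j + 1] + ch[j]
      L[[paste0("dec", j, "a")]] <- nn_conv(3, 3, cin, ch[j], act = "relu")
      L[[paste0("dec", j, "b")]] <- nn_conv(3, 3, ch[j], ch[j], act = "relu")
    }
    if (config$pyramid_fusion) {
      L[["fuse"]] <- nn_conv(1, 1, sum(ch), config$base_width, pad = 0L,
                             act = "relu")
      L[["head"]] <- nn_conv(1, 1, config$base_width, 1L, pad = 0L)
    } else {
      L[["head"]] <- nn_conv(1, 1, ch[1], 1L, pad = 0L)
    }
    structure(list(config = config, layers = L, n_params = n_params(L)),
              class = "seg_net")
  })
}

# Forward pass; caches live inside the layer environments, plus the concat
# split sizes needed by the backward pass (returned invisibly via the
# model-level cache environment).
seg_forward <- function(net, x) {
  L <- net$layers
  d <- net$config$depth
  ch <- net$config$base_width * 2^(0:(d - 1))
  skips <- vector("list", d - 1)
  h <- x
  for (i in 1:d) {
    h <- layer_fwd(L[[paste0("enc", i, "a")]], h)
    h <- layer_fwd(L[[paste0("enc", i, "b")]], h)
    if (i < d) {
      skips[[i]] <- h
      h <- layer_fwd(L[[paste0("pool", i)]], h)
    }
  }
  scale_out <- vector("list", d)
  scale_out[[d]] <- h
  for (j in (d - 1):1) {
    h <- layer_fwd(L[[paste0("up", j)]], h)
    hcat <- abind3(h, skips[[j]])
    h <- layer_fwd(L[[paste0("dec", j, "a")]], hcat)
    h <- layer_fwd(L[[paste0("dec", j, "b")]], h)
    scale_out[[j]] <- h
  }
  if (net$config$pyramid_fusion) {
    # 1x1 fusion commutes with nearest upsampling, so project each scale
    # at its native resolution and sum the upsampled projections; the
    # ReLU applies to the summed pre-activation
    fuse <- L[["fuse"]]
    fuse$x_scales <- scale_out
    acc <- NULL
    off <- 0L
    zero_b <- numeric(length(fuse$b))
    for (j in 1:d) {
      k <- ch[j]
      Wj <- fuse$W[off + seq_len(k), , drop = FALSE]
      yj <- .cpp_conv_fwd(scale_out[[j]], Wj, zero_b, 1L, 1L, 1L, 0L, 1L)
      f <- 2^(j - 1)
      if (f > 1) yj <- .cpp_upsample_fwd(yj, f)
      acc <- if (is.null(acc)) yj else acc + yj
      off <- off + k
    }
    acc <- sweep(acc, 3, fuse$b, `+`)
    h <- .cpp_relu_fwd(acc)
    fuse$y <- h
  }
  logits <- layer_fwd(L[["head"]], h)[, , 1]
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits)
}

# Backward pass from d(loss)/d(logits).
seg_backward <- function(net, glogits) {
  L <- net$layers
  d <- net$config$depth
  ch <- net$config$base_width * 2^(0:(d - 1))
  g <- layer_bwd(L[["head"]], array(glogits, c(dim(glogits), 1L)))
  gscale <- vector("list", d)
  if (net$config$pyramid_fusion) {
    fuse <- L[["fuse"]]
    g <- .cpp_relu_bwd(fuse$y, g)
    fuse$gb <- fuse$gb + colSums(matrix(g, ncol = dim(g)[3]))
    off <- 0L
    for (j in 1:d) {
      k <- ch[j]
      f <- 2^(j - 1)
      gj <- if (f == 1) g else .cpp_upsample_bwd(g, f)
      Wj <- fuse$W[off + seq_len(k), , drop = FALSE]
      r <- .cpp_conv_bwd(fuse$x_scales[[j]], Wj, gj, 1L, 1L, 1L, 0L, 1L)
      fuse$gW[off + seq_len(k), ] <- fuse$gW[off + seq_len(k), ] + r$gw
      gscale[[j]] <- r$gx
      off <- off + k
    }
  } else {
    gscale[[1]] <- g
    for (j in 2:d) gscale[[j]] <- 0
  }
  gskip <- vector("list", d - 1)
  gh <- NULL
  for (j in 1:(d - 1)) {
    g <- gscale[[j]]
    if (!is.null(gh)) g <- g + gh
    g <- layer_bwd(L[[paste0("dec", j, "a")]],
                   layer_bwd(L[[paste0("dec", j, "b")]], g))
    gup <- g[, , seq_len(ch[j + 1]), drop = FALSE]
    gskip[[j]] <- g[, , ch[j + 1] + seq_len(ch[j]), drop = FALSE]
    gh <- layer_bwd(L[[paste0("up", j)]], gup)
  }
  g <- gh
  if (!identical(gscale[[d]], 0) && !is.null(gscale[[d]]))
    g <- g + gscale[[d]]
  for (i in d:1) {
    if (i < d) {
      g <- layer_bwd(L[[paste0("pool", i)]], g)
      g <- g + gskip[[i]]
    }
    g <- layer_bwd(L[[paste0("enc", i, "a")]],
                   layer_bwd(L[[paste0("enc", i, "b")]], g))
  }
  invisible(NULL)
}

abind3 <- function(...) .cpp_concat3(list(...))

# BCE + Dice loss on a probability raster; returns loss value and gradient
# with respect to the logits.
seg_loss <- function(prob, target, smooth = 1) {
  n <- length(prob)
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  inter <- sum(p * target)
  denom <- sum(p) + sum(target) + smooth
  dice <- 1 - (2 * inter + smooth) / denom
  # d(bce)/d(logit) = (p - y)/n ; d(dice)/dp then chained through sigmoid
  g_bce <- (prob - target) / n
  g_dice_p <- -(2 * target * denom - (2 * inter + smooth)) / denom^2
  g_dice <- g_dice_p * prob * (1 - prob)
  list(loss = bce + dice, grad = g_bce + g_dice)
}

#' Train the segmentation network on synthetic patches
#'
#' Binary targets are taken from each patch's instance mask (`mask > 0`).
#' Optimised with Adam on BCE + Dice (equal weights); deterministic given
#' `seed`.
#'
#' @param net a [build_seg_net()] model.
#' @param patches list of `synth_patch` whose size equals the network input.
#' @param epochs,lr,batch_size training hyper-parameters.
#' @param seed seed controlling shuffling.
#' @return the trained net, with a numeric `loss_trace` (mean per-epoch
#'   training loss) attached.
#' @export
train_seg_net <- function(net, patches, epochs = 30L, lr = 1e-3,
                          batch_size = 5L, seed = 0L) {
  stopifnot(inherits(net, "seg_net"))
  if (length(patches) < 1) stop("empty training set", call. = FALSE)
  sz <- net$config$input_size
  for (p in patches)
    if (!all(dim(p$mask) == sz))
      stop("patch size does not match network input size", call. = FALSE)
  xs <- lapply(patches, function(p) p$image)
  ys <- lapply(patches, function(p) (p$mask > 0) * 1)
  n <- length(xs)
  trace <- numeric(epochs)
  with_seed(seed, {
    t_step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        zero_grads(net$layers)
        bl <- 0
        for (i in idx) {
          fw <- seg_forward(net, xs[[i]])
          ls <- seg_loss(fw$prob, ys[[i]])
          bl <- bl + ls$loss
          seg_backward(net, ls$grad / length(idx))
        }
        t_step <- t_step + 1L
        adam_step(net$layers, lr, t_step)
        ep_loss <- ep_loss + bl
      }
      trace[ep] <- ep_loss / n
    }
  })
  net$loss_trace <- trace
  net
}

#' Segment an image into a foreground probability raster and mask
#'
#' @param image RGB array `[H, W, 3]`.
#' @param net trained `seg_net`.
#' @param threshold foreground threshold in `(0, 1]`; the mask is
#'   `probability >= threshold`.
#' @param allow_resize if `TRUE`, images not matching the network input size
#'   are bilinearly resized for inference and the outputs resized back;
#'   otherwise (default) a size mismatch is an error.
#' @return list with `mask` (logical matrix) and `prob` (numeric matrix).
#' @export
segment_patch <- function(image, net, threshold = 0.5, allow_resize = FALSE) {
  assert_image(image)
  stopifnot(inherits(net, "seg_net"))
  sz <- net$config$input_size
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h != sz || w != sz) {
    if (!allow_resize)
      stop("image size ", h, "x", w, " does not match network input ", sz,
           "; set allow_resize = TRUE to resize", call. = FALSE)
    img_t <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
    img_t <- EBImage::resize(img_t, w = sz, h = sz)
    image <- aperm(EBImage::imageData(img_t), c(2, 1, 3))
  }
  fw <- seg_forward(net, image)
  prob <- fw$prob
  if (h != dim(prob)[1] || w != dim(prob)[2]) {
    pr <- EBImage::resize(EBImage::Image(t(prob)), w = w, h = h)
    prob <- t(EBImage::imageData(pr))
  }
  list(mask = prob >= threshold, prob = prob)
}

#' Parameter count of a DeepLab-v1-style reference at matched scale
#'
#' Analytic parameter count of a VGG-16 backbone (13 3x3 convolutions in
#' five stages with widths `base_width * c(1, 2, 4, 8, 8)`) plus the atrous
#' classification head (a 3x3 dilated convolution to `16 * base_width`
#' channels, a 1x1 of the same width, and a 1x1 scoring layer), scaled so
#' its first-stage width matches the supplied segmentation configuration.
#' Used as the budget yardstick for the compact pyramid-fusion network.
#'
#' @param config a [seg_net_config()].
#' @return integer parameter count.
#' @export
deeplab_reference_params <- function(config) {
  bw <- config$base_width
  widths <- bw * c(1, 2, 4, 8, 8)
  nconv <- c(2, 2, 3, 3, 3)
  prev <- 3
  total <- 0
  for (s in seq_along(widths)) {
    for (k in seq_len(nconv[s])) {
      total <- total + 9 * prev * widths[s] + widths[s]
      prev <- widths[s]
    }
  }
  fc <- 16 * bw
  total <- total + 9 * prev * fc + fc       # atrous fc6
  total <- total + fc * fc + fc             # fc7 1x1
  total <- total + fc * 1 + 1               # score
  as.integer(total)
}

#' @export
print.seg_net <- function(x, ...) {
  cat("<seg_net> depth ", x$config$depth, ", base width ",
      x$config$base_width, ", input ", x$config$input_size,
      if (x$config$pyramid_fusion) ", pyramid fusion" else "",
      ", ", x$n_params, " parameters\n", sep = "")
  invisible(x)
}
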