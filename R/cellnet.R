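# Large-kernel-attention cell classifier.
#
# Each stage block computes an attention map from its input through a
# depthwise k x k convolution, a depthwise dilated convolution and a
# pointwise projection; the map gates the block's transform multiplicatively
# and the result is added back to the input (residual). A global average
# pool and a linear head produce the 17 class logits. Trained with AdamW
# (decoupled weight decay) under a cosine-annealed learning rate, matching
# the published recipe (weight decay 0.05, initial learning rate 0.001).

#' Cell classifier configuration
#'
#' @param input_size square crop side in pixels (>= 32); 224 for full runs,
#'   64 in the tiny desk-scale preset.
#' @param in_channels 3 for plain RGB crops, 4 when an instance-mask
#'   channel accompanies the crop (used by the slide pipeline so the
#'   classifier knows which object in a crowded window is queried).
#' @param stage_widths channel widths of the two stages.
#' @param k_dw kernel of the depthwise convolution in the attention module.
#' @param k_dwd kernel of the depthwise dilated convolution.
#' @param dilation dilation of the second depthwise convolution.
#' @param num_classes fixed at the 17-class schema size.
#' @return object of class `cell_net_config`.
#' @export
cell_net_config <- function(input_size = 224L, in_channels = 3L,
                            stage_widths = c(16L, 32L),
                            k_dw = 5L, k_dwd = 7L, dilation = 3L,
                            num_classes = 17L) {
  if (input_size < 32) stop("input crop size must be at least 32",
                            call. = FALSE)
  if (!in_channels %in% c(3L, 4L))
    stop("in_channels must be 3 (RGB) or 4 (RGB + instance mask)",
         call. = FALSE)
  if (num_classes != 17L)
    stop("num_classes is fixed at the 17-class schema size", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 stage_widths = as.integer(stage_widths),
                 k_dw = as.integer(k_dw), k_dwd = as.integer(k_dwd),
                 dilation = as.integer(dilation),
                 num_classes = as.integer(num_classes)),
            class = "cell_net_config")
}

#' The tiny desk-scale cell classifier preset (64-px crops)
#' @param in_channels see [cell_net_config()].
#' @return a [cell_net_config()].
#' @export
cell_net_tiny <- function(in_channels = 3L)
  cell_net_config(input_size = 64L, in_channels = in_channels)

#' Build the large-kernel-attention cell classifier
#'
#' @param config a [cell_net_config()].
#' @param init_seed weight-initialisation seed; identical `(config, seed)`
#'   builds produce identical logits on a fixed input.
#' @return object of class `cell_net`.
#' @export
build_cell_net <- function(config, init_seed = 0L) {
  stopifnot(inherits(config, "cell_net_config"))
  w <- config$stage_widths
  with_seed(init_seed, {
    L <- list()
    L$stem <- nn_conv(3, 3, config$in_channels %||% 3L, w[1], stride = 2L,
                      act = "relu")
    L <- c(L, lka_block_layers("b1", w[1], config))
    L$down <- nn_conv(3, 3, w[1], w[2], stride = 2L, act = "relu")
    L <- c(L, lka_block_layers("b2", w[2], config))
    # head sees mean- and max-pooled channels: means carry bulk colour and
    # texture, maxima carry small salient structures (bright inclusions)
    L$head <- nn_linear(2L * w[2], config$num_classes)
    structure(list(config = config, layers = L, n_params = n_params(L),
                   attn_override = NULL),
              class = "cell_net")
  })
}

lka_block_layers <- function(tag, width, config) {
  l <- list(
    nn_conv(1, 1, width, width, pad = 0L, act = "relu"),  # proj1
    nn_dwconv(config$k_dw, width),                        # dw
    nn_dwconv(config$k_dwd, width, dil = config$dilation),# dw dilated
    nn_conv(1, 1, width, width, pad = 0L),                # pointwise attn
    nn_conv(1, 1, width, width, pad = 0L)                 # proj2
  )
  stats::setNames(l, paste0(tag, c("_proj1", "_dw", "_dwd", "_pw", "_proj2")))
}

# Forward through one attention block; caches a and attn in `net` scope
# via the returned list for the backward pass.
lka_block_fwd <- function(net, tag, x) {
  L <- net$layers
  a <- layer_fwd(L[[paste0(tag, "_proj1")]], x)
  attn <- layer_fwd(L[[paste0(tag, "_pw")]],
                    layer_fwd(L[[paste0(tag, "_dwd")]],
                              layer_fwd(L[[paste0(tag, "_dw")]], a)))
  if (!is.null(net$attn_override))
    attn <- array(net$attn_override, dim(attn))
  gated <- a * attn
  out <- x + layer_fwd(L[[paste0(tag, "_proj2")]], gated)
  list(out = out, a = a, attn = attn)
}

lka_block_bwd <- function(net, tag, cache, gout) {
  L <- net$layers
  g_gated <- layer_bwd(L[[paste0(tag, "_proj2")]], gout)
  g_a <- g_gated * cache$attn
  if (is.null(net$attn_override)) {
    g_attn <- g_gated * cache$a
    g_a <- g_a + layer_bwd(L[[paste0(tag, "_dw")]],
                           layer_bwd(L[[paste0(tag, "_dwd")]],
                                     layer_bwd(L[[paste0(tag, "_pw")]], g_attn)))
  }
  gout + layer_bwd(L[[paste0(tag, "_proj1")]], g_a)
}

cell_forward <- function(net, x) {
  L <- net$layers
  h <- layer_fwd(L$stem, x)
  b1 <- lka_block_fwd(net, "b1", h)
  h2 <- layer_fwd(L$down, b1$out)
  b2 <- lka_block_fwd(net, "b2", h2)
  pd <- dim(b2$out)
  flat <- matrix(b2$out, ncol = pd[3])
  gmx <- max.col(t(flat), ties.method = "first")  # argmax per channel
  pooled <- c(colMeans(flat), flat[cbind(gmx, seq_len(pd[3]))])
  logits <- layer_fwd(L$head, pooled)
  list(logits = logits, b1 = b1, b2 = b2, pool_dim = pd, argmax = gmx)
}

cell_backward <- function(net, fw, glogits) {
  L <- net$layers
  gpool <- layer_bwd(L$head, glogits)
  pd <- fw$pool_dim
  nch <- pd[3]; npx <- pd[1] * pd[2]
  gmap <- matrix(rep(gpool[seq_len(nch)] / npx, each = npx), npx, nch)
  gmap[cbind(fw$argmax, seq_len(nch))] <-
    gmap[cbind(fw$argmax, seq_len(nch))] + gpool[nch + seq_len(nch)]
  g <- lka_block_bwd(net, "b2", fw$b2, array(gmap, pd))
  g <- layer_bwd(L$down, g)
  g <- lka_block_bwd(net, "b1", fw$b1, g)
  layer_bwd(L$stem, g)
  invisible(NULL)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Augmentation: flips / quarter rotations / mild per-channel colour jitter,
# then a random crop back to the network input size.
augment_crop <- function(img, out_size) {
  if (stats::runif(1) < 0.5) img <- img[, dim(img)[2]:1, , drop = FALSE]
  k <- sample(0:3, 1)
  if (k > 0) for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))
    img <- img[dim(img)[1]:1, , , drop = FALSE]
  }
  # colour jitter touches the RGB channels only (a mask channel, if
  # present, is geometry)
  gain <- stats::runif(3, 0.92, 1.08)
  off <- stats::runif(3, -0.04, 0.04)
  for (ch in 1:3) img[, , ch] <- clip01(img[, , ch] * gain[ch] + off[ch])
  random_crop(img, out_size)
}

random_crop <- function(img, out_size) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h == out_size && w == out_size) return(img)
  r0 <- sample.int(h - out_size + 1, 1)
  c0 <- sample.int(w - out_size + 1, 1)
  img[r0:(r0 + out_size - 1), c0:(c0 + out_size - 1), , drop = FALSE]
}

center_crop <- function(img, out_size) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h == out_size && w == out_size) return(img)
  if (h < out_size || w < out_size) {
    # reflect-pad small crops up to the input size
    img_t <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
    img_t <- EBImage::resize(img_t, w = out_size, h = out_size)
    return(aperm(EBImage::imageData(img_t), c(2, 1, 3)))
  }
  r0 <- (h - out_size) %/% 2 + 1
  c0 <- (w - out_size) %/% 2 + 1
  img[r0:(r0 + out_size - 1), c0:(c0 + out_size - 1), , drop = FALSE]
}

#' Train the cell classifier
#'
#' AdamW with decoupled weight decay 0.05 and a cosine-annealed learning
#' rate starting at 0.001 (the published recipe); augmentation applies
#' flips, quarter rotations and colour jitter followed by a random crop.
#' Deterministic given `seed`.
#'
#' @param net a [build_cell_net()] model.
#' @param crops list of RGB arrays (side >= network input size).
#' @param labels character vector of class ids `C1..C17`, one per crop; at
#'   least two distinct classes required.
#' @param epochs,lr,weight_decay,batch_size training hyper-parameters.
#' @param augment apply augmentation (disable for degenerate-case tests).
#' @param seed RNG seed for shuffling, augmentation and crops.
#' @return the trained net with `loss_trace` (mean per-epoch loss) and
#'   `classes` attached.
#' @export
train_cell_net <- function(net, crops, labels, epochs = 40L, lr = 1e-3,
                           weight_decay = 0.05, batch_size = 4L,
                           augment = TRUE, seed = 0L) {
  stopifnot(inherits(net, "cell_net"))
  if (length(crops) != length(labels))
    stop("crops and labels must have equal length", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("training requires at least two distinct classes", call. = FALSE)
  if (!all(labels %in% paste0("C", 1:17)))
    stop("labels must be class ids C1..C17", call. = FALSE)
  sz <- net$config$input_size
  n <- length(crops)
  lab_idx <- match(labels, paste0("C", 1:17))
  K <- net$config$num_classes
  trace <- numeric(epochs)
  with_seed(seed, {
    t_step <- 0L
    for (ep in seq_len(epochs)) {
      lr_ep <- cosine_lr(lr, ep, epochs)
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        zero_grads(net$layers)
        for (i in idx) {
          x <- if (augment) augment_crop(crops[[i]], sz)
          else center_crop(crops[[i]], sz)
          fw <- cell_forward(net, x)
          p <- softmax_vec(fw$logits)
          ep_loss <- ep_loss - log(max(p[lab_idx[i]], 1e-12))
          gl <- p
          gl[lab_idx[i]] <- gl[lab_idx[i]] - 1
          cell_backward(net, fw, gl / length(idx))
        }
        t_step <- t_step + 1L
        adam_step(net$layers, lr_ep, t_step, wd = weight_decay)
      }
      trace[ep] <- ep_loss / n
    }
  })
  net$loss_trace <- trace
  net
}

#' Classify cell crops
#'
#' Crops larger than the network input are centre-cropped; smaller crops are
#' resized up. Softmax probabilities with lowest-index tie-break on the
#' argmax. A `logit_hook` function on the model (test hook) replaces the
#' network forward pass.
#'
#' @param crops list of RGB arrays.
#' @param net trained `cell_net`.
#' @return tibble with `net_class`, `prob` (probability of the argmax) and
#'   list-column `probs` (named 17-vector summing to 1).
#' @export
classify_patches <- function(crops, net) {
  stopifnot(inherits(net, "cell_net"))
  cls <- paste0("C", 1:17)
  if (length(crops) == 0)
    return(tibble::tibble(net_class = character(), prob = numeric(),
                          probs = list()))
  rows <- lapply(crops, function(cr) {
    logits <- if (!is.null(net$logit_hook)) net$logit_hook(cr)
    else cell_forward(net, center_crop(cr, net$config$input_size))$logits
    p <- softmax_vec(logits)
    names(p) <- cls
    k <- which.max(p)  # first maximum: lowest class index wins ties
    tibble::tibble(net_class = cls[k], prob = p[[k]], probs = list(p))
  })
  dplyr::bind_rows(rows)
}

#' Dual-model agreement gate for the epithelial classes
#'
#' For calls whose network class lies in C1-C3 or C6-C8, the morphology
#' classifier must agree before the cell enters slide-level aggregation:
#' `final_class` is the network class when the two models agree and
#' `"REJECTED"` otherwise. All other classes pass through unconditionally.
#' Agreement is evaluated at role level by default (the morphology model is
#' trained on the 9-role reduction); set `exact_id = TRUE` to require exact
#' class-id agreement.
#'
#' @param calls tibble with columns `net_class` and `morpho_class`
#'   (role names, or class ids when `exact_id = TRUE`).
#' @param schema a [class_schema()].
#' @param exact_id require exact class-id agreement instead of role-level.
#' @return `calls` with `agreed` (logical, `NA` outside the gated classes)
#'   and `final_class` columns.
#' @export
agreement_gate <- function(calls, schema = class_schema(), exact_id = FALSE) {
  stopifnot(all(c("net_class", "morpho_class") %in% names(calls)))
  gated_classes <- c("C1", "C2", "C3", "C6", "C7", "C8")
  in_gate <- calls$net_class %in% gated_classes
  if (exact_id) {
    ok <- calls$net_class == calls$morpho_class
  } else {
    net_role <- role_of_class(calls$net_class, schema)
    # morpho_class may be a role name already, or a class id
    morpho_role <- ifelse(calls$morpho_class %in% schema$role,
                          calls$morpho_class,
                          role_of_class(calls$morpho_class, schema))
    ok <- net_role == morpho_role
  }
  calls$agreed <- ifelse(in_gate, ok, NA)
  calls$final_class <- ifelse(in_gate & !ok, "REJECTED", calls$net_class)
  calls
}

#' @export
print.cell_net <- function(x, ...) {
  cat("<cell_net> input ", x$config$input_size, ", widths ",
      paste(x$config$stage_widths, collapse = "/"), ", ",
      x$n_params, " parameters\n", sep = "")
  invisible(x)
}
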