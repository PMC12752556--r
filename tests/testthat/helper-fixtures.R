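# Shared fixtures. Heavy trained models are built lazily, once per test
# run, and reused across test files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- builder()
  fixture_cache[[name]]
}

small_config <- function(...) synth_config(patch_size = 128L, ...)

# The six visually distinct benchmark classes: PTC single cell, nuclear
# groove, pseudo-inclusion, benign follicular single cell, lymphocyte,
# colloid clump.
benchmark_classes <- function() c("C3", "C4", "C5", "C8", "C10", "C12")

render_crop_set <- function(classes, n_per, seed0, size = 72L,
                            config = small_config()) {
  crops <- list(); labels <- character(); masks <- list()
  k <- 0L
  for (cl in classes) for (i in seq_len(n_per)) {
    k <- k + 1L
    p <- render_crop(config, cl, size = size, seed = sub_seed(seed0, k))
    crops[[k]] <- p$image
    masks[[k]] <- p$mask
    labels[k] <- cl
  }
  list(crops = crops, masks = masks, labels = labels)
}

# Morphometry rows (19 features + role) from ground-truth crop masks.
morpho_from_crops <- function(set) {
  rows <- list()
  for (i in seq_along(set$crops)) {
    det <- detections_from_mask(set$masks[[i]],
                                tile_size = dim(set$masks[[i]])[1])
    if (nrow(det) == 0) next
    det <- det[which.max(det$area), ]
    mv <- nuclear_morphometry(set$crops[[i]], det)
    rows[[length(rows) + 1]] <- c(as.list(mv),
                                  class = set$labels[i],
                                  role = role_of_class(set$labels[i]))
  }
  dplyr::bind_rows(rows)
}

# Ground-truth-driven slide features: calls assembled from the generator's
# class table (plausible probabilities and scores), bypassing the CNNs.
# Used to benchmark the slide-level classifiers in isolation.
features_from_truth <- function(slide, seed = 1L) {
  with_seed(seed, {
    tabs <- lapply(slide$tiles, function(t) t$class_table)
    tab <- dplyr::bind_rows(tabs)
    if (nrow(tab) == 0) {
      return(aggregate_slide_features(thyrocyto:::empty_calls()))
    }
    n <- nrow(tab)
    feats <- matrix(stats::rnorm(n * 19, mean = 1, sd = 0.2), n, 19)
    colnames(feats) <- morpho_feature_names()
    radius <- c(11, 10, 9.5, 9, 9, 6.5, 6, 5.5, 9, 3.5, 4.5, 12,
                8, 8, 7, 5, 5)[match(tab$class, paste0("C", 1:17))]
    feats[, "area"] <- pi * radius^2 * stats::runif(n, 0.7, 1.3)
    calls <- dplyr::bind_cols(
      tibble::tibble(detection_id = seq_len(n),
                     kind = ifelse(tab$is_cluster, "cluster", "nucleus"),
                     score = stats::rbeta(n, 8, 2),
                     net_class = tab$class,
                     prob = stats::rbeta(n, 9, 2),
                     morpho_class = role_of_class(tab$class)),
      tibble::as_tibble(feats))
    calls$agreed <- TRUE
    calls$final_class <- calls$net_class
    aggregate_slide_features(calls)
  })
}

# Tiny trained segmentation net for unit tests (64-px canvases rendered
# at 128-px object scale, few epochs).
tiny_seg_fit <- function() cached("tiny_seg", function() {
  cfg <- synth_config(patch_size = 64L, nuclei_range = c(3L, 6L),
                      debris_rate = 0.3)
  cfg$render_scale <- 128L
  patches <- lapply(1:12, function(i) render_patch(cfg, sub_seed(42, i)))
  net <- build_seg_net(seg_net_config(3L, 8L, TRUE, 64L), init_seed = 0L)
  net <- train_seg_net(net, patches, epochs = 20, seed = 0)
  list(net = net, config = cfg, patches = patches)
})

# Independent connected-component labelling oracle (BFS flood fill),
# deliberately not the EBImage implementation used by the package.
flood_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    h <- nrow(mask)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% h + 1L
      cc <- (cur - 1L) %/% h + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr < 1 || rr > h || c2 < 1 || c2 > ncol(mask)) next
        id <- rr + h * (c2 - 1L)
        if (mask[id] && lab[id] == 0L) {
          lab[id] <- nxt
          queue <- c(queue, id)
        }
      }
    }
  }
  lab
}
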