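# End-to-end per-slide pipeline: (optional appearance migration) ->
# segmentation -> HSV debris rejection -> detection post-processing ->
# nuclear morphometry -> neural + morphology cell classification ->
# agreement gate -> slide feature aggregation -> adequacy rule ->
# whole-slide classifier -> optional cascade gene fusion.
#
# Every stage's object counts are carried in the report for audit:
# detections in = accepted calls + gate-rejected + min-area-discarded.

#' Bundle of trained models for the slide pipeline
#'
#' @param seg_net trained segmentation network.
#' @param cell_net trained cell classifier.
#' @param morpho_gbt trained morphology classifier (role-level labels).
#' @param wsi_gbt trained whole-slide classifier.
#' @param gene_gbt optional BRAF classifier (`NULL` to skip the cascade).
#' @return list of class `pipeline_models`.
#' @export
pipeline_models <- function(seg_net, cell_net, morpho_gbt, wsi_gbt,
                            gene_gbt = NULL) {
  structure(list(seg_net = seg_net, cell_net = cell_net,
                 morpho_gbt = morpho_gbt, wsi_gbt = wsi_gbt,
                 gene_gbt = gene_gbt),
            class = "pipeline_models")
}

#' Pipeline options
#'
#' @param threshold segmentation foreground threshold.
#' @param hsv_ranges debris reject ranges ([default_hsv_ranges()]).
#' @param rule_params adequacy rule constants.
#' @param crop_margin retained for configurability of auxiliary tools;
#'   classification windows are extracted at the classifier's native
#'   input size so train and inference scales match.
#' @param reference optional reference [estimate_profile()]; when given,
#'   tiles are appearance-migrated to it before segmentation.
#' @param fg_mask foreground-mask parameters ([mask_params()]) used by the
#'   migration step.
#' @param seed seed for the stages that sample (profile estimation).
#' @return list of class `pipeline_options`.
#' @export
pipeline_options <- function(threshold = 0.5,
                             hsv_ranges = default_hsv_ranges(),
                             rule_params = decision_rule_params(),
                             crop_margin = 2.0,
                             reference = NULL,
                             fg_mask = mask_params(),
                             seed = 0L) {
  structure(list(threshold = threshold, hsv_ranges = hsv_ranges,
                 rule_params = rule_params, crop_margin = crop_margin,
                 reference = reference, fg_mask = fg_mask,
                 seed = as.integer(seed)),
            class = "pipeline_options")
}

extract_det_crop <- function(image, det, side) {
  h <- dim(image)[1]; w <- dim(image)[2]
  side <- min(side, h, w)
  cx <- floor((det$x0 + det$x1) / 2)
  cy <- floor((det$y0 + det$y1) / 2)
  x0 <- min(max(cx - side %/% 2, 0), w - side)
  y0 <- min(max(cy - side %/% 2, 0), h - side)
  image[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side), , drop = FALSE]
}

# RGB window plus a fourth channel carrying the queried instance's mask,
# so the classifier is told which object in a crowded window it rates.
window_with_mask <- function(image, det, side) {
  h <- dim(image)[1]; w <- dim(image)[2]
  side <- min(side, h, w)
  cx <- floor((det$x0 + det$x1) / 2)
  cy <- floor((det$y0 + det$y1) / 2)
  x0 <- min(max(cx - side %/% 2, 0), w - side)
  y0 <- min(max(cy - side %/% 2, 0), h - side)
  out <- array(0, c(side, side, 4))
  out[, , 1:3] <- image[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side), ,
                        drop = FALSE]
  m <- if (is.list(det$mask) && !is.matrix(det$mask)) det$mask[[1]]
  else det$mask
  full <- matrix(0, h, w)
  full[(det$y0 + 1):det$y1, (det$x0 + 1):det$x1] <- m * 1
  out[, , 4] <- full[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)]
  out
}

#' Run the cell-level stages on one tile
#'
#' Segmentation through agreement gate; returns accepted calls joined with
#' detection attributes and morphometry, plus audit counts.
#'
#' @param image RGB tile.
#' @param models a [pipeline_models()] (wsi/gene models unused here).
#' @param opts a [pipeline_options()].
#' @return list with `calls` (accepted), `rejected`, `detections`, `audit`.
#' @export
process_tile <- function(image, models, opts = pipeline_options()) {
  tile_size <- dim(image)[1]
  seg <- segment_patch(image, models$seg_net, threshold = opts$threshold,
                       allow_resize = TRUE)
  mask <- hsv_debris_filter(image, seg$mask, opts$hsv_ranges)
  det <- detections_from_mask(mask, seg$prob, tile_size = tile_size)
  if (nrow(det) == 0) {
    audit <- list(components_discarded = attr(det, "discarded"),
                  detections = 0, accepted = 0, rejected = 0)
    return(list(calls = empty_calls(), rejected = empty_calls(),
                detections = det, audit = audit))
  }
  morpho <- morphometry_table(image, det)
  classify_detections(image, det, morpho, models)
}

# Classification stage only (detections and morphometry already computed).
classify_detections <- function(image, det, morpho, models) {
  audit <- list(components_discarded = attr(det, "discarded") %||% 0L,
                detections = nrow(det))
  if (nrow(det) == 0) {
    return(list(calls = empty_calls(), rejected = empty_calls(),
                detections = det,
                audit = c(audit, accepted = 0, rejected = 0)))
  }
  # fixed-size windows at native scale, matching the training crops;
  # a 4-channel net receives the instance mask as the fourth channel
  side <- models$cell_net$config$input_size
  masked <- (models$cell_net$config$in_channels %||% 3L) == 4L
  crops <- lapply(seq_len(nrow(det)), function(i) {
    if (masked) window_with_mask(image, det[i, ], side)
    else extract_det_crop(image, det[i, ], side)
  })
  nn <- classify_patches(crops, models$cell_net)
  mo <- classify_morpho(morpho, models$morpho_gbt)
  # the morphometry `area` feature doubles as the per-call area statistic
  calls <- dplyr::bind_cols(
    det[, c("detection_id", "kind", "score")],
    tibble::tibble(net_class = nn$net_class, prob = nn$prob),
    mo["morpho_class"],
    morpho[, morpho_feature_names()])
  calls <- agreement_gate(calls)
  accepted <- calls[calls$final_class != "REJECTED", , drop = FALSE]
  rejected <- calls[calls$final_class == "REJECTED", , drop = FALSE]
  audit$accepted <- nrow(accepted)
  audit$rejected <- nrow(rejected)
  list(calls = accepted, rejected = rejected, detections = det,
       audit = audit)
}

empty_calls <- function() {
  m <- lapply(stats::setNames(nm = morpho_feature_names()),
              function(nm) numeric(0))
  dplyr::bind_cols(
    tibble::tibble(detection_id = integer(), kind = character(),
                   score = numeric(), net_class = character(),
                   prob = numeric(), morpho_class = character()),
    tibble::as_tibble(m),
    tibble::tibble(agreed = logical(), final_class = character()))
}

#' Run the full diagnostic pipeline on one slide
#'
#' @param tiles list of RGB arrays (or a `synth_slide`, whose tiles' images
#'   are used).
#' @param models a [pipeline_models()].
#' @param opts a [pipeline_options()].
#' @return list of class `slide_report`: `features`, `result`
#'   (a `tbs_result`), `final` (after cascade when a gene model is
#'   present), `gene` (prediction tibble or `NULL`), `audit` (per-stage
#'   counts summed over tiles).
#' @export
run_pipeline <- function(tiles, models, opts = pipeline_options()) {
  stopifnot(inherits(models, "pipeline_models"))
  if (inherits(tiles, "synth_slide"))
    tiles <- lapply(tiles$tiles, function(t) t$image)
  if (!is.null(opts$reference)) {
    mig <- migrate_slide(tiles, opts$reference, params = opts$fg_mask,
                         seed = opts$seed)
    tiles <- mig$tiles
  }
  per_tile <- lapply(tiles, process_tile, models = models, opts = opts)
  calls <- dplyr::bind_rows(lapply(seq_along(per_tile), function(i) {
    k <- per_tile[[i]]$calls
    if (nrow(k)) k$detection_id <- k$detection_id + i * 100000L
    k
  }))
  audit <- Reduce(function(a, b) Map(`+`, a, b),
                  lapply(per_tile, `[[`, "audit"))
  features <- aggregate_slide_features(calls, rule_params = opts$rule_params)
  result <- predict_tbs(features, models$wsi_gbt,
                        rule_params = opts$rule_params)
  gene <- NULL
  final <- result$final
  if (!is.null(models$gene_gbt) && identical(result$final, "V")) {
    gene <- predict_gene(features, models$gene_gbt)
    final <- cascade_fuse(result$final, gene$gene_pred)
  }
  structure(list(features = features, result = result, final = final,
                 gene = gene, audit = audit, n_calls = nrow(calls)),
            class = "slide_report")
}

#' @export
print.slide_report <- function(x, ...) {
  cat("<slide_report> final TBS ", x$final, "; ", x$n_calls,
      " accepted cells; adequacy LHS ", x$result$adeq_lhs, "\n", sep = "")
  invisible(x)
}

#' Train every pipeline model on a synthetic cohort
#'
#' Desk-scale training harness: renders (or takes) a cohort of synthetic
#' slides, trains the segmentation network on patches, the cell and
#' morphology classifiers on single-class crops, runs the cell-level
#' pipeline over the cohort and fits the whole-slide and gene classifiers
#' on the aggregated features.
#'
#' @param cohort list of `synth_slide` (training slides).
#' @param config the [synth_config()] the cohort was rendered with.
#' @param seed master seed.
#' @param seg_patches,seg_epochs segmentation training set size and epochs.
#' @param crops_per_class,cell_epochs cell-classifier training set size per
#'   class and epochs.
#' @param morpho_per_class training rows per class for the morphology
#'   classifier (cheap to fit, so it gets a larger harvest than the
#'   network by default).
#' @param crop_classes classes the cell/morphology classifiers are trained
#'   on (default: the classes the cohort archetypes emit).
#' @param n_classes_wsi 2 or 3 (passed to [train_wsi_gbt()]).
#' @param search_budget grid rows evaluated in the WSI grid search.
#' @param progress print stage banners.
#' @return list with the trained [pipeline_models()], the training feature
#'   matrix and labels.
#' @export
train_pipeline <- function(cohort, config = synth_config(patch_size = 128L),
                           seed = 0L, seg_patches = 50L, seg_epochs = 30L,
                           crops_per_class = 60L, cell_epochs = 25L,
                           morpho_per_class = 4L * crops_per_class,
                           crop_classes = c(paste0("C", 1:8), "C10", "C12"),
                           n_classes_wsi = 3L, search_budget = Inf,
                           seg_net = NULL, cell_net = NULL,
                           morpho_gbt = NULL, progress = FALSE) {
  say <- function(...) if (progress) message(...)
  seg <- seg_net
  if (is.null(seg)) {
    say("training segmentation network")
    patches <- lapply(seq_len(seg_patches), function(i)
      render_patch(config, sub_seed(seed, 5000 + i)))
    seg <- build_seg_net(seg_net_config(3L, 8L, TRUE, config$patch_size),
                         init_seed = seed)
    seg <- train_seg_net(seg, patches, epochs = seg_epochs, seed = seed)
  }

  cell <- cell_net
  morpho <- morpho_gbt
  det_cache <- NULL
  if (is.null(cell) || is.null(morpho)) {
    # run the detector once over every training tile (detections and
    # morphometry are cached and reused by feature extraction below) and
    # label its detections by ground-truth overlap, so the classifiers
    # train on exactly the windows, masks and morphometry they will meet
    # at inference
    say("running the detector over training tiles to harvest windows")
    win <- cell_net_tiny()$input_size
    opts0 <- pipeline_options()
    crops <- list(); labels <- character(); mor_rows <- list()
    mor_labels <- character()
    det_cache <- lapply(cohort, function(s) vector("list", length(s$tiles)))
    for (si in seq_along(cohort)) {
      s <- cohort[[si]]
      for (ti in seq_along(s$tiles)) {
        tl <- s$tiles[[ti]]
        sg <- segment_patch(tl$image, seg, threshold = opts0$threshold,
                            allow_resize = TRUE)
        fm <- hsv_debris_filter(tl$image, sg$mask, opts0$hsv_ranges)
        det <- detections_from_mask(fm, sg$prob,
                                    tile_size = dim(tl$image)[1])
        mt <- morphometry_table(tl$image, det)
        det_cache[[si]][[ti]] <- list(det = det, morpho = mt)
        if (nrow(det) == 0 || nrow(tl$class_table) == 0) next
        for (r in seq_len(nrow(det))) {
          d <- det[r, ]
          sub <- tl$mask[(d$y0 + 1):d$y1, (d$x0 + 1):d$x1]
          ids <- sub[d$mask[[1]] & sub > 0]
          if (length(ids) < 0.3 * d$area) next   # mostly unmatched: skip
          gt_id <- as.integer(names(which.max(table(ids))))
          cl <- tl$class_table$class[tl$class_table$instance_id == gt_id]
          if (!length(cl) || !cl %in% crop_classes) next
          need_crop <- sum(labels == cl) < crops_per_class
          need_mor <- sum(mor_labels == cl) < morpho_per_class
          if (!need_crop && !need_mor) next
          if (need_crop) {
            crops[[length(crops) + 1]] <- window_with_mask(tl$image, d, win)
            labels[length(labels) + 1] <- cl
          }
          if (need_mor) {
            mv <- mt[r, morpho_feature_names()]
            mor_rows[[length(mor_rows) + 1]] <-
              c(as.list(mv), role = role_of_class(cl))
            mor_labels[length(mor_labels) + 1] <- cl
          }
        }
      }
    }
    if (is.null(cell)) {
      cell <- build_cell_net(cell_net_tiny(in_channels = 4L),
                             init_seed = seed)
      cell <- train_cell_net(cell, crops, labels, epochs = cell_epochs,
                             batch_size = 8L, seed = seed)
    }
    if (is.null(morpho)) {
      say("training morphology classifier")
      mor <- dplyr::bind_rows(mor_rows)
      morpho <- train_morpho_gbt(mor[, morpho_feature_names()], mor$role,
                                 seed = seed)
    }
  }

  say("extracting slide features")
  models0 <- pipeline_models(seg, cell, morpho,
                             wsi_gbt = NULL)
  opts <- pipeline_options()
  feats <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    per_tile <- lapply(seq_along(cohort[[i]]$tiles), function(j) {
      img <- cohort[[i]]$tiles[[j]]$image
      cached <- if (!is.null(det_cache)) det_cache[[i]][[j]]
      if (!is.null(cached))
        classify_detections(img, cached$det, cached$morpho, models0)
      else process_tile(img, models0, opts)
    })
    calls <- dplyr::bind_rows(lapply(seq_along(per_tile), function(j) {
      kk <- per_tile[[j]]$calls
      if (nrow(kk)) kk$detection_id <- kk$detection_id + j * 100000L
      kk
    }))
    feats[[i]] <- aggregate_slide_features(calls,
                                           rule_params = opts$rule_params)
  }
  fm <- feature_matrix(feats)
  truth <- vapply(cohort, `[[`, character(1), "true_tbs")
  braf <- vapply(cohort, `[[`, numeric(1), "braf")

  say("training whole-slide classifiers")
  adequate <- truth != "I"
  fold <- with_seed(seed, stratified_folds(truth[adequate], 5L))
  wsi <- train_wsi_gbt(fm[adequate, ], truth[adequate],
                       n_classes = n_classes_wsi,
                       search_budget = search_budget,
                       fold_assign = fold, seed = seed)
  gene <- train_gene_gbt(fm[adequate, ], braf[adequate], seed = seed)

  list(models = pipeline_models(seg, cell, morpho, wsi, gene),
       features = fm, truth = truth, braf = braf,
       fold_assign = fold, adequate = adequate)
}
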