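# Segmentation network contracts, HSV debris filtering, detection
# post-processing and nuclear morphometry.

test_that("network shape contracts and build determinism hold", {
  cfg <- seg_net_config(2L, 8L, FALSE, 64L)
  n1 <- build_seg_net(cfg, init_seed = 1)
  n2 <- build_seg_net(cfg, init_seed = 1)
  expect_identical(n1$n_params, n2$n_params)
  x <- with_seed(7, array(runif(64 * 64 * 3), c(64, 64, 3)))
  f1 <- seg_forward(n1, x); f2 <- seg_forward(n2, x)
  expect_identical(f1$prob, f2$prob)
  expect_equal(dim(f1$prob), c(64, 64))
  expect_true(all(f1$prob > 0 & f1$prob < 1))
  expect_error(seg_net_config(3L, 8L, TRUE, 100L), "divisible")
  expect_error(seg_net_config(1L, 8L), "depth")
})

test_that("the tiny pyramid-fusion net stays under 20% of the reference
           parameter budget", {
  cfg <- seg_net_tiny()
  net <- build_seg_net(cfg)
  ref <- deeplab_reference_params(cfg)
  expect_lt(net$n_params / ref, 0.20)
})

test_that("training is deterministic and degrades gracefully on
           all-background data", {
  fit <- tiny_seg_fit()
  net_b <- build_seg_net(seg_net_config(3L, 8L, TRUE, 64L), init_seed = 0L)
  net_b <- train_seg_net(net_b, fit$patches[1:6], epochs = 2, seed = 1)
  net_c <- build_seg_net(seg_net_config(3L, 8L, TRUE, 64L), init_seed = 0L)
  net_c <- train_seg_net(net_c, fit$patches[1:6], epochs = 2, seed = 1)
  expect_identical(net_b$loss_trace, net_c$loss_trace)

  bg_cfg <- synth_config(patch_size = 64L, nuclei_range = c(0L, 0L),
                         debris_rate = 0)
  bg <- lapply(1:10, function(i) render_patch(bg_cfg, i))
  net_bg <- build_seg_net(seg_net_config(3L, 8L, TRUE, 64L), init_seed = 0L)
  net_bg <- train_seg_net(net_bg, bg, epochs = 5, seed = 0)
  pr <- segment_patch(render_patch(bg_cfg, 99)$image, net_bg)$prob
  expect_true(all(pr < 0.5))
  expect_error(train_seg_net(net_bg, list(), epochs = 1), "empty")
})

test_that("a briefly trained tiny net already localises most nuclei", {
  fit <- tiny_seg_fit()
  smoothed <- stats::filter(fit$net$loss_trace, rep(1 / 3, 3))
  smoothed <- smoothed[!is.na(smoothed)]
  expect_true(all(diff(smoothed) < 0.05))   # no sustained loss increase
  p <- render_patch(fit$config, 777)
  sg <- segment_patch(p$image, fit$net, 0.5)
  gt <- p$mask > 0
  dice <- 2 * sum(sg$mask & gt) / (sum(sg$mask) + sum(gt))
  expect_gt(dice, 0.5)
})

test_that("segment_patch threshold semantics and resize policy", {
  fit <- tiny_seg_fit()
  p <- render_patch(fit$config, 5)
  sg <- segment_patch(p$image, fit$net, threshold = 1)
  expect_false(any(sg$mask))  # probabilities are strictly below 1
  big <- render_patch(synth_config(patch_size = 128L), 5)
  expect_error(segment_patch(big$image, fit$net), "allow_resize")
  sg2 <- segment_patch(big$image, fit$net, allow_resize = TRUE)
  expect_equal(dim(sg2$prob), c(128, 128))
})

test_that("HSV debris filter removes RBC components, keeps nuclei, and is
           component-wise and idempotent", {
  cfg <- synth_config(patch_size = 128L, nuclei_range = c(6L, 8L),
                      debris_rate = 1, cluster_rate = 0)
  p <- render_patch(cfg, 21)
  hsv <- thyrocyto:::rgb_to_hsv_image(p$image)
  rbc_px <- (hsv[, , 1] > 0.95 | hsv[, , 1] < 0.05) & hsv[, , 2] > 0.5
  # a deliberately contaminated mask: nuclei plus RBC debris
  mask <- (p$mask > 0) | rbc_px
  expect_warning(ident <- hsv_debris_filter(p$image, mask, list()),
                 "no HSV ranges")
  expect_identical(ident, mask)
  filtered <- hsv_debris_filter(p$image, mask)
  # every ground-truth nucleus survives
  for (id in p$class_table$instance_id)
    expect_true(any(filtered[p$mask == id]))
  # the overwhelming majority of RBC-only pixels are gone
  rbc_only <- rbc_px & p$mask == 0
  expect_lt(sum(filtered & rbc_only) / max(1, sum(rbc_only)), 0.1)
  expect_identical(hsv_debris_filter(p$image, filtered), filtered)
})

test_that("a component whose median hue sits exactly on the upper bound is
           retained", {
  img <- array(0, c(16, 16, 3))
  # RGB (0.9, 0.396, 0.18) has HSV hue exactly 0.05 and saturation 0.8
  rgbv <- c(0.9, 0.396, 0.18)
  for (ch in 1:3) img[5:8, 5:8, ch] <- rgbv[ch]
  mask <- matrix(FALSE, 16, 16); mask[5:8, 5:8] <- TRUE
  out <- hsv_debris_filter(img, mask,
                           list(hsv_range(h = c(0, 0.05), s = c(0.5, 1))))
  expect_identical(out, mask)  # high bound exclusive
  out2 <- hsv_debris_filter(img, mask,
                            list(hsv_range(h = c(0.05, 0.1), s = c(0.5, 1))))
  expect_false(any(out2))      # low bound inclusive
})

test_that("detections_from_mask handles empty, single and merged objects", {
  empty <- detections_from_mask(matrix(FALSE, 32, 32))
  expect_equal(nrow(empty), 0)

  # one disk well under the (256-px tile) cluster threshold
  m <- matrix(FALSE, 64, 64)
  for (r in 1:64) for (c in 1:64)
    if ((r - 32)^2 + (c - 32)^2 <= 81) m[r, c] <- TRUE
  det <- detections_from_mask(m)
  expect_equal(nrow(det), 1)
  expect_identical(det$kind, "nucleus")
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  expect_equal(c(det$x0, det$y0, det$x1, det$y1),
               c(cols[1] - 1, rows[1] - 1, cols[2], rows[2]))

  # two overlapping ellipses, one component, two clear distance maxima:
  # with defaults this is one cluster detection carrying both seeds
  m2 <- matrix(FALSE, 64, 64)
  for (r in 1:64) for (c in 1:64) {
    if (((r - 32) / 8)^2 + ((c - 24) / 10)^2 <= 1) m2[r, c] <- TRUE
    if (((r - 32) / 8)^2 + ((c - 42) / 10)^2 <= 1) m2[r, c] <- TRUE
  }
  expect_equal(max(EBImage::bwlabel(m2)), 1)
  det2 <- detections_from_mask(m2)
  expect_equal(nrow(det2), 1)
  expect_identical(det2$kind, "cluster")
  expect_gte(det2$n_seeds, 2)
  # with a low max_single_area the same component is split in two nuclei
  sp <- split_params(max_single_area = 100, min_peak_distance = 5,
                     min_area = 10)
  det3 <- detections_from_mask(m2, split = sp, cluster_area_threshold = 1200)
  expect_equal(nrow(det3), 2)
  expect_true(all(det3$kind == "nucleus"))
})

test_that("with splitting disabled detections equal plain
           connected-component labelling", {
  set.seed(99)
  for (i in 1:50) {
    m <- matrix(runif(32 * 32) < 0.22, 32, 32)
    det <- detections_from_mask(m, split = NULL)
    oracle <- flood_label(m)
    expect_equal(nrow(det), max(oracle))
    if (nrow(det) == 0) next
    # reconstruct a label raster from the detections and compare supports
    rec <- matrix(FALSE, 32, 32)
    for (k in seq_len(nrow(det))) {
      d <- det[k, ]
      rec[(d$y0 + 1):d$y1, (d$x0 + 1):d$x1] <-
        rec[(d$y0 + 1):d$y1, (d$x0 + 1):d$x1] | d$mask[[1]]
    }
    expect_identical(rec, m)
  }
})

test_that("every foreground pixel is assigned to a detection or counted as
           discarded", {
  p <- render_patch(small_config(cluster_rate = 0.5), 31)
  m <- p$mask > 0
  det <- detections_from_mask(m, tile_size = 128L)
  assigned <- sum(vapply(det$mask, sum, numeric(1)))
  expect_equal(assigned + attr(det, "discarded_pixels"), sum(m))
  expect_true(all(det$score >= 0 & det$score <= 1))
  ct <- 1200 * (128 / 256)^2
  expect_true(all(det$area > ct | det$n_seeds >= 2 |
                    det$kind == "nucleus"))
})

test_that("morphometry matches closed forms on rasterised shapes", {
  mk_ellipse <- function(a, b, size = 80) {
    m <- matrix(FALSE, size, size)
    cx <- size / 2
    for (r in 1:size) for (c in 1:size)
      if (((c - cx) / a)^2 + ((r - cx) / b)^2 <= 1) m[r, c] <- TRUE
    m
  }
  img <- array(0.5, c(80, 80, 3))
  disk <- mk_ellipse(10, 10)
  det <- detections_from_mask(disk, split = NULL)
  mv <- nuclear_morphometry(img, det[1, ])
  expect_equal(mv[["area"]], 100 * pi, tolerance = 0.05 * 100 * pi)
  expect_equal(mv[["aspect_ratio"]], 1, tolerance = 0.05)
  expect_gt(mv[["circularity"]], 0.9)
  expect_gt(mv[["solidity"]], 0.95)

  ell <- mk_ellipse(20, 10)
  dete <- detections_from_mask(ell, split = NULL,
                               cluster_area_threshold = 1e6)
  mve <- nuclear_morphometry(img, dete[1, ])
  expect_equal(mve[["aspect_ratio"]], 2, tolerance = 0.05 * 2)
  expect_equal(mve[["eccentricity"]], sqrt(3) / 2,
               tolerance = 0.05 * sqrt(3) / 2)
  expect_equal(abs(mve[["orientation"]]), 0, tolerance = 0.05)

  # constant-intensity nucleus
  expect_equal(mv[["gray_std"]], 0)
  expect_equal(mv[["gray_min"]], mv[["gray_max"]])
  expect_equal(mv[["gray_mean"]], mv[["gray_min"]])

  # degenerate single pixel
  one <- matrix(FALSE, 8, 8); one[4, 4] <- TRUE
  d1 <- detections_from_mask(one, split = NULL)
  mv1 <- nuclear_morphometry(img[1:8, 1:8, , drop = FALSE], d1[1, ])
  expect_equal(mv1[["aspect_ratio"]], 1)
  expect_gte(mv1[["perimeter"]], 1)
  expect_equal(length(mv1), 19)
})

test_that("morphometry scales correctly with image resolution", {
  mk_disk <- function(r, size) {
    m <- matrix(FALSE, size, size)
    for (rr in 1:size) for (cc in 1:size)
      if ((rr - size / 2)^2 + (cc - size / 2)^2 <= r^2) m[rr, cc] <- TRUE
    m
  }
  img1 <- array(0.4, c(60, 60, 3)); img2 <- array(0.4, c(120, 120, 3))
  d1 <- detections_from_mask(mk_disk(12, 60), split = NULL,
                             cluster_area_threshold = 1e6)
  d2 <- detections_from_mask(mk_disk(24, 120), split = NULL,
                             cluster_area_threshold = 1e6)
  m1 <- nuclear_morphometry(img1, d1[1, ])
  m2 <- nuclear_morphometry(img2, d2[1, ])
  expect_equal(m2[["area"]] / m1[["area"]], 4, tolerance = 0.4)
  expect_equal(m2[["perimeter"]] / m1[["perimeter"]], 2, tolerance = 0.2)
  for (f in c("aspect_ratio", "eccentricity", "solidity"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 0.05 * max(m1[[f]], 0.05))
})

test_that("the morphology GBT separates benign-round from atypical-large
           classes and respects its contracts", {
  set <- cached("morpho_2class", function()
    render_crop_set(c("C8", "C3"), 100, seed0 = 300))
  tab <- morpho_from_crops(set)
  n <- nrow(tab)
  idx <- with_seed(1, sample.int(n))
  tr <- idx[1:floor(0.75 * n)]; te <- idx[(floor(0.75 * n) + 1):n]
  fit <- train_morpho_gbt(tab[tr, ], tab$class[tr], seed = 0)
  pred <- classify_morpho(tab[te, ], fit)
  acc <- mean(pred$morpho_class == tab$class[te])
  expect_gte(acc, 0.95)
  f1s <- vapply(c("C8", "C3"), function(cl) {
    tp <- sum(pred$morpho_class == cl & tab$class[te] == cl)
    pr <- tp / max(1, sum(pred$morpho_class == cl))
    rc <- tp / max(1, sum(tab$class[te] == cl))
    2 * pr * rc / max(1e-9, pr + rc)
  }, numeric(1))
  expect_gte(mean(f1s), 0.95)

  expect_error(train_morpho_gbt(tab[tr, ], rep("C8", length(tr))),
               "two classes")
  expect_error(classify_morpho(rnorm(18), fit), "19")
  v <- as.numeric(tab[te[1], morpho_feature_names()])
  one <- classify_morpho(stats::setNames(v, morpho_feature_names()), fit)
  expect_true(one$morpho_prob >= 0 && one$morpho_prob <= 1)

  # duplicating every row leaves predictions unchanged
  dup <- tab[rep(tr, each = 2), ]
  fit2 <- train_morpho_gbt(dup, dup$class, seed = 0)
  pred2 <- classify_morpho(tab[te, ], fit2)
  expect_identical(pred$morpho_class, pred2$morpho_class)
})
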