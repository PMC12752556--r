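# Synthetic cytology generator: determinism, mask/table consistency,
# debris behaviour, appearance perturbation, and the slide labelling rule.

test_that("identical (config, seed) pairs render byte-identical patches", {
  cfg <- small_config()
  expect_identical(render_patch(cfg, 1), render_patch(cfg, 1))
  s1 <- render_slide(cfg, n_tiles = 2, seed = 9)
  s2 <- render_slide(cfg, n_tiles = 2, seed = 9)
  expect_identical(s1, s2)
  # and the global RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(render_patch(cfg, 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a zero-nucleus config renders pure background", {
  p <- render_patch(synth_config(nuclei_range = c(0L, 0L),
                                 debris_rate = 0), 3)
  expect_equal(nrow(p$class_table), 0)
  expect_true(all(p$mask == 0))
  expect_equal(dim(p$image), c(256, 256, 3))
})

test_that("requested object count is honoured and matches a
           connected-components oracle", {
  cfg <- synth_config(patch_size = 128L, nuclei_range = c(12L, 12L),
                      cluster_rate = 0, debris_rate = 0)
  p <- render_patch(cfg, 1)
  expect_equal(nrow(p$class_table), 12)
  expect_false(any(p$class_table$is_cluster))
  # objects are spatially separated at cluster_rate 0, so the label count
  # equals the component count of the binarised mask
  expect_equal(max(EBImage::bwlabel(p$mask > 0)), 12)
})

test_that("mask labels and class table agree on every patch", {
  cfg <- small_config(cluster_rate = 0.4)
  for (seed in 1:6) {
    p <- render_patch(cfg, seed)
    ids <- sort(unique(p$mask[p$mask > 0]))
    expect_identical(as.integer(ids), p$class_table$instance_id)
    expect_identical(p$class_table$instance_id,
                     seq_len(nrow(p$class_table)))
  }
})

test_that("red blood cell debris is painted but carries no mask label", {
  cfg <- synth_config(patch_size = 128L, nuclei_range = c(0L, 0L),
                      debris_rate = 1)
  p <- render_patch(cfg, 2)
  hsv <- thyrocyto:::rgb_to_hsv_image(p$image)
  reddish <- (hsv[, , 1] > 0.95 | hsv[, , 1] < 0.05) & hsv[, , 2] > 0.5
  expect_gt(sum(reddish), 50)     # RBC pixels exist...
  expect_true(all(p$mask == 0))   # ...but are never labelled
})

test_that("appearance perturbation is an image-only, clipped channel map", {
  p <- render_patch(small_config(), 4)
  ident <- perturb_appearance(p, gain = 1, offset = 0, gamma = 1)
  expect_identical(ident, p)
  white <- perturb_appearance(p, offset = 255)
  expect_true(all(white$image == 1))
  expect_identical(white$mask, p$mask)
  expect_identical(white$class_table, p$class_table)
  red <- perturb_appearance(p, gain = c(0.8, 1, 1))
  expect_lt(mean(red$image[, , 1]), mean(p$image[, , 1]))
  expect_equal(mean(red$image[, , 2]), mean(p$image[, , 2]), tolerance = 1e-6)
  expect_equal(mean(red$image[, , 3]), mean(p$image[, , 3]), tolerance = 1e-6)
  expect_error(perturb_appearance(p, gain = 0), "gain")
})

test_that("slide counts are conserved and the label rule is reproducible", {
  cfg <- synth_config(patch_size = 64L, nuclei_range = c(4L, 8L))
  slides <- render_cohort(200, cfg, seed = 11, n_tiles = 2)
  for (s in slides) {
    counts <- table(factor(
      unlist(lapply(s$tiles, function(t) t$class_table$class)),
      levels = paste0("C", 1:17)))
    expect_identical(s$true_counts,
                     stats::setNames(as.integer(counts), paste0("C", 1:17)))
    lab <- thyrocyto:::fixture_tbs_label(s$true_counts, cfg$tbs_v_band)
    expect_identical(lab$tbs, s$true_tbs)
  }
  expect_setequal(unique(vapply(slides, `[[`, character(1), "true_tbs")),
                  c("I", "II", "V", "VI"))
})

test_that("slides forced to contain no epithelium are nondiagnostic and
           pure-benign adequate slides are TBS II", {
  other_only <- stats::setNames(rep(0, 17), paste0("C", 1:17))
  other_only[c("C10", "C13")] <- c(0.6, 0.4)
  cfg <- synth_config(patch_size = 64L, class_mix = other_only,
                      nuclei_range = c(5L, 8L))
  s <- render_slide(cfg, 2, seed = 3)
  expect_identical(s$true_tbs, "I")

  benign <- stats::setNames(rep(0, 17), paste0("C", 1:17))
  benign[c("C6", "C7", "C8")] <- c(0.4, 0.35, 0.25)
  cfg2 <- synth_config(patch_size = 128L, class_mix = benign,
                       nuclei_range = c(14L, 18L))
  s2 <- render_slide(cfg2, 3, seed = 3)
  expect_identical(s2$true_tbs, "II")
  expect_equal(s2$atypical_fraction, 0)
})

test_that("a heavily atypical adequate slide is labelled TBS VI", {
  mix <- stats::setNames(rep(0, 17), paste0("C", 1:17))
  mix[paste0("C", 1:5)] <- 0.16
  mix[c("C6", "C7")] <- 0.1
  cfg <- synth_config(patch_size = 128L, class_mix = mix,
                      nuclei_range = c(14L, 18L))
  s <- render_slide(cfg, 3, seed = 7)
  expect_gt(s$atypical_fraction, 0.5)
  expect_identical(s$true_tbs, "VI")
})

test_that("invalid configurations are rejected", {
  bad_mix <- default_class_mix()
  bad_mix[1] <- bad_mix[1] + 0.01
  expect_error(synth_config(class_mix = bad_mix), "sum to 1")
  expect_error(synth_config(patch_size = 32), "at least 64")
  expect_error(synth_config(cluster_rate = 1.2), "rates")
  expect_error(render_slide(synth_config(), n_tiles = 0), "n_tiles")
})
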