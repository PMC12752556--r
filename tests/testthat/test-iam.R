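# Appearance migration: foreground masking, profile statistics, and the
# statistics-matching migration map.

test_that("a pure glass tile yields an empty (flagged) mask", {
  white <- array(1, c(64, 64, 3))
  m <- extract_cell_mask(white)
  expect_false(any(m))
  expect_true(attr(m, "empty"))
})

test_that("the mask covers nuclei and little background on synthetic
           tiles, and closing is idempotent", {
  cfg <- small_config()
  for (seed in c(3, 11, 27)) {
    p <- render_patch(cfg, seed)
    m <- extract_cell_mask(p$image)
    gt <- p$mask > 0
    expect_gte(sum(m & gt) / sum(gt), 0.9)
    expect_lte(sum(m & !gt) / sum(!gt), 0.2)
    brush <- EBImage::makeBrush(7, "disc")
    closed <- EBImage::imageData(EBImage::closing(EBImage::Image(m * 1),
                                                  brush)) > 0.5
    again <- EBImage::imageData(EBImage::closing(EBImage::Image(closed * 1),
                                                 brush)) > 0.5
    expect_identical(again, closed)
  }
})

test_that("profiles of constant regions are exact and pooling matches a
           manual pixel pool", {
  img <- array(0, c(32, 32, 3))
  col <- c(0.3, 0.5, 0.7)
  for (ch in 1:3) img[, , ch] <- col[ch]
  m <- matrix(TRUE, 32, 32)
  pr <- estimate_profile(img, m, seed = 1)
  expect_equal(unname(pr$sd), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(pr$mean),
               as.numeric(thyrocyto:::rgb_to_lab_pixels(matrix(col, 1))),
               tolerance = 1e-12)

  cfg <- small_config()
  p1 <- render_patch(cfg, 1); p2 <- render_patch(cfg, 2)
  m1 <- extract_cell_mask(p1$image); m2 <- extract_cell_mask(p2$image)
  joint <- estimate_profile(list(p1$image, p2$image), list(m1, m2),
                            max_pixels = 1e7, seed = 0)
  manual <- rbind(
    cbind(p1$image[, , 1][m1], p1$image[, , 2][m1], p1$image[, , 3][m1]),
    cbind(p2$image[, , 1][m2], p2$image[, , 2][m2], p2$image[, , 3][m2]))
  expect_equal(unname(joint$mean),
               unname(colMeans(thyrocyto:::rgb_to_lab_pixels(manual))),
               tolerance = 1e-9)
  expect_identical(estimate_profile(list(p1$image), list(m1), seed = 4),
                   estimate_profile(list(p1$image), list(m1), seed = 4))
  expect_error(estimate_profile(p1$image, m1 & FALSE), "no foreground")
})

test_that("identity migration changes pixels by at most one intensity
           level and leaves geometry untouched", {
  p <- render_patch(small_config(), 13)
  m <- extract_cell_mask(p$image)
  pr <- estimate_profile(p$image, m, seed = 2)
  out <- migrate_image(p$image, pr, pr, mask = m)
  expect_lte(max(abs(out - p$image)) * 255, 1)
  m2 <- extract_cell_mask(out)
  expect_identical(as.logical(m2), as.logical(m))
})

test_that("migration matches foreground channel means to the reference
           within 2% of range", {
  p <- render_patch(small_config(nuclei_range = c(12L, 16L)), 13)
  ref_p <- render_patch(synth_config(patch_size = 128L, stain_style = "he",
                                     nuclei_range = c(12L, 16L)), 14)
  m <- extract_cell_mask(p$image)
  mref <- extract_cell_mask(ref_p$image)
  expect_gt(sum(m), 500)
  src <- estimate_profile(p$image, m, seed = 0)
  ref <- estimate_profile(ref_p$image, mref, seed = 0)
  out <- migrate_image(p$image, src, ref, mask = m)
  after <- estimate_profile(out, m, max_pixels = 1e7, seed = 0)
  range_lab <- abs(ref$p99 - ref$p01) + 0.05
  expect_true(all(abs(after$mean - ref$mean) <= 0.02 * pmax(range_lab, 1)))
  # sigma = 0 channels fall back to unit gain
  const <- array(0.5, c(16, 16, 3))
  cm <- matrix(TRUE, 16, 16)
  cpr <- estimate_profile(const, cm)
  out2 <- migrate_image(const, cpr, cpr, mask = cm)
  expect_lte(max(abs(out2 - const)) * 255, 1)
})

test_that("profiles from different colour spaces refuse to mix", {
  p <- render_patch(small_config(), 5)
  m <- extract_cell_mask(p$image)
  a <- estimate_profile(p$image, m)
  b <- a; b$space <- "rgb"
  expect_error(migrate_image(p$image, a, b, mask = m), "colour spaces")
})

test_that("migrating twice with an updated source profile is approximately
           idempotent", {
  p <- render_patch(small_config(), 17)
  ref_p <- render_patch(small_config(stain_style = "he"), 18)
  m <- extract_cell_mask(p$image)
  ref <- estimate_profile(ref_p$image, extract_cell_mask(ref_p$image))
  once <- migrate_image(p$image, estimate_profile(p$image, m), ref, mask = m)
  twice <- migrate_image(once, estimate_profile(once, m, max_pixels = 1e7),
                         ref, mask = m)
  expect_lte(mean(abs(twice - once)) * 255, 1)
})

test_that("slide migration uses one profile for all tiles and reduces the
           appearance distance of a shifted slide", {
  cfg <- small_config()
  tiles <- lapply(1:3, function(i) render_patch(cfg, sub_seed(400, i)))
  imgs <- lapply(tiles, function(t) t$image)
  ref <- estimate_profile(imgs,
                          lapply(imgs, extract_cell_mask), seed = 0,
                          source = "reference")
  shifted <- lapply(tiles, function(t)
    perturb_appearance(t, gain = c(1.12, 0.92, 1.0), offset = c(6, -4, 2),
                       gamma = c(1.04, 1, 0.97))$image)
  mig <- migrate_slide(shifted, ref, seed = 0)
  expect_false(mig$skipped)
  d_before <- mean(mapply(function(a, b, t) mean(abs(a - b)[t$mask > 0]),
                          shifted, imgs, tiles))
  d_after <- mean(mapply(function(a, b, t) mean(abs(a - b)[t$mask > 0]),
                         mig$tiles, imgs, tiles))
  expect_lt(d_after, d_before)

  # identical tiles migrate identically
  same <- list(imgs[[1]], imgs[[1]])
  mig2 <- migrate_slide(same, ref, seed = 0)
  expect_identical(mig2$tiles[[1]], mig2$tiles[[2]])

  blank <- list(array(1, c(64, 64, 3)))
  expect_warning(mig3 <- migrate_slide(blank, ref), "no foreground")
  expect_identical(mig3$tiles, blank)
})
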