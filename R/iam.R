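# Cytology-specific image appearance migration (IAM).
#
# Cytological smears are dispersed cells on glass, so global stain
# normalisation in the Reinhard/Macenko style (which assumes fairly uniform
# tissue) distorts them; here colour statistics are estimated over a
# cell-foreground mask only and matched slide-adaptively: one source
# profile per slide, applied tile by tile, in a log-LMS opponent colour
# space (luminance plus two chroma channels) where per-channel affine
# matching is well-behaved. Background pixels are blended through a
# feathered mask so no halo forms at cell boundaries.

#' Foreground mask parameters for cytology tiles
#'
#' @param saturation_threshold pixels with HSV saturation above this are
#'   foreground candidates, in `(0, 1)`.
#' @param min_size objects smaller than this (px) are removed.
#' @param closing_radius radius (px) of the morphological closing brush.
#' @param luminance_frac pixels darker than this fraction of the estimated
#'   glass-background luminance are also foreground.
#' @return object of class `mask_params`.
#' @export
mask_params <- function(saturation_threshold = 0.12, min_size = 20L,
                        closing_radius = 3L, luminance_frac = 0.85) {
  if (saturation_threshold <= 0 || saturation_threshold >= 1)
    stop("saturation_threshold must lie in (0, 1)", call. = FALSE)
  structure(list(saturation_threshold = saturation_threshold,
                 min_size = as.integer(min_size),
                 closing_radius = as.integer(closing_radius),
                 luminance_frac = luminance_frac),
            class = "mask_params")
}

#' H&E preset for the foreground mask
#'
#' Haematoxylin-eosin tiles have a stronger pink background, so the
#' saturation criterion alone over-selects; the preset tightens it and
#' leans on the luminance criterion.
#' @return a [mask_params()].
#' @export
mask_params_he <- function() {
  mask_params(saturation_threshold = 0.25, luminance_frac = 0.8)
}

#' Extract the cell-foreground mask of a cytology tile
#'
#' Foreground = saturated pixels (stained material) union pixels darker
#' than a fraction of the glass-background luminance, morphologically
#' closed, with small specks removed. Both criteria adapt to the tile:
#' the glass luminance is estimated as the 95th luminance percentile, and
#' the effective saturation cut is at least twice the median saturation
#' (glass dominates the median), which keeps the mask stable under global
#' stain or scanner colour shifts. A fully background tile yields an empty
#' mask flagged via the `empty` attribute (not an error).
#'
#' @param image RGB array `[H, W, 3]`.
#' @param params a [mask_params()].
#' @return logical matrix with attribute `empty`.
#' @export
extract_cell_mask <- function(image, params = mask_params()) {
  assert_image(image)
  hsv <- rgb_to_hsv_image(image)
  lum <- luminance(image)
  glass <- stats::quantile(lum, 0.95, names = FALSE)
  sat_cut <- max(params$saturation_threshold,
                 2 * stats::median(hsv[, , 2]))
  fg <- hsv[, , 2] > sat_cut | lum < params$luminance_frac * glass
  if (any(fg) && params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$closing_radius + 1, "disc")
    fg <- EBImage::imageData(EBImage::closing(EBImage::Image(fg * 1),
                                              brush)) > 0.5
  }
  if (any(fg) && params$min_size > 0) {
    lab <- EBImage::bwlabel(fg)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      drop <- which(sizes < params$min_size)
      if (length(drop)) fg[lab %in% drop] <- FALSE
    }
  }
  attr(fg, "empty") <- !any(fg)
  fg
}

#' Estimate a foreground appearance profile
#'
#' Per-channel mean, standard deviation and 1st/99th percentiles of the
#' pooled foreground pixels of one or more tiles, in the log-LMS opponent
#' space. When the pool exceeds `max_pixels` it is subsampled with a seeded
#' draw, so the profile is deterministic given `seed`.
#'
#' @param images list of RGB arrays (or a single array).
#' @param masks list of logical masks aligned with `images` (or one mask).
#' @param max_pixels sampling cap.
#' @param seed RNG seed for the subsample.
#' @param source tag recorded on the profile (e.g. a domain id).
#' @return object of class `appearance_profile`.
#' @export
estimate_profile <- function(images, masks, max_pixels = 200000L, seed = 0L,
                             source = "unspecified") {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  if (is.matrix(masks) || is.logical(masks) && !is.list(masks))
    masks <- list(masks)
  stopifnot(length(images) == length(masks))
  px <- do.call(rbind, lapply(seq_along(images), function(i) {
    m <- masks[[i]]
    if (!any(m)) return(NULL)
    img <- images[[i]]
    cbind(img[, , 1][m], img[, , 2][m], img[, , 3][m])
  }))
  if (is.null(px) || nrow(px) == 0)
    stop("no foreground to profile (all masks empty)", call. = FALSE)
  if (nrow(px) > max_pixels)
    px <- with_seed(seed, px[sample.int(nrow(px), max_pixels), , drop = FALSE])
  lab <- rgb_to_lab_pixels(px)
  structure(list(space = "lalphabeta",
                 mean = colMeans(lab),
                 sd = apply(lab, 2, stats::sd),
                 p01 = apply(lab, 2, stats::quantile, 0.01, names = FALSE),
                 p99 = apply(lab, 2, stats::quantile, 0.99, names = FALSE),
                 n_pixels = nrow(px),
                 source = source),
            class = "appearance_profile")
}

#' Migrate one tile to a reference appearance
#'
#' Foreground pixels are mapped per channel in the perceptual space by
#' `x -> (x - mu_src) * sigma_ref / sigma_src + mu_ref` (gain 1 when
#' `sigma_src` is 0), converted back to RGB and clipped. Background blends
#' through a feathered mask: weight 1 inside the mask with a smooth falloff
#' outside, which prevents halo artifacts while leaving foreground
#' statistics exactly matched (up to clipping and 8-bit rounding).
#'
#' @param image RGB array.
#' @param source source-domain [estimate_profile()].
#' @param reference reference-domain profile (same colour space).
#' @param mask logical foreground mask (default: recomputed with
#'   [extract_cell_mask()] defaults).
#' @param feather Gaussian falloff radius (px) outside the mask.
#' @return migrated RGB array, same shape as `image`.
#' @export
migrate_image <- function(image, source, reference, mask = NULL, feather = 3) {
  stopifnot(inherits(source, "appearance_profile"),
            inherits(reference, "appearance_profile"))
  if (!identical(source$space, reference$space))
    stop("profiles use different colour spaces", call. = FALSE)
  assert_image(image)
  if (is.null(mask)) mask <- extract_cell_mask(image)
  d <- dim(image)
  px <- matrix(image, ncol = 3L)
  lab <- rgb_to_lab_pixels(px)
  gain <- ifelse(source$sd > 0, reference$sd / source$sd, 1)
  mapped <- sweep(lab, 2, source$mean)
  mapped <- sweep(mapped, 2, gain, `*`)
  mapped <- sweep(mapped, 2, reference$mean, `+`)
  rgb_m <- lab_to_rgb_pixels(mapped)
  w <- mask * 1
  if (feather > 0 && any(mask) && !all(mask)) {
    wb <- EBImage::imageData(EBImage::gblur(EBImage::Image(w),
                                            sigma = feather))
    w <- pmax(w, pmin(pmax(wb, 0), 1))
  }
  wv <- as.numeric(w)
  out <- rgb_m * wv + px * (1 - wv)
  array(clip01(out), dim = d)
}

#' Migrate a whole slide to a reference appearance
#'
#' One source profile is estimated from all tiles pooled (slide-level
#' adaptation) and then applied tile by tile; per-tile profiles are never
#' used, so neighbouring tiles cannot flicker. If no tile has foreground
#' the tiles are returned unchanged with a warning flag.
#'
#' @param tiles list of RGB arrays.
#' @param reference reference-domain profile.
#' @param params a [mask_params()].
#' @param seed seed for profile subsampling.
#' @param feather blending falloff radius, as in [migrate_image()].
#' @return list with `tiles` (migrated), `profile` (the slide source
#'   profile or `NULL`), and `skipped` (TRUE when nothing was migrated).
#' @export
migrate_slide <- function(tiles, reference, params = mask_params(),
                          seed = 0L, feather = 3) {
  masks <- lapply(tiles, extract_cell_mask, params = params)
  if (all(vapply(masks, function(m) !any(m), logical(1)))) {
    warning("no foreground found on any tile; slide returned unmigrated")
    return(list(tiles = tiles, profile = NULL, skipped = TRUE))
  }
  prof <- estimate_profile(tiles, masks, seed = seed, source = "slide")
  migrated <- lapply(seq_along(tiles), function(i)
    migrate_image(tiles[[i]], prof, reference, mask = masks[[i]],
                  feather = feather))
  list(tiles = migrated, profile = prof, skipped = FALSE)
}

#' @export
print.appearance_profile <- function(x, ...) {
  cat("<appearance_profile> [", x$space, "] source ", x$source, ", ",
      x$n_pixels, " px; mean ", paste(round(x$mean, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
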