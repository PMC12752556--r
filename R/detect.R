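# Post-processing of the segmentation output: HSV debris rejection and
# conversion of the binary mask into nucleus / cluster detections with
# distance-transform watershed splitting of merged blobs.
#
# Detections are rows of a tibble: bounding box (x0, y0, x1, y1) in 0-based
# half-open pixel coordinates (x = column, origin top-left), `kind`
# ("nucleus" or "cluster"), `score` (mean foreground probability over the
# object's pixels), `area`, `n_seeds`, and a list-column `mask` holding the
# binary instance mask cropped to the box.

#' An HSV range used for component-wise debris filtering
#'
#' @param h,s,v per-channel `(low, high)` bounds, each in `[0, 1]`. A
#'   component matches the range when its median channel value lies in
#'   `[low, high)` for all three channels (upper bounds exclusive).
#' @param mode `"reject"` (drop matching components) or `"keep"`.
#' @return object of class `hsv_range`.
#' @export
hsv_range <- function(h = c(0, 1), s = c(0, 1), v = c(0, 1),
                      mode = c("reject", "keep")) {
  mode <- match.arg(mode)
  for (b in list(h, s, v)) {
    if (length(b) != 2 || b[1] > b[2] || any(b < 0) || any(b > 1))
      stop("each bound must be (low, high) with 0 <= low <= high <= 1",
           call. = FALSE)
  }
  structure(list(h = h, s = s, v = v, mode = mode), class = "hsv_range")
}

#' Default red-debris reject ranges
#'
#' Red blood cells sit at the hue wrap-around with high saturation; the
#' default covers hue in `[0.95, 1] U [0, 0.05]` with saturation >= 0.5.
#' Stain-dependent, so always config-exposed.
#' @return list of [hsv_range()] objects.
#' @export
default_hsv_ranges <- function() {
  list(hsv_range(h = c(0.95, 1), s = c(0.5, 1)),
       hsv_range(h = c(0, 0.05), s = c(0.5, 1)))
}

in_hsv_range <- function(med, range) {
  inside <- med[1] >= range$h[1] & med[1] < range$h[2] &
    med[2] >= range$s[1] & med[2] < range$s[2] &
    med[3] >= range$v[1] & med[3] < range$v[2]
  inside
}

#' Reject debris components by their median HSV colour
#'
#' Connected components of `mask` whose median hue/saturation/value falls
#' inside any `"reject"` range (and outside every `"keep"` range, when keep
#' ranges are given) are removed whole; removal is component-wise, never
#' pixel-wise, so nuclei are never fragmented. Applying the filter twice
#' equals applying it once.
#'
#' @param image RGB array `[H, W, 3]`.
#' @param mask logical (or 0/1) matrix aligned with `image`.
#' @param ranges list of [hsv_range()]; an empty list is the identity (a
#'   warning is emitted).
#' @return filtered logical mask.
#' @export
hsv_debris_filter <- function(image, mask, ranges = default_hsv_ranges()) {
  assert_image(image)
  mask <- mask > 0
  if (length(ranges) == 0) {
    warning("no HSV ranges supplied; returning mask unchanged")
    return(mask)
  }
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(mask)
  hsv <- rgb_to_hsv_image(image)
  keep <- rep(TRUE, n)
  flat <- matrix(hsv, ncol = 3L)
  for (k in seq_len(n)) {
    px <- which(lab == k)
    med <- c(stats::median(flat[px, 1]), stats::median(flat[px, 2]),
             stats::median(flat[px, 3]))
    rejected <- FALSE
    kept <- FALSE
    for (r in ranges) {
      if (r$mode == "reject" && in_hsv_range(med, r)) rejected <- TRUE
      if (r$mode == "keep" && in_hsv_range(med, r)) kept <- TRUE
    }
    keep[k] <- kept || !rejected
  }
  out <- mask
  drop_ids <- which(!keep)
  if (length(drop_ids)) out[lab %in% drop_ids] <- FALSE
  out
}

#' Watershed / splitting parameters
#'
#' Defaults are calibrated for 256-px tiles; areas scale with
#' `(tile_size / 256)^2` and the peak distance linearly.
#'
#' @param max_single_area components larger than this (px^2) are split by
#'   distance-transform watershed.
#' @param min_peak_distance minimum separation (px) between watershed seed
#'   peaks.
#' @param min_area objects smaller than this are discarded.
#' @param tile_size tile side used to scale the defaults.
#' @return object of class `split_params`.
#' @export
split_params <- function(max_single_area = 2500 * (tile_size / 256)^2,
                         min_peak_distance = max(2, round(7 * tile_size / 256)),
                         min_area = 30 * (tile_size / 256)^2,
                         tile_size = 256L) {
  structure(list(max_single_area = max_single_area,
                 min_peak_distance = min_peak_distance,
                 min_area = min_area),
            class = "split_params")
}

# Seed peaks of the distance map: local maxima over a disc of radius
# min_peak_distance, labelled; plateaus collapse to one seed.
distance_seeds <- function(dm, min_peak_distance) {
  brush <- EBImage::makeBrush(2 * round(min_peak_distance) + 1, "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(dm), brush))
  peaks <- dm >= dil & dm >= 1
  EBImage::bwlabel(peaks)
}

#' Convert a foreground mask into nucleus / cluster detections
#'
#' Connected components are extracted; components larger than
#' `split$max_single_area` are split by a distance-transform watershed
#' seeded at distance-map maxima separated by at least
#' `split$min_peak_distance`. Each resulting object is a cluster when its
#' area exceeds `cluster_area_threshold` or it contains two or more seed
#' peaks, otherwise a single nucleus. Objects below `split$min_area` are
#' discarded (counted in the `discarded` attribute for audit). Scores are
#' mean foreground probabilities over each object's pixels.
#'
#' @param mask binary matrix.
#' @param prob probability raster aligned with `mask` (defaults to 1).
#' @param split a [split_params()]; pass `NULL` to disable splitting (then
#'   the result is exactly connected-component labelling).
#' @param cluster_area_threshold area (px^2) above which an object is a
#'   cluster; default 1200 at 256-px tiles.
#' @param tile_size used only to scale the default threshold.
#' @return tibble of detections (possibly 0 rows) with attributes
#'   `discarded` (count) and `discarded_pixels`.
#' @export
detections_from_mask <- function(mask, prob = NULL,
                                 split = split_params(tile_size = tile_size),
                                 cluster_area_threshold = 1200 * (tile_size / 256)^2,
                                 tile_size = 256L) {
  mask <- mask > 0
  if (is.null(prob)) prob <- matrix(1, nrow(mask), ncol(mask))
  stopifnot(all(dim(prob) == dim(mask)))
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  empty <- tibble::tibble(detection_id = integer(), x0 = integer(),
                          y0 = integer(), x1 = integer(), y1 = integer(),
                          kind = character(), score = numeric(),
                          area = integer(), n_seeds = integer(),
                          mask = list())
  if (n == 0) {
    attr(empty, "discarded") <- 0L
    attr(empty, "discarded_pixels") <- 0L
    return(empty)
  }

  objects <- list()
  for (k in seq_len(n)) {
    comp <- lab == k
    area <- sum(comp)
    seeds_n <- 0L
    parts <- list(comp)
    if (!is.null(split)) {
      # distance transform on the component crop
      rows <- range(which(rowSums(comp) > 0))
      cols <- range(which(colSums(comp) > 0))
      crop <- comp[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
      pad <- matrix(FALSE, nrow(crop) + 2, ncol(crop) + 2)
      pad[2:(nrow(crop) + 1), 2:(ncol(crop) + 1)] <- crop
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(pad * 1)))
      seed_lab <- distance_seeds(dm, split$min_peak_distance)
      seeds_n <- max(seed_lab)
      if (area > split$max_single_area && seeds_n >= 2) {
        ws <- EBImage::imageData(EBImage::propagate(
          EBImage::Image(-dm), EBImage::Image(seed_lab),
          mask = EBImage::Image(pad * 1)))
        parts <- lapply(seq_len(max(ws)), function(s) {
          part <- matrix(FALSE, nrow(mask), ncol(mask))
          sub <- ws[2:(nrow(crop) + 1), 2:(ncol(crop) + 1)] == s
          part[rows[1]:rows[2], cols[1]:cols[2]] <- sub
          part
        })
        parts <- Filter(function(p) any(p), parts)
        # per-part seed counts are 1 by construction
        seeds_n <- 1L
      }
    }
    for (p in parts)
      objects[[length(objects) + 1]] <- list(mask = p, seeds = seeds_n)
  }

  discarded <- 0L
  discarded_px <- 0L
  rows_out <- list()
  id <- 0L
  for (ob in objects) {
    area <- sum(ob$mask)
    if (!is.null(split) && area < split$min_area) {
      discarded <- discarded + 1L
      discarded_px <- discarded_px + area
      next
    }
    rr <- range(which(rowSums(ob$mask) > 0))
    cc <- range(which(colSums(ob$mask) > 0))
    kind <- if (area > cluster_area_threshold || ob$seeds >= 2) "cluster"
    else "nucleus"
    id <- id + 1L
    rows_out[[id]] <- tibble::tibble(
      detection_id = id,
      x0 = cc[1] - 1L, y0 = rr[1] - 1L, x1 = cc[2], y1 = rr[2],
      kind = kind,
      score = mean(prob[ob$mask]),
      area = as.integer(area),
      n_seeds = as.integer(ob$seeds),
      mask = list(ob$mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]))
  }
  out <- if (length(rows_out)) dplyr::bind_rows(rows_out) else empty
  attr(out, "discarded") <- discarded
  attr(out, "discarded_pixels") <- as.integer(discarded_px)
  out
}
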