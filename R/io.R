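# Readers and writers for on-disk artifacts: patches (PNG + 16-bit TIFF
# masks + CSV class tables), slide manifests (JSON), detections (GeoJSON /
# CSV), appearance profiles (JSON) and model weights (JSON archive).
# Coordinates on disk are 0-based with half-open boxes, matching the
# in-memory convention; GeoJSON polygons wind counter-clockwise.

#' Write a synthetic patch to disk
#'
#' The image goes to `<stem>.png`, the instance mask to `<stem>_mask.tif`
#' (16-bit), and the class table to `<stem>_classes.csv`.
#'
#' @param patch a `synth_patch`.
#' @param stem path prefix (no extension).
#' @return invisibly, the three file paths.
#' @export
write_patch <- function(patch, stem) {
  stopifnot(inherits(patch, "synth_patch"))
  paths <- c(image = paste0(stem, ".png"),
             mask = paste0(stem, "_mask.tif"),
             classes = paste0(stem, "_classes.csv"))
  png::writePNG(patch$image, paths[["image"]])
  tiff::writeTIFF(patch$mask / 65535, paths[["mask"]], bits.per.sample = 16L,
                  compression = "none")
  utils::write.csv(patch$class_table, paths[["classes"]], row.names = FALSE)
  invisible(paths)
}

#' Read a synthetic patch written by [write_patch()]
#' @param stem path prefix used at write time.
#' @return a `synth_patch`.
#' @export
read_patch <- function(stem) {
  img <- png::readPNG(paste0(stem, ".png"))
  mask <- round(tiff::readTIFF(paste0(stem, "_mask.tif")) * 65535)
  tab <- tibble::as_tibble(utils::read.csv(paste0(stem, "_classes.csv"),
                                           stringsAsFactors = FALSE))
  structure(list(image = img, mask = matrix(as.integer(mask), nrow(mask)),
                 class_table = tab),
            class = "synth_patch")
}

#' Write a slide manifest plus tiles
#'
#' Tiles are written under `dir` as `tile_###.(png|_mask.tif|_classes.csv)`;
#' the manifest JSON lists tile paths and the slide truth fields.
#'
#' @param slide a `synth_slide`.
#' @param dir output directory (created if needed).
#' @param slide_id identifier recorded in the manifest.
#' @param magnification,stain closed-vocabulary tags.
#' @return the manifest path, invisibly.
#' @export
write_slide <- function(slide, dir, slide_id = "slide",
                        magnification = c("20x", "40x"),
                        stain = c("pap", "he")) {
  stopifnot(inherits(slide, "synth_slide"))
  magnification <- match.arg(magnification)
  stain <- match.arg(stain)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tile_paths <- character(length(slide$tiles))
  for (i in seq_along(slide$tiles)) {
    stem <- file.path(dir, sprintf("tile_%03d", i))
    write_patch(slide$tiles[[i]], stem)
    tile_paths[i] <- paste0(stem, ".png")
  }
  manifest <- list(slide_id = slide_id, tiles = basename(tile_paths),
                   magnification = magnification, stain = stain,
                   true_tbs = slide$true_tbs, braf = slide$braf,
                   true_counts = as.list(slide$true_counts))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a slide manifest
#' @param path manifest JSON path.
#' @return list with `slide_id`, tags, truth fields and `tiles` (list of
#'   `synth_patch`; tile paths are resolved relative to the manifest).
#' @export
read_slide <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  missing <- !file.exists(file.path(dir, man$tiles))
  if (any(missing))
    stop("manifest tile(s) not found: ",
         paste(man$tiles[missing], collapse = ", "), call. = FALSE)
  stems <- sub("\\.png$", "", file.path(dir, man$tiles))
  man$tiles <- lapply(stems, read_patch)
  man
}

# Counter-clockwise polygon (image y axis points down, so clockwise in
# row/col terms is counter-clockwise in conventional orientation).
polygon_ccw <- function(pts) {
  n <- nrow(pts)
  a <- sum(pts[, 1] * pts[c(2:n, 1), 2] - pts[c(2:n, 1), 1] * pts[, 2]) / 2
  if (a < 0) pts[n:1, , drop = FALSE] else pts
}

detection_polygon <- function(det) {
  m <- det$mask[[1]]
  oc <- EBImage::ocontour(EBImage::Image(t(m * 1)))
  pts <- oc[[which.max(vapply(oc, nrow, numeric(1)))]]
  # ocontour returns (x, y) in 0-based crop coordinates
  pts <- cbind(pts[, 1] + det$x0, pts[, 2] + det$y0)
  polygon_ccw(rbind(pts, pts[1, , drop = FALSE]))
}

#' Write detections to GeoJSON or CSV
#'
#' GeoJSON: a FeatureCollection of polygons (mask contours, CCW winding)
#' with `kind` and `score` properties plus the bounding box. CSV: columns
#' `x0, y0, x1, y1, kind, score` (no instance masks). Scores are written
#' with 6 decimals.
#'
#' @param detections tibble from [detections_from_mask()].
#' @param path output path ending in `.geojson`/`.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- detections[, c("x0", "y0", "x1", "y1", "kind", "score")]
    df$score <- round(df$score, 6)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext %in% c("geojson", "json")) {
    features <- lapply(seq_len(nrow(detections)), function(i) {
      det <- detections[i, ]
      poly <- detection_polygon(det)
      list(type = "Feature",
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(poly)),
                                                     function(k) poly[k, ]))),
           properties = list(detection_id = det$detection_id,
                             kind = det$kind,
                             score = round(det$score, 6),
                             bbox = c(det$x0, det$y0, det$x1, det$y1)))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = 8)
  } else stop("unsupported detection format: .", ext, call. = FALSE)
  invisible(path)
}

#' Read detections written by [write_detections()]
#'
#' Boxes and kinds round-trip exactly and scores to 6 decimals; GeoJSON
#' polygons are rasterised back into instance masks.
#'
#' @param path `.geojson`/`.json` or `.csv` path.
#' @return detections tibble (CSV input lacks the `mask` column).
#' @export
read_detections <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    bad <- which(df$x1 <= df$x0 | df$y1 <= df$y0 | df$x0 < 0 | df$y0 < 0)
    if (length(bad))
      stop("invalid bounding box in CSV row ", bad[1], call. = FALSE)
    return(tibble::as_tibble(cbind(detection_id = seq_len(nrow(df)), df)))
  }
  if (!ext %in% c("geojson", "json"))
    stop("unsupported detection format: .", ext, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (is.null(f$geometry) || is.null(f$properties))
      stop("malformed feature at index ", i, call. = FALSE)
    pr <- f$properties
    bb <- as.integer(unlist(pr$bbox))
    ring <- f$geometry$coordinates[[1]]
    pts <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    m <- matrix(FALSE, bb[4] - bb[2], bb[3] - bb[1])
    inside <- grDevices::xy.coords(pts[, 1], pts[, 2])
    # rasterise the polygon over the bbox grid (pixel centres)
    xs <- seq(bb[1], bb[3] - 1)
    ys <- seq(bb[2], bb[4] - 1)
    grid <- expand.grid(y = ys, x = xs)
    pip <- point_in_polygon(grid$x, grid$y, pts)
    m[cbind(grid$y - bb[2] + 1, grid$x - bb[1] + 1)] <- pip
    tibble::tibble(detection_id = as.integer(pr$detection_id %||% i),
                   x0 = bb[1], y0 = bb[2], x1 = bb[3], y1 = bb[4],
                   kind = as.character(pr$kind),
                   score = as.numeric(pr$score),
                   mask = list(m))
  })
  dplyr::bind_rows(rows)
}

# Even-odd rule point-in-polygon (vectorised over points; the loop runs
# over polygon edges). Points exactly on edges follow the even-odd
# crossing convention.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly) - 1  # closed ring
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-12) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write / read an appearance profile as JSON
#' @param profile an `appearance_profile`.
#' @param path JSON path.
#' @return `path` (write) or the profile (read).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "appearance_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p, class = "appearance_profile")
}

#' Save / load network weights with their configuration
#'
#' A JSON archive holding the configuration header and all trainable
#' parameters, so models survive plain-text storage.
#'
#' @param net a `seg_net` or `cell_net`.
#' @param path JSON path.
#' @return `path` (save) or the rebuilt model (load).
#' @export
save_net <- function(net, path) {
  kind <- class(net)[1]
  stopifnot(kind %in% c("seg_net", "cell_net"))
  payload <- list(kind = kind, config = unclass(net$config),
                  weights = lapply(nn_weights(net$layers), function(w)
                    list(W = list(dim = dim(w$W) %||% length(w$W),
                                  data = as.numeric(w$W)),
                         b = as.numeric(w$b))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- if (p$kind == "seg_net") {
    cfg <- do.call(seg_net_config, p$config[c("depth", "base_width",
                                              "pyramid_fusion", "input_size")])
    build_seg_net(cfg)
  } else {
    cfg <- cell_net_config(input_size = p$config$input_size,
                           in_channels = p$config$in_channels %||% 3L,
                           stage_widths = p$config$stage_widths,
                           k_dw = p$config$k_dw, k_dwd = p$config$k_dwd,
                           dilation = p$config$dilation)
    build_cell_net(cfg)
  }
  weights <- lapply(seq_len(nrow(p$weights$b %||% data.frame())), identity)
  # jsonlite simplification varies; rebuild explicitly
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  weights <- lapply(raw$weights, function(w) {
    dm <- as.integer(unlist(w$W$dim))
    W <- array(as.numeric(unlist(w$W$data)), dim = dm)
    if (length(dm) == 2) W <- matrix(W, dm[1], dm[2])
    list(W = W, b = as.numeric(unlist(w$b)))
  })
  nn_set_weights(net$layers, weights)
  net$n_params <- n_params(net$layers)
  net
}
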