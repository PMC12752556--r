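# Nineteen-feature nuclear morphometry and the morphology-based
# gradient-boosted cell classifier.
#
# The feature list (11 geometry + 8 intensity/texture) is this package's
# documented convention, chosen to capture the cues cytopathologists use:
# nuclear size, membrane shape (circularity, solidity, boundary
# irregularity via eccentricity/aspect), and chromatin texture (intensity
# statistics and gradient energy).

#' Names of the 19 nuclear morphometry features, in fixed order
#' @return character vector of length 19.
#' @export
morpho_feature_names <- function() {
  c("area", "perimeter", "equivalent_diameter", "major_axis", "minor_axis",
    "aspect_ratio", "eccentricity", "circularity", "solidity", "extent",
    "orientation", "gray_mean", "gray_std", "gray_min", "gray_max",
    "hue_mean", "saturation_mean", "value_mean", "gradient_energy")
}

# Perimeter of the object's boundary polygon (pixel-centre contour).
contour_perimeter <- function(mask) {
  oc <- tryCatch(EBImage::ocontour(EBImage::Image(t(mask * 1))),
                 error = function(e) NULL)
  if (is.null(oc) || length(oc) == 0) return(1)
  per <- sum(vapply(oc, function(pts) {
    if (nrow(pts) < 2) return(1)
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
    sum(d)
  }, numeric(1)))
  max(per, 1)
}

# Rasterised convex hull area: the number of pixel centres inside (or on)
# the hull polygon of the mask's pixel centres. For convex rasterised
# shapes this equals the pixel count, so solidity is exactly 1 there and
# in (0, 1] in general.
hull_area <- function(rows, cols) {
  n <- length(rows)
  if (n < 3) return(n)
  pts <- cbind(cols, rows)
  h <- grDevices::chull(pts)
  poly <- pts[c(h, h[1]), , drop = FALSE]
  grid <- expand.grid(x = min(cols):max(cols), y = min(rows):max(rows))
  inside <- point_in_polygon(grid$x, grid$y, poly)
  max(sum(inside), n)
}

#' Nuclear morphometry of one detection
#'
#' Computes the 19 features (see [morpho_feature_names()]) on the
#' detection's instance mask and the masked image region. Geometry comes
#' from pixel counts and second-order central moments (axis lengths as for
#' the equivalent-inertia ellipse); `circularity = 4*pi*A/P^2` uses the
#' boundary-polygon perimeter and is clipped at 1.05 to absorb
#' rasterisation bias on very small objects; `orientation` is the major
#' axis angle in `(-pi/2, pi/2]` measured from the x axis, y pointing down.
#' Intensity features use Rec.-601 luminance in `[0, 1]`; `gradient_energy`
#' is the mean squared central-difference gradient of luminance inside the
#' mask.
#'
#' @param image RGB array the detection was made on.
#' @param detection one detection row (see [detections_from_mask()]), or a
#'   list with `x0, y0, x1, y1` and `mask`.
#' @return named numeric vector of length 19.
#' @export
nuclear_morphometry <- function(image, detection) {
  assert_image(image)
  m <- if (is.list(detection$mask) && !is.matrix(detection$mask))
    detection$mask[[1]] else detection$mask
  if (!any(m)) stop("detection mask is empty", call. = FALSE)
  x0 <- detection$x0[[1]]; y0 <- detection$y0[[1]]
  rows_local <- which(m, arr.ind = TRUE)
  # absolute 0-based coordinates of mask pixels
  ys <- rows_local[, 1] - 1 + y0
  xs <- rows_local[, 2] - 1 + x0

  area <- nrow(rows_local)
  per <- contour_perimeter(m)
  eqd <- 2 * sqrt(area / pi)

  xc <- mean(xs); yc <- mean(ys)
  mu20 <- mean((xs - xc)^2) + 1 / 12  # pixel-square correction
  mu02 <- mean((ys - yc)^2) + 1 / 12
  mu11 <- mean((xs - xc) * (ys - yc))
  tr <- mu20 + mu02
  det_ <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + det_) / 2
  l2 <- max((tr - det_) / 2, 1e-9)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  aspect <- if (area <= 1) 1 else major / minor
  ecc <- if (area <= 1) 0 else sqrt(max(0, 1 - l2 / l1))
  circ <- min(4 * pi * area / per^2, 1.05)
  sol <- min(area / hull_area(ys, xs), 1)
  extent <- area / (dim(m)[1] * dim(m)[2])
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi

  # image statistics over the masked region
  h <- dim(image)[1]
  px_idx <- (ys + 1) + h * xs  # column-major linear index into a channel
  r <- image[, , 1][px_idx]; g <- image[, , 2][px_idx]; b <- image[, , 3][px_idx]
  gray <- 0.299 * r + 0.587 * g + 0.114 * b
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)

  # gradient energy: central differences of luminance on the crop
  crop <- image[(y0 + 1):detection$y1[[1]], (x0 + 1):detection$x1[[1]], ,
                drop = FALSE]
  lum <- matrix(luminance(crop), dim(crop)[1], dim(crop)[2])
  gx <- lum * 0; gy <- lum * 0
  if (ncol(lum) > 2)
    gx[, 2:(ncol(lum) - 1)] <- (lum[, 3:ncol(lum), drop = FALSE] -
                                  lum[, 1:(ncol(lum) - 2), drop = FALSE]) / 2
  if (nrow(lum) > 2)
    gy[2:(nrow(lum) - 1), ] <- (lum[3:nrow(lum), , drop = FALSE] -
                                  lum[1:(nrow(lum) - 2), , drop = FALSE]) / 2
  ge <- mean((gx^2 + gy^2)[m])

  stats::setNames(
    c(area, per, eqd, major, minor, aspect, ecc, circ, sol, extent, theta,
      mean(gray), stats::sd(gray) %||% 0, min(gray), max(gray),
      mean(hsv[1, ]), mean(hsv[2, ]), mean(hsv[3, ]), ge),
    morpho_feature_names()
  ) |> (\(v) { v[is.na(v)] <- 0; v })()
}

#' Morphometry for every detection on a tile
#'
#' @param image RGB array.
#' @param detections tibble from [detections_from_mask()].
#' @return tibble with `detection_id` and the 19 feature columns.
#' @export
morphometry_table <- function(image, detections) {
  if (nrow(detections) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, 19))
    names(out) <- morpho_feature_names()
    return(tibble::as_tibble(cbind(detection_id = integer(), out)))
  }
  feats <- t(vapply(seq_len(nrow(detections)), function(i)
    nuclear_morphometry(image, detections[i, ]), numeric(19)))
  tibble::as_tibble(cbind(detection_id = detections$detection_id,
                          as.data.frame(feats)))
}

# Class-probability matrix (n x K) from a multi:softprob booster,
# tolerant of the vector/matrix return-shape differences across xgboost
# versions.
predict_prob_matrix <- function(booster, X, k) {
  pr <- stats::predict(booster, xgboost::xgb.DMatrix(X, nthread = 1))
  if (is.matrix(pr)) pr else matrix(pr, ncol = k, byrow = TRUE)
}

#' Train the morphology gradient-boosted cell classifier
#'
#' An XGBoost multiclass model over the 19 morphometry features. Labels are
#' typically the 9-role reduction (so the dual-model agreement gate compares
#' at role level), but any factor with at least two levels present works.
#'
#' @param features data frame / tibble whose columns include the 19
#'   morphometry features (extra columns ignored).
#' @param labels vector of class labels, length `nrow(features)`.
#' @param nrounds boosting rounds.
#' @param max_depth,eta tree depth and learning rate.
#' @param seed RNG seed (deterministic with single-thread training).
#' @return object of class `morpho_gbt` with the booster, level order, and
#'   training accuracy.
#' @export
train_morpho_gbt <- function(features, labels, nrounds = 60L, max_depth = 4L,
                             eta = 0.3, seed = 0L) {
  X <- as.matrix(features[, morpho_feature_names(), drop = FALSE])
  lev <- sort(unique(as.character(labels)))
  if (length(lev) < 2)
    stop("training requires at least two classes present", call. = FALSE)
  y <- match(as.character(labels), lev) - 1L
  # lambda = 0 / min_child_weight = 0 make the fit a pure function of the
  # empirical distribution, so duplicating every row leaves it unchanged
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(lev),
                  max_depth = max_depth, eta = eta, lambda = 0,
                  min_child_weight = 0, nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0))
  pr <- predict_prob_matrix(booster, X, length(lev))
  acc <- mean(max.col(pr, ties.method = "first") - 1L == y)
  structure(list(booster = booster, classes = lev,
                 feature_names = morpho_feature_names(),
                 train_accuracy = acc),
            class = "morpho_gbt")
}

#' Classify morphometry vectors with the gradient-boosted model
#'
#' @param features a named 19-vector, or a data frame with the 19 feature
#'   columns (one row per object). A feature-length mismatch is an error.
#' @param model a [train_morpho_gbt()] fit.
#' @return tibble with `morpho_class` and `morpho_prob` (argmax
#'   probability; ties broken towards the lowest class index).
#' @export
classify_morpho <- function(features, model) {
  stopifnot(inherits(model, "morpho_gbt"))
  if (is.numeric(features) && is.null(dim(features))) {
    if (length(features) != 19)
      stop("expected a feature vector of length 19, got ",
           length(features), call. = FALSE)
    X <- matrix(features, nrow = 1,
                dimnames = list(NULL, model$feature_names))
  } else {
    if (!all(model$feature_names %in% colnames(features)))
      stop("feature columns do not match the 19-feature morphometry contract",
           call. = FALSE)
    X <- as.matrix(features[, model$feature_names, drop = FALSE])
  }
  pr <- predict_prob_matrix(model$booster, X, length(model$classes))
  k <- max.col(pr, ties.method = "first")
  tibble::tibble(morpho_class = model$classes[k],
                 morpho_prob = pr[cbind(seq_len(nrow(pr)), k)])
}

#' @export
print.morpho_gbt <- function(x, ...) {
  cat("<morpho_gbt> ", length(x$classes), " classes, training accuracy ",
      round(x$train_accuracy, 4), "\n", sep = "")
  invisible(x)
}
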