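# Synthetic thyroid-FNA cytology generator.
#
# Patches emulate liquid-based Pap / H&E smears at a schematic level:
# textured elliptical nuclei in 17 classes (papillary-carcinoma phenotypes
# including nuclear grooves and pseudo-inclusions, benign follicular cells,
# and a tail of "other" cell types), overlapping clusters sharing one
# instance label, plus unlabelled red-blood-cell and colloid debris. Every
# patch carries its ground-truth instance mask and class table so each
# downstream stage can be trained and scored offline.

#' The 17-class cell schema
#'
#' Returns the ordered class identifiers `C1..C17`, their display names and
#' the 9-role reduction used by slide-level feature aggregation: C1-C3 map
#' to the papillary-carcinoma roles PTCA/PTCB/PTCC, C4 to NUCLEAR (nuclear
#' groove), C5 to INCIS (intranuclear pseudo-inclusion), C6-C8 to the benign
#' follicular roles TFECA/TFECB/TFECC, and C9-C17 to OTHER. The mapping is
#' data, not code, so an alternative ordering can be supplied wherever a
#' `schema` argument is accepted.
#'
#' @return A tibble with columns `class`, `name`, `role`.
#' @export
class_schema <- function() {
  tibble::tibble(
    class = paste0("C", 1:17),
    name = c("PTC large group", "PTC small group", "PTC single cell",
             "nuclear groove", "pseudo-inclusion",
             "TFEC large group", "TFEC small group", "TFEC single cell",
             "macrophage", "lymphocyte", "neutrophil", "colloid clump",
             "histiocyte", "oncocytic cell", "squamous cell",
             "degenerate nucleus", "artifact"),
    role = c("PTCA", "PTCB", "PTCC", "NUCLEAR", "INCIS",
             "TFECA", "TFECB", "TFECC", rep("OTHER", 9))
  )
}

#' Map class ids to aggregation roles
#' @param class character vector of class ids (`"C1"`..`"C17"`).
#' @param schema a schema tibble from [class_schema()].
#' @return character vector of roles.
#' @export
role_of_class <- function(class, schema = class_schema()) {
  schema$role[match(class, schema$class)]
}

#' The 9 aggregation roles, in registry order
#' @return character vector.
#' @export
roles <- function() {
  c("PTCA", "PTCB", "PTCC", "TFECA", "TFECB", "TFECC",
    "NUCLEAR", "INCIS", "OTHER")
}

default_class_mix <- function() {
  mix <- c(C1 = 0.03, C2 = 0.03, C3 = 0.04, C4 = 0.02, C5 = 0.02,
           C6 = 0.12, C7 = 0.15, C8 = 0.18, C9 = 0.05, C10 = 0.08,
           C11 = 0.05, C12 = 0.05, C13 = 0.04, C14 = 0.04, C15 = 0.04,
           C16 = 0.03, C17 = 0.03)
  mix / sum(mix)
}

#' Synthetic-cytology generator configuration
#'
#' @param patch_size tile side in pixels (square tiles), at least 64.
#' @param nuclei_range integer range `c(lo, hi)` for the number of labelled
#'   objects per patch.
#' @param class_mix named probability vector over `C1..C17`; must sum to 1.
#' @param cluster_rate background rate of overlapping-group rendering, in
#'   `[0, 1]`. Group structure follows the class semantics: the
#'   large-group classes C1/C6 and small-group classes C2/C7 form groups
#'   with probability `min(1, 4 * cluster_rate)` (so they are always
#'   grouped at the 0.25 default), the single-cell classes C3/C8 never
#'   group, and all other classes group at `cluster_rate` itself. A group
#'   shares one instance label across its member nuclei.
#' @param debris_rate density of unlabelled red-blood-cell and colloid
#'   debris, in `[0, 1]` (0 = clean background).
#' @param stain_style `"pap"` (Papanicolaou) or `"he"` (H&E) colour palette.
#' @param tbs_v_band atypical-fraction band `(lo, hi]` labelled TBS V by the
#'   fixture rule; above `hi` is TBS VI (see [render_slide()]).
#' @param braf_link `c(intercept, slope)` of the logistic link from the
#'   slide atypical fraction to the BRAF-V600E probability.
#' @param seed default seed used when an operation is called without one.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(patch_size = 256L,
                         nuclei_range = c(6L, 14L),
                         class_mix = default_class_mix(),
                         cluster_rate = 0.25,
                         debris_rate = 0.5,
                         stain_style = c("pap", "he"),
                         tbs_v_band = c(0.1, 0.5),
                         braf_link = c(intercept = -4, slope = 8),
                         seed = 0L) {
  stain_style <- match.arg(stain_style)
  if (patch_size < 64) stop("patch_size must be at least 64", call. = FALSE)
  if (length(nuclei_range) == 1) nuclei_range <- rep(nuclei_range, 2)
  if (!setequal(names(class_mix), paste0("C", 1:17)))
    stop("class_mix must be named over C1..C17", call. = FALSE)
  class_mix <- class_mix[paste0("C", 1:17)]
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1 (got ", format(sum(class_mix)), ")",
         call. = FALSE)
  if (any(class_mix < 0)) stop("class_mix entries must be non-negative",
                               call. = FALSE)
  for (r in c(cluster_rate, debris_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(patch_size = as.integer(patch_size),
                 nuclei_range = as.integer(nuclei_range),
                 class_mix = class_mix,
                 cluster_rate = cluster_rate,
                 debris_rate = debris_rate,
                 stain_style = stain_style,
                 tbs_v_band = tbs_v_band,
                 braf_link = braf_link,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Per-class rendering style: nucleus radius (px at 256-px tiles), colour
# family, boundary irregularity, texture amplitude, and the PTC hallmark
# decorations. C9-C17 are schematic stand-ins for the long tail of "other"
# cell types.
class_styles <- function(stain_style) {
  pal <- if (stain_style == "pap") {
    list(dark = c(0.23, 0.20, 0.46), pale = c(0.48, 0.42, 0.62),
         other = c(0.40, 0.36, 0.42), bg = c(0.84, 0.87, 0.90),
         cyto = c(0.70, 0.78, 0.82))
  } else {
    list(dark = c(0.32, 0.16, 0.38), pale = c(0.55, 0.38, 0.55),
         other = c(0.50, 0.36, 0.42), bg = c(0.93, 0.86, 0.88),
         cyto = c(0.86, 0.72, 0.78))
  }
  st <- tibble::tibble(
    class = paste0("C", 1:17),
    radius = c(11, 10, 9.5, 9, 9, 6.5, 6, 5.5, 9, 3, 4.5, 12,
               8, 8, 7, 5, 5),
    colour = c(rep(list(pal$pale), 5),
               rep(list(pal$dark), 3),
               list(pal$other, pal$dark * 0.45, pal$other,
                    c(0.62, 0.72, 0.66), pal$other,
                    c(0.58, 0.34, 0.36), c(0.55, 0.50, 0.40),
                    pal$dark * 0.85, c(0.45, 0.45, 0.45))),
    irregularity = c(0.25, 0.22, 0.2, 0.12, 0.1, 0.05, 0.05, 0.05,
                     0.15, 0.03, 0.45, 0.35, 0.15, 0.1, 0.3, 0.4, 0.5),
    texture = c(0.16, 0.16, 0.15, 0.12, 0.1, 0.07, 0.07, 0.07,
                0.12, 0.04, 0.1, 0.03, 0.1, 0.1, 0.08, 0.14, 0.2),
    special = c("none", "none", "none", "groove", "inclusion",
                rep("none", 12)),
    members = list(c(8L, 12L), c(4L, 6L), c(2L, 3L), c(2L, 3L), c(2L, 3L),
                   c(8L, 12L), c(4L, 6L), c(2L, 3L), c(2L, 3L), c(3L, 6L),
                   c(2L, 3L), c(2L, 2L), c(2L, 3L), c(2L, 3L), c(2L, 3L),
                   c(2L, 4L), c(2L, 3L))
  )
  list(styles = st, pal = pal)
}

# Rasterize an irregular ellipse; returns a logical matrix over the full
# patch. Coordinates are 0-based (x = column, y = row).
ellipse_pixels <- function(size, cx, cy, a, b, theta, irr, phases) {
  r <- ceiling(max(a, b) * (1 + irr) + 1)
  x0 <- max(0, floor(cx - r)); x1 <- min(size - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(size - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), nrow = length(ys)) - cx
  gy <- matrix(rep(ys, times = length(xs)), nrow = length(ys)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v / b, u / a)
  edge <- 1 + irr * (sin(3 * phi + phases[1]) + 0.5 * sin(5 * phi + phases[2])) / 1.5
  inside <- rho <= edge
  list(rows = ys + 1L, cols = xs + 1L, inside = inside, u = u, v = v,
       rho = rho, a = a, b = b)
}

# Smooth per-pixel chromatin texture over a local window.
texture_field <- function(nr, nc, amp) {
  n <- matrix(stats::runif(nr * nc, -1, 1), nr, nc)
  k <- matrix(1 / 9, 3, 3)
  pad <- rbind(n[1, , drop = FALSE], n, n[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sm <- matrix(0, nr, nc)
  for (dx in -1:1) for (dy in -1:1)
    sm <- sm + pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)] / 9
  amp * sm
}

paint_blob <- function(canvas, px, colour, alpha = 1, texture = 0) {
  sel <- px$inside
  if (!any(sel)) return(canvas)
  tex <- if (texture > 0) texture_field(nrow(sel), ncol(sel), texture) else 0
  for (ch in 1:3) {
    sub <- canvas[px$rows, px$cols, ch]
    val <- colour[ch] * (1 + (if (is.matrix(tex)) tex[sel] else 0))
    sub[sel] <- (1 - alpha) * sub[sel] + alpha * clip01(val)
    canvas[px$rows, px$cols, ch] <- sub
  }
  canvas
}

#' Render one synthetic cytology patch
#'
#' Draws labelled nuclei (with class-specific size, colour, texture and the
#' groove / pseudo-inclusion hallmarks), optional overlapping clusters that
#' share a single instance label, and unlabelled red-blood-cell and colloid
#' debris. Output is byte-identical for identical `(config, seed)`.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return An object of class `synth_patch`: a list with `image` (array
#'   `[H, W, 3]` in `[0, 1]`, on the 8-bit grid), `mask` (integer label
#'   matrix, 0 = background, instance ids consecutive from 1), and
#'   `class_table` (tibble: `instance_id`, `class`, `cx`, `cy`,
#'   `is_cluster`, `n_members`; coordinates 0-based, x = column).
#' @export
render_patch <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, render_patch_impl(config))
}

render_patch_impl <- function(config) {
  size <- config$patch_size
  # render_scale lets small crop canvases keep the object scale of their
  # parent tile size (see render_crop)
  scale <- (config$render_scale %||% size) / 256
  sty <- class_styles(config$stain_style)
  styles <- sty$styles; pal <- sty$pal

  # background with gentle low-frequency shading
  canvas <- array(0, dim = c(size, size, 3))
  xs <- seq(0, 1, length.out = size)
  shade <- 0.02 * outer(sin(2 * pi * (xs + stats::runif(1))),
                        cos(2 * pi * (xs + stats::runif(1))))
  for (ch in 1:3) canvas[, , ch] <- clip01(pal$bg[ch] + shade)

  n_obj <- if (config$nuclei_range[1] >= config$nuclei_range[2])
    config$nuclei_range[1]
  else sample(config$nuclei_range[1]:config$nuclei_range[2], 1)

  # colloid debris first (underneath everything, unlabelled)
  n_colloid <- stats::rpois(1, 1.5 * config$debris_rate)
  for (i in seq_len(n_colloid)) {
    px <- ellipse_pixels(size, stats::runif(1, 0, size - 1),
                         stats::runif(1, 0, size - 1),
                         stats::runif(1, 15, 30) * scale,
                         stats::runif(1, 10, 20) * scale,
                         stats::runif(1, 0, pi), 0.4, stats::runif(2, 0, 2 * pi))
    if (!is.null(px))
      canvas <- paint_blob(canvas, px, pal$bg * 0.92 + c(0, 0.02, -0.02),
                           alpha = 0.6, texture = 0.02)
  }

  mask <- matrix(0L, size, size)
  rows <- list()
  centres <- matrix(numeric(0), ncol = 3)  # cx, cy, radius

  draw_nucleus <- function(canvas, mask, id, cls, cx, cy, rad, style) {
    theta <- stats::runif(1, -pi / 2, pi / 2)
    aspect <- stats::runif(1, 1.05, if (cls %in% paste0("C", 1:3)) 1.8 else 1.4)
    a <- rad * sqrt(aspect); b <- rad / sqrt(aspect)
    px <- ellipse_pixels(size, cx, cy, a, b, theta, style$irregularity,
                         stats::runif(2, 0, 2 * pi))
    if (is.null(px)) return(list(canvas = canvas, mask = mask))
    # faint cytoplasm halo for epithelial classes
    if (cls %in% paste0("C", 1:8)) {
      halo <- ellipse_pixels(size, cx, cy, a * 1.7, b * 1.7, theta, 0.1,
                             stats::runif(2, 0, 2 * pi))
      canvas <- paint_blob(canvas, halo, pal$cyto, alpha = 0.35)
    }
    canvas <- paint_blob(canvas, px, unlist(style$colour), alpha = 1,
                         texture = style$texture)
    if (style$special == "groove") {
      groove <- px$inside & abs(px$v) < max(1, 0.1 * b)
      sel <- groove
      for (ch in 1:3) {
        sub <- canvas[px$rows, px$cols, ch]
        sub[sel] <- sub[sel] * 0.45
        canvas[px$rows, px$cols, ch] <- sub
      }
    } else if (style$special == "inclusion") {
      inc <- px$inside & (px$u^2 + px$v^2) < (0.45 * min(a, b))^2
      for (ch in 1:3) {
        sub <- canvas[px$rows, px$cols, ch]
        sub[inc] <- 0.3 * sub[inc] + 0.7 * pal$cyto[ch] * 1.1
        canvas[px$rows, px$cols, ch] <- sub
      }
    }
    sub <- mask[px$rows, px$cols]
    claim <- px$inside & sub == 0L
    sub[claim] <- id
    mask[px$rows, px$cols] <- sub
    list(canvas = canvas, mask = mask)
  }

  for (id in seq_len(n_obj)) {
    cls <- sample(styles$class, 1, prob = config$class_mix)
    style <- styles[styles$class == cls, ]
    rad <- style$radius * scale * stats::runif(1, 0.85, 1.2)
    # group structure follows class semantics: A classes form large groups,
    # B classes small groups, C classes stay single; other classes group
    # at the configured background rate
    p_grp <- if (cls %in% c("C1", "C2", "C6", "C7"))
      min(1, 4 * config$cluster_rate)
    else if (cls %in% c("C3", "C8")) 0
    else config$cluster_rate
    is_cluster <- stats::runif(1) < p_grp
    mrange <- style$members[[1]]
    n_members <- if (is_cluster) sample(mrange[1]:mrange[2], 1) else 1L
    spread <- rad * (1 + 0.6 * sqrt(n_members))
    # rejection placement to limit inter-instance occlusion
    margin <- min(spread + 2, (size - 1) / 2 - 1)
    for (try in 1:40) {
      cx <- stats::runif(1, margin, size - 1 - margin)
      cy <- stats::runif(1, margin, size - 1 - margin)
      if (nrow(centres) == 0) break
      d <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
      if (all(d > 0.8 * (centres[, 3] + spread))) break
    }
    centres <- rbind(centres, c(cx, cy, spread))
    offs <- if (n_members == 1L) matrix(c(0, 0), ncol = 2) else {
      ang <- stats::runif(n_members, 0, 2 * pi)
      dd <- stats::runif(n_members, 0.4, 1) * spread * 0.7
      cbind(dd * cos(ang), dd * sin(ang))
    }
    for (m in seq_len(n_members)) {
      res <- draw_nucleus(canvas, mask, id, cls,
                          cx + offs[m, 1], cy + offs[m, 2],
                          rad * stats::runif(1, 0.85, 1.1), style)
      canvas <- res$canvas; mask <- res$mask
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      instance_id = id, class = cls, cx = cx, cy = cy,
      is_cluster = is_cluster && n_members >= 2L, n_members = n_members)
  }

  # red blood cells on top of the background only (never over nuclei)
  n_rbc <- stats::rpois(1, 12 * config$debris_rate)
  rbc_col <- c(0.82, 0.16, 0.18)
  for (i in seq_len(n_rbc)) {
    px <- ellipse_pixels(size, stats::runif(1, 0, size - 1),
                         stats::runif(1, 0, size - 1),
                         stats::runif(1, 3, 4.5) * scale,
                         stats::runif(1, 2.5, 4) * scale,
                         stats::runif(1, 0, pi), 0.05, stats::runif(2, 0, 2 * pi))
    if (is.null(px)) next
    free <- mask[px$rows, px$cols] == 0L
    px$inside <- px$inside & free
    canvas <- paint_blob(canvas, px, rbc_col, alpha = 1, texture = 0.06)
  }

  table <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(instance_id = integer(), class = character(),
                   cx = numeric(), cy = numeric(), is_cluster = logical(),
                   n_members = integer())

  # drop instances fully occluded by earlier ones and relabel consecutively
  present <- sort(unique(mask[mask > 0L]))
  if (!identical(as.integer(present), table$instance_id)) {
    table <- table[table$instance_id %in% present, , drop = FALSE]
    relab <- match(mask, c(0L, present)) - 1L
    mask <- matrix(as.integer(relab), nrow(mask), ncol(mask))
    table$instance_id <- seq_len(nrow(table))
  }

  structure(list(image = quantize8(canvas), mask = mask, class_table = table),
            class = "synth_patch")
}

#' Render a single-cell crop for classifier training
#'
#' A small patch containing exactly one object of the requested class,
#' centred; used to build classifier training sets with known labels.
#'
#' @param config a [synth_config()].
#' @param class class id `"C1"`..`"C17"`.
#' @param size crop side in pixels (min 32).
#' @param seed integer seed.
#' @return `synth_patch` of side `size` with a single labelled instance.
#' @export
render_crop <- function(config, class, size = 64L, seed = config$seed) {
  stopifnot(class %in% paste0("C", 1:17))
  mix <- stats::setNames(rep(0, 17), paste0("C", 1:17))
  mix[class] <- 1
  cfg <- config
  cfg$patch_size <- max(64L, as.integer(size))
  cfg$render_scale <- config$render_scale %||% config$patch_size
  cfg$class_mix <- mix
  cfg$nuclei_range <- c(1L, 1L)
  # keep the configured group semantics: a C1/C6 crop shows its group
  cfg$debris_rate <- 0
  p <- render_patch(cfg, seed)
  if (cfg$patch_size > size) {
    lo <- (cfg$patch_size - size) %/% 2 + 1L
    hi <- lo + size - 1L
    p$image <- p$image[lo:hi, lo:hi, , drop = FALSE]
    p$mask <- p$mask[lo:hi, lo:hi]
  }
  p
}

#' Apply an appearance shift to a patch
#'
#' Simulates stain / scanner variation by a per-channel gamma followed by an
#' affine gain and offset: `x' = clip(gain * x^gamma + offset / 255)`. Only
#' the image changes; mask and class table are untouched.
#'
#' @param patch a `synth_patch`.
#' @param gain per-channel multiplicative gain (length 1 or 3), strictly
#'   positive.
#' @param offset per-channel additive offset in 8-bit intensity levels.
#' @param gamma per-channel gamma exponent, strictly positive.
#' @return the patch with a perturbed image (still on the 8-bit grid).
#' @export
perturb_appearance <- function(patch, gain = 1, offset = 0, gamma = 1) {
  stopifnot(inherits(patch, "synth_patch"))
  gain <- rep_len(gain, 3); offset <- rep_len(offset, 3)
  gamma <- rep_len(gamma, 3)
  if (any(gain <= 0)) stop("gain must be strictly positive", call. = FALSE)
  if (any(gamma <= 0)) stop("gamma must be strictly positive", call. = FALSE)
  img <- patch$image
  for (ch in 1:3)
    img[, , ch] <- clip01(gain[ch] * img[, , ch]^gamma[ch] + offset[ch] / 255)
  patch$image <- quantize8(img)
  patch
}

#' Render a synthetic multi-tile slide
#'
#' Tiles are rendered independently under sub-seeds derived from `seed`.
#' The ground-truth Bethesda label follows the documented fixture rule:
#' the slide is TBS I when the adequacy-weighted epithelial group count
#' `10 * (N_PTCA + N_TFECA) + 5 * (N_PTCB + N_TFECB)` falls below 60
#' (see [tbs1_rule()]); otherwise let `f` be the atypical fraction
#' (objects in C1-C5 over all epithelial objects C1-C8): TBS VI when
#' `f > hi`, TBS V when `lo < f <= hi` (band from `config$tbs_v_band`),
#' TBS II otherwise. BRAF-V600E status is drawn from a logistic link on
#' `f` with coefficients `config$braf_link`.
#'
#' @param config a [synth_config()].
#' @param n_tiles number of tiles (>= 1).
#' @param seed integer seed; defaults to `config$seed`.
#' @return An object of class `synth_slide`: list with `tiles` (list of
#'   `synth_patch`), `true_counts` (named integer vector over C1..C17),
#'   `true_tbs` (`"I"`, `"II"`, `"V"`, `"VI"`), `braf` (0/1) and
#'   `atypical_fraction`.
#' @export
render_slide <- function(config, n_tiles = 2L, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (n_tiles < 1) stop("n_tiles must be at least 1", call. = FALSE)
  tiles <- lapply(seq_len(n_tiles), function(k)
    render_patch(config, sub_seed(seed, k)))
  counts <- table(factor(unlist(lapply(tiles, function(t) t$class_table$class)),
                         levels = paste0("C", 1:17)))
  counts <- stats::setNames(as.integer(counts), paste0("C", 1:17))
  lab <- fixture_tbs_label(counts, config$tbs_v_band)
  braf <- with_seed(sub_seed(seed, 999L), {
    stats::rbinom(1, 1, stats::plogis(config$braf_link[[1]] +
                                        config$braf_link[[2]] * lab$f))
  })
  structure(list(tiles = tiles, true_counts = counts, true_tbs = lab$tbs,
                 braf = braf, atypical_fraction = lab$f),
            class = "synth_slide")
}

# The documented fixture labelling rule (shared with tests).
fixture_tbs_label <- function(counts, band = c(0.1, 0.5)) {
  lhs <- 10 * (counts[["C1"]] + counts[["C6"]]) +
    5 * (counts[["C2"]] + counts[["C7"]])
  atyp <- sum(counts[paste0("C", 1:5)])
  epi <- atyp + sum(counts[paste0("C", 6:8)])
  f <- if (epi == 0) 0 else atyp / epi
  tbs <- if (lhs < 60) "I"
  else if (f > band[2]) "VI"
  else if (f > band[1]) "V"
  else "II"
  list(tbs = tbs, f = f, adeq_lhs = lhs)
}

# Class-mix archetypes used by the cohort generator. The atypical share is
# drawn per slide so labels arise from realized counts, not from the
# archetype directly.
archetype_mix <- function(kind, u) {
  # benign background cells: lymphocytes and colloid, the classes every
  # pipeline classifier is trained on
  other <- c(C9 = 0, C10 = 0.6, C11 = 0, C12 = 0.4, C13 = 0, C14 = 0,
             C15 = 0, C16 = 0, C17 = 0)
  mk <- function(atyp_w, benign_w, other_w) {
    atyp <- c(C1 = 0.25, C2 = 0.25, C3 = 0.2, C4 = 0.15, C5 = 0.15)
    benign <- c(C6 = 0.4, C7 = 0.35, C8 = 0.25)
    m <- c(atyp * atyp_w, benign * benign_w, other * other_w)
    m / sum(m)
  }
  switch(kind,
    nondiagnostic = mk(0.02, 0.18, 0.80),
    benign = mk(0.02 + 0.04 * u, 0.78, 0.20 - 0.04 * u),
    suspicious = mk(0.62 * (0.15 + 0.25 * u), 0.62 * (0.85 - 0.25 * u), 0.38),
    malignant = mk(0.70 * (0.60 + 0.30 * u), 0.70 * (0.40 - 0.30 * u), 0.30),
    stop("unknown archetype: ", kind)
  )
}

#' Render a cohort of synthetic slides
#'
#' Draws per-slide conditions from four archetypes (nondiagnostic, benign,
#' suspicious, malignant) so that all four fixture labels occur, then
#' renders each slide with [render_slide()].
#'
#' @param n_slides number of slides.
#' @param config base [synth_config()]; per-slide class mixes override
#'   `class_mix`.
#' @param seed integer seed.
#' @param n_tiles tiles per slide.
#' @param probs archetype probabilities (nondiagnostic, benign, suspicious,
#'   malignant).
#' @return list of `synth_slide` objects.
#' @export
render_cohort <- function(n_slides, config = synth_config(), seed = config$seed,
                          n_tiles = 3L,
                          probs = c(0.15, 0.35, 0.25, 0.25)) {
  kinds <- c("nondiagnostic", "benign", "suspicious", "malignant")
  draws <- with_seed(seed, list(
    kind = sample(kinds, n_slides, replace = TRUE, prob = probs),
    u = stats::runif(n_slides)))
  lapply(seq_len(n_slides), function(i) {
    cfg <- config
    cfg$class_mix <- archetype_mix(draws$kind[i], draws$u[i])
    if (draws$kind[i] == "nondiagnostic") cfg$nuclei_range <- c(0L, 2L)
    else cfg$nuclei_range <- c(12L, 18L)
    render_slide(cfg, n_tiles = n_tiles, seed = sub_seed(seed, i))
  })
}

#' @export
print.synth_patch <- function(x, ...) {
  cat("<synth_patch> ", nrow(x$mask), "x", ncol(x$mask), ", ",
      nrow(x$class_table), " labelled objects\n", sep = "")
  invisible(x)
}

#' @export
print.synth_slide <- function(x, ...) {
  cat("<synth_slide> ", length(x$tiles), " tiles, TBS ", x$true_tbs,
      ", BRAF ", x$braf, ", atypical fraction ",
      round(x$atypical_fraction, 3), "\n", sep = "")
  invisible(x)
}
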