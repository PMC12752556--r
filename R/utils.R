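# Shared helpers: seeded evaluation, colour-space conversions and small
# image-array utilities. Images are arrays [H, W, 3] of doubles in [0, 1],
# row index = y (top-left origin), column index = x; masks are integer
# matrices of the same H x W shape.

#' Evaluate code under a temporary RNG state
#'
#' Sets the R RNG to `seed`, runs `code`, and restores the previous state,
#' so library calls never disturb the caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministic sub-stream seeds
#'
#' Derives a reproducible child seed from `(seed, k)` (Lehmer-style step),
#' always below 2^31 so it is a valid R integer seed.
#' @param seed integer master seed.
#' @param k integer stream index.
#' @return integer seed.
#' @export
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + as.numeric(k) * 9973 + 1) %%
               2147483647)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmax/pmin keep attributes of arg 1

#' @keywords internal
assert_image <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3))
    stop("expected an RGB image array [H, W, 3]", call. = FALSE)
  invisible(image)
}

# Quantize to the 8-bit grid; generated patches live on this grid so that
# PNG round-trips are lossless and determinism is byte-level.
quantize8 <- function(image) round(clip01(image) * 255) / 255

# --- HSV ------------------------------------------------------------------

# Vectorised RGB -> HSV on an image array; returns an [H, W, 3] array with
# hue, saturation, value each in [0, 1].
rgb_to_hsv_image <- function(image) {
  d <- dim(image)
  m <- matrix(image, ncol = 3L)                 # pixels x RGB
  hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
  array(hsv, dim = d)
}

# --- Reinhard lalphabeta perceptual space ---------------------------------
# Fixed matrices for the log-LMS opponent space commonly used for colour
# statistics matching. Inputs/outputs are pixel matrices (n x 3) in [0, 1].

.lab_rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                         0.1967, 0.7244, 0.0782,
                         0.0241, 0.1288, 0.8444),
                       nrow = 3, byrow = TRUE)
.lab_lms2rgb <- solve(.lab_rgb2lms)
.lab_mix <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), nrow = 3, byrow = TRUE)
.lab_unmix <- solve(.lab_mix)
.lab_eps <- 1e-4   # floor on LMS before the log; keeps black pixels finite

rgb_to_lab_pixels <- function(px) {
  lms <- px %*% t(.lab_rgb2lms)
  lms[lms < .lab_eps] <- .lab_eps
  log10(lms) %*% t(.lab_mix)
}

lab_to_rgb_pixels <- function(lab) {
  lms <- 10^(lab %*% t(.lab_unmix))
  clip01(lms %*% t(.lab_lms2rgb))
}

# Luminance used by foreground masking (Rec. 601 weights).
luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}
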