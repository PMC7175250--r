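# The 15 per-crystal descriptors: 6 shape (area, perimeter, major/minor axis
# length, eccentricity, circularity), 5 intensity (mean, variance, min, max,
# spread), 4 texture (GLCM correlation, contrast, homogeneity, energy).
#
# Conventions (the standard regionprops / graycoprops ones):
#  - axis lengths and eccentricity come from the equivalent ellipse of the
#    second central moments of the pixel coordinates;
#  - circularity = 4*pi*area / perimeter^2 with a marching-squares boundary
#    length estimate (straight steps weighted 1, corner cuts sqrt(2)/2);
#  - intensity_spread = interquartile range / bit-depth range, a robust
#    single-scalar width of the intensity distribution;
#  - GLCM is quantized to 32 gray levels over the FULL bit-depth range (not
#    per-region min-max, so a constant intensity shift leaves texture
#    features unchanged up to quantization), distance 1 px, the four
#    standard angles averaged, symmetric, normalized.

GLCM_LEVELS <- 32L

#' Extract the 15 descriptors for every segment of a field
#'
#' @param image A [field_image()].
#' @param labels Integer label matrix from [segment_crystals()].
#' @param segments Segment table from [segment_crystals()]; if `NULL` it is
#'   recomputed from `labels`.
#' @return Data frame with `segment_id` plus the 15 [feature_names()]
#'   columns, one row per segment. Lengths are in µm, areas in µm²;
#'   intensity features are in raw intensity units.
#' @export
extract_features <- function(image, labels, segments = NULL) {
  stopifnot(inherits(image, "field_image"), is.matrix(labels))
  if (is.null(segments)) segments <- .segment_table(labels, image)
  k <- nrow(segments)
  out <- as.data.frame(matrix(NA_real_, k, 15L,
                              dimnames = list(NULL, feature_names())))
  out <- cbind(data.frame(segment_id = segments$segment_id), out)
  if (k == 0L) return(out)
  for (i in seq_len(k)) {
    s <- segments[i, ]
    sub <- labels[s$r0:(s$r1 - 1L), s$c0:(s$c1 - 1L), drop = FALSE]
    m <- sub == s$segment_id
    px <- image$pixels[s$r0:(s$r1 - 1L), s$c0:(s$c1 - 1L), drop = FALSE]
    out[i, feature_names()] <- .features_one(m, px, image$pixel_size,
                                             image$bit_depth)
  }
  out
}

.features_one <- function(mask, pixels, pixel_size, bit_depth) {
  stopifnot(any(mask))
  vals <- pixels[mask]
  rng <- 2^bit_depth - 1
  shp <- .shape_features(mask, pixel_size)
  glcm <- glcm_features(pixels, mask, bit_depth)
  c(shp,
    mean_intensity = mean(vals),
    intensity_variance = if (length(vals) > 1) stats::var(vals) else 0,
    min_intensity = min(vals),
    max_intensity = max(vals),
    intensity_spread = unname(diff(stats::quantile(vals, c(0.25, 0.75),
                                                   names = FALSE))) / rng,
    glcm)
}

.shape_features <- function(mask, pixel_size) {
  n <- sum(mask)
  idx <- which(mask)
  r <- (idx - 1L) %% nrow(mask)
  cc <- (idx - 1L) %/% nrow(mask)
  mu_r <- mean(r); mu_c <- mean(cc)
  # second central moments of the pixel-coordinate cloud
  m20 <- mean((r - mu_r)^2); m02 <- mean((cc - mu_c)^2)
  m11 <- mean((r - mu_r) * (cc - mu_c))
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2       # eigenvalues of the covariance matrix
  l2 <- (m20 + m02 - common) / 2
  l2 <- max(l2, 0)
  major <- 4 * sqrt(l1) * pixel_size
  minor <- 4 * sqrt(l2) * pixel_size
  ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
  per_px <- perimeter_marching(mask)
  area <- n * pixel_size^2
  per <- per_px * pixel_size
  circ <- if (per > 0) min(1, 4 * pi * area / per^2) else 1
  c(area = area, perimeter = per, major_axis = major, minor_axis = minor,
    eccentricity = ecc, circularity = circ)
}

#' Marching-squares boundary length of a binary mask
#'
#' Sums the iso-contour segment lengths of the 0.5 level set over all 2x2
#' pixel windows: straight edge pieces contribute 1, corner cuts
#' `sqrt(2)/2`, diagonal (saddle) configurations two corner cuts. A
#' single-pixel object has perimeter `2*sqrt(2)` (its diamond contour).
#'
#' @param mask Logical matrix.
#' @return Boundary length in pixel units.
#' @export
perimeter_marching <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  p00 <- m[1:(nr - 1), 1:(nc - 1)]
  p10 <- m[2:nr, 1:(nc - 1)]
  p01 <- m[1:(nr - 1), 2:nc]
  p11 <- m[2:nr, 2:nc]
  code <- p00 + 2L * p10 + 4L * p01 + 8L * p11
  h <- sqrt(2) / 2
  len <- c(0, h, h, 1, h, 1, 2 * h, h, h, 2 * h, 1, h, 1, h, h, 0)
  sum(len[code + 1L])
}

#' Gray-level co-occurrence texture features of a masked region
#'
#' Quantizes the region's pixels to 32 levels over the full bit-depth range,
#' accumulates symmetric co-occurrence counts at distance 1 px for the four
#' standard angles (0°, 45°, 90°, 135°) restricted to pixel pairs inside the
#' mask, normalizes each angle's matrix, computes the Haralick/graycoprops
#' correlation, contrast, homogeneity (inverse difference) and energy
#' (angular second moment), and averages over angles.
#'
#' A region that is constant after quantization has energy 1, contrast 0,
#' homogeneity 1 and (by convention, as the zero-variance limit)
#' correlation 1; a region too small to contain any pixel pair falls back to
#' the same constant-region values.
#'
#' @param pixels Numeric intensity matrix (the segment's bounding box).
#' @param mask Logical matrix, same shape; `TRUE` = region member.
#' @param bit_depth 8 or 16; fixes the quantization range.
#' @param levels Number of gray levels (default 32).
#' @return Named vector `glcm_correlation`, `glcm_contrast`,
#'   `glcm_homogeneity`, `glcm_energy`.
#' @export
glcm_features <- function(pixels, mask, bit_depth, levels = GLCM_LEVELS) {
  const <- c(glcm_correlation = 1, glcm_contrast = 0,
             glcm_homogeneity = 1, glcm_energy = 1)
  q <- matrix(NA_integer_, nrow(pixels), ncol(pixels))
  q[mask] <- pmin(levels - 1L,
                  as.integer(floor(pixels[mask] / 2^bit_depth * levels)))
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  acc <- c(glcm_correlation = 0, glcm_contrast = 0,
           glcm_homogeneity = 0, glcm_energy = 0)
  n_ang <- 0L
  nr <- nrow(q); nc <- ncol(q)
  for (o in offs) {
    r1 <- max(1L, 1L - o[1]):min(nr, nr - o[1])
    c1 <- max(1L, 1L - o[2]):min(nc, nc - o[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + o[1], c1 + o[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    i <- c(a[ok], b[ok])          # symmetric: count both directions
    j <- c(b[ok], a[ok])
    cnt <- tabulate(i * levels + j + 1L, nbins = levels * levels)
    p <- matrix(cnt / sum(cnt), levels, levels, byrow = TRUE)
    lv <- 0:(levels - 1L)
    pi_ <- rowSums(p)
    mu <- sum(lv * pi_)
    sig2 <- sum((lv - mu)^2 * pi_)
    dif <- outer(lv, lv, "-")
    contrast <- sum(dif^2 * p)
    homog <- sum(p / (1 + abs(dif)))
    energy <- sum(p^2)
    corr <- if (sig2 > 0)
      sum(outer(lv - mu, lv - mu) * p) / sig2 else 1
    acc <- acc + c(corr, contrast, homog, energy)
    n_ang <- n_ang + 1L
  }
  if (n_ang == 0L) return(const)
  out <- acc / n_ang
  names(out) <- names(const)
  out
}
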