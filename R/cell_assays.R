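# Cell-assay image readouts.
#
# Adhesion assay: crystals bound to a confluent epithelial monolayer imaged
# by DIC appear as high-relief, high-local-contrast objects on a flat cell
# background, so the crystal-occupied area is segmented by local-variance
# thresholding. Viability assay: dead cells carry a punctate red
# fluorescence signal; dots are counted as above-threshold connected
# components within a size band, with touching dots split by watershed.

#' Crystal-occupied area fraction of a DIC-like image
#'
#' Local variance (box window) is compared against a threshold on the local
#' standard deviation expressed as a fraction of the bit-depth range;
#' above-threshold pixels are closed and hole-filled into the crystal mask.
#'
#' @param image A [field_image()] (single DIC channel).
#' @param window Box window side (px, odd) for the local variance.
#' @param sd_threshold Local standard deviation threshold as a fraction of
#'   the intensity range; flat cell background stays below it, crystal
#'   texture above.
#' @return Occupied fraction in `[0, 1]`.
#' @export
crystal_occupied_area <- function(image, window = 7L, sd_threshold = 0.03) {
  stopifnot(inherits(image, "field_image"), window >= 3, window %% 2 == 1)
  g <- image$pixels / (2^image$bit_depth - 1)
  box <- matrix(1 / window^2, window, window)
  m1 <- as.matrix(EBImage::filter2(g, box))
  m2 <- as.matrix(EBImage::filter2(g^2, box))
  v <- pmax(m2 - m1^2, 0)
  mask <- sqrt(v) > sd_threshold
  brush <- EBImage::makeBrush(5, shape = "disc")
  mask <- as.matrix(EBImage::closing(EBImage::as.Image(mask * 1), brush)) > 0.5
  mask <- as.matrix(EBImage::fillHull(EBImage::as.Image(mask * 1))) > 0.5
  # the sliding window flags pixels up to (window-1)/2 outside the texture;
  # erode by that margin so the fraction tracks the true footprint
  shrink <- EBImage::makeBrush(window, shape = "disc")
  mask <- as.matrix(EBImage::erode(EBImage::as.Image(mask * 1), shrink)) > 0.5
  mean(mask)
}

#' Count dead-cell dots in a red-fluorescence image
#'
#' Thresholds the channel at a fixed fraction of the intensity range,
#' splits touching dots by watershed on the distance transform, and counts
#' components whose area lies within the dot-size band.
#'
#' @param image A [field_image()] (red channel).
#' @param intensity_threshold Fraction of the intensity range.
#' @param min_area_px,max_area_px Dot-size band (px).
#' @return Integer dot count.
#' @export
count_dead_cells <- function(image, intensity_threshold = 0.25,
                             min_area_px = 6L, max_area_px = 400L) {
  stopifnot(inherits(image, "field_image"))
  g <- image$pixels / (2^image$bit_depth - 1)
  mask <- g > intensity_threshold
  if (!any(mask)) return(0L)
  lab <- split_touching(mask, distance_smooth_sigma = 1, tolerance = 0.5)
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  sum(sizes >= min_area_px & sizes <= max_area_px)
}

#' Normalize per-condition cell-assay means to the control
#'
#' Mirrors the screening normalization: per experiment, the mean readout of
#' each condition is expressed as a percentage of the control (no-inhibitor)
#' condition's mean.
#'
#' @param measurements Data frame with `experiment_id`, `concentration_nM`
#'   and a `value` column (occupied fraction or dot count per image).
#' @return Per (experiment, concentration) data frame with `mean_value` and
#'   `normalized` (percent of control).
#' @export
normalize_cell_assay <- function(measurements) {
  stopifnot(all(c("experiment_id", "concentration_nM", "value") %in%
                  names(measurements)))
  key <- unique(measurements[, c("experiment_id", "concentration_nM")])
  key <- key[order(key$experiment_id, key$concentration_nM), ]
  rownames(key) <- NULL
  key$mean_value <- NA_real_
  for (i in seq_len(nrow(key))) {
    sel <- measurements$experiment_id == key$experiment_id[i] &
      measurements$concentration_nM == key$concentration_nM[i]
    key$mean_value[i] <- mean(measurements$value[sel])
  }
  key$normalized <- NA_real_
  for (ex in unique(key$experiment_id)) {
    sel <- key$experiment_id == ex
    ctrl <- key$mean_value[sel & key$concentration_nM == 0]
    if (length(ctrl) != 1L || !is.finite(ctrl) || ctrl <= 0)
      stop("experiment ", ex, " lacks a usable control condition")
    key$normalized[sel] <- 100 * key$mean_value[sel] / ctrl
  }
  key
}

#' Render a synthetic DIC-like adhesion field
#'
#' Flat, low-variance cell background with high-contrast textured crystal
#' patches covering approximately the requested fraction of the field.
#'
#' @param coverage Target crystal-occupied fraction in `[0, 1)`.
#' @param image_size Side length (px).
#' @param seed Integer seed.
#' @param texture_amplitude Per-pixel SD of the crystal texture (fraction).
#' @return List: `image` (a [field_image()]) and `true_coverage`, the
#'   painted ground-truth fraction.
#' @export
render_adhesion_field <- function(coverage = 0.12, image_size = 256L,
                                  seed = 1L, texture_amplitude = 0.12) {
  stopifnot(coverage >= 0, coverage < 0.9)
  .with_seed(seed, {
    n <- image_size
    canvas <- 0.55 + matrix(stats::rnorm(n * n, 0, 0.004), n, n)
    painted <- matrix(FALSE, n, n)
    guard <- 0L
    while (mean(painted) < coverage && guard < 10000L) {
      guard <- guard + 1L
      rb <- stats::runif(1, 4, 11)
      ctr <- stats::runif(2, rb + 1, n - rb)
      hit <- .raster_star(ctr, rb * stats::runif(8, 0.7, 1.3), n, n)
      if (is.null(hit)) next
      idx <- cbind(hit$r, hit$c)
      canvas[idx] <- 0.5 + stats::rnorm(nrow(idx), 0, texture_amplitude)
      painted[idx] <- TRUE
    }
    canvas <- round(pmin(pmax(canvas, 0), 1) * 65535)
    list(image = field_image(canvas, pixel_size = 0.1, bit_depth = 16L),
         true_coverage = mean(painted))
  })
}

#' Render a synthetic dead-cell fluorescence field
#'
#' Dark background with bright, roughly Gaussian dots; dot centres keep a
#' minimum separation unless `allow_touching` is set.
#'
#' @param n_dots Number of dots.
#' @param image_size Side length (px).
#' @param seed Integer seed.
#' @param dot_sigma Gaussian radius of a dot (px).
#' @param allow_touching If `TRUE`, dot centres may fall close together.
#' @return List: `image` (a [field_image()]) and `centers` (n x 2 matrix).
#' @export
render_dead_cell_field <- function(n_dots = 25L, image_size = 256L, seed = 1L,
                                   dot_sigma = 2.2, allow_touching = FALSE) {
  .with_seed(seed, {
    n <- image_size
    canvas <- matrix(0.02, n, n)
    centers <- matrix(NA_real_, n_dots, 2)
    min_sep <- if (allow_touching) 0 else 8 * dot_sigma
    for (i in seq_len(n_dots)) {
      for (try in 1:500) {
        p <- stats::runif(2, 10, n - 10)
        if (i == 1L || min_sep == 0 ||
            all(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                              matrix(p, i - 1L, 2, byrow = TRUE))^2)) > min_sep)) {
          centers[i, ] <- p
          break
        }
      }
      if (anyNA(centers[i, ])) stop("cannot place ", n_dots, " separated dots")
      amp <- stats::runif(1, 0.5, 0.9)
      r0 <- max(1L, floor(centers[i, 1] - 5 * dot_sigma))
      r1 <- min(n, ceiling(centers[i, 1] + 5 * dot_sigma))
      c0 <- max(1L, floor(centers[i, 2] - 5 * dot_sigma))
      c1 <- min(n, ceiling(centers[i, 2] + 5 * dot_sigma))
      rr <- rep(r0:r1, times = c1 - c0 + 1L)
      cc <- rep(c0:c1, each = r1 - r0 + 1L)
      d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
      canvas[cbind(rr, cc)] <- canvas[cbind(rr, cc)] +
        amp * exp(-d2 / (2 * dot_sigma^2))
    }
    canvas <- canvas + matrix(stats::rnorm(n * n, 0, 0.005), n, n)
    canvas <- round(pmin(pmax(canvas, 0), 1) * 65535)
    list(image = field_image(canvas, pixel_size = 0.65, bit_depth = 16L),
         centers = centers)
  })
}
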