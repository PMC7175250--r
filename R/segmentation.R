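# Crystals in brightfield appear as dark-rimmed, internally textured objects
# on a bright background; the rim gradient is the robust cue, so detection is
# edge-based: Gaussian smoothing -> Sobel gradient magnitude -> Otsu (or
# fixed) threshold -> morphological closing + hole fill -> watershed split of
# touching objects on the smoothed negated distance transform.

#' Segmentation parameters
#'
#' @param edge_sigma Gaussian pre-smoothing sigma (px) before the gradient.
#' @param edge_threshold_mode `"automatic"` (Otsu on the gradient magnitude)
#'   or `"fixed"`.
#' @param edge_threshold Gradient threshold as a fraction of the intensity
#'   range, used when `edge_threshold_mode = "fixed"`.
#' @param edge_floor Absolute lower bound on the automatic gradient
#'   threshold; keeps a featureless (noise-only) field from producing
#'   spurious edges, since Otsu always splits whatever distribution it sees.
#' @param min_object_area Minimum object area in µm²; smaller detections are
#'   discarded before labeling. The default 4 µm² keeps sub-crystal debris
#'   for the classifier's noise class rather than silently dropping it.
#' @param fill_holes Fill enclosed background inside edge rings (crystals are
#'   solid objects).
#' @param close_size Diameter (px) of the disc used for morphological closing
#'   of the edge map before hole filling.
#' @param shrink_px Radius (px) of the final mask erosion that compensates
#'   the outward widening of the gradient band (roughly the smoothing
#'   sigma); 0 disables.
#' @param split_touching Apply watershed splitting of touching objects.
#' @param distance_smooth_sigma Gaussian sigma (px) applied to the distance
#'   transform before watershed seeding; suppresses spurious maxima on
#'   angular crystal outlines.
#' @param watershed_tolerance Minimum depth (px of distance) separating two
#'   watershed seeds; maxima closer in depth are merged (h-maxima style).
#' @param border_policy `"keep"` (default; dropping border objects would bias
#'   total area per field) or `"drop"`.
#' @return A `segmentation_params` object (list).
#' @export
segmentation_params <- function(edge_sigma = 1.5,
                                edge_threshold_mode = c("automatic", "fixed"),
                                edge_threshold = 0.05,
                                edge_floor = 0.04,
                                min_object_area = 4,
                                fill_holes = TRUE,
                                close_size = 5L,
                                shrink_px = 2L,
                                split_touching = TRUE,
                                distance_smooth_sigma = 2,
                                watershed_tolerance = 1,
                                border_policy = c("keep", "drop")) {
  edge_threshold_mode <- match.arg(edge_threshold_mode)
  border_policy <- match.arg(border_policy)
  stopifnot(edge_sigma >= 0, distance_smooth_sigma >= 0,
            min_object_area >= 0, edge_threshold > 0, watershed_tolerance >= 0)
  structure(list(edge_sigma = edge_sigma,
                 edge_threshold_mode = edge_threshold_mode,
                 edge_threshold = edge_threshold,
                 edge_floor = edge_floor,
                 min_object_area = min_object_area,
                 fill_holes = isTRUE(fill_holes),
                 close_size = as.integer(close_size),
                 shrink_px = as.integer(shrink_px),
                 split_touching = isTRUE(split_touching),
                 distance_smooth_sigma = distance_smooth_sigma,
                 watershed_tolerance = watershed_tolerance,
                 border_policy = border_policy),
            class = "segmentation_params")
}

.sobel_gradient <- function(g, sigma) {
  if (sigma > 0) g <- as.matrix(EBImage::gblur(g, sigma = sigma))
  # normalized so that a unit step edge gives gradient magnitude 1
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) / 4
  gx <- as.matrix(EBImage::filter2(g, kx))
  gy <- as.matrix(EBImage::filter2(g, t(kx)))
  sqrt(gx^2 + gy^2)
}

#' Split touching objects by watershed on the distance transform
#'
#' Computes the Euclidean distance transform of the foreground, smooths it,
#' and runs a seeded watershed so that each distance maximum (deeper than
#' `tolerance`) yields one object. A single convex object is never split;
#' fused objects with multiple distance maxima are cut at the saddle.
#'
#' @param mask Logical or 0/1 matrix of foreground pixels.
#' @param distance_smooth_sigma Gaussian sigma (px) for the distance map.
#' @param tolerance Watershed tolerance (h-maxima depth, px).
#' @return Integer label matrix; 0 = background, labels form 1..K.
#' @export
split_touching <- function(mask, distance_smooth_sigma = 2, tolerance = 1) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (all(m > 0)) return(matrix(1L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(m)
  if (distance_smooth_sigma > 0)
    d <- EBImage::gblur(d, sigma = distance_smooth_sigma)
  d <- as.matrix(d) * m            # smoothing bleeds over edges; re-clip
  lab <- EBImage::watershed(EBImage::as.Image(d), tolerance = tolerance, ext = 1)
  .relabel(as.matrix(EBImage::imageData(lab)))
}

# compact positive labels to 1..K preserving first-occurrence order
.relabel <- function(lab) {
  lab <- round(lab)
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

#' Segment crystals in a brightfield field of view
#'
#' Edge detection (smoothed Sobel gradient, automatic or fixed threshold),
#' morphological closing and hole filling to obtain solid crystal masks,
#' then optional watershed splitting of touching crystals. Deterministic for
#' fixed input and parameters. A constant-intensity image yields zero
#' segments, not an error.
#'
#' @param image A [field_image()].
#' @param params A [segmentation_params()] object.
#' @return A list with `labels` (integer matrix, 0 = background, k = segment
#'   k) and `segments`, a data frame with one row per segment: `segment_id`,
#'   `pixel_area`, `area` (µm²), bounding box (`r0`, `c0`, `r1`, `c1`,
#'   half-open), and centroid (`cr`, `cc`, px).
#' @export
segment_crystals <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "field_image"),
            inherits(params, "segmentation_params"))
  maxval <- 2^image$bit_depth - 1
  g <- image$pixels / maxval
  grad <- .sobel_gradient(g, params$edge_sigma)
  rng <- range(grad)
  if (diff(rng) < .Machine$double.eps) {
    # constant image: no edges, no objects
    empty <- matrix(0L, nrow(g), ncol(g))
    return(list(labels = empty, segments = .segment_table(empty, image)))
  }
  thr <- if (params$edge_threshold_mode == "automatic") {
    gn <- (grad - rng[1]) / diff(rng)
    max(rng[1] + diff(rng) * EBImage::otsu(EBImage::as.Image(gn),
                                           range = c(0, 1)),
        params$edge_floor)
  } else params$edge_threshold
  mask <- grad > thr
  if (params$close_size > 1) {
    brush <- EBImage::makeBrush(params$close_size, shape = "disc")
    mask <- as.matrix(EBImage::closing(EBImage::as.Image(mask * 1), brush)) > 0.5
  }
  if (params$fill_holes)
    mask <- as.matrix(EBImage::fillHull(EBImage::as.Image(mask * 1))) > 0.5
  if (params$shrink_px > 0) {
    brush <- EBImage::makeBrush(2L * params$shrink_px + 1L, shape = "disc")
    mask <- as.matrix(EBImage::erode(EBImage::as.Image(mask * 1), brush)) > 0.5
  }
  min_px <- ceiling(params$min_object_area / image$pixel_size^2)
  # pre-filter components below the area floor before the (costly) watershed
  comp <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(mask * 1))))
  if (max(comp) > 0) {
    sizes <- tabulate(comp[comp > 0], nbins = max(comp))
    mask <- matrix(comp > 0 & sizes[pmax(comp, 1L)] >= min_px, nrow(comp))
  }
  lab <- if (params$split_touching) {
    split_touching(mask, params$distance_smooth_sigma,
                   params$watershed_tolerance)
  } else {
    .relabel(as.matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::as.Image(mask * 1)))))
  }
  # watershed fragments can fall below the floor; enforce it on final labels
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < min_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  if (params$border_policy == "drop" && max(lab) > 0) {
    touching <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    touching <- touching[touching > 0]
    if (length(touching)) lab[lab %in% touching] <- 0L
  }
  lab <- .relabel(lab)
  list(labels = lab, segments = .segment_table(lab, image))
}

.segment_table <- function(lab, image) {
  k <- max(lab)
  if (k == 0L)
    return(data.frame(segment_id = integer(0), pixel_area = integer(0),
                      area = numeric(0), r0 = integer(0), c0 = integer(0),
                      r1 = integer(0), c1 = integer(0), cr = numeric(0),
                      cc = numeric(0)))
  idx <- which(lab > 0)
  id <- lab[idx]
  r <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  pixel_area <- tabulate(id, nbins = k)
  data.frame(segment_id = seq_len(k),
             pixel_area = pixel_area,
             area = pixel_area * image$pixel_size^2,
             r0 = as.integer(tapply(r, id, min)),
             c0 = as.integer(tapply(cc, id, min)),
             r1 = as.integer(tapply(r, id, max)) + 1L,
             c1 = as.integer(tapply(cc, id, max)) + 1L,
             cr = as.numeric(tapply(r, id, mean)),
             cc = as.numeric(tapply(cc, id, mean)))
}
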