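# Ground-truthed synthetic brightfield crystal scenes.
#
# Appearance model: bright background with an illumination tilt, objects with
# a dark rim (the edge-detection cue of real brightfield crystals), textured
# interiors, whole-field defocus blur and additive sensor noise. Four object
# classes mirror the screening vocabulary:
#   COM  (class 0): small compact diamonds, target length 10 µm, abundant;
#   COD  (class 1): larger tetragonal-bipyramid projections (elongated
#                   diamonds) with a bright refractile centre, target length
#                   20 µm, elongating into needles under high inhibitor;
#   n.d. (class 2): irregular star-convex blobs of intermediate contrast;
#   noise(class 3): small dark specks plus faint out-of-focus blobs.

#' Specification of one synthetic crystal scene
#'
#' Defaults reproduce the screening phenomenology: COM more abundant and
#' smaller (lognormal length, mean 10 µm) than COD (mean 20 µm), with
#' illumination tilt and focus jitter enabled.
#'
#' @param image_size Side length in px (square field).
#' @param pixel_size µm per pixel.
#' @param n_com,n_cod,n_nd,n_noise Per-class object counts.
#' @param com_length_um,cod_length_um Mean crystal lengths (µm, the mean of
#'   the lognormal length distribution).
#' @param com_length_sdlog,cod_length_sdlog Lognormal sdlog of the lengths.
#' @param cod_elongation Needle factor >= 1; stretches the COD long axis
#'   (high-inhibitor phenotype).
#' @param background_level Background intensity as a fraction of the
#'   bit-depth range.
#' @param background_jitter SD of the per-scene background-level jitter.
#' @param rim_intensity Intensity of the dark crystal rim (fraction).
#' @param texture_amplitude SD of the per-pixel interior texture (fraction).
#' @param illumination_amplitude Peak-to-centre amplitude of the linear
#'   illumination tilt (fraction); 0 disables it.
#' @param focus_sigma,focus_jitter Gaussian defocus sigma (px) and the upper
#'   bound of its uniform per-scene jitter; jitter 0 disables.
#' @param noise_sd SD of additive sensor noise (fraction).
#' @param overlap_probability Probability that an object is allowed to be
#'   placed touching/overlapping another.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; fixed seed gives a bit-identical scene.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(image_size = 512L, pixel_size = 0.32,
                       n_com = 40L, n_cod = 8L, n_nd = 6L, n_noise = 6L,
                       com_length_um = 10, com_length_sdlog = 0.25,
                       cod_length_um = 20, cod_length_sdlog = 0.2,
                       cod_elongation = 1,
                       background_level = 0.78, background_jitter = 0.025,
                       rim_intensity = 0.22, texture_amplitude = 0.055,
                       illumination_amplitude = 0.05,
                       focus_sigma = 0.8, focus_jitter = 0.5,
                       noise_sd = 0.012, overlap_probability = 0.05,
                       bit_depth = 16L, seed = 1L) {
  stopifnot(image_size >= 64, pixel_size > 0,
            n_com >= 0, n_cod >= 0, n_nd >= 0, n_noise >= 0,
            com_length_um > 0, cod_length_um > 0, cod_elongation >= 1,
            overlap_probability >= 0, overlap_probability <= 1)
  structure(as.list(environment()), class = "scene_spec")
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

.derive_seed <- function(seed, i) as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483629)

# pixels inside a convex polygon (vertices k x 2, (r, c)), clipped to the field
.raster_convex <- function(verts, nr, nc) {
  ctr <- colMeans(verts)
  o <- order(atan2(verts[, 1] - ctr[1], verts[, 2] - ctr[2]))
  v <- verts[o, , drop = FALSE]
  r0 <- max(1L, floor(min(v[, 1]))); r1 <- min(nr, ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2]))); c1 <- min(nc, ceiling(max(v[, 2])))
  if (r1 < r0 || c1 < c0) return(NULL)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  inside <- rep(TRUE, length(rr))
  k <- nrow(v)
  for (e in seq_len(k)) {
    a <- v[e, ]; b <- v[if (e == k) 1L else e + 1L, ]
    s <- (rr - a[1]) * (b[2] - a[2]) - (cc - a[2]) * (b[1] - a[1])
    s_ctr <- (ctr[1] - a[1]) * (b[2] - a[2]) - (ctr[2] - a[2]) * (b[1] - a[1])
    inside <- inside & s * sign(s_ctr) >= -1e-9
  }
  if (!any(inside)) return(NULL)
  list(r = rr[inside], c = cc[inside], r0 = r0, c0 = c0)
}

# pixels inside a star-convex blob: radius profile interpolated over angle
.raster_star <- function(ctr, radii, nr, nc) {
  rmax <- max(radii)
  r0 <- max(1L, floor(ctr[1] - rmax)); r1 <- min(nr, ceiling(ctr[1] + rmax))
  c0 <- max(1L, floor(ctr[2] - rmax)); c1 <- min(nc, ceiling(ctr[2] + rmax))
  if (r1 < r0 || c1 < c0) return(NULL)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  dr <- rr - ctr[1]; dc <- cc - ctr[2]
  d <- sqrt(dr^2 + dc^2)
  th <- atan2(dr, dc) %% (2 * pi)
  k <- length(radii)
  step <- 2 * pi / k
  i0 <- floor(th / step)
  w <- th / step - i0
  rad <- radii[(i0 %% k) + 1L] * (1 - w) + radii[((i0 + 1L) %% k) + 1L] * w
  inside <- d <= rad
  if (!any(inside)) return(NULL)
  list(r = rr[inside], c = cc[inside])
}

# diamond (tetragonal-bipyramid projection) vertices for a crystal of
# length L px and width W px at angle theta, with slight vertex jitter
.diamond_verts <- function(ctr, L, W, theta, jitter = 0.06) {
  u <- c(sin(theta), cos(theta))
  v <- c(cos(theta), -sin(theta))
  base <- rbind(ctr + u * L / 2, ctr + v * W / 2,
                ctr - u * L / 2, ctr - v * W / 2)
  base + matrix(stats::rnorm(8, 0, jitter * W / 4), 4, 2)
}

.erode4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  p[2:(nr + 1L), 2:(nc + 1L)] & p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
}

#' Render one synthetic scene with ground truth
#'
#' Deterministic for a fixed spec (the spec carries its seed): the same spec
#' rendered twice is bit-identical. Object placement is rejection-sampled;
#' with `overlap_probability = 0` objects never touch. Counts that cannot be
#' placed at the requested overlap setting raise an error.
#'
#' @param spec A [scene_spec()].
#' @param meta An [acquisition_meta()] stamped onto the image.
#' @return A list with `image` (a [field_image()]) and `truth`: `labels`
#'   (integer instance map, later objects overprint earlier at overlaps) and
#'   `instances` (data frame: `instance`, `class`, `pixel_area` of the
#'   rasterized polygon, `area` in µm², `length_um`).
#' @export
render_scene <- function(spec, meta = acquisition_meta()) {
  stopifnot(inherits(spec, "scene_spec"))
  .with_seed(spec$seed, .render_scene_impl(spec, meta))
}

.render_scene_impl <- function(spec, meta) {
  n <- spec$image_size
  ps <- spec$pixel_size
  classes <- rep(c(0L, 1L, 2L, 3L),
                 c(spec$n_com, spec$n_cod, spec$n_nd, spec$n_noise))
  if (length(classes)) classes <- sample(classes)
  # geometry draws; place large objects first (better packing)
  geom <- lapply(classes, function(cl) .draw_geometry(cl, spec))
  rad <- vapply(geom, `[[`, numeric(1), "radius")
  o <- order(rad, decreasing = TRUE)
  classes <- classes[o]; geom <- geom[o]; rad <- rad[o]
  pos <- matrix(NA_real_, length(classes), 2)
  for (i in seq_along(classes)) {
    placed <- FALSE
    relax <- stats::runif(1) < spec$overlap_probability
    if (1 + rad[i] >= n - rad[i])
      stop("object counts cannot fit in the field at this overlap setting")
    for (try in 1:2000) {
      p <- stats::runif(2, 1 + rad[i], n - rad[i])
      if (i == 1L) { pos[i, ] <- p; placed <- TRUE; break }
      dmin <- (rad[i] + rad[seq_len(i - 1L)]) * (if (relax) 0.45 else 1) +
        (if (relax) 0 else 6)
      if (all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                            matrix(p, i - 1L, 2, byrow = TRUE))^2)) > dmin)) {
        pos[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("object counts cannot fit in the field at this overlap setting")
  }
  bg <- min(0.95, max(0.55, spec$background_level +
                        stats::rnorm(1, 0, spec$background_jitter)))
  canvas <- matrix(bg, n, n)
  gt <- matrix(0L, n, n)
  inst <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    pix <- .paint_object(canvas, gt, geom[[i]], pos[i, ], i, bg, spec)
    canvas <- pix$canvas; gt <- pix$gt
    inst[[i]] <- data.frame(instance = i, class = classes[i],
                            pixel_area = pix$pixel_area,
                            area = pix$pixel_area * ps^2,
                            length_um = geom[[i]]$length_px * ps)
  }
  if (spec$illumination_amplitude > 0) {
    th <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.4, 1) * spec$illumination_amplitude
    gx <- (col(canvas) - (n + 1) / 2) / (n / 2)
    gy <- (row(canvas) - (n + 1) / 2) / (n / 2)
    canvas <- canvas + amp * (cos(th) * gx + sin(th) * gy)
  }
  sig <- spec$focus_sigma + stats::runif(1, 0, spec$focus_jitter)
  if (sig > 0) canvas <- as.matrix(EBImage::gblur(canvas, sigma = sig))
  if (spec$noise_sd > 0)
    canvas <- canvas + stats::rnorm(length(canvas), 0, spec$noise_sd)
  maxval <- 2^spec$bit_depth - 1
  canvas <- round(pmin(pmax(canvas, 0), 1) * maxval)
  instances <- if (length(inst)) do.call(rbind, inst) else
    data.frame(instance = integer(0), class = integer(0),
               pixel_area = integer(0), area = numeric(0),
               length_um = numeric(0))
  list(image = field_image(canvas, pixel_size = ps,
                           bit_depth = spec$bit_depth, meta = meta),
       truth = list(labels = gt, instances = instances))
}

.draw_geometry <- function(cl, spec) {
  ps <- spec$pixel_size
  if (cl == 0L) {                         # COM: compact diamond
    L <- stats::rlnorm(1, log(spec$com_length_um) - spec$com_length_sdlog^2 / 2,
                       spec$com_length_sdlog) / ps
    W <- L * stats::runif(1, 0.45, 0.7)
    list(kind = "diamond", class = 0L, length_px = L, width_px = W,
         theta = stats::runif(1, 0, pi), radius = L / 2 + 2)
  } else if (cl == 1L) {                  # COD: larger, elongates to needles
    L <- stats::rlnorm(1, log(spec$cod_length_um) - spec$cod_length_sdlog^2 / 2,
                       spec$cod_length_sdlog) / ps * spec$cod_elongation
    W <- L / spec$cod_elongation * stats::runif(1, 0.5, 0.75) /
      sqrt(spec$cod_elongation)
    list(kind = "diamond", class = 1L, length_px = L, width_px = W,
         theta = stats::runif(1, 0, pi), radius = L / 2 + 2)
  } else if (cl == 2L) {                  # n.d.: irregular blob
    rb <- stats::runif(1, 2.2, 3.8) / ps
    k <- 10L
    radii <- rb * stats::runif(k, 0.55, 1.45)
    list(kind = "blob", class = 2L, radii = radii, length_px = 2 * max(radii),
         radius = max(radii) + 2)
  } else {                                # noise: speck or faint blob
    faint <- stats::runif(1) < 0.4
    rb <- stats::runif(1, 1.8, 2.6) / ps
    radii <- rb * stats::runif(8L, 0.75, 1.25)
    list(kind = if (faint) "faint" else "speck", class = 3L, radii = radii,
         length_px = 2 * max(radii), radius = max(radii) + 2)
  }
}

.paint_object <- function(canvas, gt, g, ctr, id, bg, spec) {
  n <- nrow(canvas)
  tex <- spec$texture_amplitude
  if (g$kind == "diamond") {
    v <- .diamond_verts(ctr, g$length_px, g$width_px, g$theta)
    hit <- .raster_convex(v, n, n)
  } else {
    hit <- .raster_star(ctr, g$radii, n, n)
  }
  if (is.null(hit)) return(list(canvas = canvas, gt = gt, pixel_area = 0L))
  idx <- cbind(hit$r, hit$c)
  mask <- matrix(FALSE, n, n); mask[idx] <- TRUE
  npx <- nrow(idx)
  if (g$kind == "diamond" && g$length_px / g$width_px < 10) {
    core <- .erode4(.erode4(mask))
    rim <- mask & !core
    is_cod <- g$class == 1L
    base <- if (is_cod) 0.60 else 0.52
    canvas[mask] <- base + stats::rnorm(1, 0, 0.03) +
      stats::rnorm(npx, 0, tex * (if (is_cod) 0.6 else 1))
    if (is_cod) {
      # bright refractile centre typical of thick bipyramids
      vc <- .diamond_verts(ctr, g$length_px * 0.45, g$width_px * 0.45, g$theta,
                           jitter = 0)
      hc <- .raster_convex(vc, n, n)
      if (!is.null(hc))
        canvas[cbind(hc$r, hc$c)] <- 0.88 + stats::rnorm(length(hc$r), 0, tex * 0.4)
    }
    canvas[rim] <- spec$rim_intensity + stats::rnorm(sum(rim), 0, 0.02)
  } else if (g$kind == "diamond") {         # extreme needles: thin, all rim
    canvas[mask] <- spec$rim_intensity + 0.1 + stats::rnorm(npx, 0, tex)
  } else if (g$kind == "blob") {
    core <- .erode4(mask)
    rim <- mask & !core
    canvas[mask] <- 0.63 + stats::rnorm(1, 0, 0.02) + stats::rnorm(npx, 0, tex * 0.7)
    canvas[rim] <- 0.45 + stats::rnorm(sum(rim), 0, 0.02)
  } else if (g$kind == "speck") {
    canvas[mask] <- 0.30 + stats::rnorm(1, 0, 0.04) + stats::rnorm(npx, 0, tex)
  } else {                                  # faint out-of-focus blob
    dr <- hit$r - ctr[1]; dc <- hit$c - ctr[2]
    d2 <- dr^2 + dc^2
    s2 <- (max(g$radii) / 1.6)^2
    canvas[idx] <- canvas[idx] - 0.24 * exp(-d2 / (2 * s2))
  }
  gt[idx] <- id
  list(canvas = canvas, gt = gt, pixel_area = npx)
}

#' Match segments to ground-truth instances
#'
#' Assigns each segment the class of the ground-truth instance covering the
#' largest share of its pixels, provided that share reaches `min_overlap`;
#' uncovered segments (spurious detections) are assigned the background-noise
#' class. Also reports the intersection-over-union with the matched instance.
#'
#' @param labels Segment label matrix from [segment_crystals()].
#' @param truth Ground truth list from [render_scene()].
#' @param min_overlap Minimum fraction of segment pixels covered by the
#'   matched instance.
#' @param noise_class Class code for unmatched segments (default 3).
#' @return Data frame: `segment_id`, `class`, `truth_instance` (NA if
#'   unmatched), `overlap_fraction`, `iou`.
#' @export
match_segments_to_truth <- function(labels, truth, min_overlap = 0.3,
                                    noise_class = 3L) {
  k <- max(labels)
  gt <- truth$labels
  inst <- truth$instances
  out <- data.frame(segment_id = seq_len(k), class = rep(noise_class, k),
                    truth_instance = rep(NA_integer_, k),
                    overlap_fraction = rep(0, k), iou = rep(0, k))
  if (k == 0L) return(out)
  sel <- labels > 0
  seg_px <- tabulate(labels[sel], nbins = k)
  gt_px <- tabulate(gt[gt > 0], nbins = max(gt, 1L))
  both <- sel & gt > 0
  if (any(both)) {
    pair <- paste(labels[both], gt[both], sep = ":")
    tab <- table(pair)
    parts <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
    ov <- data.frame(seg = as.integer(parts[, 1]), inst = as.integer(parts[, 2]),
                     n = as.integer(tab))
    ov <- ov[order(ov$seg, -ov$n), ]
    best <- ov[!duplicated(ov$seg), ]
    frac <- best$n / seg_px[best$seg]
    hit <- frac >= min_overlap
    out$truth_instance[best$seg[hit]] <- best$inst[hit]
    out$overlap_fraction[best$seg] <- frac
    out$class[best$seg[hit]] <- inst$class[match(best$inst[hit], inst$instance)]
    out$iou[best$seg] <- best$n / (seg_px[best$seg] + gt_px[best$inst] - best$n)
  }
  out
}

#' Per-instance best-segment intersection-over-union
#'
#' For each ground-truth instance, finds the segment with the largest
#' overlap and reports the IoU; instances with no overlapping segment get
#' IoU 0.
#'
#' @inheritParams match_segments_to_truth
#' @return Data frame: `instance`, `class`, `segment_id` (NA if undetected),
#'   `iou`.
#' @export
truth_segment_iou <- function(labels, truth) {
  inst <- truth$instances
  gt <- truth$labels
  m <- max(gt)
  out <- data.frame(instance = inst$instance, class = inst$class,
                    segment_id = rep(NA_integer_, nrow(inst)),
                    iou = rep(0, nrow(inst)))
  if (m == 0L || max(labels) == 0L) return(out)
  seg_px <- tabulate(labels[labels > 0], nbins = max(labels))
  gt_px <- tabulate(gt[gt > 0], nbins = m)
  both <- labels > 0 & gt > 0
  if (!any(both)) return(out)
  pair <- paste(gt[both], labels[both], sep = ":")
  tab <- table(pair)
  parts <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  ov <- data.frame(inst = as.integer(parts[, 1]), seg = as.integer(parts[, 2]),
                   n = as.integer(tab))
  ov <- ov[order(ov$inst, -ov$n), ]
  best <- ov[!duplicated(ov$inst), ]
  i <- match(best$inst, out$instance)
  out$segment_id[i] <- best$seg
  out$iou[i] <- best$n / (seg_px[best$seg] + gt_px[best$inst] - best$n)
  out
}
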