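#' @importFrom stats quantile sd var median rnorm runif rlnorm predict cor
#' @importFrom utils read.csv write.csv head
NULL

# Canonical concentration unit is nanomolar: every value the screen reports
# (40 nM .. 100 uM) is then an exact integer and unit arithmetic is additive.
.unit_to_nM <- c(nm = 1, nM = 1, um = 1e3, uM = 1e3, "µm" = 1e3,
                 "µM" = 1e3, mm = 1e6, mM = 1e6, m = 1e9, M = 1e9)

#' Acquisition metadata for one field of view
#'
#' Identifies a single acquired image within the plate layout of a
#' crystallization screen: the experiment (biological replicate), the well,
#' the field index within the well, and the treatment (compound and
#' concentration). Controls carry concentration 0.
#'
#' @param experiment_id,well_id Character identifiers.
#' @param field_index Integer field number within the well, >= 1.
#' @param compound Compound name; use `"control"` (or any name) with
#'   `is_control = TRUE` for the no-inhibitor condition.
#' @param concentration_nM Concentration in nanomolar (canonical unit).
#' @param timepoint_h Incubation time in hours.
#' @param is_control Logical; control records must have concentration 0.
#' @return An `acquisition_meta` object.
#' @export
acquisition_meta <- function(experiment_id = "E1", well_id = "W1",
                             field_index = 1L, compound = "control",
                             concentration_nM = 0, timepoint_h = 7,
                             is_control = concentration_nM == 0) {
  stopifnot(length(experiment_id) == 1, length(well_id) == 1)
  field_index <- as.integer(field_index)
  if (is.na(field_index) || field_index < 1L)
    stop("field_index must be an integer >= 1")
  if (!is.finite(concentration_nM) || concentration_nM < 0)
    stop("concentration_nM must be finite and >= 0")
  if (isTRUE(is_control) && concentration_nM != 0)
    stop("control records must have concentration 0")
  structure(list(experiment_id = as.character(experiment_id),
                 well_id = as.character(well_id),
                 field_index = field_index,
                 compound = as.character(compound),
                 concentration_nM = as.numeric(concentration_nM),
                 timepoint_h = as.numeric(timepoint_h),
                 is_control = isTRUE(is_control)),
            class = "acquisition_meta")
}

#' Calibrated single-channel field image
#'
#' The container every downstream module consumes: a rectangular grid of
#' non-negative integer intensities (brightfield, one channel), the spatial
#' calibration in micrometres per pixel, the bit depth, and acquisition
#' metadata.
#'
#' @param pixels Numeric matrix of intensities in `[0, 2^bit_depth - 1]`;
#'   at least 64 px per side.
#' @param pixel_size Micrometres per pixel, finite and > 0. The default
#'   0.32 corresponds to a 20x-class objective on a typical sCMOS camera.
#' @param bit_depth 8 or 16.
#' @param meta An [acquisition_meta()] object.
#' @return A `field_image` object.
#' @export
field_image <- function(pixels, pixel_size = 0.32, bit_depth = 16L,
                        meta = acquisition_meta()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(dim(pixels) < 64L))
    stop("image must be at least 64 px per side")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be finite and positive (µm/px)")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxval)
    stop("intensities must lie within the bit-depth range")
  if (!inherits(meta, "acquisition_meta")) stop("meta must be acquisition_meta")
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size),
                 bit_depth = as.integer(bit_depth), meta = meta),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px, %d-bit, %.3g µm/px (%s/%s field %d)\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size,
              x$meta$experiment_id, x$meta$well_id, x$meta$field_index))
  invisible(x)
}

#' Read a calibrated grayscale image
#'
#' Reads a single-channel 8- or 16-bit TIFF or PNG and attaches the pixel
#' calibration. Intensities are restored losslessly to their integer range.
#' Multi-channel images are rejected: the screening assay is brightfield
#' only, with exactly one channel.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size Micrometres per pixel (from the acquisition config; the
#'   files themselves are not trusted to carry calibration).
#' @param meta Optional [acquisition_meta()].
#' @return A [field_image()].
#' @export
read_field_image <- function(path, pixel_size = 0.32, meta = acquisition_meta()) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be finite and positive (µm/px)")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
  } else if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    if (!bits %in% c(8L, 16L)) stop("unsupported PNG bit depth: ", bits)
    # png normalizes to [0,1]; undo to integer counts
    raw <- round(raw * (2^bits - 1))
  } else stop("unsupported image format: .", ext)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] > 1L) stop("multi-channel image rejected; expected one channel")
    raw <- raw[, , 1L]
  }
  if (length(raw) == 0L) stop("empty image")
  field_image(raw, pixel_size = pixel_size, bit_depth = as.integer(bits),
              meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a field image to TIFF or PNG
#'
#' Integer intensities are stored losslessly at the image's bit depth;
#' reading the file back with [read_field_image()] reproduces the pixel grid
#' bit for bit.
#'
#' @param image A [field_image()].
#' @param path Output path ending in `.tif`, `.tiff`, or `.png`.
#' @return `path`, invisibly.
#' @export
write_field_image <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  maxval <- 2^image$bit_depth - 1
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels / maxval, path,
                    bits.per.sample = image$bit_depth)
  } else if (ext == "png") {
    png::writePNG(image$pixels / maxval, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Load a plate manifest
#'
#' A manifest maps image files to their position in the screen: experiment,
#' well, field, compound, concentration (with unit), timepoint and control
#' flag. Concentrations are converted to nanomolar, the canonical unit.
#'
#' @param path CSV file with columns `experiment_id, well_id, field_index,
#'   compound, concentration, unit, timepoint, image_path, is_control`.
#' @return A data frame with one row per field image, concentrations in a
#'   `concentration_nM` column, sorted by (experiment, well, field).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("experiment_id", "well_id", "field_index", "compound",
                "concentration", "unit", "timepoint", "image_path", "is_control")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(man) == 0L) {
    man$concentration_nM <- numeric(0)
    return(man[, c(required[required != "concentration"], "concentration_nM")])
  }
  conc <- suppressWarnings(as.numeric(man$concentration))
  if (anyNA(conc)) stop("unparseable concentration in manifest row(s): ",
                        paste(which(is.na(conc)), collapse = ", "))
  fac <- .unit_to_nM[trimws(man$unit)]
  if (anyNA(fac)) stop("unknown concentration unit(s): ",
                       paste(unique(man$unit[is.na(fac)]), collapse = ", "))
  man$concentration_nM <- conc * unname(fac)
  man$is_control <- as.logical(man$is_control)
  man$field_index <- as.integer(man$field_index)
  key <- paste(man$experiment_id, man$well_id, man$field_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (experiment, well, field) key(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  if (any(man$is_control & man$concentration_nM != 0))
    stop("control rows must have concentration 0")
  man <- man[order(man$experiment_id, man$well_id, man$field_index), ]
  rownames(man) <- NULL
  man[, c("experiment_id", "well_id", "field_index", "compound",
          "concentration_nM", "timepoint", "image_path", "is_control")]
}

#' Names of the 15 per-crystal descriptors
#'
#' Six shape, five intensity and four gray-level co-occurrence texture
#' features, in the canonical column order used throughout the package.
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("area", "perimeter", "major_axis", "minor_axis", "eccentricity",
    "circularity", "mean_intensity", "intensity_variance", "min_intensity",
    "max_intensity", "intensity_spread", "glcm_correlation", "glcm_contrast",
    "glcm_homogeneity", "glcm_energy")
}

#' Write / read a per-crystal table
#'
#' One row per crystal: identifiers, acquisition metadata, the 15 features,
#' and (optionally) the class label, restricted to the vocabulary
#' 0 = COM, 1 = COD, 2 = not defined, 3 = background noise. The round trip
#' write -> read reproduces every value to full double precision.
#'
#' @param crystals Data frame as produced by the feature/classification
#'   modules; must contain the 15 feature columns.
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_crystal_table <- function(crystals, path) {
  stopifnot(is.data.frame(crystals))
  feat <- intersect(feature_names(), names(crystals))
  if (nrow(crystals) > 0 && length(feat) < 15L)
    stop("crystal table is missing feature column(s): ",
         paste(setdiff(feature_names(), feat), collapse = ", "))
  if ("class" %in% names(crystals) && nrow(crystals) > 0) {
    if (!all(crystals$class %in% 0:3))
      stop("class labels must be in {0, 1, 2, 3}")
  }
  num <- vapply(crystals, is.numeric, logical(1))
  out <- crystals
  # full-precision text round trip
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_crystal_table
#' @export
read_crystal_table <- function(path) {
  if (!file.exists(path)) stop("crystal table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c(feature_names(), "class", "segment_id", "pixel_area",
                         "concentration_nM", "field_index", "truth_instance"),
                       names(tab)))
    tab[[nm]] <- as.numeric(tab[[nm]])
  if ("class" %in% names(tab)) tab$class <- as.integer(tab$class)
  if ("field_index" %in% names(tab)) tab$field_index <- as.integer(tab$field_index)
  if ("segment_id" %in% names(tab)) tab$segment_id <- as.integer(tab$segment_id)
  tab
}

#' Write a QC overlay of segment contours colored by class
#'
#' Diagnostic only: paints segment boundaries over the grayscale field,
#' green = COM, blue = COD, orange = not defined, red = noise.
#'
#' @param image A [field_image()].
#' @param labels Integer label matrix from [segment_crystals()].
#' @param classes Integer vector of class codes, one per label (0..3), or
#'   `NULL` for uncolored contours.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, labels, classes = NULL, path) {
  stopifnot(inherits(image, "field_image"), is.matrix(labels))
  g <- image$pixels / (2^image$bit_depth - 1)
  rgb <- array(rep(g, 3L), dim = c(dim(g), 3L))
  cols <- rbind(c(0, 0.8, 0), c(0.1, 0.3, 1), c(1, 0.6, 0), c(1, 0, 0))
  # contour = labelled pixel with a differently-labelled 4-neighbour
  pad <- cbind(0L, rbind(0L, labels, 0L), 0L)
  n <- nrow(pad); m <- ncol(pad)
  core <- pad[2:(n - 1), 2:(m - 1)]
  edge <- core > 0 & (core != pad[1:(n - 2), 2:(m - 1)] |
                      core != pad[3:n, 2:(m - 1)] |
                      core != pad[2:(n - 1), 1:(m - 2)] |
                      core != pad[2:(n - 1), 3:m])
  idx <- which(edge)
  if (length(idx)) {
    cls <- if (is.null(classes)) rep(0L, max(labels)) else as.integer(classes)
    ci <- cls[core[idx]] + 1L
    npix <- length(g)
    for (ch in 1:3) rgb[idx + (ch - 1L) * npix] <- cols[ci, ch]
  }
  png::writePNG(rgb, path)
  invisible(path)
}
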