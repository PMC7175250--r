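# Full synthetic dose series: the plate layout of the screening assay
# (N experiments x conditions x wells x fields per well) with per-
# concentration effect functions that emulate inhibitor action — reduction
# of total crystallization, shrinking COM, a COM-to-COD proportion shift and
# COD needle elongation. The realized ground truth makes every downstream
# quantity (normalized areas, MICs) computable exactly without the pipeline.

#' Specification of a synthetic dose series
#'
#' Effect vectors are aligned with `concentrations_nM`; scale-type factors
#' lie in `[0, 1]` (1 = control behaviour), elongation is >= 1. Layout
#' defaults follow the screening assay: 3 independent experiments, 2 wells
#' per sample, 5 fields per well.
#'
#' @param concentrations_nM Tested concentration grid (nM), ascending.
#' @param total_scale Fraction of control crystal formation (scales COM,
#'   COD and n.d. counts) at each concentration.
#' @param com_size_scale Multiplier on the mean COM length.
#' @param com_to_cod_shift Fraction of would-be COM crystals that appear as
#'   COD instead (polymorph shift).
#' @param cod_elongation COD needle-elongation factor, >= 1.
#' @param n_experiments,wells_per_sample,fields_per_well Plate layout.
#' @param compound Compound name written into the manifest.
#' @param base_spec A [scene_spec()] giving the control per-field object
#'   counts and appearance; its seed is ignored (scene seeds derive from
#'   `seed`).
#' @param experiment_sdlog Lognormal sdlog of the per-experiment
#'   crystallization multiplier (inter-experimental variability that
#'   in-experiment normalization must remove).
#' @param seed Master seed; all scenes derive from it.
#' @return A `dose_series_spec` object.
#' @export
dose_series_spec <- function(concentrations_nM = c(100, 300, 1000, 3000),
                             total_scale = c(0.9, 0.5, 0.15, 0.01),
                             com_size_scale = c(1, 0.9, 0.75, 0.6),
                             com_to_cod_shift = c(0, 0.1, 0.25, 0.4),
                             cod_elongation = c(1, 1.1, 1.3, 1.6),
                             n_experiments = 3L, wells_per_sample = 2L,
                             fields_per_well = 5L, compound = "cmpdA",
                             base_spec = scene_spec(),
                             experiment_sdlog = 0.15, seed = 1L) {
  k <- length(concentrations_nM)
  stopifnot(k >= 1, !is.unsorted(concentrations_nM), all(concentrations_nM > 0),
            length(total_scale) == k, length(com_size_scale) == k,
            length(com_to_cod_shift) == k, length(cod_elongation) == k,
            all(total_scale >= 0 & total_scale <= 1),
            all(com_size_scale >= 0 & com_size_scale <= 1),
            all(com_to_cod_shift >= 0 & com_to_cod_shift <= 1),
            all(cod_elongation >= 1),
            n_experiments >= 1, wells_per_sample >= 1, fields_per_well >= 1,
            inherits(base_spec, "scene_spec"))
  structure(as.list(environment())[c("concentrations_nM", "total_scale",
                                     "com_size_scale", "com_to_cod_shift",
                                     "cod_elongation", "n_experiments",
                                     "wells_per_sample", "fields_per_well",
                                     "compound", "base_spec",
                                     "experiment_sdlog", "seed")],
            class = "dose_series_spec")
}

#' Generate a full synthetic dose series with ground truth
#'
#' Renders every field of the plate layout. Object counts per field are the
#' deterministic rounded product of the control counts, the concentration's
#' `total_scale`, and a random per-experiment multiplier (so the ground-truth
#' normalized series within an experiment tracks the effect function
#' closely); sizes, orientations and placements are random under the master
#' seed, and regeneration with the same spec is bit-exact.
#'
#' @param spec A [dose_series_spec()].
#' @param out_dir If non-NULL, images (16-bit TIFF), `manifest.csv` and
#'   `truth.csv` are also written there.
#' @return List: `manifest` (one row per field: experiment, well, field,
#'   compound, concentration_nM, is_control, scene index, image_path),
#'   `scenes` (list of [render_scene()] results, indexed by the manifest's
#'   `scene` column), and `spec`.
#' @export
generate_dose_series <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "dose_series_spec"))
  base <- spec$base_spec
  conc_all <- c(0, spec$concentrations_nM)
  eff <- data.frame(concentration_nM = conc_all,
                    total_scale = c(1, spec$total_scale),
                    com_size_scale = c(1, spec$com_size_scale),
                    com_to_cod_shift = c(0, spec$com_to_cod_shift),
                    cod_elongation = c(1, spec$cod_elongation))
  rows <- list(); scenes <- list(); sid <- 0L
  .with_seed(spec$seed, {
    for (e in seq_len(spec$n_experiments)) {
      mult <- stats::rlnorm(1, 0, spec$experiment_sdlog)
      for (j in seq_len(nrow(eff))) {
        n_com0 <- base$n_com * eff$total_scale[j] * mult
        n_com <- max(0L, round(n_com0 * (1 - eff$com_to_cod_shift[j])))
        n_cod <- max(0L, round(base$n_cod * eff$total_scale[j] * mult +
                                 n_com0 * eff$com_to_cod_shift[j]))
        n_nd <- max(0L, round(base$n_nd * eff$total_scale[j] * mult))
        for (w in seq_len(spec$wells_per_sample)) {
          for (f in seq_len(spec$fields_per_well)) {
            sid <- sid + 1L
            ssp <- base
            ssp$n_com <- n_com; ssp$n_cod <- n_cod; ssp$n_nd <- n_nd
            ssp$com_length_um <- base$com_length_um * eff$com_size_scale[j]
            ssp$cod_elongation <- eff$cod_elongation[j]
            ssp$seed <- .derive_seed(spec$seed, sid)
            meta <- acquisition_meta(
              experiment_id = sprintf("E%d", e),
              well_id = sprintf("c%02d_w%d", j, w),
              field_index = f,
              compound = if (j == 1L) "control" else spec$compound,
              concentration_nM = eff$concentration_nM[j],
              timepoint_h = 7,
              is_control = j == 1L)
            scenes[[sid]] <- render_scene(ssp, meta = meta)
            rows[[sid]] <- data.frame(
              experiment_id = meta$experiment_id, well_id = meta$well_id,
              field_index = f,
              compound = meta$compound,
              concentration_nM = meta$concentration_nM,
              is_control = meta$is_control, scene = sid,
              image_path = sprintf("E%d_%s_f%d.tif", e, meta$well_id, f))
          }
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  out <- list(manifest = manifest, scenes = scenes, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest)))
      write_field_image(scenes[[manifest$scene[i]]]$image,
                        file.path(out_dir, manifest$image_path[i]))
    man <- manifest
    man$concentration <- man$concentration_nM
    man$unit <- "nM"
    man$timepoint <- 7
    utils::write.csv(man[, c("experiment_id", "well_id", "field_index",
                             "compound", "concentration", "unit", "timepoint",
                             "image_path", "is_control")],
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
    tr <- do.call(rbind, lapply(seq_along(scenes), function(i)
      cbind(scene = i, scenes[[i]]$truth$instances)))
    utils::write.csv(tr, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  out
}

#' Ground-truth normalized area series of a generated dose series
#'
#' Computes, from the ground-truth instances alone (no segmentation or
#' classification), the per-condition crystal total (classes COM, COD,
#' n.d.) and COM areas normalized to the in-experiment control — the oracle
#' against which the pipeline's output is compared.
#'
#' @param series Output of [generate_dose_series()].
#' @return Data frame per (experiment_id, concentration_nM):
#'   `normalized_total`, `normalized_COM` (percent of control).
#' @export
truth_normalized_series <- function(series) {
  man <- series$manifest
  tot <- com <- numeric(nrow(man))
  for (i in seq_len(nrow(man))) {
    inst <- series$scenes[[man$scene[i]]]$truth$instances
    tot[i] <- sum(inst$area[inst$class %in% 0:2])
    com[i] <- sum(inst$area[inst$class == 0L])
  }
  key <- unique(man[, c("experiment_id", "concentration_nM")])
  key <- key[order(key$experiment_id, key$concentration_nM), ]
  rownames(key) <- NULL
  key$total_area <- NA_real_; key$com_area <- NA_real_
  for (i in seq_len(nrow(key))) {
    sel <- man$experiment_id == key$experiment_id[i] &
      man$concentration_nM == key$concentration_nM[i]
    key$total_area[i] <- sum(tot[sel])
    key$com_area[i] <- sum(com[sel])
  }
  key$normalized_total <- NA_real_; key$normalized_COM <- NA_real_
  for (ex in unique(key$experiment_id)) {
    sel <- key$experiment_id == ex
    denom <- key$total_area[sel & key$concentration_nM == 0]
    key$normalized_total[sel] <- 100 * key$total_area[sel] / denom
    key$normalized_COM[sel] <- 100 * key$com_area[sel] / denom
  }
  key
}

#' Build the labeled synthetic training fixture
#'
#' Emulates the screen's training set: crystals spread over 13 images of
#' varying conditions (per-image size, illumination and focus jitter), with
#' class imbalance favouring COM and COD. Each image is rendered with
#' non-touching objects, segmented, featurized, and every segment labeled
#' with the class of its ground-truth instance (unmatched segments get the
#' background-noise class).
#'
#' @param n_crystals Target size of the labeled training table (default
#'   1710). The rendered scenes contain ~6% more ground-truth objects than
#'   this to offset the detection shortfall of small, faint debris, so under
#'   default settings the returned table has at least `n_crystals` rows.
#' @param seed Master seed.
#' @param n_images Number of training images (default 13).
#' @param image_size,pixel_size Field geometry.
#' @param proportions Class proportions (COM, COD, n.d., noise); each class
#'   is floored at 5 examples so fivefold CV is always stratifiable.
#' @param seg_params [segmentation_params()] used to segment the fixture.
#' @return Labeled crystal table: `image_id`, `segment_id`, the 15
#'   [feature_names()] columns, `class` (ground-truth derived),
#'   `truth_instance`.
#' @export
make_training_fixture <- function(n_crystals = 1710L, seed = 1L,
                                  n_images = 13L, image_size = 896L,
                                  pixel_size = 0.32,
                                  proportions = c(0.42, 0.26, 0.17, 0.15),
                                  seg_params = segmentation_params()) {
  stopifnot(n_crystals >= 20, n_images >= 1, length(proportions) == 4,
            all(proportions > 0))
  proportions <- proportions / sum(proportions)
  # over-populate by ~6% against detection losses, and floor each class at 7
  # rendered objects so at least 5 survive segmentation for stratified CV
  n_render <- max(ceiling(n_crystals * 1.06), 28L)
  counts <- .apportion(n_render, proportions, minimum = 7L)
  tabs <- vector("list", n_images)
  .with_seed(seed, {
    cls <- sample(rep(0:3, counts))
    chunk <- rep(seq_len(n_images), length.out = length(cls))
    chunk <- sort(chunk)
    for (i in seq_len(n_images)) {
      ci <- cls[chunk == i]
      ssp <- scene_spec(
        image_size = image_size, pixel_size = pixel_size,
        n_com = sum(ci == 0L), n_cod = sum(ci == 1L),
        n_nd = sum(ci == 2L), n_noise = sum(ci == 3L),
        com_length_um = 10 * stats::runif(1, 0.85, 1.15),
        cod_length_um = 20 * stats::runif(1, 0.85, 1.15),
        cod_elongation = sample(c(1, 1, 1, 1.4), 1),   # needle images occur
        overlap_probability = 0,                        # annotated singles
        seed = .derive_seed(seed, i))
      sc <- render_scene(ssp)
      seg <- segment_crystals(sc$image, seg_params)
      fe <- extract_features(sc$image, seg$labels, seg$segments)
      mt <- match_segments_to_truth(seg$labels, sc$truth)
      tabs[[i]] <- cbind(data.frame(image_id = sprintf("train_%02d", i)),
                         fe, class = mt$class,
                         truth_instance = mt$truth_instance)
    }
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

# largest-remainder apportionment with a per-class floor
.apportion <- function(n, p, minimum = 0L) {
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(n * p - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  while (any(base < minimum)) {
    i <- which.min(base); j <- which.max(base)
    base[i] <- base[i] + 1L; base[j] <- base[j] - 1L
  }
  as.integer(base)
}
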