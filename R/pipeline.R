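# End-to-end glue: field image -> segments -> features -> classes ->
# per-condition quantification and MIC calls.

#' Segment and featurize one field of view
#'
#' @param image A [field_image()] (its [acquisition_meta()] is propagated
#'   into the output columns).
#' @param seg_params [segmentation_params()].
#' @return Crystal table: acquisition key columns, `segment_id`,
#'   `pixel_area`, `area` and the 15 [feature_names()] columns.
#' @export
analyze_field <- function(image, seg_params = segmentation_params()) {
  seg <- segment_crystals(image, seg_params)
  fe <- extract_features(image, seg$labels, seg$segments)
  meta <- image$meta
  n <- nrow(fe)
  cbind(data.frame(experiment_id = rep(meta$experiment_id, n),
                   well_id = rep(meta$well_id, n),
                   field_index = rep(meta$field_index, n),
                   compound = rep(meta$compound, n),
                   concentration_nM = rep(meta$concentration_nM, n),
                   is_control = rep(meta$is_control, n),
                   segment_id = seg$segments$segment_id,
                   pixel_area = seg$segments$pixel_area),
        fe[, feature_names(), drop = FALSE])
}

#' Run the full screening pipeline on a generated dose series
#'
#' Segments and featurizes every field, classifies crystals with the given
#' model, aggregates class areas per condition, normalizes to the
#' in-experiment controls, and calls the minimal inhibitory concentrations
#' at the threshold rule.
#'
#' @param series Output of [generate_dose_series()].
#' @param model A trained `crystal_classifier`.
#' @param seg_params [segmentation_params()].
#' @param threshold MIC threshold as a fraction of control (default 0.05).
#' @return List: `crystals` (labeled table), `quants`, `normalized`,
#'   `inhibition` (an `inhibition_result` for the series' compound).
#' @export
screen_dose_series <- function(series, model,
                               seg_params = segmentation_params(),
                               threshold = 0.05) {
  man <- series$manifest
  tabs <- lapply(seq_len(nrow(man)), function(i)
    analyze_field(series$scenes[[man$scene[i]]]$image, seg_params))
  crystals <- do.call(rbind, tabs)
  crystals$class <- classify(model, crystals)
  quants <- quantify_wells(crystals, man)
  normalized <- normalize_to_control(quants)
  inhibition <- inhibition_result(normalized, series$spec$compound,
                                  threshold = threshold)
  list(crystals = crystals, quants = quants, normalized = normalized,
       inhibition = inhibition)
}
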