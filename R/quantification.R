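# Dose-response quantification: per-condition class areas summed over a
# sample's fields of view, normalized to the in-experiment no-inhibitor
# control, and minimal inhibitory concentrations called at the 5% rule
# (lowest tested concentration whose mean normalized area falls strictly
# below 5% of control). The noise class is tracked but excluded from the
# crystal total; the crystal total is COM + COD + n.d.

.class_cols <- c(COM = 0L, COD = 1L, ND = 2L, noise = 3L)

#' Aggregate labeled crystals into per-condition class areas
#'
#' Sums area and counts per class for every (experiment, compound,
#' concentration) condition over all of its fields of view (the layout unit
#' being wells x fields per well).
#'
#' @param crystals Labeled crystal table: columns `experiment_id`,
#'   `well_id`, `field_index`, `compound`, `concentration_nM`, `area` (µm²)
#'   and `class` (0..3, no NA).
#' @param manifest Optional manifest data frame (from [load_manifest()] or
#'   [generate_dose_series()]); supplies the true number of fields per
#'   condition so that fields without any detected crystal still count.
#' @return Data frame keyed by (experiment_id, compound, concentration_nM)
#'   with `total_area_<class>`, `count_<class>`, `mean_area_per_field_<class>`
#'   for COM/COD/ND/noise, `crystal_total_area` (COM + COD + n.d.), and
#'   `n_fields`.
#' @export
quantify_wells <- function(crystals, manifest = NULL) {
  stopifnot(is.data.frame(crystals))
  need <- c("experiment_id", "compound", "concentration_nM", "area", "class")
  miss <- setdiff(need, names(crystals))
  if (length(miss)) stop("crystal table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(crystals) && anyNA(crystals$class))
    stop("unlabeled segment(s): classify before quantifying")
  if (nrow(crystals) && !all(crystals$class %in% 0:3))
    stop("class labels must be in {0,1,2,3}")
  src <- if (!is.null(manifest)) manifest else crystals
  key <- unique(src[, c("experiment_id", "compound", "concentration_nM")])
  key <- key[order(key$experiment_id, key$compound, key$concentration_nM), ]
  rownames(key) <- NULL
  nf <- function(d) {
    if (all(c("well_id", "field_index") %in% names(d)))
      nrow(unique(d[, c("well_id", "field_index")]))
    else NA_integer_
  }
  out <- key
  for (cl in names(.class_cols)) {
    out[[paste0("total_area_", cl)]] <- 0
    out[[paste0("count_", cl)]] <- 0L
  }
  out$n_fields <- NA_integer_
  for (i in seq_len(nrow(key))) {
    sel <- crystals$experiment_id == key$experiment_id[i] &
      crystals$compound == key$compound[i] &
      crystals$concentration_nM == key$concentration_nM[i]
    sub <- crystals[sel, , drop = FALSE]
    msel <- src$experiment_id == key$experiment_id[i] &
      src$compound == key$compound[i] &
      src$concentration_nM == key$concentration_nM[i]
    out$n_fields[i] <- nf(src[msel, , drop = FALSE])
    for (cl in names(.class_cols)) {
      v <- sub$area[sub$class == .class_cols[[cl]]]
      out[[paste0("total_area_", cl)]][i] <- sum(v)
      out[[paste0("count_", cl)]][i] <- length(v)
    }
  }
  for (cl in names(.class_cols))
    out[[paste0("mean_area_per_field_", cl)]] <-
      out[[paste0("total_area_", cl)]] / out$n_fields
  out$crystal_total_area <- out$total_area_COM + out$total_area_COD +
    out$total_area_ND
  out
}

#' Normalize condition totals to the in-experiment control
#'
#' Expresses each condition's crystal total (COM + COD + n.d. area) as a
#' percentage of the same experiment's no-inhibitor control; normalization
#' never pools across experiments, which removes inter-experimental
#' variability in absolute crystallization. `normalized_COM` and
#' `normalized_COD` are, by default, the class areas relative to the
#' control's *total* crystal area (the literal reading of the 5% rule for
#' COM-only inhibition); set `com_denominator = "class"` to normalize each
#' class to the control's same-class area instead.
#'
#' @param quants Output of [quantify_wells()].
#' @param com_denominator `"total"` (default) or `"class"`.
#' @return `quants` with `normalized_total`, `normalized_COM`,
#'   `normalized_COD` columns (percent; each experiment's control is exactly
#'   100).
#' @export
normalize_to_control <- function(quants, com_denominator = c("total", "class")) {
  com_denominator <- match.arg(com_denominator)
  stopifnot(is.data.frame(quants), "crystal_total_area" %in% names(quants))
  out <- quants
  out$normalized_total <- NA_real_
  out$normalized_COM <- NA_real_
  out$normalized_COD <- NA_real_
  for (ex in unique(quants$experiment_id)) {
    sel <- quants$experiment_id == ex
    ctrl <- sel & quants$concentration_nM == 0
    if (!any(ctrl))
      stop("experiment ", ex, " has no control (concentration 0) condition")
    if (sum(ctrl) > 1L)
      stop("experiment ", ex, " has multiple control conditions")
    denom <- quants$crystal_total_area[ctrl]
    if (!is.finite(denom) || denom <= 0)
      stop("experiment ", ex, " control has zero crystal area; cannot normalize")
    out$normalized_total[sel] <- 100 * quants$crystal_total_area[sel] / denom
    dcom <- if (com_denominator == "total") denom else quants$total_area_COM[ctrl]
    dcod <- if (com_denominator == "total") denom else quants$total_area_COD[ctrl]
    out$normalized_COM[sel] <- 100 * quants$total_area_COM[sel] /
      max(dcom, .Machine$double.xmin)
    out$normalized_COD[sel] <- 100 * quants$total_area_COD[sel] /
      max(dcod, .Machine$double.xmin)
  }
  out
}

#' Format a nanomolar concentration the way screen reports print it
#' @param nM Concentration in nanomolar.
#' @return e.g. `"40 nM"`, `"3 µM"`.
#' @export
format_concentration <- function(nM) {
  ifelse(nM >= 1000, paste0(format(nM / 1000, trim = TRUE), " µM"),
         paste0(format(nM, trim = TRUE), " nM"))
}

#' Minimal inhibitory concentration at the 5% rule
#'
#' The lowest tested concentration whose mean normalized area lies strictly
#' below the threshold; if none does, the sentinel "not reached" with the
#' label `"> <max tested>"`. Concentrations are never interpolated: the MIC
#' is always a member of the tested grid.
#'
#' @param concentrations_nM Tested concentrations (nM), need not be sorted;
#'   the control (0) is ignored if present.
#' @param mean_normalized Mean normalized areas (percent of control), same
#'   order as `concentrations_nM`.
#' @param threshold Fraction of control (default 0.05, i.e. 5%).
#' @return List: `reached` (logical), `concentration_nM` (NA when not
#'   reached), `label` (formatted, e.g. `"1 µM"` or `"> 100 µM"`),
#'   `threshold`.
#' @export
min_inhibitory_concentration <- function(concentrations_nM, mean_normalized,
                                         threshold = 0.05) {
  if (length(concentrations_nM) != length(mean_normalized))
    stop("concentration and mean vectors must have equal length")
  keep <- concentrations_nM > 0
  concentrations_nM <- concentrations_nM[keep]
  mean_normalized <- mean_normalized[keep]
  if (!length(concentrations_nM)) stop("empty concentration series")
  o <- order(concentrations_nM)
  concentrations_nM <- concentrations_nM[o]
  mean_normalized <- mean_normalized[o]
  below <- which(mean_normalized < threshold * 100)
  if (length(below)) {
    mic <- concentrations_nM[min(below)]
    list(reached = TRUE, concentration_nM = mic,
         label = format_concentration(mic), threshold = threshold)
  } else {
    list(reached = FALSE, concentration_nM = NA_real_,
         label = paste0("> ", format_concentration(max(concentrations_nM))),
         threshold = threshold)
  }
}

#' Dose-response summary and MIC calls for one compound
#'
#' Averages the normalized areas across experiments at each tested
#' concentration and calls the minimal concentrations for complete
#' inhibition (COM + COD + n.d. total < threshold) and COM-only inhibition
#' (COM area < threshold, relative to the control total by default, see
#' [normalize_to_control()]).
#'
#' @param normalized Output of [normalize_to_control()], possibly spanning
#'   several experiments; rows of other compounds are ignored.
#' @param compound Compound name to summarize.
#' @param threshold Fraction of control (default 0.05).
#' @param per_experiment If `TRUE`, MICs are called per experiment and then
#'   averaged (NA if any experiment never reaches the threshold) instead of
#'   the default call on the across-experiment mean series.
#' @return An `inhibition_result` list: `compound`, `threshold`, `series`
#'   (data frame: concentration, mean and sd of normalized total/COM/COD,
#'   number of experiments), `MIC_complete`, `MIC_COM` (each a
#'   [min_inhibitory_concentration()] result).
#' @export
inhibition_result <- function(normalized, compound, threshold = 0.05,
                              per_experiment = FALSE) {
  sel <- normalized$compound == compound & normalized$concentration_nM > 0
  if (!any(sel)) stop("no tested concentrations for compound ", compound)
  sub <- normalized[sel, , drop = FALSE]
  agg <- function(col, f) tapply(sub[[col]], sub$concentration_nM, f)
  conc <- sort(unique(sub$concentration_nM))
  series <- data.frame(
    concentration_nM = conc,
    mean_normalized_total = as.numeric(agg("normalized_total", mean)[as.character(conc)]),
    sd_normalized_total = as.numeric(agg("normalized_total", stats::sd)[as.character(conc)]),
    mean_normalized_COM = as.numeric(agg("normalized_COM", mean)[as.character(conc)]),
    sd_normalized_COM = as.numeric(agg("normalized_COM", stats::sd)[as.character(conc)]),
    mean_normalized_COD = as.numeric(agg("normalized_COD", mean)[as.character(conc)]),
    n_experiments = as.integer(agg("normalized_total", length)[as.character(conc)]))
  if (per_experiment) {
    mic_of <- function(col) {
      per <- vapply(split(sub, sub$experiment_id), function(d)
        min_inhibitory_concentration(d$concentration_nM, d[[col]],
                                     threshold)$concentration_nM,
        numeric(1))
      if (anyNA(per))
        list(reached = FALSE, concentration_nM = NA_real_,
             label = paste0("> ", format_concentration(max(conc))),
             threshold = threshold)
      else list(reached = TRUE, concentration_nM = mean(per),
                label = format_concentration(mean(per)), threshold = threshold)
    }
    mic_c <- mic_of("normalized_total")
    mic_m <- mic_of("normalized_COM")
  } else {
    mic_c <- min_inhibitory_concentration(series$concentration_nM,
                                          series$mean_normalized_total, threshold)
    mic_m <- min_inhibitory_concentration(series$concentration_nM,
                                          series$mean_normalized_COM, threshold)
  }
  structure(list(compound = compound, threshold = threshold, series = series,
                 MIC_complete = mic_c, MIC_COM = mic_m),
            class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("<inhibition_result> %s (threshold %.0f%% of control)\n",
              x$compound, 100 * x$threshold))
  print(x$series, digits = 3)
  cat("MIC complete:", x$MIC_complete$label,
      "| MIC COM-only:", x$MIC_COM$label, "\n")
  invisible(x)
}

#' Pooled single-crystal COM size distribution per condition
#'
#' Pools the areas of single COM-class crystals over all experiments, wells
#' and fields of each (compound, concentration) condition — the input for
#' crystal-size distribution plots, where a dose-dependent reduction in COM
#' size indicates growth inhibition.
#'
#' @param crystals Labeled crystal table (see [quantify_wells()]).
#' @return List with `summary` (data frame per condition: `compound`,
#'   `concentration_nM`, `n`, `n_experiments`, quartiles of area) and
#'   `areas` (named list of pooled area vectors, µm²).
#' @export
com_size_distribution <- function(crystals) {
  com <- crystals[!is.na(crystals$class) & crystals$class == 0L, , drop = FALSE]
  key <- unique(com[, c("compound", "concentration_nM")])
  key <- key[order(key$compound, key$concentration_nM), , drop = FALSE]
  rownames(key) <- NULL
  areas <- list()
  summ <- key
  summ$n <- 0L; summ$n_experiments <- 0L
  summ$q25 <- summ$median <- summ$q75 <- NA_real_
  for (i in seq_len(nrow(key))) {
    sub <- com[com$compound == key$compound[i] &
                 com$concentration_nM == key$concentration_nM[i], , drop = FALSE]
    a <- sub$area
    nm <- paste0(key$compound[i], "@", key$concentration_nM[i])
    areas[[nm]] <- a
    summ$n[i] <- length(a)
    summ$n_experiments[i] <- length(unique(sub$experiment_id))
    if (length(a)) {
      q <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
      summ$q25[i] <- q[1]; summ$median[i] <- q[2]; summ$q75[i] <- q[3]
    }
  }
  list(summary = summ, areas = areas)
}
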