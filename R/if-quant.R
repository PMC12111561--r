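#' Fill enclosed vessel lumina in an endothelial mask
#'
#' The plain endothelial (RECA1) area fraction underestimates the vascular
#' volume because capillary lumina are unstained. This operation adds to
#' the mask every background component that is fully enclosed by foreground
#' (does not touch the image border) and whose area does not exceed
#' `max_hole_area` pixels — a bounded hole fill at the capillary-lumen
#' scale. The result always contains the input (monotone) and refilling
#' changes nothing (idempotent).
#'
#' @param vessel_mask a `binary_mask` or logical matrix.
#' @param max_hole_area largest lumen area (pixels) that will be filled;
#'   default 2000 px, roughly the capillary lumen scale at 400x.
#' @return A `binary_mask` with lumina filled.
#' @export
fill_lumina <- function(vessel_mask, max_hole_area = 2000) {
  if (max_hole_area <= 0) stop_quant("'max_hole_area' must be > 0")
  m <- as_mask(vessel_mask)
  # background components under 4-connectivity (complement of 8-connected
  # foreground); those not touching the border are holes
  bg_lab <- label_components(!m, connectivity = 4)
  if (max(bg_lab) > 0L) {
    border_labels <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                              bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
    border_labels <- border_labels[border_labels > 0L]
    sizes <- tabulate(bg_lab[bg_lab > 0L])
    fill <- setdiff(which(sizes <= max_hole_area), border_labels)
    if (length(fill)) m[bg_lab %in% fill] <- TRUE
  }
  out <- if (inherits(vessel_mask, "binary_mask")) vessel_mask else binary_mask(m)
  out$mask <- m
  out
}

#' Remove nuclear areas from a marker mask
#'
#' Subtracts the DAPI (nuclear) mask from the marker mask, leaving only the
#' cytoplasmic marker signal: `marker \ dapi`.
#'
#' @param marker_mask,dapi_mask `binary_mask` objects or logical matrices of
#'   equal shape.
#' @return A `binary_mask` of the cytoplasmic marker signal.
#' @export
cytoplasmic_marker_mask <- function(marker_mask, dapi_mask) {
  m <- as_mask(marker_mask); d <- as_mask(dapi_mask)
  if (!identical(dim(m), dim(d))) stop_quant("masks must share the same shape")
  binary_mask(m & !d, source_channel = "marker")
}

#' Normalised RECA1 peritubular capillary score
#'
#' The lumen-filled endothelial area fraction divided by the pancytokeratin
#' area fraction of the same section, giving a dimensionless capillary
#' density score that accounts for the tissue content of the field.
#'
#' @param filled_vascular_fraction lumen-filled RECA1-positive area fraction
#'   of the section, in \[0,1\].
#' @param pancytokeratin_fraction pancytokeratin-positive area fraction,
#'   must be > 0 (a section without epithelium is unusable).
#' @return The score (dimensionless).
#' @export
normalized_reca1 <- function(filled_vascular_fraction, pancytokeratin_fraction) {
  check_fraction(filled_vascular_fraction, "filled_vascular_fraction")
  if (!is.numeric(pancytokeratin_fraction) || pancytokeratin_fraction <= 0)
    stop_quant("pancytokeratin_fraction must be > 0: section unusable")
  filled_vascular_fraction / pancytokeratin_fraction
}

#' Nuclear marker score (nuclear PGC-1alpha equation)
#'
#' Implements the per-section score
#' `[(total - cytoplasmic) / total] * [pancytokeratin / DAPI count]`.
#' The first factor is the nuclear co-localised share of the marker signal
#' (in \[0,1\], dimensionless and scale-invariant); the second normalises by
#' tissue content per cell. The score is returned together with the clean
#' first factor (`nuclear_share`), which is the quantity used for recovery
#' validation.
#'
#' @param total_marker_fraction total marker-positive area fraction (> 0).
#' @param cytoplasmic_marker_fraction marker-positive area fraction outside
#'   nuclei; must not exceed the total.
#' @param pancytokeratin_fraction pancytokeratin area fraction.
#' @param dapi_count nuclei count for the section (> 0).
#' @return A list with `score` and `nuclear_share`.
#' @export
nuclear_fraction_score <- function(total_marker_fraction,
                                   cytoplasmic_marker_fraction,
                                   pancytokeratin_fraction, dapi_count) {
  if (!is.numeric(total_marker_fraction) || total_marker_fraction <= 0)
    stop_quant("total_marker_fraction must be > 0: score undefined")
  if (cytoplasmic_marker_fraction < 0 ||
      cytoplasmic_marker_fraction > total_marker_fraction + 1e-12)
    stop_quant("cytoplasmic_marker_fraction must lie in [0, total_marker_fraction]")
  if (!is.numeric(dapi_count) || dapi_count <= 0)
    stop_quant("dapi_count must be > 0: score undefined")
  check_fraction(pancytokeratin_fraction, "pancytokeratin_fraction")
  share <- (total_marker_fraction - cytoplasmic_marker_fraction) /
    total_marker_fraction
  list(score = share * (pancytokeratin_fraction / dapi_count),
       nuclear_share = share)
}

#' Normalised COX4 score
#'
#' Same contract and arithmetic as [nuclear_fraction_score()], applied to
#' the COX4 (mitochondrial protein mass) channel.
#'
#' @inheritParams nuclear_fraction_score
#' @return A list with `score` and `nuclear_share`.
#' @export
normalized_cox4 <- function(total_marker_fraction, cytoplasmic_marker_fraction,
                            pancytokeratin_fraction, dapi_count) {
  nuclear_fraction_score(total_marker_fraction, cytoplasmic_marker_fraction,
                         pancytokeratin_fraction, dapi_count)
}

#' Fibrosis percentage
#'
#' @param fibrosis_area,tissue_area areas in pixels; fibrosis must not
#'   exceed the tissue area and tissue area must be > 0.
#' @return 100 * fibrosis_area / tissue_area.
#' @export
fibrosis_percent <- function(fibrosis_area, tissue_area) {
  if (any(tissue_area <= 0)) stop_quant("tissue_area must be > 0")
  if (any(fibrosis_area < 0) || any(fibrosis_area > tissue_area))
    stop_quant("fibrosis_area must lie in [0, tissue_area]")
  100 * fibrosis_area / tissue_area
}

#' Score one micrograph through the full image pipeline
#'
#' Runs correction, segmentation and scoring on a [micrograph()]:
#' each channel is background-corrected (when dark/flat frames are present),
#' thresholded (Otsu by default), and the marker score computed —
#' the normalised RECA1 ratio for `marker = "reca1"`, the nuclear-fraction
#' score otherwise.
#'
#' @param mg a [micrograph()].
#' @param marker one of `"reca1"`, `"pgc1a"`, `"cox4"`.
#' @param threshold_method `"otsu"` (default) or `"manual"`.
#' @param manual_values optional named list of per-channel manual thresholds.
#' @param max_hole_area lumen fill bound for RECA1 (see [fill_lumina()]).
#' @param min_nucleus_area minimum component area for the DAPI count.
#' @param correct_first logical; apply background correction before
#'   thresholding (default TRUE, recorded in the audit output).
#' @param exclusion_mask optional logical matrix of pixels to exclude (e.g.
#'   glomeruli for the RECA1 analysis); excluded pixels count neither as
#'   marker nor as tissue.
#' @return A one-row data.frame: area fractions, DAPI count, score (and
#'   `nuclear_share` for nuclear markers), thresholds used.
#' @export
quantify_micrograph <- function(mg, marker = c("pgc1a", "cox4", "reca1"),
                                threshold_method = c("otsu", "manual"),
                                manual_values = NULL,
                                max_hole_area = 2000,
                                min_nucleus_area = 5,
                                correct_first = TRUE,
                                exclusion_mask = NULL) {
  stopifnot(inherits(mg, "micrograph"))
  marker <- match.arg(marker)
  threshold_method <- match.arg(threshold_method)
  get_channel <- function(nm) {
    ch <- mg$channels[[nm]]
    if (correct_first && !is.null(mg$dark) && !is.null(mg$flat))
      ch <- background_correct(ch, mg$dark, mg$flat)
    ch
  }
  seg <- function(nm) {
    threshold_mask(get_channel(nm), method = threshold_method,
                   manual_value = manual_values[[nm]], source_channel = nm)
  }
  dapi <- seg("dapi"); pck <- seg("pancytokeratin"); mk <- seg("marker")
  keep <- if (is.null(exclusion_mask)) {
    matrix(TRUE, nrow(mk$mask), ncol(mk$mask))
  } else {
    if (!identical(dim(exclusion_mask), dim(mk$mask)))
      stop_quant("exclusion_mask must match the image shape")
    !exclusion_mask
  }
  npx <- sum(keep)
  if (npx == 0) stop_quant("exclusion_mask excludes the whole image")
  area_frac <- function(m) sum(as_mask(m) & keep) / npx
  e_frac <- area_frac(pck)
  res <- data.frame(marker = marker,
                    pancytokeratin_fraction = e_frac,
                    dapi_count = count_nuclei(dapi, min_area = min_nucleus_area),
                    threshold_dapi = dapi$threshold_value,
                    threshold_pancytokeratin = pck$threshold_value,
                    threshold_marker = mk$threshold_value,
                    corrected_first = correct_first,
                    stringsAsFactors = FALSE)
  # uniform schema across markers; inapplicable fields are NA
  res$total_marker_fraction <- area_frac(mk)
  res$cytoplasmic_marker_fraction <- NA_real_
  res$filled_vascular_fraction <- NA_real_
  if (marker == "reca1") {
    filled <- fill_lumina(mk, max_hole_area = max_hole_area)
    res$filled_vascular_fraction <- area_frac(filled)
    res$score <- normalized_reca1(res$filled_vascular_fraction, e_frac)
    res$nuclear_share <- NA_real_
  } else {
    cyto <- cytoplasmic_marker_mask(mk, dapi)
    res$cytoplasmic_marker_fraction <- area_frac(cyto)
    sc <- nuclear_fraction_score(res$total_marker_fraction,
                                 res$cytoplasmic_marker_fraction,
                                 e_frac, res$dapi_count)
    res$score <- sc$score
    res$nuclear_share <- sc$nuclear_share
  }
  res
}

#' Aggregate per-section scores to animal level
#'
#' Mean, SD and section count of the score per animal x region x marker.
#' Missing sections simply reduce `n`; nothing is imputed.
#'
#' @param records data.frame with columns `animal_id`, `region`, `marker`,
#'   `score` (one row per section).
#' @return data.frame with columns `animal_id`, `region`, `marker`,
#'   `mean_score`, `sd_score`, `n_sections`.
#' @export
aggregate_sections <- function(records) {
  need <- c("animal_id", "region", "marker", "score")
  if (!all(need %in% names(records)))
    stop_quant("records must have columns: %s", paste(need, collapse = ", "))
  if (nrow(records) == 0) stop_quant("no records to aggregate")
  key <- interaction(records$animal_id, records$region, records$marker,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(animal_id = d$animal_id[1], region = d$region[1],
               marker = d$marker[1],
               mean_score = mean(d$score),
               sd_score = if (nrow(d) > 1) stats::sd(d$score) else 0,
               n_sections = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$animal_id, agg$region, agg$marker), , drop = FALSE]
}

#' Fold changes versus the vehicle group's global average
#'
#' Per-animal marker scores expressed as fold changes over the global mean
#' of all vehicle-group sections of the same marker x region, so the
#' vehicle-group mean fold is 1 by construction.
#'
#' @param records data.frame with columns `animal_id`, `group`, `region`,
#'   `marker`, `score` (one row per section).
#' @param vehicle_group_ids character vector of group labels forming the
#'   vehicle (reference) arm.
#' @return data.frame with `animal_id`, `group`, `region`, `marker`,
#'   `mean_score`, `fold_change`.
#' @export
fold_change_vs_vehicle <- function(records, vehicle_group_ids) {
  need <- c("animal_id", "group", "region", "marker", "score")
  if (!all(need %in% names(records)))
    stop_quant("records must have columns: %s", paste(need, collapse = ", "))
  out <- list()
  for (rg in unique(records$region)) for (mk in unique(records$marker[records$region == rg])) {
    d <- records[records$region == rg & records$marker == mk, , drop = FALSE]
    veh <- d[d$group %in% vehicle_group_ids, , drop = FALSE]
    if (nrow(veh) == 0)
      stop_quant("no vehicle-group sections for marker %s / region %s", mk, rg)
    ref <- mean(veh$score)
    if (ref == 0) stop_quant("vehicle global average is 0 for %s / %s", mk, rg)
    per_animal <- do.call(rbind, lapply(split(d, d$animal_id, drop = TRUE), function(a) {
      data.frame(animal_id = a$animal_id[1], group = a$group[1],
                 region = rg, marker = mk,
                 mean_score = mean(a$score),
                 fold_change = mean(a$score) / ref, stringsAsFactors = FALSE)
    }))
    out[[paste(rg, mk)]] <- per_animal
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$region, res$marker, res$animal_id), , drop = FALSE]
}
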