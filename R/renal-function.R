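#' Kidney functional reserve
#'
#' KFR is the rise in glomerular filtration rate after a stimulus (oral
#' protein load): stimulated GFR minus unstimulated GFR, in mL/min.
#' Negative values are physiologically meaningful (a kidney unable to
#' recruit reserve) and are returned as-is; use [cohort_indices()] to get a
#' per-row negative-KFR flag.
#'
#' @param gfr_stimulated,gfr_unstimulated GFR in mL/min (finite; vectorised).
#' @return KFR in mL/min.
#' @export
kfr <- function(gfr_stimulated, gfr_unstimulated) {
  if (!all(is.finite(gfr_stimulated)) || !all(is.finite(gfr_unstimulated)))
    stop_quant("GFR values must be finite")
  gfr_stimulated - gfr_unstimulated
}

#' Creatinine clearance (UV/P)
#'
#' `CrCl = uCr * urine_flow / sCr` after harmonising both creatinine
#' concentrations to a common unit; the result is in the units of
#' `urine_flow` (mL/min). Units must be declared explicitly — there is no
#' silent guessing.
#'
#' @param ucr urinary creatinine concentration.
#' @param urine_flow urine flow in mL/min.
#' @param scr serum creatinine concentration (> 0).
#' @param ucr_unit,scr_unit `"umol/L"` or `"mmol/L"`.
#' @return Clearance in mL/min (vectorised).
#' @export
creatinine_clearance <- function(ucr, urine_flow, scr,
                                 ucr_unit = c("mmol/L", "umol/L"),
                                 scr_unit = c("umol/L", "mmol/L")) {
  ucr_unit <- match.arg(ucr_unit)
  scr_unit <- match.arg(scr_unit)
  to_umol <- c("umol/L" = 1, "mmol/L" = 1000)
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop_quant("scr must be finite and > 0")
  if (any(ucr < 0) || any(urine_flow < 0))
    stop_quant("ucr and urine_flow must be >= 0")
  (ucr * to_umol[[ucr_unit]] * urine_flow) / (scr * to_umol[[scr_unit]])
}

#' Urine flow from a timed collection
#'
#' The collection interval is a required input: it is never defaulted,
#' because a wrong assumed interval silently rescales every clearance.
#'
#' @param volume_ml collected urine volume in mL.
#' @param interval_min collection interval in minutes (required, > 0).
#' @return Flow in mL/min.
#' @export
urine_flow_from_collection <- function(volume_ml, interval_min) {
  if (missing(interval_min)) stop_quant("'interval_min' is required (no default)")
  check_positive(interval_min, "interval_min")
  if (any(volume_ml < 0)) stop_quant("volume_ml must be >= 0")
  volume_ml / interval_min
}

#' Normalise a urinary biomarker to urinary creatinine
#'
#' @param concentration biomarker concentration (>= 0).
#' @param ucr urinary creatinine (> 0), same sample.
#' @return concentration / uCr (units: concentration unit per uCr unit).
#' @export
normalize_biomarker <- function(concentration, ucr) {
  if (any(!is.finite(ucr)) || any(ucr <= 0)) stop_quant("ucr must be > 0")
  if (any(concentration < 0)) stop_quant("concentration must be >= 0")
  concentration / ucr
}

#' Physiology indices for a cohort table
#'
#' Adds KFR, creatinine clearance and uCr-normalised biomarkers to a
#' cohort table (one row per animal x timepoint, as produced by
#' [generate_cohort()] or read from CSV).
#'
#' @param cohort data.frame with columns `gfr_stimulated`,
#'   `gfr_unstimulated`, `scr`, `ucr`, `urine_flow` and biomarker columns.
#' @param biomarkers names of biomarker columns to normalise (default
#'   `ukim1`, `uclu`); each gains a `<name>_ucr` column.
#' @param ucr_unit,scr_unit declared creatinine units.
#' @return The cohort with added columns `kfr`, `kfr_negative` (flag),
#'   `crcl`, and `<biomarker>_ucr`.
#' @export
cohort_indices <- function(cohort, biomarkers = c("ukim1", "uclu"),
                           ucr_unit = "mmol/L", scr_unit = "umol/L") {
  need <- c("gfr_stimulated", "gfr_unstimulated", "scr", "ucr", "urine_flow")
  if (!all(need %in% names(cohort)))
    stop_quant("cohort must have columns: %s", paste(need, collapse = ", "))
  cohort$kfr <- kfr(cohort$gfr_stimulated, cohort$gfr_unstimulated)
  cohort$kfr_negative <- cohort$kfr < 0
  cohort$crcl <- creatinine_clearance(cohort$ucr, cohort$urine_flow,
                                      cohort$scr, ucr_unit = ucr_unit,
                                      scr_unit = scr_unit)
  for (b in biomarkers) {
    if (!b %in% names(cohort)) stop_quant("biomarker column '%s' missing", b)
    cohort[[paste0(b, "_ucr")]] <- normalize_biomarker(cohort[[b]], cohort$ucr)
  }
  cohort
}
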