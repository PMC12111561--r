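# File formats: micrographs and Doppler stacks as multi-page TIFF with a
# JSON sidecar of acquisition metadata; tables as CSV with a JSON units
# sidecar. TIFF pixel data are stored as 32-bit float scaled into [0, 1]
# by a constant recorded in the sidecar.

TIFF_SCALE <- 65535

sidecar_path <- function(path) paste0(path, ".json")

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

read_json_sidecar <- function(path) {
  jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
}

#' Write a micrograph as multi-page TIFF + JSON sidecar
#'
#' Page order: dapi, pancytokeratin, marker, then dark and flat if present.
#' Intensities are divided by a fixed scale (recorded in the sidecar) and
#' stored as 32-bit float.
#'
#' @param mg a [micrograph()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(mg, path) {
  stopifnot(inherits(mg, "micrograph"))
  pages <- unname(mg$channels[c("dapi", "pancytokeratin", "marker")])
  order <- c("dapi", "pancytokeratin", "marker")
  if (!is.null(mg$dark)) { pages <- c(pages, list(mg$dark)); order <- c(order, "dark") }
  if (!is.null(mg$flat)) { pages <- c(pages, list(mg$flat)); order <- c(order, "flat") }
  tiff::writeTIFF(lapply(pages, function(p) p / TIFF_SCALE), path,
                  bits.per.sample = 32L, reduce = FALSE)
  write_json_sidecar(list(page_order = order, intensity_scale = TIFF_SCALE,
                          pixel_size = mg$pixel_size,
                          exposure_ms = as.list(mg$exposure_ms),
                          binning = mg$binning), path)
  invisible(path)
}

#' Read a micrograph written by [write_micrograph()]
#'
#' @param path TIFF path with its `<path>.json` sidecar.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path) {
  meta <- read_json_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) p * meta$intensity_scale)
  names(pages) <- meta$page_order
  micrograph(pages[c("dapi", "pancytokeratin", "marker")],
             dark = pages[["dark"]], flat = pages[["flat"]],
             pixel_size = meta$pixel_size,
             exposure_ms = unlist(meta$exposure_ms),
             binning = meta$binning)
}

#' Write ground-truth masks as boolean TIFF + JSON sidecar of scalar truths
#'
#' @param truth a `ground_truth` object from a generator.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  is_mask <- vapply(truth, function(x) is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1))),
                    logical(1))
  masks <- truth[is_mask]
  tiff::writeTIFF(lapply(masks, function(m) (m != 0) * 1), path,
                  bits.per.sample = 8L, compression = "LZW", reduce = FALSE)
  scalars <- truth[!is_mask]
  scalars <- scalars[vapply(scalars, function(x) is.numeric(x) && length(x) == 1, logical(1))]
  write_json_sidecar(list(page_order = names(masks), scalars = scalars), path)
  invisible(path)
}

#' Write a binary mask as single-page TIFF
#' @param mask `binary_mask` or logical matrix.
#' @param path output path; the threshold audit goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask(mask)
  tiff::writeTIFF(m * 1, path, bits.per.sample = 8L, compression = "LZW")
  audit <- if (inherits(mask, "binary_mask")) {
    list(source_channel = mask$source_channel, method = mask$method,
         threshold_value = mask$threshold_value, area = mask_area(mask))
  } else list(area = sum(m))
  write_json_sidecar(audit, path)
  invisible(path)
}

#' Read a binary mask TIFF
#' @param path TIFF path written by [write_mask()].
#' @return A `binary_mask`.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path) > 0.5
  audit <- if (file.exists(sidecar_path(path))) read_json_sidecar(path) else list()
  binary_mask(m, source_channel = audit$source_channel %||% NA_character_,
              threshold_value = audit$threshold_value %||% NA_real_,
              method = audit$method %||% NA_character_)
}

#' Write a Doppler study (frames + masks) as TIFF pair + JSON header
#'
#' @param study a [doppler_study()].
#' @param frames_path,masks_path output TIFF paths; the header JSON sits
#'   beside `frames_path`.
#' @return `frames_path`, invisibly.
#' @export
write_doppler_study <- function(study, frames_path, masks_path) {
  stopifnot(inherits(study, "doppler_study"))
  nf <- dim(study$frames)[3]
  tiff::writeTIFF(lapply(seq_len(nf), function(k) study$frames[, , k] / TIFF_SCALE),
                  frames_path, bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(lapply(seq_len(nf), function(k) study$kidney_masks[, , k] * 1),
                  masks_path, bits.per.sample = 8L, compression = "LZW",
                  reduce = FALSE)
  write_json_sidecar(list(pixel_size = study$pixel_size,
                          slice_thickness = study$slice_thickness,
                          vascular_threshold = study$vascular_threshold,
                          intensity_scale = TIFF_SCALE,
                          masks_file = basename(masks_path)), frames_path)
  invisible(frames_path)
}

#' Read a Doppler study written by [write_doppler_study()]
#' @param frames_path TIFF path of the frames (header JSON beside it).
#' @param masks_path TIFF path of the kidney masks (default from header).
#' @return A [doppler_study()].
#' @export
read_doppler_study <- function(frames_path, masks_path = NULL) {
  meta <- read_json_sidecar(frames_path)
  if (is.null(masks_path))
    masks_path <- file.path(dirname(frames_path), meta$masks_file)
  fr <- tiff::readTIFF(frames_path, all = TRUE)
  mk <- tiff::readTIFF(masks_path, all = TRUE)
  frames <- array(unlist(fr), c(dim(fr[[1]]), length(fr))) * meta$intensity_scale
  masks <- array(unlist(mk), c(dim(mk[[1]]), length(mk))) > 0.5
  vt <- meta$vascular_threshold
  if (!is.numeric(vt) || length(vt) != 1) vt <- NULL
  doppler_study(frames, masks, pixel_size = meta$pixel_size,
                slice_thickness = meta$slice_thickness,
                vascular_threshold = vt)
}

#' Write a table as CSV with a JSON units sidecar
#'
#' @param df data.frame.
#' @param path CSV path.
#' @param units optional named list/vector of per-column units, recorded in
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, units = NULL) {
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(units)) write_json_sidecar(list(units = as.list(units)), path)
  invisible(path)
}

#' Read a CSV table (with optional units sidecar)
#' @param path CSV path.
#' @return data.frame; units (if any) in the `"units"` attribute.
#' @export
read_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (file.exists(sidecar_path(path)))
    attr(df, "units") <- read_json_sidecar(path)$units
  df
}
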