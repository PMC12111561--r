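#' Parameters for the synthetic micrograph generator
#'
#' Describes a simulated double-stained kidney cryosection: DAPI nuclei as
#' non-overlapping disks, a pancytokeratin (tubular epithelium) region of a
#' prescribed area fraction, ring-shaped endothelial vessel profiles with
#' hollow lumina, and a marker channel whose signal is split between the
#' nuclear and cytoplasmic compartments with a known nuclear share. The raw
#' channels are corrupted by a multiplicative illumination field, additive
#' dark current and Gaussian noise; matched dark and flat frames are
#' produced alongside, so the correction step can be tested against the
#' pre-corruption ground truth.
#'
#' @param width,height image size in pixels (>= 64).
#' @param n_nuclei number of nuclei (non-overlapping disks).
#' @param nucleus_radius nucleus radius in pixels.
#' @param tubule_area_fraction pancytokeratin-positive area fraction in \[0,1\].
#' @param n_vessels number of ring-shaped vessel profiles.
#' @param vessel_outer_radius,vessel_wall_thickness vessel geometry in pixels;
#'   the wall is the annulus between `outer - thickness` and `outer`, the
#'   lumen the enclosed disk. Thickness must be < outer radius.
#' @param marker_nuclear_fraction ground-truth share of marker-positive area
#'   lying inside nuclei, in \[0,1\].
#' @param marker_area_fraction total marker-positive area fraction (generator
#'   convention; abundance scales are not constrained by the assay).
#' @param marker_type `"puncta"` (nuclear/cytoplasmic protein, e.g.
#'   PGC-1alpha or COX4) or `"vessel"` (marker channel renders the vessel
#'   walls, the RECA1 geometry).
#' @param illumination_gradient_amplitude relative range of the multiplicative
#'   shading field (0 = flat; must be < 2 so the field stays positive).
#' @param dark_offset_mean camera dark offset, intensity units.
#' @param noise_sd additive Gaussian read-noise SD, intensity units.
#' @param bg_level,stain_level clean background and stained-pixel intensities.
#' @param seed integer seed; the whole simulation is a pure function of
#'   (params, seed).
#' @return A validated list of class `image_sim_params`.
#' @export
image_sim_params <- function(width = 256, height = 256,
                             n_nuclei = 80, nucleus_radius = 5,
                             tubule_area_fraction = 0.5,
                             n_vessels = 10, vessel_outer_radius = 9,
                             vessel_wall_thickness = 3,
                             marker_nuclear_fraction = 0.5,
                             marker_area_fraction = 0.04,
                             marker_type = c("puncta", "vessel"),
                             illumination_gradient_amplitude = 0.3,
                             dark_offset_mean = 100,
                             noise_sd = 25,
                             bg_level = 50, stain_level = 800,
                             seed = 1L) {
  marker_type <- match.arg(marker_type)
  if (width < 64 || height < 64) stop_quant("width and height must be >= 64")
  check_fraction(tubule_area_fraction, "tubule_area_fraction")
  check_fraction(marker_nuclear_fraction, "marker_nuclear_fraction")
  check_fraction(marker_area_fraction, "marker_area_fraction")
  if (vessel_wall_thickness >= vessel_outer_radius)
    stop_quant("vessel_wall_thickness (%g) must be < vessel_outer_radius (%g)",
               vessel_wall_thickness, vessel_outer_radius)
  check_positive(nucleus_radius, "nucleus_radius")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(dark_offset_mean, "dark_offset_mean", strict = FALSE)
  if (illumination_gradient_amplitude < 0 || illumination_gradient_amplitude >= 2)
    stop_quant("illumination_gradient_amplitude must be in [0, 2)")
  structure(as.list(environment()), class = "image_sim_params")
}

#' Generate a synthetic micrograph with ground truth
#'
#' See [image_sim_params()] for the model. The marker channel is laid down
#' pixel-wise: `round(f * A)` of its `A` positive pixels are sampled inside
#' nuclei and the remainder in the extranuclear epithelium, so the realised
#' nuclear share matches the requested `marker_nuclear_fraction` up to the
#' one-pixel rounding quantum. Ground-truth masks are recorded before
#' illumination, offset and noise are applied.
#'
#' @param params an [image_sim_params()] object.
#' @return A list with elements `micrograph` (a [micrograph()], including
#'   dark and flat frames) and `truth` (class `ground_truth`: the clean
#'   `nuclei_mask`, `tubule_mask`, `vessel_wall_mask`, `vessel_lumen_mask`,
#'   `marker_mask`, the `nuclei_count`, the realised
#'   `marker_nuclear_fraction`, and the illumination field).
#' @export
generate_micrograph <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  p <- params
  with_seed(p$seed, {
    nr <- p$height; nc <- p$width
    # nuclei: non-overlapping disks (rejection sampling)
    nuclei <- matrix(FALSE, nr, nc)
    if (p$n_nuclei > 0) {
      ctr <- sample_disk_centres(p$n_nuclei, nr, nc, p$nucleus_radius,
                                 min_dist = 2 * p$nucleus_radius + 2)
      for (i in seq_len(nrow(ctr)))
        nuclei <- draw_disk(nuclei, ctr[i, "x"], ctr[i, "y"], p$nucleus_radius)
    }
    # tubular epithelium: smooth random region at the exact area fraction
    tubule <- random_blob_mask(nr, nc, p$tubule_area_fraction)
    # vessels: non-overlapping annuli (wall) with hollow lumina
    wall <- matrix(FALSE, nr, nc)
    lumen <- matrix(FALSE, nr, nc)
    if (p$n_vessels > 0) {
      R <- p$vessel_outer_radius
      ctr <- sample_disk_centres(p$n_vessels, nr, nc, R, min_dist = 2 * R + 2)
      for (i in seq_len(nrow(ctr))) {
        outer_d <- draw_disk(matrix(FALSE, nr, nc), ctr[i, "x"], ctr[i, "y"], R)
        inner_d <- draw_disk(matrix(FALSE, nr, nc), ctr[i, "x"], ctr[i, "y"],
                             R - p$vessel_wall_thickness)
        wall <- wall | (outer_d & !inner_d)
        lumen <- lumen | inner_d
      }
    }
    # marker: pixel point process with an exact nuclear share
    if (p$marker_type == "vessel") {
      marker <- wall
    } else {
      a_total <- round(p$marker_area_fraction * nr * nc)
      n_nuc <- round(p$marker_nuclear_fraction * a_total)
      nuc_px <- which(nuclei)
      if (n_nuc > length(nuc_px))
        stop_quant(paste0("marker_nuclear_fraction %.2f needs %d nuclear pixels ",
                          "but nuclei cover only %d; increase n_nuclei or ",
                          "nucleus_radius"), p$marker_nuclear_fraction, n_nuc,
                   length(nuc_px))
      cyto_px <- which(tubule & !nuclei)
      if (length(cyto_px) < a_total - n_nuc) cyto_px <- which(!nuclei)
      if (length(cyto_px) < a_total - n_nuc)
        stop_quant("not enough extranuclear pixels for the marker channel")
      marker <- matrix(FALSE, nr, nc)
      if (n_nuc > 0) marker[sample(nuc_px, n_nuc)] <- TRUE
      if (a_total - n_nuc > 0) marker[sample(cyto_px, a_total - n_nuc)] <- TRUE
    }
    # corruption model: raw = clean * illumination + dark + noise
    illum <- make_illumination_field(nr, nc, p$illumination_gradient_amplitude)
    clean <- list(
      dapi = p$bg_level + p$stain_level * nuclei,
      pancytokeratin = p$bg_level + p$stain_level * tubule,
      marker = p$bg_level + p$stain_level * marker
    )
    corrupt <- function(ch) {
      raw <- ch * illum + p$dark_offset_mean +
        matrix(stats::rnorm(nr * nc, sd = p$noise_sd), nr, nc)
      raw[raw < 0] <- 0
      raw
    }
    channels <- lapply(clean, corrupt)
    dark <- matrix(p$dark_offset_mean, nr, nc)
    flat <- illum * 1000 + dark
    mg <- micrograph(channels, dark = dark, flat = flat,
                     exposure_ms = c(dapi = 10, pancytokeratin = 100,
                                     marker = if (p$marker_type == "vessel") 500 else 100))
    realised_nf <- if (p$marker_type == "vessel" || mask_area(marker) == 0) NA_real_
                   else sum(marker & nuclei) / sum(marker)
    truth <- structure(list(
      nuclei_mask = nuclei, tubule_mask = tubule,
      vessel_wall_mask = wall, vessel_lumen_mask = lumen,
      marker_mask = marker,
      nuclei_count = p$n_nuclei,
      marker_nuclear_fraction = realised_nf,
      illumination = illum
    ), class = "ground_truth")
    list(micrograph = mg, truth = truth)
  })
}
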