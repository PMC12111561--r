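# Pipeline orchestration: one flat config, stages run in dependency order,
# every applied default echoed into the run manifest, outputs hashed so a
# rerun with the same config + seed is verifiably bit-identical.

pipeline_stage_order <- c("simulate", "quantify", "rbv", "physiology",
                          "qpcr", "discriminate")

pipeline_defaults <- function() {
  list(
    stages = pipeline_stage_order,
    seed = 1L,
    micrograph = list(
      width = 128, height = 128, n_sections = 2,
      groups = c("IRI+Veh", "IRI+NR"), n_animals_per_group = 2,
      markers = c("pgc1a", "reca1"),
      marker_nuclear_fraction = 0.6,
      n_nuclei = 25, n_vessels = 4, noise_sd = 25
    ),
    doppler = list(n_frames = 8, frame_shape = c(64, 64),
                   kidney_ellipsoid_axes = c(2.2, 1.6, 1.6),
                   target_rbv_percent = 5),
    qpcr = list(genes = c("Pgc1a", "Actb", "Pabpn1"),
                housekeeping = c("Actb", "Pabpn1"),
                groups = c("IRI+Veh", "IRI+NR"),
                n_animals_per_group = 6,
                fold_change = list(Pgc1a = list("IRI+NR" = 2)),
                ct_noise_sd = 0.2),
    cohort = list(n_per_group = 6),
    quantify = list(threshold_method = "otsu", max_hole_area = 2000,
                    min_nucleus_area = 5, correct_first = TRUE,
                    vehicle_groups = "IRI+Veh"),
    rbv = list(threshold = NULL),
    discriminate = list(mode = "lasso", day = 98,
                        positive_group = "IRI+Veh",
                        exclude_groups = "sham+Veh",
                        features = c("ukim1_ucr", "uclu_ucr", "kfr",
                                     "rbv_percent"),
                        n_boot = 2000)
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks stage names, fills missing
#' fields with documented defaults and records which defaults were applied
#' (echoed into the run manifest — no hidden defaults).
#'
#' @param config path to a YAML file, or a (possibly partial) named list.
#' @return A fully resolved config of class `run_config`, with the applied
#'   defaults in the `"applied_defaults"` attribute.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_quant("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  if (!is.list(config)) stop_quant("config must be a YAML file path or a list")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_quant("unknown config section(s): %s (valid: %s)",
               paste(unknown, collapse = ", "),
               paste(names(defaults), collapse = ", "))
  applied <- character(0)
  merged <- defaults
  for (top in names(defaults)) {
    if (is.null(config[[top]])) {
      applied <- c(applied, top)
    } else if (is.list(defaults[[top]])) {
      user <- config[[top]]
      bad <- setdiff(names(user), names(defaults[[top]]))
      if (length(bad))
        stop_quant("unknown field(s) in config$%s: %s", top,
                   paste(bad, collapse = ", "))
      for (f in names(defaults[[top]])) {
        # [f] <- list(...) keeps the slot even when the value is NULL
        if (f %in% names(user)) merged[[top]][f] <- list(user[[f]])
        else applied <- c(applied, paste(top, f, sep = "."))
      }
    } else {
      merged[[top]] <- config[[top]]
    }
  }
  bad_stages <- setdiff(merged$stages, pipeline_stage_order)
  if (length(bad_stages))
    stop_quant("unknown stage(s): %s (valid: %s)",
               paste(bad_stages, collapse = ", "),
               paste(pipeline_stage_order, collapse = ", "))
  merged$seed <- as.integer(merged$seed)
  # canonical YAML-stable form for gene -> (group -> fold) maps
  if (!is.null(merged$qpcr$fold_change))
    merged$qpcr$fold_change <- lapply(merged$qpcr$fold_change, as.list)
  structure(merged, class = "run_config", applied_defaults = applied)
}

#' Write a resolved config to YAML
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order
#' (simulate, quantify, rbv, physiology, qpcr, discriminate), writing every
#' stage's outputs under `out_dir` and a `manifest.json` recording the
#' resolved configuration, applied defaults, and an md5 hash of every
#' output file. Given the same config and seed the manifest and all
#' outputs are byte-identical across runs.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- pipeline_stage_order[pipeline_stage_order %in% config$stages]
  outputs <- list()
  for (st in stages) {
    fn <- switch(st,
      simulate = stage_simulate, quantify = stage_quantify,
      rbv = stage_rbv, physiology = stage_physiology,
      qpcr = stage_qpcr, discriminate = stage_discriminate)
    outputs[[st]] <- fn(config, out_dir)
  }
  hash_files <- function(files)
    lapply(stats::setNames(files, basename(files)), file_md5)
  manifest <- list(
    package = "renoquant",
    version = as.character(utils::packageVersion("renoquant")),
    seed = config$seed,
    stages = stages,
    applied_defaults = attr(config, "applied_defaults"),
    config = unclass(config),
    outputs = lapply(outputs, hash_files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

require_upstream <- function(path, stage, needed_by) {
  if (!file.exists(path))
    stop_quant("stage '%s' needs '%s' produced by stage '%s'; run it first",
               needed_by, basename(path), stage)
  path
}

stage_simulate <- function(config, out_dir) {
  files <- character(0)
  # cohort
  cohort <- generate_cohort(cohort_sim_params(n_per_group = config$cohort$n_per_group,
                                              seed = config$seed))
  f <- file.path(out_dir, "cohort.csv")
  write_table_csv(cohort, f, units = list(
    gfr_unstimulated = "mL/min", gfr_stimulated = "mL/min", scr = "umol/L",
    ucr = "mmol/L", urine_flow = "mL/min", ukim1 = "ng/mL", uclu = "ng/mL",
    rbv_percent = "%"))
  files <- c(files, f, sidecar_path(f))
  # qPCR Ct table
  q <- config$qpcr
  qp <- qpcr_sim_params(genes = q$genes, housekeeping = q$housekeeping,
                        groups = q$groups,
                        n_animals_per_group = q$n_animals_per_group,
                        fold_change = q$fold_change,
                        ct_noise_sd = q$ct_noise_sd,
                        seed = config$seed + 101L)
  ct <- generate_ct_table(qp)
  f <- file.path(out_dir, "ct_table.csv")
  write_table_csv(ct$table$data, f)
  files <- c(files, f)
  roles_file <- file.path(out_dir, "gene_roles.yaml")
  yaml::write_yaml(list(gene_roles = as.list(ct$table$gene_roles),
                        reference_group = ct$table$reference_group),
                   roles_file)
  files <- c(files, roles_file)
  # micrographs
  mgdir <- file.path(out_dir, "micrographs")
  dir.create(mgdir, showWarnings = FALSE)
  mc <- config$micrograph
  idx <- 0L
  for (g in mc$groups) for (a in seq_len(mc$n_animals_per_group))
    for (mk in mc$markers) for (s in seq_len(mc$n_sections)) {
      idx <- idx + 1L
      p <- image_sim_params(width = mc$width, height = mc$height,
                            n_nuclei = mc$n_nuclei, n_vessels = mc$n_vessels,
                            marker_nuclear_fraction = mc$marker_nuclear_fraction,
                            marker_type = if (mk == "reca1") "vessel" else "puncta",
                            noise_sd = mc$noise_sd,
                            seed = config$seed * 1000L + idx)
      sim <- generate_micrograph(p)
      aid <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g), a)
      f <- file.path(mgdir, sprintf("%s_%s_s%02d.tif", aid, mk, s))
      write_micrograph(sim$micrograph, f)
      files <- c(files, f, sidecar_path(f))
    }
  # index of micrographs (animal/group/marker/section -> file)
  index <- do.call(rbind, lapply(list.files(mgdir, pattern = "\\.tif$"), function(fn) {
    parts <- strsplit(sub("\\.tif$", "", fn), "_")[[1]]
    data.frame(file = file.path("micrographs", fn),
               animal_id = paste(parts[1], parts[2], sep = "_"),
               marker = parts[3],
               section_index = as.integer(sub("^s", "", parts[4])),
               stringsAsFactors = FALSE)
  }))
  group_of <- stats::setNames(rep(mc$groups, each = mc$n_animals_per_group),
    unlist(lapply(mc$groups, function(g)
      sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g), seq_len(mc$n_animals_per_group)))))
  index$group <- unname(group_of[index$animal_id])
  f <- file.path(out_dir, "micrograph_index.csv")
  write_table_csv(index, f)
  files <- c(files, f)
  # Doppler study
  dp <- config$doppler
  sim <- generate_doppler_study(doppler_sim_params(
    n_frames = dp$n_frames, frame_shape = dp$frame_shape,
    kidney_ellipsoid_axes = dp$kidney_ellipsoid_axes,
    target_rbv_percent = dp$target_rbv_percent,
    seed = config$seed + 202L))
  ff <- file.path(out_dir, "doppler_frames.tif")
  fm <- file.path(out_dir, "doppler_masks.tif")
  write_doppler_study(sim$study, ff, fm)
  files <- c(files, ff, sidecar_path(ff), fm)
  files
}

stage_quantify <- function(config, out_dir) {
  qc <- config$quantify
  idx_file <- require_upstream(file.path(out_dir, "micrograph_index.csv"),
                               "simulate", "quantify")
  index <- read_table_csv(idx_file)
  recs <- do.call(rbind, lapply(seq_len(nrow(index)), function(i) {
    mg <- read_micrograph(file.path(out_dir, index$file[i]))
    r <- quantify_micrograph(mg, marker = index$marker[i],
                             threshold_method = qc$threshold_method,
                             max_hole_area = qc$max_hole_area,
                             min_nucleus_area = qc$min_nucleus_area,
                             correct_first = qc$correct_first)
    cbind(data.frame(animal_id = index$animal_id[i], group = index$group[i],
                     region = "cortex", section_index = index$section_index[i],
                     stringsAsFactors = FALSE), r)
  }))
  f1 <- file.path(out_dir, "quant_records.csv")
  write_table_csv(recs, f1)
  f2 <- file.path(out_dir, "quant_summary.csv")
  write_table_csv(aggregate_sections(recs), f2)
  f3 <- file.path(out_dir, "quant_folds.csv")
  write_table_csv(fold_change_vs_vehicle(recs, qc$vehicle_groups), f3)
  c(f1, f2, f3)
}

stage_rbv <- function(config, out_dir) {
  ff <- require_upstream(file.path(out_dir, "doppler_frames.tif"),
                         "simulate", "rbv")
  study <- read_doppler_study(ff)
  res <- doppler_rbv(study, threshold = config$rbv$threshold)
  f1 <- file.path(out_dir, "rbv.csv")
  write_table_csv(data.frame(kidney_volume_mm3 = res$kidney_volume_mm3,
                             vascular_volume_mm3 = res$vascular_volume_mm3,
                             rbv_percent = res$rbv_percent,
                             rbv_percent_frame_mean = res$rbv_percent_frame_mean,
                             threshold = res$threshold), f1)
  f2 <- file.path(out_dir, "rbv_per_frame.csv")
  write_table_csv(res$per_frame, f2)
  c(f1, f2)
}

stage_physiology <- function(config, out_dir) {
  f0 <- require_upstream(file.path(out_dir, "cohort.csv"),
                         "simulate", "physiology")
  cohort <- read_table_csv(f0)
  f <- file.path(out_dir, "indices.csv")
  write_table_csv(cohort_indices(cohort), f, units = list(
    kfr = "mL/min", crcl = "mL/min", ukim1_ucr = "ng/mL per mmol/L",
    uclu_ucr = "ng/mL per mmol/L"))
  c(f, sidecar_path(f))
}

stage_qpcr <- function(config, out_dir) {
  f0 <- require_upstream(file.path(out_dir, "ct_table.csv"), "simulate", "qpcr")
  roles <- yaml::read_yaml(file.path(out_dir, "gene_roles.yaml"))
  tab <- ct_table(read_table_csv(f0), unlist(roles$gene_roles),
                  roles$reference_group)
  folds <- relative_expression(tab)
  f1 <- file.path(out_dir, "expression_folds.csv")
  write_table_csv(folds, f1)
  f2 <- file.path(out_dir, "expression_group_summary.csv")
  write_table_csv(group_fold_summary(folds), f2)
  c(f1, f2)
}

stage_discriminate <- function(config, out_dir) {
  dc <- config$discriminate
  f0 <- require_upstream(file.path(out_dir, "indices.csv"),
                         "physiology", "discriminate")
  ind <- read_table_csv(f0)
  d <- ind[ind$day == dc$day & !(ind$group %in% dc$exclude_groups), , drop = FALSE]
  y <- as.integer(d$group == dc$positive_group)
  fit <- if (dc$mode == "lasso") {
    fit_lasso_logistic(d[, dc$features, drop = FALSE], y)
  } else {
    fit_logistic(d[, dc$features, drop = FALSE], y)
  }
  ci <- auc_with_ci(fit$scores, y, n_boot = dc$n_boot, seed = config$seed)
  report <- list(mode = dc$mode, features = dc$features,
                 positive_group = dc$positive_group, day = dc$day,
                 n = nrow(d), n_positive = sum(y),
                 coefficients = as.list(fit$coefficients),
                 penalty = fit$penalty %||% NA,
                 selected_features = fit$selected_features %||% dc$features,
                 separable = fit$separable %||% FALSE,
                 auc = ci$auc, auc_ci = c(ci$lower, ci$upper))
  f1 <- file.path(out_dir, "discrimination_model.json")
  jsonlite::write_json(report, f1, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  f2 <- file.path(out_dir, "discrimination_scores.csv")
  write_table_csv(data.frame(animal_id = d$animal_id, group = d$group,
                             label = y, score = fit$scores), f2)
  c(f1, f2)
}
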