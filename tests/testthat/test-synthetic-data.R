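test_that("marker nuclear fraction edge cases place pixels exactly", {
  # all-cytoplasmic marker: no overlap with nuclei
  sim0 <- generate_micrograph(image_sim_params(marker_nuclear_fraction = 0, seed = 11))
  expect_equal(sum(sim0$truth$marker_mask & sim0$truth$nuclei_mask), 0)
  # all-nuclear marker: marker is a subset of the nuclei
  sim1 <- generate_micrograph(image_sim_params(marker_nuclear_fraction = 1,
                                               noise_sd = 0, seed = 11))
  expect_true(all(!sim1$truth$marker_mask | sim1$truth$nuclei_mask))
})

test_that("requested nuclear fraction is met to pixel quantisation", {
  for (f in c(0.2, 0.37, 0.8)) {
    sim <- generate_micrograph(image_sim_params(marker_nuclear_fraction = f, seed = 5))
    a <- sum(sim$truth$marker_mask)
    realised <- sum(sim$truth$marker_mask & sim$truth$nuclei_mask) / a
    expect_lte(abs(realised - f), 1 / a + 1e-12)
    expect_equal(sim$truth$marker_nuclear_fraction, realised)
  }
})

test_that("generated nuclei count matches connected components of the mask", {
  sim <- generate_micrograph(image_sim_params(n_nuclei = 50, seed = 7))
  lab <- label_components(sim$truth$nuclei_mask, connectivity = 8)
  expect_identical(max(lab), 50L)
  expect_identical(sim$truth$nuclei_count, 50)
})

test_that("lumen and wall masks are disjoint and geometry errors are explicit", {
  sim <- generate_micrograph(image_sim_params(marker_type = "vessel", seed = 2))
  expect_equal(sum(sim$truth$vessel_wall_mask & sim$truth$vessel_lumen_mask), 0)
  expect_gt(sum(sim$truth$vessel_lumen_mask), 0)
  # degenerate: wall as thick as the vessel
  expect_error(image_sim_params(vessel_outer_radius = 5, vessel_wall_thickness = 5),
               "vessel_wall_thickness")
  # overcrowded geometry cannot be placed
  expect_error(
    generate_micrograph(image_sim_params(width = 64, height = 64, n_nuclei = 500)),
    "non-overlapping")
})

test_that("micrograph generation is deterministic in the seed and leaves RNG alone", {
  p <- image_sim_params(seed = 42)
  a <- generate_micrograph(p)
  set.seed(123); before <- rnorm(3)
  set.seed(123)
  b <- generate_micrograph(p)  # must not perturb the caller's RNG stream
  after <- rnorm(3)
  expect_identical(a$micrograph$channels, b$micrograph$channels)
  expect_identical(a$truth$marker_mask, b$truth$marker_mask)
  expect_identical(before, after)
})

test_that("doppler ground truth hits the target rBV to voxel quantisation", {
  sim <- generate_doppler_study(doppler_sim_params(target_rbv_percent = 5, seed = 3))
  measured <- 100 * sum(sim$truth$vascular_masks) / sum(sim$truth$kidney_masks)
  expect_lte(abs(measured - 5), 0.2)
  expect_true(all(!sim$truth$vascular_masks | sim$truth$kidney_masks))
  # zero target: no vascular voxels at all
  sim0 <- generate_doppler_study(doppler_sim_params(target_rbv_percent = 0, seed = 3))
  expect_equal(sum(sim0$truth$vascular_masks), 0)
  expect_error(doppler_sim_params(n_frames = 1), "n_frames")
  expect_error(doppler_sim_params(target_rbv_percent = 120), "target_rbv_percent")
})

test_that("noiseless Ct tables encode fold changes exactly", {
  p <- qpcr_sim_params(fold_change = list(Pgc1a = c("IRI+NR" = 2)),
                       ct_noise_sd = 0, sample_shift_sd = 0, seed = 1)
  sim <- generate_ct_table(p)
  d <- sim$table$data
  base <- d$ct[d$gene == "Pgc1a" & d$group == "IRI+Veh"][1]
  trt <- d$ct[d$gene == "Pgc1a" & d$group == "IRI+NR"][1]
  expect_equal(trt, base - 1)  # log2(2) = 1 cycle
  # housekeeping genes carry fold 1 everywhere
  for (hk in c("Actb", "Pabpn1"))
    expect_equal(length(unique(d$ct[d$gene == hk])), 1L)
  expect_true(all(sim$truth$true_fold_changes[c("Actb", "Pabpn1"), ] == 1))
  # housekeeping folds other than 1 are rejected at construction
  expect_error(qpcr_sim_params(fold_change = list(Actb = c("IRI+NR" = 2))),
               "housekeeping")
})

test_that("cohort table has the full design and is seed-deterministic", {
  p <- cohort_sim_params(seed = 9)
  co <- generate_cohort(p)
  expect_equal(nrow(co), 5 * 6 * 5)  # groups x animals x timepoints
  expect_equal(sum(co$day == 98), 30) # 30 animals per timepoint (sham 6 + IRI 24)
  expect_identical(generate_cohort(p), co)
  # zero SDs: every animal equals its group mean
  eff <- default_cohort_effects()
  eff$sd <- 0
  co0 <- generate_cohort(cohort_sim_params(effects = eff, seed = 1))
  mu <- eff$mean[eff$group == "IRI+Veh" & eff$day == 98 & eff$variable == "ukim1"]
  expect_true(all(co0$ukim1[co0$group == "IRI+Veh" & co0$day == 98] == mu))
})
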