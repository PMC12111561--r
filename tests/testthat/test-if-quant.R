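test_that("lumen filling matches the analytic annulus oracle exactly", {
  ann <- render_annulus(41, r_out = 10, r_in = 6)
  filled <- fill_lumina(ann$wall, max_hole_area = 2000)
  expect_identical(filled$mask, ann$wall | ann$lumen)
  expect_equal(mask_area(filled) - sum(ann$wall), sum(ann$lumen))
  # a solid disk has no holes
  disk <- renoquant:::draw_disk(matrix(FALSE, 41, 41), 21, 21, 10)
  expect_identical(fill_lumina(disk)$mask, disk)
  # a lumen larger than the bound is left open
  small_cap <- fill_lumina(ann$wall, max_hole_area = sum(ann$lumen) - 1)
  expect_identical(small_cap$mask, ann$wall)
  at_cap <- fill_lumina(ann$wall, max_hole_area = sum(ann$lumen))
  expect_identical(at_cap$mask, ann$wall | ann$lumen)
})

test_that("lumen filling is monotone and idempotent on arbitrary masks", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(2500) < 0.45, 50, 50)
    f1 <- fill_lumina(m, max_hole_area = 40)$mask
    expect_true(all(f1 | !m))          # output contains input
    f2 <- fill_lumina(f1, max_hole_area = 40)$mask
    expect_identical(f2, f1)           # idempotent
  }
})

test_that("normalised RECA1 is the filled fraction over the epithelial fraction", {
  expect_equal(normalized_reca1(0.10, 0.50), 0.20)
  expect_equal(normalized_reca1(0, 0.4), 0)
  expect_error(normalized_reca1(0.1, 0), "unusable")
  # simulator ground truth: hand-computed mask ratio
  sim <- generate_micrograph(image_sim_params(marker_type = "vessel", seed = 8))
  filled_frac <- sum(sim$truth$vessel_wall_mask | sim$truth$vessel_lumen_mask) /
    length(sim$truth$vessel_wall_mask)
  e <- mean(sim$truth$tubule_mask)
  expect_equal(normalized_reca1(filled_frac, e), filled_frac / e, tolerance = 1e-9)
})

test_that("nuclear fraction score follows the stated equation", {
  sc <- nuclear_fraction_score(0.10, 0.06, 0.5, 50)
  expect_equal(sc$score, 0.004)
  expect_equal(sc$nuclear_share, 0.4)
  # fully cytoplasmic marker scores zero
  expect_equal(nuclear_fraction_score(0.2, 0.2, 0.5, 10)$score, 0)
  expect_error(nuclear_fraction_score(0, 0, 0.5, 10), "total_marker_fraction")
  expect_error(nuclear_fraction_score(0.1, 0.05, 0.5, 0), "dapi_count")
  # the nuclear share is scale-invariant: doubling all areas changes nothing
  a <- nuclear_fraction_score(0.10, 0.06, 0.5, 50)$nuclear_share
  b <- nuclear_fraction_score(0.20, 0.12, 0.5, 50)$nuclear_share
  expect_equal(a, b)
  # COX4 shares the contract
  expect_equal(normalized_cox4(0.10, 0.06, 0.5, 50)$score, 0.004)
})

test_that("cytoplasmic mask is exact set subtraction", {
  set.seed(5)
  mk <- matrix(runif(900) < 0.3, 30, 30)
  dp <- matrix(runif(900) < 0.3, 30, 30)
  out <- cytoplasmic_marker_mask(mk, dp)
  expect_equal(mask_area(out), sum(mk) - sum(mk & dp))
  expect_identical(out$mask, mk & !dp)
  # marker inside nuclei vanishes; disjoint masks pass through
  expect_equal(mask_area(cytoplasmic_marker_mask(mk & dp, dp)), 0)
  expect_identical(cytoplasmic_marker_mask(mk & !dp, dp)$mask, mk & !dp)
})

test_that("full image pipeline recovers the imposed nuclear share", {
  sim <- generate_micrograph(image_sim_params(marker_nuclear_fraction = 0.6, seed = 31))
  r <- quantify_micrograph(sim$micrograph, marker = "pgc1a")
  expect_lte(abs(r$nuclear_share - 0.6), 0.05)
  expect_identical(r$dapi_count, 80L)
})

test_that("section aggregation matches a streaming oracle", {
  recs <- data.frame(animal_id = "r1", region = "cortex", marker = "pgc1a",
                     score = rep(0.004, 30))
  agg <- aggregate_sections(recs)
  expect_equal(agg$sd_score, 0)
  expect_equal(agg$n_sections, 30)
  recs2 <- data.frame(animal_id = "r1", region = "cortex", marker = "pgc1a",
                      score = 1:30)
  expect_equal(aggregate_sections(recs2)$mean_score, 15.5)
  set.seed(2)
  x <- rlnorm(25)
  recs3 <- data.frame(animal_id = "r2", region = "medulla", marker = "cox4",
                      score = x)
  agg3 <- aggregate_sections(recs3)
  o <- oracle_streaming_stats(x)
  expect_equal(agg3$mean_score, o$mean, tolerance = 1e-12)
  expect_equal(agg3$sd_score, o$sd, tolerance = 1e-12)
})

test_that("fold changes are expressed against the vehicle global average", {
  recs <- expand.grid(animal_id = paste0("r", 1:6), section = 1:5)
  recs$group <- ifelse(recs$animal_id %in% paste0("r", 1:3), "IRI+Veh", "IRI+NR")
  recs$region <- "cortex"; recs$marker <- "pgc1a"
  recs$score <- 0.004
  # all equal scores: every fold is 1
  fc <- fold_change_vs_vehicle(recs, "IRI+Veh")
  expect_true(all(fc$fold_change == 1))
  # a doubled animal scores fold 2 against the vehicle global mean
  recs$score[recs$animal_id == "r4"] <- 0.008
  fc2 <- fold_change_vs_vehicle(recs, "IRI+Veh")
  expect_equal(fc2$fold_change[fc2$animal_id == "r4"], 2)
  # conservation: vehicle-group mean fold is exactly 1 (balanced sections)
  set.seed(8)
  recs$score <- rlnorm(nrow(recs), sdlog = 0.4)
  fc3 <- fold_change_vs_vehicle(recs, "IRI+Veh")
  expect_equal(mean(fc3$fold_change[fc3$group == "IRI+Veh"]), 1, tolerance = 1e-12)
  expect_error(fold_change_vs_vehicle(transform(recs, score = 0), "IRI+Veh"),
               "average is 0")
})

test_that("fibrosis percentage is a guarded ratio", {
  expect_equal(fibrosis_percent(0, 1000), 0)
  expect_equal(fibrosis_percent(250, 1000), 25)
  set.seed(3)
  fib <- matrix(runif(400) < 0.2, 20, 20)
  tis <- fib | matrix(runif(400) < 0.5, 20, 20)
  expect_equal(fibrosis_percent(sum(fib), sum(tis)), 100 * sum(fib) / sum(tis))
  expect_error(fibrosis_percent(10, 0), "tissue_area")
  expect_error(fibrosis_percent(20, 10), "fibrosis_area")
})
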