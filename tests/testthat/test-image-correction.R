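test_that("background correction satisfies its identities", {
  set.seed(1)
  flat <- matrix(runif(400, 200, 800), 20, 20)
  zero <- matrix(0, 20, 20)
  # flat-field identity: raw = flat, dark = 0 -> constant mean(flat)
  out <- background_correct(flat, zero, flat)
  expect_equal(out, matrix(mean(flat), 20, 20))
  # raw = dark -> identically zero
  dark <- matrix(runif(400, 50, 100), 20, 20)
  expect_equal(background_correct(dark, dark, flat), zero)
})

test_that("background correction recovers the clean image from the simulator model", {
  sim <- generate_micrograph(image_sim_params(seed = 4))
  mg <- sim$micrograph
  corrected <- background_correct(mg$channels$pancytokeratin, mg$dark, mg$flat)
  clean <- 50 + 800 * sim$truth$tubule_mask  # generator's clean channel
  expect_gte(cor(as.vector(corrected), as.vector(clean)), 0.99)
})

test_that("unusable calibration frames abort with the offending pixel fraction", {
  flat <- matrix(100, 10, 10)
  dark <- matrix(100, 10, 10)  # flat - dark == 0 everywhere
  expect_error(background_correct(flat, dark, flat), "100\\.000%")
  # a single clamped pixel within the 0.1% default tolerance is repaired
  flat2 <- matrix(200, 40, 40); dark2 <- matrix(100, 40, 40)
  flat2[1, 1] <- 100
  expect_silent(background_correct(flat2, dark2, flat2 + 100))
})

test_that("otsu threshold equals the exhaustive between-class variance argmax", {
  # two-level image: exactly the bright 10% selected
  img <- matrix(c(rep(10, 90), rep(200, 10)), 10, 10)
  bm <- threshold_mask(img, method = "otsu")
  expect_identical(bm$mask, img == 200)
  # quantised random images: mask agrees with the brute-force oracle
  set.seed(7)
  for (i in 1:5) {
    levels <- sample(16:64, 1)
    img <- matrix(sample(seq_len(levels), 900, replace = TRUE,
                         prob = runif(levels)), 30, 30)
    if (length(unique(as.vector(img))) < 2) next
    bm <- threshold_mask(img, method = "otsu")
    expect_identical(bm$mask, oracle_otsu_mask(img))
  }
  expect_error(threshold_mask(matrix(5, 4, 4)), "constant")
})

test_that("manual thresholds behave at the extremes and are recorded", {
  img <- matrix(runif(100, 0, 50), 10, 10)
  hi <- threshold_mask(img, method = "manual", manual_value = 100)
  expect_equal(mask_area(hi), 0)
  lo <- threshold_mask(img, method = "manual", manual_value = -1)
  expect_equal(mask_area(lo), length(img))
  expect_identical(lo$method, "manual")
  expect_identical(lo$threshold_value, -1)
  expect_error(threshold_mask(img, method = "manual"), "manual_value")
})

test_that("nucleus counting is exact on simulator truth and respects min_area", {
  expect_identical(count_nuclei(matrix(FALSE, 10, 10)), 0L)
  sim <- generate_micrograph(image_sim_params(n_nuclei = 50, seed = 7))
  expect_identical(count_nuclei(sim$truth$nuclei_mask, min_area = 5), 50L)
  # single-pixel specks are removed by the area floor
  speckled <- sim$truth$nuclei_mask
  speckled[1, c(3, 9, 40)] <- TRUE
  expect_identical(count_nuclei(speckled, min_area = 5), 50L)
  expect_identical(count_nuclei(speckled, min_area = 0), 53L)
})

test_that("nucleus counting is invariant to translation and rotation", {
  sim <- generate_micrograph(image_sim_params(n_nuclei = 30, seed = 12))
  m <- sim$truth$nuclei_mask
  n0 <- count_nuclei(m)
  # padded translation: no disk is split at the border
  pad <- matrix(FALSE, nrow(m) + 10, ncol(m) + 10)
  pad[6:(5 + nrow(m)), 6:(5 + ncol(m))] <- m
  expect_identical(count_nuclei(pad), n0)
  expect_identical(count_nuclei(t(m)), n0)                # transpose
  expect_identical(count_nuclei(m[nrow(m):1, ]), n0)      # flip
  expect_identical(count_nuclei(t(m)[ncol(m):1, ]), n0)   # 90-degree rotation
})

test_that("touching nuclei merge into one 8-connected component", {
  m <- matrix(FALSE, 20, 40)
  m <- renoquant:::draw_disk(m, 10, 10, 5)
  m <- renoquant:::draw_disk(m, 20, 10, 5)  # touches the first disk
  expect_identical(count_nuclei(m, min_area = 5), 1L)
  # diagonal adjacency joins under 8- but not 4-connectivity
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_identical(max(label_components(d, connectivity = 8)), 1L)
  expect_identical(max(label_components(d, connectivity = 4)), 2L)
})

test_that("component labelling agrees with EBImage on 4-connected cases", {
  skip_if_not_installed("EBImage")
  set.seed(3)
  for (i in 1:3) {
    m <- matrix(runif(625) < 0.35, 25, 25)
    mine <- label_components(m, connectivity = 4)
    ref <- EBImage::bwlabel(m * 1)
    expect_identical(max(mine), as.integer(max(ref)))
  }
})
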