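test_that("replicate averaging is the arithmetic mean per sample x gene", {
  d <- data.frame(sample_id = "s1", group = "g1", gene = "A",
                  replicate = 1:3, ct = c(19, 20, 21))
  tab <- ct_table(rbind(d, transform(d, gene = "HK1"), transform(d, gene = "HK2")),
                  c(A = "target", HK1 = "housekeeping", HK2 = "housekeeping"), "g1")
  avg <- average_replicates(tab)
  expect_equal(avg$data$ct, rep(20, 3))
  expect_equal(avg$data$n_replicates, rep(3L, 3))
  # random tables match the mean oracle
  set.seed(11)
  sim <- generate_ct_table(qpcr_sim_params(seed = 11))
  avg2 <- average_replicates(sim$table)
  d2 <- sim$table$data
  one <- d2[d2$sample_id == d2$sample_id[1] & d2$gene == "Pgc1a", ]
  expect_equal(avg2$data$ct[avg2$data$sample_id == one$sample_id[1] &
                            avg2$data$gene == "Pgc1a"],
               oracle_streaming_stats(one$ct)$mean, tolerance = 1e-12)
})

test_that("noiseless ddCt recovers imposed folds at machine precision", {
  # sample-level loading shifts are shared by all genes, so housekeeping
  # normalisation must cancel them exactly even when they are nonzero
  p <- qpcr_sim_params(fold_change = list(Pgc1a = c("IRI+NR" = 2)),
                       ct_noise_sd = 0, sample_shift_sd = 0.7, seed = 2)
  folds <- relative_expression(generate_ct_table(p)$table)
  expect_equal(folds$fold[folds$group == "IRI+NR"], rep(2, 6), tolerance = 1e-12)
  expect_equal(exp(mean(log(folds$fold[folds$group == "IRI+Veh"]))), 1,
               tolerance = 1e-12)
})

test_that("ddCt hand arithmetic: one cycle below reference doubles the fold", {
  d <- expand.grid(sample_id = c("ref1", "ref2", "low"), gene = c("T", "H1", "H2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$sample_id == "low", "treated", "reference")
  d$replicate <- 1L
  d$ct <- 20
  d$ct[d$sample_id == "low" & d$gene == "T"] <- 19  # one cycle earlier
  tab <- ct_table(d, c(T = "target", H1 = "housekeeping", H2 = "housekeeping"),
                  "reference")
  folds <- relative_expression(tab)
  expect_equal(folds$fold[folds$group == "treated"], 2)
  expect_equal(folds$fold[folds$group == "reference"], c(1, 1))
})

test_that("Ct-scale arithmetic mean equals the geometric mean of linear quantities", {
  set.seed(9)
  hk_ct <- matrix(runif(40, 15, 25), 20, 2)
  via_ct <- 2^(-rowMeans(hk_ct))
  via_geo <- sqrt(2^(-hk_ct[, 1]) * 2^(-hk_ct[, 2]))
  expect_equal(via_ct, via_geo, tolerance = 1e-12)
})

test_that("samples missing a housekeeping Ct are excluded with a reason", {
  d <- expand.grid(sample_id = c("s1", "s2"), gene = c("T", "H1", "H2"),
                   stringsAsFactors = FALSE)
  d$group <- "ref"; d$replicate <- 1L; d$ct <- 20
  d <- d[!(d$sample_id == "s2" & d$gene == "H2"), ]  # s2 lacks H2
  tab <- ct_table(d, c(T = "target", H1 = "housekeeping", H2 = "housekeeping"),
                  "ref")
  folds <- relative_expression(tab)
  expect_identical(unique(folds$sample_id), "s1")
  expect_match(attr(folds, "excluded"), "s2.*H2")
})

test_that("mitochondrial DNA ratio runs on the nuclear reference pair", {
  p <- qpcr_sim_params(genes = c("MtNd1", "MtCox1", "Ndufv1", "Ubc"),
                       housekeeping = c("Ndufv1", "Ubc"),
                       groups = c("IRI+Veh", "IRI+NR"),
                       fold_change = list(MtNd1 = c("IRI+NR" = 1.5),
                                          MtCox1 = c("IRI+NR" = 0.5)),
                       ct_noise_sd = 0, sample_shift_sd = 0.4, seed = 5)
  ratios <- mito_dna_ratio(generate_ct_table(p)$table)
  s <- group_fold_summary(ratios)
  expect_equal(s$geo_mean_fold[s$gene == "MtNd1" & s$group == "IRI+NR"], 1.5,
               tolerance = 1e-12)
  expect_equal(s$geo_mean_fold[s$gene == "MtCox1" & s$group == "IRI+NR"], 0.5,
               tolerance = 1e-12)
})

test_that("a single housekeeping gene is rejected", {
  d <- data.frame(sample_id = "s1", group = "g", gene = c("T", "H1"),
                  replicate = 1L, ct = 20)
  tab <- ct_table(d, c(T = "target", H1 = "housekeeping"), "g")
  expect_error(relative_expression(tab), "exactly 2 housekeeping")
})
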