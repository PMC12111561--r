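test_that("Pearson screen applies the one-sided significance rule verbatim", {
  x <- 1:20
  r1 <- pearson_screen(x, x + rnorm(20, sd = 1e-8))
  expect_equal(r1$r, 1, tolerance = 1e-6)
  expect_true(r1$significant)
  # a perfect negative correlation fails the r > 0.2 rule by design
  r2 <- pearson_screen(x, -x)
  expect_equal(r2$r, -1, tolerance = 1e-12)
  expect_false(r2$significant)
  # independent data: |r| stays small at n = 1000
  set.seed(13)
  for (i in 1:3) {
    a <- rnorm(1000); b <- rnorm(1000)
    expect_lt(abs(pearson_screen(a, b)$r), 0.1)
  }
  expect_error(pearson_screen(1:2, 1:2), "n >= 3")
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  expect_equal(auc_with_ci(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auc_with_ci(rep(1, 10), rep(0:1, 5))$auc, 0.5)  # all ties
  expect_equal(auc_with_ci(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(17)
  for (i in 1:10) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(auc_with_ci(s, y)$auc, oracle_auc_pairs(s, y))
  }
})

test_that("AUC is antisymmetric under score negation and CI is ordered", {
  set.seed(19)
  y <- rbinom(30, 1, 0.5); y[1:2] <- 0:1
  s <- rnorm(30)
  a <- auc_with_ci(s, y, seed = 7)
  b <- auc_with_ci(-s, y, seed = 7)
  expect_equal(a$auc + b$auc, 1)
  expect_true(a$lower <= a$auc && a$auc <= a$upper)
  expect_error(auc_with_ci(s, y, n_boot = 50), "n_boot")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- c(0, 1, rbinom(38, 1, 0.4))
  s <- rnorm(40) + y
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(auc_with_ci(s, y)$auc, ref)
})

test_that("logistic fit flags complete separation and caps coefficients", {
  x <- data.frame(f = c(1:6, 11:16))
  y <- rep(c(0, 1), each = 6)
  fit <- fit_logistic(x, y)
  expect_true(fit$separable)
  expect_equal(fit$auc, 1)
  expect_lte(sqrt(sum(fit$coefficients[-1]^2)), 10 + 1e-9)
  expect_error(fit_logistic(x, rep(1, 12)), "binary")
  expect_error(fit_logistic(x[1:4, , drop = FALSE], c(0, 0, 1, 1)), "3 animals")
})

test_that("logistic coefficients are recovered on generated data", {
  set.seed(29)
  n <- 500
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  beta <- c(1.2, -0.8)
  y <- rbinom(n, 1, plogis(x %*% beta))
  fit <- fit_logistic(as.data.frame(x), y)
  expect_false(fit$separable)
  # features are standardised internally; true slopes scale by the sample SD
  truth <- beta * apply(x, 2, sd)
  est <- fit$coefficients[c("a", "b")]
  expect_true(all(abs(est - truth) / abs(truth) < 0.15))
})

test_that("model scores are at chance against permuted labels", {
  set.seed(31)
  x <- data.frame(f1 = rnorm(24), f2 = rnorm(24))
  y <- rep(c(0, 1), 12)
  scores <- fit_logistic(x, y)$scores
  null_aucs <- replicate(500, auc_rank_for_test(scores, sample(y)))
  expect_gte(median(null_aucs), 0.4)
  expect_lte(median(null_aucs), 0.6)
})

test_that("LASSO limits: infinite penalty nulls the model, zero penalty matches MLE", {
  set.seed(37)
  n <- 80
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.8 * x$a))
  # essentially-infinite penalties: all slopes zero, chance AUC
  null_fit <- fit_lasso_logistic(x, y, penalty_grid = c(1000, 999))
  expect_true(all(null_fit$coefficients[-1] == 0))
  expect_equal(null_fit$auc, 0.5)
  # vanishing penalty: scores converge to the unpenalised fit
  small <- fit_lasso_logistic(x, y, penalty_grid = c(2e-6, 1e-6))
  mle <- fit_logistic(x, y)
  expect_false(mle$separable)
  expect_equal(small$scores, mle$scores, tolerance = 1e-4)
})

test_that("LASSO retains informative features among noise at small n", {
  set.seed(41)
  hits <- 0L
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    n <- 24
    x <- matrix(rnorm(10 * n), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- rep(c(0, 1), each = 12)
    x[, 1] <- x[, 1] + 2 * y  # 2-SD effects on the two informative features
    x[, 2] <- x[, 2] - 2 * y
    fit <- fit_lasso_logistic(as.data.frame(x), y)
    if (all(c("f1", "f2") %in% fit$selected_features)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.8)
})
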