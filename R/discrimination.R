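#' Pearson correlation screen
#'
#' Pearson's r with a two-sided t-based p-value, flagged significant under
#' the screening rule r > 0.2 and p < 0.05. Note the rule is one-sided in
#' r: strong *negative* correlations are not flagged — the rule is applied
#' verbatim, not symmetrised.
#'
#' @param x,y numeric vectors, length >= 3, finite.
#' @return A list of class `correlation_result`: `r`, `p`, `n`,
#'   `significant`.
#' @export
pearson_screen <- function(x, y) {
  if (length(x) != length(y)) stop_quant("x and y must have equal length")
  if (length(x) < 3) stop_quant("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_quant("values must be finite")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(r = r, p = ct$p.value, n = length(x),
                 significant = (r > 0.2) && (ct$p.value < 0.05)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.3g, n = %d — %s\n", x$r, x$p, x$n,
              if (x$significant) "significant (r > 0.2, p < 0.05)" else "not significant"))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney) with bootstrap CI
#'
#' AUC computed as the probability that a positive is ranked above a
#' negative (ties count 1/2), via midranks. The confidence interval is a
#' percentile bootstrap over animals, stratified by class so every
#' resample keeps both classes.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (0/1, logical, or two-level factor).
#' @param n_boot bootstrap replicates (>= 200; default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return A list: `auc`, `lower`, `upper`, `n_pos`, `n_neg`, `n_boot`.
#' @export
auc_with_ci <- function(scores, labels, n_boot = 2000, seed = 1L, conf = 0.95) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop_quant("scores and labels must align")
  if (n_boot < 200) stop_quant("n_boot must be >= 200")
  a <- auc_rank(scores, y)
  pos <- which(y == 1); neg <- which(y == 0)
  # sample.int avoids the sample() scalar pitfall when a class has size 1
  resample <- function(idx) idx[sample.int(length(idx), length(idx), replace = TRUE)]
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- c(resample(pos), resample(neg))
    auc_rank(scores[idx], y[idx])
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(auc = a, lower = qs[1], upper = qs[2],
       n_pos = length(pos), n_neg = length(neg), n_boot = n_boot)
}

# Midrank AUC; ties contribute 1/2.
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_quant("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1)) || length(u) < 2)
    stop_quant("labels must be binary with both classes present")
  as.integer(labels)
}

#' Nominal logistic discrimination model
#'
#' Maximum-likelihood logistic regression of a binary group label on a
#' feature subset (features standardised internally). Complete separation
#' — the regime where groups differ so strongly that the likelihood has no
#' finite maximiser — is detected and handled by capping the coefficient
#' norm: the fitted direction is rescaled to L2 norm `coef_norm_cap` on the
#' standardised scale and the fit is flagged `separable` instead of
#' reporting divergent estimates. Scores (fitted probabilities) and their
#' ranking are unaffected by the cap.
#'
#' @param x data.frame or matrix of features (rows = animals).
#' @param y binary labels (0/1, logical or two-level factor).
#' @param feature_subset columns to use (default: all).
#' @param coef_norm_cap L2 cap on the standardised slope vector under
#'   separation (default 10).
#' @return An object of class `logistic_fit`: `coefficients` (standardised
#'   scale), `scores`, `separable`, `auc`, `features`, `center`, `scale`.
#' @export
fit_logistic <- function(x, y, feature_subset = NULL, coef_norm_cap = 10) {
  prep <- prep_features(x, y, feature_subset)
  if (min(table(prep$y)) < 3) stop_quant("need >= 3 animals per class")
  fit_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, prep$xs), prep$y,
                   family = stats::binomial()),
    warning = function(w) {
      fit_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  slopes <- beta[-1]
  norm <- sqrt(sum(slopes^2))
  separable <- fit_warned && norm > coef_norm_cap ||
    max(abs(slopes)) > 50   # runaway estimates without an emitted warning
  if (separable && norm > 0) {
    beta <- beta * (coef_norm_cap / norm)
  }
  eta <- drop(cbind(1, prep$xs) %*% beta)
  scores <- stats::plogis(eta)
  structure(list(coefficients = stats::setNames(beta, c("(Intercept)", prep$features)),
                 scores = scores, separable = separable,
                 auc = auc_rank(scores, prep$y),
                 features = prep$features,
                 center = prep$center, scale = prep$scale,
                 labels = prep$y),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> features: %s | AUC %.3f%s\n",
              paste(x$features, collapse = ", "), x$auc,
              if (x$separable) " | complete separation (coefficients capped)" else ""))
  invisible(x)
}

#' LASSO-penalised logistic discrimination model
#'
#' L1-penalised logistic regression over a log-spaced penalty grid with the
#' penalty chosen by leave-one-out cross-validated binomial deviance — a
#' defensible selection rule at the study's small n. Features are
#' standardised to mean 0, SD 1 before fitting. The unpenalised limit
#' (penalty -> 0) coincides with [fit_logistic()] on non-separable data.
#'
#' @param x data.frame or matrix of features.
#' @param y binary labels.
#' @param feature_subset columns to use (default: all).
#' @param penalty_grid decreasing vector of penalties (glmnet lambda);
#'   default `10^seq(0.5, -4, length.out = 60)`.
#' @return An object of class `lasso_logistic_fit`: `coefficients`
#'   (standardised scale), `penalty` (selected), `selected_features`
#'   (nonzero slopes), `scores`, `auc`, `cv_deviance` (per-penalty mean
#'   LOO deviance), `features`, `center`, `scale`.
#' @export
fit_lasso_logistic <- function(x, y, feature_subset = NULL,
                               penalty_grid = 10^seq(0.5, -4, length.out = 60)) {
  prep <- prep_features(x, y, feature_subset)
  n <- length(prep$y)
  penalty_grid <- sort(penalty_grid, decreasing = TRUE)
  # leave-one-out folds have 1 observation by design; glmnet cautions about
  # small classes per fold, which is the intended regime here
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(prep$xs, prep$y, family = "binomial", alpha = 1,
                      lambda = penalty_grid, standardize = FALSE,
                      nfolds = n, foldid = seq_len(n), grouped = FALSE,
                      type.measure = "deviance"),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  lam <- cv$lambda.min
  co <- as.numeric(stats::coef(cv$glmnet.fit, s = lam))
  names(co) <- c("(Intercept)", prep$features)
  eta <- drop(cbind(1, prep$xs) %*% co)
  scores <- stats::plogis(eta)
  structure(list(coefficients = co, penalty = lam,
                 selected_features = prep$features[co[-1] != 0],
                 scores = scores, auc = auc_rank(scores, prep$y),
                 cv_deviance = data.frame(penalty = cv$lambda, deviance = cv$cvm),
                 features = prep$features,
                 center = prep$center, scale = prep$scale,
                 labels = prep$y),
            class = "lasso_logistic_fit")
}

#' @export
print.lasso_logistic_fit <- function(x, ...) {
  cat(sprintf("<lasso_logistic_fit> penalty %.4g | selected: %s | AUC %.3f\n",
              x$penalty,
              if (length(x$selected_features)) paste(x$selected_features, collapse = ", ")
              else "(none)", x$auc))
  invisible(x)
}

prep_features <- function(x, y, feature_subset) {
  y <- as_binary_labels(y)
  xm <- as.matrix(as.data.frame(x))
  if (is.null(colnames(xm))) colnames(xm) <- paste0("V", seq_len(ncol(xm)))
  if (!is.null(feature_subset)) {
    missing_f <- setdiff(feature_subset, colnames(xm))
    if (length(missing_f))
      stop_quant("unknown feature(s): %s", paste(missing_f, collapse = ", "))
    xm <- xm[, feature_subset, drop = FALSE]
  }
  if (anyNA(xm) || !all(is.finite(xm)))
    stop_quant("features contain missing or non-finite values; exclude rows explicitly")
  if (nrow(xm) != length(y)) stop_quant("features and labels must align")
  ctr <- colMeans(xm)
  scl <- apply(xm, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(xm, 2, ctr), 2, scl, "/")
  list(xs = xs, y = y, features = colnames(xm), center = ctr, scale = scl)
}
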