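# Independent oracles used by the tests. These deliberately use naive,
# direct formulations (exhaustive search, pair enumeration, set arithmetic)
# so they stay independent of the implementation paths they check.

# AUC by exhaustive enumeration of all positive/negative pairs; ties 1/2.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Otsu by brute force: try every observed value as a candidate threshold
# (foreground = strictly above) and maximise the between-class variance.
oracle_otsu_mask <- function(x) {
  v <- as.numeric(x)
  cands <- sort(unique(v))
  cands <- cands[-length(cands)] # all-background split is undefined
  best <- -Inf; best_mask <- NULL
  for (t in cands) {
    fg <- v > t
    w1 <- mean(fg); w0 <- 1 - w1
    bcv <- w0 * w1 * (mean(v[fg]) - mean(v[!fg]))^2
    if (bcv > best) { best <- bcv; best_mask <- fg }
  }
  matrix(best_mask, nrow(x), ncol(x))
}

# Streaming (Welford) mean/SD, an independent route to aggregate statistics.
oracle_streaming_stats <- function(x) {
  m <- 0; s <- 0; n <- 0
  for (xi in x) {
    n <- n + 1
    d <- xi - m
    m <- m + d / n
    s <- s + d * (xi - m)
  }
  list(mean = m, sd = if (n > 1) sqrt(s / (n - 1)) else 0)
}

# Render a centred annulus mask (outer radius r_out, inner radius r_in)
# on an n x n grid, the same discretisation rule as the generator's disks.
render_annulus <- function(n, r_out, r_in) {
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  list(wall = d2 <= r_out^2 & d2 > r_in^2, lumen = d2 <= r_in^2)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Point AUC without the bootstrap, for permutation loops.
auc_rank_for_test <- function(scores, labels) renoquant:::auc_rank(scores, labels)
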