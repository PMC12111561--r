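# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generator functions route their randomness through this,
# so a call is a pure function of (params, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_quant <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop_quant("'%s' must be a single finite number in [0, 1], got %s",
               name, paste(format(x), collapse = ","))
  x
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && (if (strict) all(x > 0) else all(x >= 0))
  if (!ok) stop_quant("'%s' must be %s", name,
                      if (strict) "finite and > 0" else "finite and >= 0")
  x
}

as_mask <- function(x) {
  if (inherits(x, "binary_mask")) return(x$mask)
  if (is.matrix(x)) return(x != 0)
  stop_quant("expected a matrix or a 'binary_mask' object")
}

#' Label connected components of a binary mask
#'
#' Two-dimensional connected-component labelling with selectable pixel
#' connectivity. Foreground pixels are any non-zero entries; labels are
#' assigned in column-major order of first occurrence, starting at 1.
#'
#' @param mask logical or 0/1 matrix (or a [binary_mask]).
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent,
#'   the default used for nucleus counting).
#' @return An integer matrix of the same shape; 0 marks background.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- as_mask(mask)
  if (!connectivity %in% c(4, 8)) stop_quant("connectivity must be 4 or 8")
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  idx <- which(m)
  n <- length(idx)
  if (n == 0L) return(out)
  node_of <- rep(NA_integer_, nr * nc)
  node_of[idx] <- seq_len(n)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (off in offsets) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- node_of[(c2[ok] - 1L) * nr + r2[ok]]
    keep <- !is.na(nb)
    from <- c(from, which(ok)[keep])
    to <- c(to, nb[keep])
  }
  g <- igraph::make_graph(c(rbind(from, to)), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber so labels appear in column-major order of first occurrence
  relab <- integer(max(memb))
  nxt <- 1L
  lab <- integer(n)
  for (i in seq_len(n)) {
    mi <- memb[i]
    if (relab[mi] == 0L) { relab[mi] <- nxt; nxt <- nxt + 1L }
    lab[i] <- relab[mi]
  }
  out[idx] <- lab
  out
}

# Render a filled disk onto a logical matrix (in place semantics via return).
draw_disk <- function(mask, cx, cy, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  hit <- outer(dy^2, dx^2, "+") <= r^2
  mask[rows, cols] <- mask[rows, cols] | hit
  mask
}

# Rejection-sample `n` non-overlapping disk centres (min centre distance
# `min_dist`, margin `r` from the border). Errors after `max_attempts`.
sample_disk_centres <- function(n, nr, nc, r, min_dist, max_attempts = 10000) {
  cx <- numeric(0); cy <- numeric(0)
  attempts <- 0L
  while (length(cx) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_quant(paste0("could not place %d non-overlapping disks of radius %g ",
                        "in a %d x %d image within %d attempts; ",
                        "geometry too crowded"), n, r, nr, nc, max_attempts)
    x <- stats::runif(1, r + 1, nc - r)
    y <- stats::runif(1, r + 1, nr - r)
    if (length(cx) == 0 || all((cx - x)^2 + (cy - y)^2 > min_dist^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  cbind(x = cx, y = cy)
}

# Smooth strictly positive illumination field: tilted plane plus a Gaussian
# bump, rescaled to mean 1 with total relative range `amplitude`.
make_illumination_field <- function(nr, nc, amplitude) {
  if (amplitude < 0 || amplitude >= 2)
    stop_quant("illumination_gradient_amplitude must be in [0, 2)")
  X <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc) - 0.5
  Y <- matrix(rep(seq_len(nr) / nr, nc), nr, nc) - 0.5
  b <- stats::runif(2, -1, 1)
  ctr <- stats::runif(2, -0.25, 0.25)
  s <- stats::runif(1, 0.15, 0.35)
  g <- b[1] * X + b[2] * Y + stats::runif(1, 0.5, 1.5) *
    exp(-((X - ctr[1])^2 + (Y - ctr[2])^2) / (2 * s^2))
  g <- g - mean(g)
  span <- max(g) - min(g)
  if (span > 0) g <- g / span
  1 + amplitude * g
}

# Threshold a smooth random field at an exact area quantile; returns a
# logical matrix whose foreground fraction equals `fraction` up to one pixel.
random_blob_mask <- function(nr, nc, fraction, grid = 12) {
  if (fraction <= 0) return(matrix(FALSE, nr, nc))
  if (fraction >= 1) return(matrix(TRUE, nr, nc))
  coarse <- matrix(stats::rnorm(grid * grid), grid, grid)
  # bilinear upsample to full resolution
  xs <- seq(1, grid, length.out = nc)
  ys <- seq(1, grid, length.out = nr)
  x0 <- pmin(floor(xs), grid - 1L); y0 <- pmin(floor(ys), grid - 1L)
  fx <- xs - x0; fy <- ys - y0
  f00 <- coarse[cbind(rep(y0, nc), rep(x0, each = nr))]
  f10 <- coarse[cbind(rep(y0 + 1, nc), rep(x0, each = nr))]
  f01 <- coarse[cbind(rep(y0, nc), rep(x0 + 1, each = nr))]
  f11 <- coarse[cbind(rep(y0 + 1, nc), rep(x0 + 1, each = nr))]
  wy <- rep(fy, nc); wx <- rep(fx, each = nr)
  field <- matrix((1 - wy) * (1 - wx) * f00 + wy * (1 - wx) * f10 +
                  (1 - wy) * wx * f01 + wy * wx * f11, nr, nc)
  k <- round(fraction * nr * nc)
  cut <- sort(field, decreasing = TRUE)[max(k, 1L)]
  field >= cut
}

# md5 of a file, as character (stable across platforms for text and TIFF).
file_md5 <- function(path) unname(tools::md5sum(path))
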