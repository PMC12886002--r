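# Shared fixtures: small phantom configurations and reference oracles used
# across the module tests. Everything is generated in code at test time.

# Desk-scale phantom sized for 32 px tests (lesions that fit a 24 mm FOV).
small_phantom_config <- function(size = 32L, seed = 1L, ...) {
  phantom_config(image_size = size, diameter_mean_mm = 12, diameter_sd_mm = 5,
                 diameter_min_mm = 4, diameter_max_mm = 18, seed = seed, ...)
}

small_cases <- function(n, size = 32L, seed = 1L, ...) {
  cfg <- small_phantom_config(size = size, seed = seed, ...)
  lapply(seq_len(n), function(i) generate_case(cfg, seed = seed + i))
}

# --- independent oracles ------------------------------------------------------

# Brute-force one-level 2D subband with circular extension: explicit 2D
# convolution with the separable kernel, downsampled by 2 at the analysis
# phase offset.
oracle_dwt2_per <- function(x, f_row, f_col) {
  n1 <- nrow(x); n2 <- ncol(x)
  L1 <- length(f_row); L2 <- length(f_col)
  out <- matrix(0, n1 %/% 2, n2 %/% 2)
  for (k1 in 0:(n1 %/% 2 - 1)) for (k2 in 0:(n2 %/% 2 - 1)) {
    acc <- 0
    for (m1 in seq_len(L1)) for (m2 in seq_len(L2)) {
      i <- (2 * k1 - (m1 - 1) + L1 %/% 2) %% n1 + 1
      j <- (2 * k2 - (m2 - 1) + L2 %/% 2) %% n2 + 1
      acc <- acc + f_row[m1] * f_col[m2] * x[i, j]
    }
    out[k1 + 1, k2 + 1] <- acc
  }
  out
}

# Plain scaled dot-product attention, computed with explicit loops.
oracle_attention <- function(Q, K, V) {
  N <- nrow(Q); dk <- ncol(K)
  out <- matrix(0, N, ncol(V))
  for (i in seq_len(N)) {
    logits <- vapply(seq_len(N), function(j) sum(Q[i, ] * K[j, ]) / sqrt(dk),
                     numeric(1))
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(N)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# All-pairs boundary distances; boundary = mask pixel with a 4-neighbour
# outside the mask (or on the image edge).
oracle_boundary <- function(mask) {
  pts <- which(mask == 1, arr.ind = TRUE)
  keep <- logical(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    i <- pts[r, 1]; j <- pts[r, 2]
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    on_edge <- any(nb[, 1] < 1 | nb[, 1] > nrow(mask) |
                     nb[, 2] < 1 | nb[, 2] > ncol(mask))
    inside <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(mask) &
                   nb[, 2] >= 1 & nb[, 2] <= ncol(mask), , drop = FALSE]
    keep[r] <- on_edge || any(mask[inside] == 0)
  }
  pts[keep, , drop = FALSE]
}

oracle_hausdorff <- function(a, b, spacing) {
  pa <- oracle_boundary(a); pb <- oracle_boundary(b)
  dmat <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
    dmat[i, j] <- sqrt(sum(((pa[i, ] - pb[j, ]) * spacing)^2))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

oracle_max_diameter <- function(mask, spacing) {
  pts <- which(mask == 1, arr.ind = TRUE)
  best <- 0
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts)))
    best <- max(best, sqrt(sum(((pts[i, ] - pts[j, ]) * spacing)^2)))
  best
}

# Random nonempty binary mask.
random_mask <- function(n = 16L, p = 0.25) {
  m <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  if (!any(m == 1)) m[sample.int(n, 1), sample.int(n, 1)] <- 1
  m
}

# Mean of a truncated normal by numerical integration.
truncnorm_mean_numeric <- function(mean, sd, lo, hi) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), lo, hi)$value
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd), lo, hi)$value / z
}
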