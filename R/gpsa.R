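# Gaussian position-sensitive attention: tumor-region intensity statistics,
# multi-scale Gaussian weight maps, rank-1 attention bias, biased
# self-attention, attention-supervision targets, population statistics.

GPSA_EPSILON <- 1e-5
GPSA_SCALES <- c(0.5, 1.0, 2.0)

#' Tumor-region intensity statistics
#'
#' Mean and spread of feature-map values inside the tumor region:
#' `mu = mean(I[mask])`, `sigma = sqrt(mean((I[mask] - mu)^2) + epsilon)`.
#' The stabilizer `epsilon = 1e-5` keeps `sigma` strictly positive even for
#' constant regions. When the mask lives at a finer grid than the feature
#' map, reduce it first with [mask_to_grid()].
#'
#' @param feature_map Numeric matrix `I` (one value per spatial location).
#' @param mask Binary matrix aligned with `feature_map`.
#' @param epsilon Variance stabilizer, default `1e-5`.
#' @param scales Multi-scale width factors, default `c(0.5, 1, 2)`.
#' @return A `gaussian_stats` list with `mu`, `sigma`, `epsilon`, `scales`.
#' @export
tumor_stats <- function(feature_map, mask, epsilon = GPSA_EPSILON,
                        scales = GPSA_SCALES) {
  if (!all(dim(feature_map) == dim(mask)))
    stop("feature_map and mask must be aligned", call. = FALSE)
  sel <- mask == 1
  if (!any(sel))
    stop("empty tumor mask: per-case statistics are undefined; use ",
         "population_stats() from training instead", call. = FALSE)
  mu <- mean(feature_map[sel])
  sigma <- sqrt(mean((feature_map[sel] - mu)^2) + epsilon)
  gaussian_stats(mu, sigma, epsilon, scales)
}

#' Construct Gaussian statistics directly
#'
#' @param mu Mean feature intensity over the tumor region.
#' @param sigma Intensity spread (must satisfy `sigma >= sqrt(epsilon)`).
#' @param epsilon Stabilizer.
#' @param scales Positive multi-scale factors.
#' @return A `gaussian_stats` object.
#' @export
gaussian_stats <- function(mu, sigma, epsilon = GPSA_EPSILON, scales = GPSA_SCALES) {
  if (length(scales) == 0L || any(scales <= 0))
    stop("scales must be a non-empty positive vector", call. = FALSE)
  if (sigma < sqrt(epsilon) - 1e-12)
    stop("sigma must be >= sqrt(epsilon)", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, epsilon = epsilon, scales = scales),
            class = "gaussian_stats")
}

#' Single-scale Gaussian weight map
#'
#' `G = exp(-(I - mu)^2 / (2 (k sigma)^2 + epsilon))`, elementwise; values in
#' `(0, 1]`, equal to 1 exactly where the feature matches the tumor mean.
#'
#' @param feature_map Numeric matrix `I`.
#' @param stats A `gaussian_stats`.
#' @param k Positive scale-width factor.
#' @return Matrix of weights in `(0, 1]`.
#' @export
gaussian_map <- function(feature_map, stats, k = 1.0) {
  if (k <= 0) stop("scale factor k must be positive", call. = FALSE)
  dev2 <- (feature_map - stats$mu)^2
  exp(-dev2 / (2 * (k * stats$sigma)^2 + stats$epsilon))
}

#' Multi-scale Gaussian weight map
#'
#' Unweighted mean of the per-scale maps over `stats$scales`
#' (default `k` in 0.5, 1, 2), capturing both tight and loose intensity
#' neighbourhoods of the tumor mean.
#'
#' @inheritParams gaussian_map
#' @return Matrix of weights in `(0, 1]`.
#' @export
multiscale_gaussian <- function(feature_map, stats) {
  if (length(stats$scales) == 0L) stop("empty scale set", call. = FALSE)
  maps <- lapply(stats$scales, function(k) gaussian_map(feature_map, stats, k))
  Reduce(`+`, maps) / length(maps)
}

#' Build the rank-1 attention bias
#'
#' Flattens the weight map row-major into `g` and forms the bias matrix
#' `B = g g^T` — symmetric, positive semidefinite, rank <= 1 — together with
#' the learnable scale `lambda_bias` (initialized at 0.5).
#'
#' @param G Weight-map matrix with finite positive entries, or a numeric
#'   vector already flattened.
#' @param lambda_bias Initial bias scale.
#' @return An `attention_bias` list with `g`, `B`, `lambda_bias`, `N`.
#' @export
build_bias <- function(G, lambda_bias = 0.5) {
  if (!all(is.finite(G))) stop("non-finite values in weight map", call. = FALSE)
  if (any(G <= 0)) stop("weight map must be strictly positive", call. = FALSE)
  usage_bump("gpsa")
  g <- if (is.matrix(G)) as.vector(t(G)) else as.numeric(G)  # row-major
  structure(list(g = g, B = tcrossprod(g), lambda_bias = lambda_bias,
                 N = length(g)),
            class = "attention_bias")
}

#' Scaled dot-product attention with a Gaussian bias
#'
#' `A = Q K^T / sqrt(d_k) + lambda_bias * B`, `Output = softmax(A) V` with a
#' row-wise softmax. With `lambda_bias = 0` this is standard scaled
#' dot-product attention; with a constant `g` the bias adds the same value to
#' every logit in a row, leaving the softmax unchanged.
#'
#' @param Q,K,V Numeric matrices with `N` rows (tokens); `Q` and `K` share
#'   the key dimension `d_k`.
#' @param bias An [build_bias()] result, or `NULL` for plain attention.
#' @param return_logits Also return the logit matrix `A`.
#' @return Output token matrix (`N x ncol(V)`); with `return_logits = TRUE`,
#'   a list with `output`, `A` and the attention weights `P`.
#' @export
biased_attention <- function(Q, K, V, bias = NULL, return_logits = FALSE) {
  if (nrow(Q) != nrow(K) || nrow(Q) != nrow(V))
    stop("Q, K, V must have equal token counts", call. = FALSE)
  if (ncol(Q) != ncol(K)) stop("Q and K key dimensions differ", call. = FALSE)
  A <- tcrossprod(Q, K) / sqrt(ncol(K))
  if (!is.null(bias)) {
    if (bias$N != nrow(Q))
      stop("bias dimension ", bias$N, " != token count ", nrow(Q), call. = FALSE)
    A <- A + bias$lambda_bias * bias$B
  }
  P <- softmax_rows(A)
  out <- P %*% V
  if (return_logits) list(output = out, A = A, P = P) else out
}

softmax_rows <- function(A) {
  m <- apply(A, 1, max)
  E <- exp(A - m)
  E / rowSums(E)
}

#' Reduce a mask to a coarser token grid
#'
#' Area-fraction pooling: each token cell receives the fraction of tumor
#' pixels it covers; `threshold` turns that into a binary per-token label.
#'
#' @param mask Binary matrix whose sides are multiples of the token grid.
#' @param grid_shape Length-2 token grid shape.
#' @param threshold Binarization threshold on the area fraction (0.5), or
#'   `NA` to return the raw fractions.
#' @return Matrix of shape `grid_shape`.
#' @export
mask_to_grid <- function(mask, grid_shape, threshold = 0.5) {
  g1 <- grid_shape[1]; g2 <- grid_shape[2]
  if (g1 > nrow(mask) || g2 > ncol(mask))
    stop("token grid larger than the mask", call. = FALSE)
  if (nrow(mask) %% g1 != 0 || ncol(mask) %% g2 != 0)
    stop("mask sides must be multiples of the token grid", call. = FALSE)
  f1 <- nrow(mask) %/% g1; f2 <- ncol(mask) %/% g2
  frac <- matrix(0, g1, g2)
  ri <- (seq_len(nrow(mask)) - 1L) %/% f1 + 1L
  ci <- (seq_len(ncol(mask)) - 1L) %/% f2 + 1L
  frac <- rowsum(t(rowsum(mask + 0, ri)), ci)  # g2 x g1 sums
  frac <- t(frac) / (f1 * f2)
  if (is.na(threshold)) frac else (frac >= threshold) + 0
}

#' Per-token attention supervision target
#'
#' Downsamples the pixel mask to the token grid (area fraction, threshold
#' 0.5) and flattens it row-major into the binary label vector the attention
#' supervision loss compares against.
#'
#' @param mask Binary pixel mask.
#' @param token_grid_shape Length-2 token grid shape.
#' @return Binary vector of length `prod(token_grid_shape)`.
#' @export
attention_supervision_target <- function(mask, token_grid_shape) {
  as.vector(t(mask_to_grid(mask, token_grid_shape, threshold = 0.5)))
}

#' Attention supervision loss
#'
#' Scores how well attention lands on tumor tokens: each query row of the
#' logit matrix is softmaxed into an attended-mass distribution over tokens,
#' which is compared to the binary token target with binary cross-entropy
#' (probabilities clamped to `[1e-7, 1 - 1e-7]`); the result is averaged over
#' queries. Nonnegative; lower when attended mass concentrates on tumor
#' tokens.
#'
#' @param A `N x N` attention logit matrix.
#' @param target Binary token target of length `N`.
#' @return Scalar loss.
#' @export
attention_supervision_loss <- function(A, target) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square logit matrix", call. = FALSE)
  if (length(target) != nrow(A))
    stop("target length ", length(target), " != token count ", nrow(A),
         call. = FALSE)
  P <- softmax_rows(A)
  P <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  tg <- matrix(target, nrow = nrow(A), ncol = ncol(A), byrow = TRUE)
  bce <- -(tg * log(P) + (1 - tg) * log(1 - P))
  mean(rowMeans(bce))
}

#' Population-level Gaussian statistics
#'
#' Plain averages of the per-case means and spreads accumulated during
#' training; used at inference when no annotation is available to drive the
#' per-case statistics.
#'
#' @param per_case_stats Non-empty list of `gaussian_stats`.
#' @return A `gaussian_stats` with `mu_learned`/`sigma_learned` semantics.
#' @export
population_stats <- function(per_case_stats) {
  if (length(per_case_stats) == 0L)
    stop("empty statistics list", call. = FALSE)
  mu <- mean(vapply(per_case_stats, `[[`, numeric(1), "mu"))
  sigma <- mean(vapply(per_case_stats, `[[`, numeric(1), "sigma"))
  eps <- per_case_stats[[1]]$epsilon
  gaussian_stats(mu, sigma, eps, per_case_stats[[1]]$scales)
}

# Token-grid mask with a small-lesion fallback: area-fraction pooling at
# threshold 0.5; when a lesion is too small to claim half of any token cell,
# the cell(s) with the largest tumor fraction stand in, so per-case
# statistics stay defined for Tiny lesions. NULL for an empty pixel mask.
grid_mask_robust <- function(mask, grid_side) {
  frac <- mask_to_grid(mask, c(grid_side, grid_side), threshold = NA)
  gm <- (frac >= 0.5) + 0
  if (!any(gm == 1)) {
    if (max(frac) <= 0) return(NULL)
    gm <- (frac == max(frac)) + 0
  }
  gm
}
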