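# CT preprocessing: HU windowing to [0,1], resampling to a target mm grid,
# and paired image/mask augmentation (rotation, scaling, horizontal flip).

#' Preprocessing configuration
#'
#' HU values are clipped to the liver window \[-150, 250\] HU and scaled to
#' \[0, 1\]; volumes are resampled to 0.75 x 0.75 x 1.5 mm^3; training-time
#' augmentation draws a rotation in +/-15 degrees, an isotropic scale in
#' \[0.9, 1.1\] and a horizontal flip with probability 0.5. Augmentation is a
#' training-time operation only; validation and test data pass through
#' untouched.
#'
#' @param hu_window Length-2 `(low, high)` HU window.
#' @param target_spacing_mm Length-3 target spacing in mm.
#' @param rotation_deg Maximum absolute rotation angle (degrees).
#' @param scale_range Length-2 scale factor range.
#' @param hflip_prob Horizontal-flip probability in \[0, 1\].
#' @param augment_enabled Master switch for [augment()].
#' @param seed Seed for augmentation draws.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(hu_window = c(-150, 250),
                              target_spacing_mm = c(0.75, 0.75, 1.5),
                              rotation_deg = 15,
                              scale_range = c(0.9, 1.1),
                              hflip_prob = 0.5,
                              augment_enabled = TRUE,
                              seed = 1L) {
  if (hu_window[1] >= hu_window[2])
    stop("hu_window low must be < high", call. = FALSE)
  if (scale_range[1] >= scale_range[2])
    stop("scale_range low must be < high", call. = FALSE)
  if (hflip_prob < 0 || hflip_prob > 1)
    stop("hflip_prob must be in [0, 1]", call. = FALSE)
  structure(list(hu_window = hu_window, target_spacing_mm = target_spacing_mm,
                 rotation_deg = rotation_deg, scale_range = scale_range,
                 hflip_prob = hflip_prob, augment_enabled = augment_enabled,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Clip HU values and scale to the unit interval
#'
#' `out = (clip(v, low, high) - low) / (high - low)`, a monotone map of the
#' HU axis onto \[0, 1\].
#'
#' @param volume A [ct_volume()] or numeric array.
#' @param window Length-2 `(low, high)` HU window, default `c(-150, 250)`.
#' @return Same type as the input, values in \[0, 1\].
#' @export
hu_clip_normalize <- function(volume, window = c(-150, 250)) {
  if (window[1] >= window[2])
    stop("degenerate HU window: low must be < high", call. = FALSE)
  f <- function(v) (pmin(pmax(v, window[1]), window[2]) - window[1]) /
    (window[2] - window[1])
  if (inherits(volume, "ct_volume")) {
    volume$data <- f(volume$data)
    volume
  } else f(volume)
}

# Separable linear interpolation of an array along one dimension onto new
# (0-based, voxel-center) coordinates given in units of source voxels.
interp_axis <- function(arr, axis, new_coords, nearest = FALSE) {
  d <- dim(arr) %||% length(arr)
  n <- d[axis]
  x <- pmin(pmax(new_coords, 0), n - 1)
  if (nearest) {
    idx <- round(x) + 1
    return(index_axis(arr, axis, idx))
  }
  i0 <- pmin(floor(x), n - 2); w <- x - i0
  a0 <- index_axis(arr, axis, i0 + 1)
  a1 <- index_axis(arr, axis, i0 + 2)
  if (length(d) == 1L) return(a0 * (1 - w) + a1 * w)
  perm_to_first <- c(axis, setdiff(seq_along(d), axis))
  a0p <- aperm(a0, perm_to_first); a1p <- aperm(a1, perm_to_first)
  outp <- a0p * (1 - w) + a1p * w
  aperm(outp, order(perm_to_first))
}

index_axis <- function(arr, axis, idx) {
  d <- dim(arr)
  if (is.null(d)) return(arr[idx])
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

#' Resample a CT volume to a target spacing
#'
#' Linear interpolation (separable, axis by axis) onto the target mm grid;
#' the output shape is `round(shape * spacing / target)`. Masks must be
#' resampled with `nearest = TRUE` to stay binary.
#'
#' @param volume A [ct_volume()], or a plain array with `spacing` given.
#' @param target_spacing Target spacing (mm), one value per array dimension
#'   or length 3 (extra entries ignored for 2D input).
#' @param spacing Source spacing when `volume` is a plain array.
#' @param nearest Use nearest-neighbour interpolation (for masks).
#' @return Same type as the input with updated spacing.
#' @export
resample <- function(volume, target_spacing, spacing = NULL, nearest = FALSE) {
  is_cv <- inherits(volume, "ct_volume")
  arr <- if (is_cv) volume$data else volume
  src <- if (is_cv) volume$spacing else spacing
  if (is.null(src)) stop("source `spacing` required", call. = FALSE)
  nd <- length(dim(arr) %||% length(arr))
  src <- src[seq_len(nd)]
  tgt <- target_spacing[seq_len(nd)]
  if (any(tgt <= 0) || any(src <= 0))
    stop("spacings must be positive", call. = FALSE)
  d <- dim(arr) %||% length(arr)
  for (ax in seq_len(nd)) {
    if (abs(src[ax] - tgt[ax]) < 1e-12) next
    n_new <- max(1L, round(d[ax] * src[ax] / tgt[ax]))
    # voxel-center alignment: first output center maps onto first input center
    coords <- (seq_len(n_new) - 1) * tgt[ax] / src[ax]
    arr <- interp_axis(arr, ax, coords, nearest = nearest)
    d <- dim(arr) %||% length(arr)
  }
  if (is_cv) {
    volume$data <- arr
    volume$spacing[seq_len(nd)] <- tgt
    volume
  } else arr
}

# Bilinear (or nearest) sampling of `img` at a grid mapped through the
# inverse affine: out(r, c) = img(A %*% (r, c) + t), coordinates in pixels
# about the image centre.
affine_sample <- function(img, A_inv, nearest = FALSE) {
  n1 <- nrow(img); n2 <- ncol(img)
  ctr <- c((n1 + 1) / 2, (n2 + 1) / 2)
  g <- expand.grid(r = seq_len(n1) - ctr[1], c = seq_len(n2) - ctr[2])
  src_r <- A_inv[1, 1] * g$r + A_inv[1, 2] * g$c + ctr[1]
  src_c <- A_inv[2, 1] * g$r + A_inv[2, 2] * g$c + ctr[2]
  if (nearest) {
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 1 & ri <= n1 & ci >= 1 & ci <= n2
    out <- numeric(n1 * n2)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    return(matrix(out, n1, n2))
  }
  r0 <- floor(src_r); c0 <- floor(src_c)
  wr <- src_r - r0; wc <- src_c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n1 & ci >= 1 & ci <= n2
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  out <- val(r0, c0) * (1 - wr) * (1 - wc) + val(r0 + 1, c0) * wr * (1 - wc) +
    val(r0, c0 + 1) * (1 - wr) * wc + val(r0 + 1, c0 + 1) * wr * wc
  matrix(out, n1, n2)
}

#' Paired image/mask augmentation
#'
#' Samples one transform — rotation angle in `+/-rotation_deg`, isotropic
#' scale in `scale_range`, horizontal flip with probability `hflip_prob`,
#' all three composed into a single affine — and applies it to the image
#' (bilinear interpolation, one resampling pass) and the mask
#' (nearest-neighbour, so it stays binary). Shapes never change.
#'
#' @param image Numeric matrix.
#' @param mask Binary matrix aligned with `image` (optional).
#' @param config A [preprocess_config()].
#' @param seed Seed for the transform draw.
#' @param force Optional list to pin components for testing:
#'   `list(angle_deg =, scale =, flip =)`.
#' @return List with `image`, `mask` and the sampled `transform`.
#' @export
augment <- function(image, mask = NULL, config = preprocess_config(),
                    seed = config$seed, force = NULL) {
  if (!is.null(mask) && !all(dim(image) == dim(mask)))
    stop("image and mask must be aligned", call. = FALSE)
  if (!config$augment_enabled && is.null(force))
    return(list(image = image, mask = mask,
                transform = list(angle_deg = 0, scale = 1, flip = FALSE)))
  tr <- with_seed(seed, list(
    angle_deg = stats::runif(1, -config$rotation_deg, config$rotation_deg),
    scale = stats::runif(1, config$scale_range[1], config$scale_range[2]),
    flip = stats::runif(1) < config$hflip_prob
  ))
  if (!is.null(force)) tr <- utils::modifyList(tr, force)
  th <- tr$angle_deg * pi / 180
  # forward affine = flip o scale o rotation; sampling uses its inverse
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- diag(2) * tr$scale
  Fm <- diag(c(1, if (tr$flip) -1 else 1))
  A <- Fm %*% S %*% R
  A_inv <- solve(A)
  out_img <- affine_sample(image, A_inv, nearest = FALSE)
  out_mask <- if (!is.null(mask)) affine_sample(mask, A_inv, nearest = TRUE)
  list(image = out_img, mask = out_mask, transform = tr)
}
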