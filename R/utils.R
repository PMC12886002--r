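`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based sub-stream derivation: one master seed plus a counter yields
# an independent, reproducible seed for any case/phase without generating the
# ones before it. Kept below 2^31 for R's integer seeds.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483647)
}

#' CT volume container
#'
#' A minimal container for an HU-valued voxel grid: the array (2D slice or 3D
#' stack), its physical spacing in mm, and the acquisition phase.
#'
#' @param data Numeric matrix (slice) or 3D array (stack).
#' @param spacing Numeric length-3 vector `(row_mm, col_mm, slice_mm)`,
#'   default `c(0.75, 0.75, 1.5)`.
#' @param phase `"noncontrast"` or `"venous"`.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(data, spacing = c(0.75, 0.75, 1.5),
                      phase = c("noncontrast", "venous")) {
  phase <- match.arg(phase)
  if (!is.numeric(data) || !(length(dim(data)) %in% c(2L, 3L)))
    stop("`data` must be a numeric matrix or 3D array", call. = FALSE)
  if (length(spacing) == 2L) spacing <- c(spacing, 1.5)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values", call. = FALSE)
  structure(list(data = data, spacing = as.numeric(spacing), phase = phase),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume>", x$phase, paste(dim(x$data), collapse = "x"),
      "voxels @", paste(signif(x$spacing, 4), collapse = "x"), "mm\n")
  invisible(x)
}

is_binary_mask <- function(m) is.numeric(m) && all(m %in% c(0, 1))
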