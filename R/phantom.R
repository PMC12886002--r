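# Paired-phase synthetic CT phantom generator. Emulates the statistical
# structure the cross-phase method assumes: identical anatomy in both phases,
# tumors strongly hypodense in the venous phase and faintly hypodense without
# contrast, lesion diameters from a truncated normal, calibrated mm spacing.

#' Phantom generator configuration
#'
#' Defines the study conditions the generator emulates. Lesion maximum
#' diameters follow a truncated normal with mean 24.6 mm, sd 18.3 mm on
#' \[3.2, 87.5\] mm; in-plane pixel spacing is 0.75 x 0.75 mm^2 with 1.5 mm
#' slices. The defining premise of the paired phases is that the venous-phase
#' tumor/parenchyma HU offset strictly exceeds the non-contrast offset in
#' magnitude (conspicuous with contrast agent, subtle without). The intensity
#' model itself is free: defaults are parenchyma 60 HU, tumor offset -40 HU
#' (venous) and -12 HU (non-contrast), additive noise sd 8 HU.
#'
#' @param image_size Pixels per side (default 64, the desk-scale size).
#' @param pixel_spacing_mm In-plane spacing `(row, col)` in mm.
#' @param slice_thickness_mm Slice thickness in mm.
#' @param n_tumors_per_slice Number of lesions per case (>= 0).
#' @param diameter_mean_mm,diameter_sd_mm,diameter_min_mm,diameter_max_mm
#'   Truncated-normal parameters of the lesion maximum diameter (mm).
#' @param liver_hu Parenchyma HU level.
#' @param liver_texture_sd_hu Sd of the smooth parenchymal texture shared by
#'   both phases (anatomy, not noise).
#' @param tumor_contrast_hu Named numeric: tumor-minus-liver HU offset per
#'   phase, `c(noncontrast = -12, venous = -40)`.
#' @param noise_sd_hu Sd of phase-independent additive noise.
#' @param eccentricity_range Lesion major/minor axis ratio range.
#' @param n_slices 1 for 2D slices (default); > 1 builds a thin 3D stack.
#' @param seed Master seed for the generator's counter-based streams.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 64L,
                           pixel_spacing_mm = c(0.75, 0.75),
                           slice_thickness_mm = 1.5,
                           n_tumors_per_slice = 1L,
                           diameter_mean_mm = 24.6,
                           diameter_sd_mm = 18.3,
                           diameter_min_mm = 3.2,
                           diameter_max_mm = 87.5,
                           liver_hu = 60,
                           liver_texture_sd_hu = 5,
                           tumor_contrast_hu = c(noncontrast = -12, venous = -40),
                           noise_sd_hu = 8,
                           eccentricity_range = c(1.0, 1.8),
                           n_slices = 1L,
                           seed = 1L) {
  if (diameter_min_mm >= diameter_max_mm)
    stop("diameter bounds invalid: min must be < max", call. = FALSE)
  if (diameter_sd_mm <= 0) stop("diameter sd must be positive", call. = FALSE)
  if (n_tumors_per_slice < 0) stop("n_tumors_per_slice must be >= 0", call. = FALSE)
  if (!all(c("noncontrast", "venous") %in% names(tumor_contrast_hu)))
    stop("tumor_contrast_hu needs 'noncontrast' and 'venous' entries", call. = FALSE)
  if (abs(tumor_contrast_hu[["venous"]]) <= abs(tumor_contrast_hu[["noncontrast"]]))
    stop("venous tumor contrast must exceed the non-contrast contrast in ",
         "magnitude (the generator's defining premise)", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size),
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    slice_thickness_mm = slice_thickness_mm,
    n_tumors_per_slice = as.integer(n_tumors_per_slice),
    diameter_mean_mm = diameter_mean_mm, diameter_sd_mm = diameter_sd_mm,
    diameter_min_mm = diameter_min_mm, diameter_max_mm = diameter_max_mm,
    liver_hu = liver_hu, liver_texture_sd_hu = liver_texture_sd_hu,
    tumor_contrast_hu = tumor_contrast_hu, noise_sd_hu = noise_sd_hu,
    eccentricity_range = eccentricity_range,
    n_slices = as.integer(n_slices), seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Sample lesion maximum diameters
#'
#' Draws `n` diameters (mm) from the truncated normal defined by the config
#' (inverse-CDF sampling, so every draw lies inside the bounds exactly).
#'
#' @param config A [phantom_config()].
#' @param n Number of draws (>= 0).
#' @param seed Optional seed; defaults to the config's.
#' @return Numeric vector of length `n`, all within
#'   `[diameter_min_mm, diameter_max_mm]`.
#' @export
sample_tumor_diameters <- function(config, n, seed = config$seed) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    plo <- stats::pnorm(config$diameter_min_mm, config$diameter_mean_mm, config$diameter_sd_mm)
    phi <- stats::pnorm(config$diameter_max_mm, config$diameter_mean_mm, config$diameter_sd_mm)
    u <- stats::runif(n, plo, phi)
    stats::qnorm(u, config$diameter_mean_mm, config$diameter_sd_mm)
  })
}

# Smooth shared parenchymal texture: white noise blurred with a separable
# moving average, rescaled to the requested sd.
smooth_texture <- function(n1, n2, sd_hu, width = 5L) {
  if (sd_hu <= 0) return(matrix(0, n1, n2))
  z <- matrix(stats::rnorm(n1 * n2), n1, n2)
  k <- rep(1 / width, width)
  z <- apply(z, 2, function(v) stats::filter(v, k, circular = TRUE))
  z <- t(apply(z, 1, function(v) stats::filter(v, k, circular = TRUE)))
  sd_hu * z / stats::sd(z)
}

# Rasterize an axis-aligned ellipse on the pixel-center grid (mm coordinates).
ellipse_mask <- function(n1, n2, spacing, center, semi_row, semi_col) {
  rr <- ((seq_len(n1) - 0.5) * spacing[1] - center[1]) / semi_row
  cc <- ((seq_len(n2) - 0.5) * spacing[2] - center[2]) / semi_col
  outer(rr^2, cc^2, `+`) <= 1
}

#' Generate one paired-phase phantom case
#'
#' Builds a non-contrast/venous slice pair with identical anatomy (shared
#' parenchymal texture), elliptical tumors offset from parenchyma by the
#' phase-specific contrast, independent additive noise per phase, and the
#' binary tumor mask. Lesion placement is retried (resampling diameter and
#' center) when an ellipse does not fit the field of view or would overlap an
#' existing lesion; generation fails after `max_retries` attempts.
#'
#' @param config A [phantom_config()].
#' @param seed Case seed (defaults to the config's master seed).
#' @param diameters_mm Optional fixed lesion diameters (mm), bypassing the
#'   truncated-normal draw; length must equal `n_tumors_per_slice`.
#' @param max_retries Placement attempts per lesion before erroring.
#' @return A `phantom_case`: `noncontrast` and `venous` [ct_volume()]s, the
#'   binary `mask`, and `tumor_records` (center, measured maximum diameter in
#'   mm, size stratum).
#' @export
generate_case <- function(config, seed = config$seed, diameters_mm = NULL,
                          max_retries = 100L) {
  n <- config$image_size
  sp <- c(config$pixel_spacing_mm, config$slice_thickness_mm)
  nt <- config$n_tumors_per_slice
  if (!is.null(diameters_mm) && length(diameters_mm) != nt)
    stop("diameters_mm must have length n_tumors_per_slice", call. = FALSE)
  with_seed(derive_seed(seed, 1L), {
    mask <- matrix(0L, n, n)
    placed <- list()
    for (t in seq_len(nt)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        d <- if (is.null(diameters_mm))
          sample_tumor_diameters(config, 1, seed = derive_seed(seed, 100L + 7L * t + try))
        else diameters_mm[t]
        ecc <- stats::runif(1, config$eccentricity_range[1], config$eccentricity_range[2])
        semi_col <- d / 2                # major axis along columns
        semi_row <- d / (2 * ecc)
        fov <- c(n * sp[1], n * sp[2])
        margin <- 2 * sp[1:2]
        lo <- c(semi_row, semi_col) + margin
        hi <- c(fov[1] - semi_row, fov[2] - semi_col) - margin
        if (any(hi <= lo)) {
          if (!is.null(diameters_mm))
            stop("tumor diameter ", signif(d, 4), " mm exceeds the field of view",
                 call. = FALSE)
          next
        }
        center <- stats::runif(2, lo, hi)
        cand <- ellipse_mask(n, n, sp, center, semi_row, semi_col)
        if (!any(cand)) next
        if (any(cand & (dilate3x3(mask == 1L)))) next   # keep lesions disjoint
        mask[cand] <- 1L
        placed[[t]] <- list(center = center, component = cand)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place tumor ", t, " after ", max_retries,
             " attempts (diameters too large for the field of view?)",
             call. = FALSE)
    }
    texture <- smooth_texture(n, n, config$liver_texture_sd_hu)
    base <- config$liver_hu + texture
    make_phase <- function(phase, counter) {
      img <- base + config$tumor_contrast_hu[[phase]] * (mask == 1L)
      if (config$noise_sd_hu > 0) {
        noise <- with_seed(derive_seed(seed, counter),
                           matrix(stats::rnorm(n * n, 0, config$noise_sd_hu), n, n))
        img <- img + noise
      }
      img
    }
    nc <- make_phase("noncontrast", 2L)
    ve <- make_phase("venous", 3L)
    if (config$n_slices > 1L) {
      nc <- replicate(config$n_slices, nc)
      ve <- replicate(config$n_slices, ve)
      mask3 <- replicate(config$n_slices, mask)
      mask <- mask3
    }
    records <- if (length(placed)) {
      do.call(rbind, lapply(seq_along(placed), function(i) {
        comp <- placed[[i]]$component
        dmm <- max_diameter_mm(comp, sp[1:2])
        data.frame(tumor = i,
                   center_row_mm = placed[[i]]$center[1],
                   center_col_mm = placed[[i]]$center[2],
                   max_diameter_mm = dmm,
                   stratum = stratify(dmm),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(tumor = integer(0), center_row_mm = numeric(0),
                 center_col_mm = numeric(0), max_diameter_mm = numeric(0),
                 stratum = character(0), stringsAsFactors = FALSE)
    }
    structure(list(
      noncontrast = ct_volume(nc, sp, "noncontrast"),
      venous = ct_volume(ve, sp, "venous"),
      mask = mask,
      tumor_records = records,
      seed = seed
    ), class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case>", paste(dim(x$mask), collapse = "x"), "voxels,",
      nrow(x$tumor_records), "tumor(s)\n")
  invisible(x)
}

#' Generate a split phantom dataset
#'
#' Generates `n_cases` independent cases (counter-based seeds, so any case is
#' regenerable in isolation) and splits them case-wise into disjoint
#' train/validation/test sets. Validation and test sizes are
#' `floor(n * fraction)`; training takes the remainder, so 654 cases under an
#' 80/10/10 split give 524/65/65.
#'
#' @param config A [phantom_config()].
#' @param n_cases Number of cases.
#' @param split Length-3 fractions (train, val, test) summing to 1.
#' @param seed Master seed (defaults to the config's).
#' @return List with `train`, `val`, `test` lists of `phantom_case`s.
#' @export
generate_dataset <- function(config, n_cases, split = c(0.8, 0.1, 0.1),
                             seed = config$seed) {
  if (length(split) != 3L || abs(sum(split) - 1) > 1e-8)
    stop("`split` must be three fractions summing to 1", call. = FALSE)
  n_val <- floor(n_cases * split[2])
  n_test <- floor(n_cases * split[3])
  n_train <- n_cases - n_val - n_test
  if (n_train < 1 || (split[2] > 0 && n_val < 1) || (split[3] > 0 && n_test < 1))
    stop("n_cases = ", n_cases, " too small for split ",
         paste(split, collapse = "/"), call. = FALSE)
  cases <- lapply(seq_len(n_cases), function(i)
    generate_case(config, seed = derive_seed(seed, 1000L + i)))
  perm <- with_seed(derive_seed(seed, 2L), sample.int(n_cases))
  list(train = cases[perm[seq_len(n_train)]],
       val = cases[perm[n_train + seq_len(n_val)]],
       test = cases[perm[n_train + n_val + seq_len(n_test)]])
}

#' Write a phantom case to NIfTI
#'
#' Writes the two phase volumes and the mask as `.nii.gz` files with the
#' voxel spacing in the header, plus the tumor manifest as CSV.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_case_nifti <- function(case, dir, prefix = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- case$noncontrast$spacing
  wr <- function(arr, name) {
    path <- file.path(dir, paste0(prefix, "_", name, ".nii.gz"))
    img <- RNifti::asNifti(arr + 0)
    RNifti::pixdim(img) <- sp[seq_along(dim(arr))]
    RNifti::writeNifti(img, path)
    path
  }
  paths <- c(wr(case$noncontrast$data, "noncontrast"),
             wr(case$venous$data, "venous"),
             wr(case$mask + 0, "mask"))
  manifest <- file.path(dir, paste0(prefix, "_tumors.csv"))
  utils::write.csv(case$tumor_records, manifest, row.names = FALSE)
  invisible(c(paths, manifest))
}

#' Read a phantom case from NIfTI
#'
#' Inverse of [write_case_nifti()].
#'
#' @param dir Directory containing the files.
#' @param prefix File name prefix used at write time.
#' @return A `phantom_case` (tumor records restored from the manifest).
#' @export
read_case_nifti <- function(dir, prefix = "case") {
  rd <- function(name) {
    img <- RNifti::readNifti(file.path(dir, paste0(prefix, "_", name, ".nii.gz")))
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))
    list(data = arr, spacing = RNifti::pixdim(img))
  }
  nc <- rd("noncontrast"); ve <- rd("venous"); mk <- rd("mask")
  sp <- nc$spacing
  if (length(sp) < 3) sp <- c(sp, 1.5)
  structure(list(
    noncontrast = ct_volume(nc$data, sp, "noncontrast"),
    venous = ct_volume(ve$data, sp, "venous"),
    mask = round(mk$data),
    tumor_records = utils::read.csv(file.path(dir, paste0(prefix, "_tumors.csv")),
                                    stringsAsFactors = FALSE),
    seed = NA_integer_
  ), class = "phantom_case")
}
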