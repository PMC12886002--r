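# Segmentation metrics (Dice, IoU, pixel accuracy, Hausdorff distance in mm),
# lesion diameter measurement, tumor-size strata, and the reporting harnesses.

#' Dice, IoU and pixel accuracy
#'
#' Overlap metrics between two aligned binary masks, as percentages:
#' `dice = 200 |T n P| / (|T| + |P|)`, `iou = 100 |T n P| / |T u P|`,
#' `acc = 100 (TP + TN) / total`. When both masks are empty the segmentation
#' is vacuously correct: dice and iou are reported as 100.
#'
#' @param truth,pred Aligned binary masks (matrix or array).
#' @return Named numeric vector `c(dice, iou, acc)` in percent.
#' @export
dice_iou_acc <- function(truth, pred) {
  if (!all(dim(truth) == dim(pred)))
    stop("mask shapes differ", call. = FALSE)
  if (!is_binary_mask(truth) || !is_binary_mask(pred))
    stop("masks must be binary", call. = FALSE)
  t1 <- sum(truth == 1); p1 <- sum(pred == 1)
  inter <- sum(truth == 1 & pred == 1)
  union <- t1 + p1 - inter
  dice <- if (t1 + p1 == 0) 100 else 200 * inter / (t1 + p1)
  iou <- if (union == 0) 100 else 100 * inter / union
  acc <- 100 * sum(truth == pred) / length(truth)
  c(dice = dice, iou = iou, acc = acc)
}

# Boundary pixels: mask pixels with at least one 4-neighbour outside the mask
# (image border counts as outside-adjacent).
boundary_pixels <- function(mask) {
  m <- mask == 1
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- matrix(FALSE, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- m
  core <- pad[1:n1, 2:(n2 + 1)] & pad[3:(n1 + 2), 2:(n2 + 1)] &
    pad[2:(n1 + 1), 1:n2] & pad[2:(n1 + 1), 3:(n2 + 2)]
  which(m & !core, arr.ind = TRUE)
}

directed_hausdorff <- function(from_mm, to_mm) {
  max(vapply(seq_len(nrow(from_mm)), function(i) {
    d2 <- (to_mm[, 1] - from_mm[i, 1])^2 + (to_mm[, 2] - from_mm[i, 2])^2
    sqrt(min(d2))
  }, numeric(1)))
}

#' Hausdorff distance between mask boundaries (mm)
#'
#' Symmetric maximum of the directed nearest-boundary distances between the
#' two mask surfaces, with pixel coordinates scaled by the in-plane spacing.
#' The maximum (100th percentile) variant is the default; `percentile = 95`
#' gives HD95. For 3D inputs the distance is computed per slice and averaged
#' over slices where both masks are nonempty.
#'
#' @param truth,pred Aligned binary masks.
#' @param spacing In-plane spacing `(row_mm, col_mm)`, default 0.75 mm.
#' @param percentile Percentile of the boundary distance distribution (100 =
#'   classic Hausdorff).
#' @return Distance in mm, or `NA` with a `"missing_reason"` attribute when
#'   either mask is empty.
#' @export
hausdorff_mm <- function(truth, pred, spacing = c(0.75, 0.75), percentile = 100) {
  if (!all(dim(truth) == dim(pred)))
    stop("mask shapes differ", call. = FALSE)
  if (length(dim(truth)) == 3L) {
    vals <- vapply(seq_len(dim(truth)[3]), function(s)
      hausdorff_mm(truth[, , s], pred[, , s], spacing, percentile), numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L)
      return(structure(NA_real_, missing_reason = "empty mask"))
    return(mean(vals))
  }
  if (!any(truth == 1) || !any(pred == 1))
    return(structure(NA_real_, missing_reason = "empty mask"))
  bt <- boundary_pixels(truth); bp <- boundary_pixels(pred)
  tm <- cbind(bt[, 1] * spacing[1], bt[, 2] * spacing[2])
  pm <- cbind(bp[, 1] * spacing[1], bp[, 2] * spacing[2])
  if (percentile >= 100) {
    max(directed_hausdorff(tm, pm), directed_hausdorff(pm, tm))
  } else {
    d_tp <- vapply(seq_len(nrow(tm)), function(i)
      sqrt(min((pm[, 1] - tm[i, 1])^2 + (pm[, 2] - tm[i, 2])^2)), numeric(1))
    d_pt <- vapply(seq_len(nrow(pm)), function(i)
      sqrt(min((tm[, 1] - pm[i, 1])^2 + (tm[, 2] - pm[i, 2])^2)), numeric(1))
    max(stats::quantile(d_tp, percentile / 100, names = FALSE),
        stats::quantile(d_pt, percentile / 100, names = FALSE))
  }
}

#' Maximum lesion diameter (mm)
#'
#' Maximum pairwise Euclidean distance between boundary pixel centres of a
#' connected mask component, scaled by the in-plane spacing — the clinical
#' "maximum diameter" measurement.
#'
#' @param mask_component Binary matrix containing one lesion.
#' @param spacing In-plane spacing `(row_mm, col_mm)`.
#' @return Diameter in mm (0 for a single-pixel lesion).
#' @export
max_diameter_mm <- function(mask_component, spacing = c(0.75, 0.75)) {
  if (!any(mask_component == 1))
    stop("empty mask component", call. = FALSE)
  b <- boundary_pixels(mask_component)
  if (nrow(b) == 1L) return(0)
  pts <- cbind(b[, 1] * spacing[1], b[, 2] * spacing[2])
  max(stats::dist(pts))
}

#' Tumor size strata
#'
#' Half-open diameter intervals: Tiny `[0, 10)` mm, Small `[10, 20)` mm,
#' Big `[20, Inf)` mm.
#'
#' @param diameters_mm Nonnegative diameters in mm.
#' @return Character vector of `"Tiny"`, `"Small"`, `"Big"`.
#' @export
stratify <- function(diameters_mm) {
  if (any(diameters_mm < 0)) stop("negative diameter", call. = FALSE)
  cut(diameters_mm, breaks = c(-Inf, 10, 20, Inf), right = FALSE,
      labels = c("Tiny", "Small", "Big")) |> as.character()
}

case_stratum <- function(case) {
  if (nrow(case$tumor_records) == 0L) return(NA_character_)
  stratify(max(case$tumor_records$max_diameter_mm))
}

#' Evaluate a model on phantom cases
#'
#' Runs the model's predictor on every case, scores Dice/IoU/accuracy and
#' Hausdorff distance against the truth masks, and aggregates overall and
#' per tumor-size stratum (a case is stratified by its largest lesion).
#'
#' @param model A trained model (see [train_noncontrast()]) or any object
#'   with a working [predict_mask()] method; a function `case -> mask` is
#'   also accepted.
#' @param cases Non-empty list of `phantom_case`s.
#' @param mode Prediction mode passed to [predict_mask()].
#' @return A `metrics_report`: overall `dice`, `hd_mm`, `iou`, `acc`
#'   (percent / mm), `per_stratum` Dice, per-stratum case counts and the
#'   per-case table.
#' @export
evaluate_model <- function(model, cases, mode = c("paired", "single")) {
  mode <- match.arg(mode)
  if (length(cases) == 0L) stop("empty case list", call. = FALSE)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    pred <- if (is.function(model)) model(cs) else predict_mask(model, cs, mode = mode)
    m <- dice_iou_acc(cs$mask, pred)
    hd <- hausdorff_mm(cs$mask, pred, spacing = cs$noncontrast$spacing[1:2])
    data.frame(case = i, stratum = case_stratum(cs),
               dice = m[["dice"]], iou = m[["iou"]], acc = m[["acc"]],
               hd_mm = as.numeric(hd), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  per_stratum <- tapply(tab$dice, factor(tab$stratum, c("Tiny", "Small", "Big")), mean)
  n_cases <- tapply(tab$case, factor(tab$stratum, c("Tiny", "Small", "Big")), length)
  structure(list(
    dice = mean(tab$dice), iou = mean(tab$iou), acc = mean(tab$acc),
    hd_mm = if (all(is.na(tab$hd_mm))) NA_real_ else mean(tab$hd_mm, na.rm = TRUE),
    per_stratum = per_stratum, n_cases = n_cases, per_case = tab
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> Dice %.2f%%  IoU %.2f%%  ACC %.2f%%  HD %.2f mm  (n=%d)\n",
              x$dice, x$iou, x$acc, x$hd_mm, nrow(x$per_case)))
  ps <- x$per_stratum[!is.na(x$per_stratum)]
  if (length(ps))
    cat("  per-stratum Dice:",
        paste(sprintf("%s %.2f%%", names(ps), ps), collapse = ", "), "\n")
  invisible(x)
}

#' Ablation table over module flags
#'
#' Trains and evaluates the desk-scale model for every requested combination
#' of the three module flags — cross-phase `transfer`, Gaussian attention
#' (`gpsa`), wavelet enhancement (`weem`) — across seeds, and reports mean
#' and sd per metric per configuration. The default design is the full
#' 2 x 2 x 2 factorial (eight rows).
#'
#' @param cases List of `phantom_case`s (split internally per seed).
#' @param configs Data frame with logical columns `transfer`, `gpsa`, `weem`;
#'   default all eight combinations.
#' @param seeds Integer vector of training seeds.
#' @param ... Passed to [run_experiment()] (e.g. `epochs`, `model_config`).
#' @return Data frame with one row per configuration: flags, `dice_mean`,
#'   `dice_sd`, `iou_mean`, `acc_mean`, `hd_mean`, `n_runs`.
#' @export
ablation_table <- function(cases,
                           configs = expand.grid(transfer = c(FALSE, TRUE),
                                                 gpsa = c(FALSE, TRUE),
                                                 weem = c(FALSE, TRUE)),
                           seeds = 1L, ...) {
  if (nrow(configs) == 0L) stop("no configurations", call. = FALSE)
  rows <- lapply(seq_len(nrow(configs)), function(i) {
    runs <- lapply(seeds, function(s)
      run_experiment(cases, transfer = configs$transfer[i],
                     gpsa = configs$gpsa[i], weem = configs$weem[i],
                     seed = s, ...)$report)
    dice <- vapply(runs, `[[`, numeric(1), "dice")
    data.frame(transfer = configs$transfer[i], gpsa = configs$gpsa[i],
               weem = configs$weem[i],
               dice_mean = mean(dice), dice_sd = stats::sd(dice),
               iou_mean = mean(vapply(runs, `[[`, numeric(1), "iou")),
               acc_mean = mean(vapply(runs, `[[`, numeric(1), "acc")),
               hd_mean = mean(vapply(runs, `[[`, numeric(1), "hd_mm")),
               n_runs = length(seeds))
  })
  do.call(rbind, rows)
}

#' Write a metrics report
#'
#' Writes the per-case table as CSV and the summary as JSON.
#'
#' @param report A `metrics_report`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_case, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summary <- list(dice = report$dice, iou = report$iou, acc = report$acc,
                    hd_mm = report$hd_mm,
                    per_stratum = as.list(report$per_stratum),
                    n_cases = as.list(report$n_cases))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(report)
}
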