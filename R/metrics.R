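#' Edema index
#'
#' Volumetric measure of peritumoral brain edema relative to tumor size,
#' computed from voxel counts on the analysis grid:
#' `EI = (|tumor| + |edema|) / |tumor|`. A tumor without edema has EI = 1.
#'
#' @param masks a `segmentation_masks` object (or a list with `tumor` and
#'   `edema` voxel grids).
#' @return EI as a single number >= 1.
#' @export
edema_index <- function(masks) {
  n_tumor <- sum(masks$tumor$values)
  if (n_tumor == 0) stop("empty tumor mask: EI undefined", call. = FALSE)
  n_edema <- sum(masks$edema$values)
  (n_tumor + n_edema) / n_tumor
}

#' Relative ADC statistics
#'
#' Tumor ADC summary statistics normalized by the mean ADC of a reference
#' region (intended: contralateral normal-appearing white matter):
#' `rADCstat = stat(ADC over tumor) / mean(ADC over reference)` for
#' stat in mean, max, min, and `rADCdif = rADCmax - rADCmin`.
#'
#' The voxelwise extrema are noise-dominated, so by default the top and
#' bottom `trim` fraction of tumor ADC voxels are excluded before taking
#' min and max (the mean always uses all tumor voxels). Set `trim = 0` for
#' raw extrema.
#'
#' @param adc ADC `voxel_grid` (units 1e-6 mm^2/s or any consistent scale;
#'   the ratios are scale-invariant).
#' @param masks a `segmentation_masks` object.
#' @param trim fraction trimmed from each tail for the extrema (default 0.005).
#' @return Named numeric vector `c(rADCmean, rADCmax, rADCmin, rADCdif)`.
#' @export
radc_stats <- function(adc, masks, trim = 0.005) {
  stopifnot_grid(adc)
  if (!grids_aligned(adc, masks$tumor)) {
    stop("ADC grid and masks are misaligned", call. = FALSE)
  }
  tum <- adc$values[masks$tumor$values == 1]
  ref <- adc$values[masks$reference$values == 1]
  if (length(tum) == 0 || length(ref) == 0) {
    stop("tumor and reference masks must be nonempty", call. = FALSE)
  }
  ref_mean <- mean(ref)
  if (ref_mean <= 0) stop("reference mean ADC must be positive", call. = FALSE)
  if (trim > 0) {
    q <- stats::quantile(tum, c(trim, 1 - trim), names = FALSE)
    kept <- tum[tum >= q[1] & tum <= q[2]]
    if (length(kept) == 0) kept <- tum
  } else {
    kept <- tum
  }
  r_mean <- mean(tum) / ref_mean
  r_max <- max(kept) / ref_mean
  r_min <- min(kept) / ref_mean
  c(rADCmean = r_mean, rADCmax = r_max, rADCmin = r_min,
    rADCdif = r_max - r_min)
}

#' Maximal tumor diameter (3-D Feret diameter)
#'
#' Maximal pairwise Euclidean distance between tumor voxel centres in
#' physical (mm) coordinates. A single-voxel tumor has diameter 0. The
#' search is restricted to the per-line extreme voxels (for every (j, k)
#' the smallest and largest i in the tumor), which contain the convex-hull
#' vertices along the first axis, so the quadratic pairwise scan stays
#' small even for large tumors.
#'
#' @param masks a `segmentation_masks` object (only `tumor` is used).
#' @param spacing optional spacing override; defaults to the mask spacing.
#' @return Diameter in mm.
#' @export
tumor_diameter <- function(masks, spacing = NULL) {
  tumor <- masks$tumor
  if (is.null(spacing)) spacing <- tumor$spacing
  idx <- which(tumor$values == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty tumor mask", call. = FALSE)
  if (nrow(idx) == 1) return(0)
  key <- paste(idx[, 2], idx[, 3])
  keep <- unlist(lapply(split(seq_len(nrow(idx)), key), function(rows) {
    rows[c(which.min(idx[rows, 1]), which.max(idx[rows, 1]))]
  }), use.names = FALSE)
  pts <- idx[unique(keep), , drop = FALSE]
  pts <- sweep(pts, 2, spacing, "*")
  max(stats::dist(pts))
}

#' All imaging metrics for one patient
#'
#' Convenience wrapper computing EI, the four rADC statistics, and the
#' tumor diameter from one patient's ADC grid and masks.
#'
#' @inheritParams radc_stats
#' @return Named numeric vector with `EI`, `rADCmean`, `rADCmax`, `rADCmin`,
#'   `rADCdif`, `diameter_mm`.
#' @export
imaging_metrics <- function(adc, masks, trim = 0.005) {
  c(EI = edema_index(masks),
    radc_stats(adc, masks, trim = trim),
    diameter_mm = tumor_diameter(masks))
}
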