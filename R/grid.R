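#' Voxel grid: a 3-D scalar field with physical spacing
#'
#' The elementary container for one MRI volume (or one binary mask): a 3-D
#' numeric array together with its voxel spacing in millimetres and the
#' physical position of the centre of the first voxel. All geometry in the
#' package is voxel-centre based: voxel `(i, j, k)` sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values 3-D numeric array of intensities (or 0/1 for masks).
#' @param spacing numeric length-3, voxel edge lengths in mm; must be > 0.
#' @param origin numeric length-3, physical coordinate (mm) of the first
#'   voxel centre.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive numbers", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite numbers", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("voxel values must be finite", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_grid <- function(x, name = deparse(substitute(x))) {
  if (!is_voxel_grid(x)) stop("`", name, "` must be a voxel_grid", call. = FALSE)
  invisible(x)
}

#' Check that two grids share shape and spacing
#' @noRd
grids_aligned <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Segmentation masks for one patient
#'
#' Bundles the tumor, peritumoral-edema and normal-reference masks, all
#' aligned to the patient's intensity grids. Tumor and edema must be
#' disjoint voxel sets and the tumor must be nonempty.
#'
#' @param tumor,edema,reference `voxel_grid` objects with 0/1 values.
#' @return An object of class `segmentation_masks`.
#' @export
segmentation_masks <- function(tumor, edema, reference) {
  for (m in list(tumor, edema, reference)) {
    stopifnot_grid(m, "mask")
    if (!all(m$values %in% c(0, 1))) {
      stop("masks must contain only 0/1 values", call. = FALSE)
    }
  }
  if (!grids_aligned(tumor, edema) || !grids_aligned(tumor, reference)) {
    stop("all masks must share shape and spacing", call. = FALSE)
  }
  if (sum(tumor$values) == 0) stop("tumor mask is empty", call. = FALSE)
  if (any(tumor$values == 1 & edema$values == 1)) {
    stop("tumor and edema masks overlap", call. = FALSE)
  }
  structure(list(tumor = tumor, edema = edema, reference = reference),
            class = "segmentation_masks")
}

#' Read / write a voxel grid as NIfTI
#'
#' Thin wrappers around RNifti. `write_voxel_grid()` records the spacing in
#' the NIfTI pixdim; `read_voxel_grid()` restores it. The origin is kept in
#' the qform translation.
#'
#' @param grid a `voxel_grid`.
#' @param path file path, conventionally ending in `.nii` or `.nii.gz`.
#' @return `read_voxel_grid()` returns a `voxel_grid`;
#'   `write_voxel_grid()` returns `path` invisibly.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot_grid(grid)
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  voxel_grid(vals, spacing = RNifti::pixdim(img)[1:3])
}

#' Largest-remainder apportionment of integer counts
#'
#' Distributes `total` units over categories proportionally to `fractions`,
#' rounding so the counts sum to `total` exactly: each category receives the
#' floor of its exact share, and the leftover units go to the categories with
#' the largest fractional remainders (ties to the lower index).
#'
#' @param fractions nonnegative weights (need not sum to 1).
#' @param total nonnegative integer to distribute.
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(fractions, total) {
  if (any(fractions < 0) || total < 0) {
    stop("fractions and total must be nonnegative", call. = FALSE)
  }
  s <- sum(fractions)
  if (s == 0) stop("fractions sum to zero", call. = FALSE)
  exact <- fractions / s * total
  base <- floor(exact)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
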