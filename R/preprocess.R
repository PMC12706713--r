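#' Resample a voxel grid to a target spacing
#'
#' Resamples onto a new grid that covers the same physical extent as the
#' input (voxel-centre convention, extent = dim * spacing). Intensity grids
#' use trilinear interpolation; masks use nearest-neighbour with ties at the
#' exact midpoint broken toward the smaller (background-favouring) value.
#'
#' @param grid a `voxel_grid`.
#' @param target_spacing numeric length-3, new spacing in mm (> 0).
#' @param mode `"linear"` for intensities, `"nearest"` for masks/labels.
#' @return A `voxel_grid` at exactly `target_spacing`.
#' @export
resample <- function(grid, target_spacing, mode = c("linear", "nearest")) {
  stopifnot_grid(grid)
  mode <- match.arg(mode)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0)) {
    stop("`target_spacing` must be three positive numbers", call. = FALSE)
  }
  d_in <- dim(grid$values)
  if (prod(d_in) == 0) stop("empty grid", call. = FALSE)
  if (all(abs(grid$spacing - target_spacing) < 1e-9)) {
    return(voxel_grid(grid$values, target_spacing, grid$origin))
  }
  extent <- d_in * grid$spacing
  d_out <- pmax(1L, as.integer(round(extent / target_spacing)))

  # centre of output voxel i (axis a), in continuous input-index coordinates:
  # physical x = origin - s_in/2 + (i - 1/2) * s_out ; index t = x/s_in + 1
  idx_axis <- function(a) {
    x <- (seq_len(d_out[a]) - 0.5) * target_spacing[a] - grid$spacing[a] / 2
    t <- x / grid$spacing[a] + 1
    pmin(pmax(t, 1), d_in[a])
  }
  tx <- idx_axis(1); ty <- idx_axis(2); tz <- idx_axis(3)

  gather <- function(ix, iy, iz) {
    grid$values[cbind(rep(ix, times = length(iy) * length(iz)),
                      rep(rep(iy, each = length(ix)), times = length(iz)),
                      rep(iz, each = length(ix) * length(iy)))]
  }

  if (mode == "nearest") {
    near_axis <- function(t, dmax) {
      lo <- pmin(floor(t), dmax - 1); lo <- pmax(lo, 1)
      hi <- lo + 1
      frac <- t - lo
      list(lo = as.integer(lo), hi = as.integer(hi), frac = frac)
    }
    ax <- near_axis(tx, d_in[1]); ay <- near_axis(ty, d_in[2]); az <- near_axis(tz, d_in[3])
    pick <- function(v_lo, v_hi, frac) {
      # frac < .5 -> lower; > .5 -> upper; == .5 -> the smaller value
      out <- ifelse(frac < 0.5, v_lo, v_hi)
      tie <- abs(frac - 0.5) < 1e-12
      if (any(tie)) out[tie] <- pmin(v_lo[tie], v_hi[tie])
      out
    }
    fx <- rep(ax$frac, times = d_out[2] * d_out[3])
    fy <- rep(rep(ay$frac, each = d_out[1]), times = d_out[3])
    fz <- rep(az$frac, each = d_out[1] * d_out[2])
    # resolve axis-by-axis: nearest along x among the 8 corners reduces to
    # picking per-axis nearest indices, with tie -> min handled jointly below
    vals <- array(0, d_out)
    v000 <- gather(ax$lo, ay$lo, az$lo); v100 <- gather(ax$hi, ay$lo, az$lo)
    v010 <- gather(ax$lo, ay$hi, az$lo); v110 <- gather(ax$hi, ay$hi, az$lo)
    v001 <- gather(ax$lo, ay$lo, az$hi); v101 <- gather(ax$hi, ay$lo, az$hi)
    v011 <- gather(ax$lo, ay$hi, az$hi); v111 <- gather(ax$hi, ay$hi, az$hi)
    v00 <- pick(v000, v100, fx); v10 <- pick(v010, v110, fx)
    v01 <- pick(v001, v101, fx); v11 <- pick(v011, v111, fx)
    v0 <- pick(v00, v10, fy); v1 <- pick(v01, v11, fy)
    vals[] <- pick(v0, v1, fz)
    return(voxel_grid(vals, target_spacing, grid$origin))
  }

  lin_axis <- function(t, dmax) {
    if (dmax == 1L) return(list(lo = rep(1L, length(t)), frac = rep(0, length(t))))
    lo <- pmin(pmax(floor(t), 1), dmax - 1)
    list(lo = as.integer(lo), frac = t - lo)
  }
  ax <- lin_axis(tx, d_in[1]); ay <- lin_axis(ty, d_in[2]); az <- lin_axis(tz, d_in[3])
  hx <- pmin(ax$lo + 1L, d_in[1]); hy <- pmin(ay$lo + 1L, d_in[2]); hz <- pmin(az$lo + 1L, d_in[3])
  fx <- rep(ax$frac, times = d_out[2] * d_out[3])
  fy <- rep(rep(ay$frac, each = d_out[1]), times = d_out[3])
  fz <- rep(az$frac, each = d_out[1] * d_out[2])
  v000 <- gather(ax$lo, ay$lo, az$lo); v100 <- gather(hx, ay$lo, az$lo)
  v010 <- gather(ax$lo, hy, az$lo);    v110 <- gather(hx, hy, az$lo)
  v001 <- gather(ax$lo, ay$lo, hz);    v101 <- gather(hx, ay$lo, hz)
  v011 <- gather(ax$lo, hy, hz);       v111 <- gather(hx, hy, hz)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  vals <- array(v0 * (1 - fz) + v1 * fz, d_out)
  voxel_grid(vals, target_spacing, grid$origin)
}

#' 3-D gradient magnitude by central differences
#'
#' Central differences in the grid interior, one-sided at the faces, each
#' axis divided by its physical spacing so the result is an intensity
#' change per mm.
#' @noRd
gradient_magnitude <- function(grid) {
  v <- grid$values
  d <- dim(v)
  diff_axis <- function(axis) {
    n <- d[axis]
    if (n == 1L) return(array(0, d))
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    denom <- (idx_p - idx_m) * grid$spacing[axis]
    if (axis == 1L) {
      g <- (v[idx_p, , , drop = FALSE] - v[idx_m, , , drop = FALSE]) /
        array(denom, d)
    } else if (axis == 2L) {
      g <- (v[, idx_p, , drop = FALSE] - v[, idx_m, , drop = FALSE]) /
        array(rep(denom, each = d[1]), d)
    } else {
      g <- (v[, , idx_p, drop = FALSE] - v[, , idx_m, drop = FALSE]) /
        array(rep(denom, each = d[1] * d[2]), d)
    }
    g
  }
  sqrt(diff_axis(1)^2 + diff_axis(2)^2 + diff_axis(3)^2)
}

#' Gradient-anchored 0-255 intensity normalization
#'
#' Maps an intensity volume to the 0-255 range using a window derived from
#' the image gradient rather than from the raw histogram: the gradient
#' magnitude is computed by central differences within `body_mask`; voxels
#' whose gradient magnitude exceeds its within-mask mean are taken as edge
#' voxels; the mean and standard deviation of the *original* intensities over
#' those edge voxels define a window `[mu - 3 sigma, mu + 3 sigma]` that is
#' mapped linearly to `[0, 255]` and clipped. Because both the edge set and
#' the window transform equivariantly under `a * I + b` (a > 0), the output
#' is invariant to positive affine rescaling of the input.
#'
#' @param grid intensity `voxel_grid`.
#' @param body_mask `voxel_grid` with 0/1 values, or `NULL` to use the whole
#'   volume.
#' @return A `voxel_grid` with values in `[0, 255]`.
#' @export
gradient_normalize <- function(grid, body_mask = NULL) {
  stopifnot_grid(grid)
  if (is.null(body_mask)) {
    inside <- rep(TRUE, length(grid$values))
  } else {
    stopifnot_grid(body_mask, "body_mask")
    if (!grids_aligned(grid, body_mask)) {
      stop("body_mask is not aligned with the intensity grid", call. = FALSE)
    }
    inside <- body_mask$values == 1
    if (!any(inside)) stop("body_mask is empty", call. = FALSE)
  }
  vals <- grid$values
  if (diff(range(vals[inside])) == 0) {
    stop("image is constant within the body mask: normalization window has zero width",
         call. = FALSE)
  }
  g <- gradient_magnitude(grid)
  gm <- g[inside]
  edge <- inside & (g > mean(gm))
  if (!any(edge)) edge <- inside  # flat-gradient fallback keeps the contract
  mu <- mean(vals[edge])
  sigma <- stats::sd(vals[edge])
  if (sigma == 0) {
    stop("degenerate normalization window (zero intensity spread at edges)",
         call. = FALSE)
  }
  lo <- mu - 3 * sigma
  hi <- mu + 3 * sigma
  out <- (vals - lo) / (hi - lo) * 255
  out[out < 0] <- 0
  out[out > 255] <- 255
  voxel_grid(out, grid$spacing, grid$origin)
}
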