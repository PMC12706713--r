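#' K-means habitat clustering of tumor voxels
#'
#' Partitions the tumor voxels of one patient into `k` clusters by Lloyd's
#' algorithm on the paired (T1-CE, ADC) feature vectors, with k-means++
#' seeding and multiple restarts. Both channels are standardized to zero
#' mean and unit variance *within the tumor* before clustering, so that the
#' raw ADC scale (thousands of 1e-6 mm^2/s units) cannot dominate the 0-255
#' T1-CE channel. Clustering is per patient: "high" and "low" are relative
#' to the tumor's own intensity distribution.
#'
#' Determinism: for a fixed `seed` the result is reproducible; ties in
#' nearest-centroid assignment break toward the lowest cluster index; an
#' empty cluster during iteration is re-seeded at the point farthest from
#' its assigned centroid.
#'
#' @param t1ce,adc aligned intensity `voxel_grid`s (T1-CE conventionally
#'   already normalized to 0-255).
#' @param tumor binary tumor mask (`voxel_grid`).
#' @param k number of clusters (default 3).
#' @param seed integer RNG seed.
#' @param n_restarts independent k-means++ restarts; the labeling with the
#'   lowest within-cluster sum of squares is kept.
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `habitat_map`: integer labels for tumor voxels
#'   (in array storage order of the tumor mask), the linear indices of those
#'   voxels, centroids both in feature (standardized) and original units,
#'   the within-cluster SSE, and the mask geometry.
#' @export
cluster_voxels <- function(t1ce, adc, tumor, k = 3L, seed = 1L,
                           n_restarts = 10L, max_iter = 100L) {
  stopifnot_grid(t1ce); stopifnot_grid(adc); stopifnot_grid(tumor)
  if (!grids_aligned(t1ce, adc) || !grids_aligned(t1ce, tumor)) {
    stop("t1ce, adc and tumor mask must share shape and spacing", call. = FALSE)
  }
  k <- as.integer(k)
  idx <- which(tumor$values == 1)
  n <- length(idx)
  if (n < k) stop("tumor has fewer voxels than clusters", call. = FALSE)
  raw <- cbind(t1ce = t1ce$values[idx], adc = adc$values[idx])
  if (nrow(unique(raw)) < k) {
    stop("fewer distinct (T1-CE, ADC) feature vectors than clusters", call. = FALSE)
  }
  feats <- apply(raw, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) col - mean(col) else (col - mean(col)) / s
  })
  fit <- withr::with_seed(seed, kmeans_lloyd(feats, k, n_restarts, max_iter))
  # original-unit centroids: per-cluster means of the raw features
  cent_raw <- t(vapply(seq_len(k), function(j) colMeans(raw[fit$labels == j, , drop = FALSE]),
                       numeric(2)))
  colnames(cent_raw) <- c("t1ce", "adc")
  structure(list(labels = fit$labels, voxel_idx = idx, k = k,
                 centroids = cent_raw, centroids_feature = fit$centers,
                 sse = fit$sse, dim = dim(tumor$values),
                 spacing = tumor$spacing, seed = seed),
            class = "habitat_map")
}

# Lloyd's algorithm with k-means++ seeding and restarts; consumes the
# current RNG stream (caller fixes the seed).
kmeans_lloyd <- function(x, k, n_restarts, max_iter) {
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_init(x, k)
    labels <- integer(n)
    for (it in seq_len(max_iter)) {
      d2 <- dist2_to_centers(x, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      # empty-cluster repair: move the centroid to the point farthest from
      # its currently assigned centroid
      for (j in seq_len(k)) {
        if (!any(new_labels == j)) {
          far <- which.max(d2[cbind(seq_len(n), new_labels)])
          new_labels[far] <- j
        }
      }
      for (j in seq_len(k)) {
        centers[j, ] <- colMeans(x[new_labels == j, , drop = FALSE])
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
    }
    d2 <- dist2_to_centers(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    sse <- sum(d2[cbind(seq_len(n), labels)])
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(labels = labels, centers = centers, sse = sse)
    }
  }
  best
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L)
  centers[1L, ] <- x[first, ]
  if (k > 1L) {
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  centers
}

dist2_to_centers <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

#' @export
print.habitat_map <- function(x, ...) {
  cat("<habitat_map> ", length(x$labels), " tumor voxels, k = ", x$k,
      ", SSE = ", format(x$sse), "\n", sep = "")
  invisible(x)
}

#' Relabel clusters as the three canonical tumor habitats
#'
#' Applies the naming rule for the three-habitat model: the cluster with the
#' maximal ADC centroid becomes Habitat 3 (nonviable tissue); of the two
#' remaining clusters, the one with the higher T1-CE centroid becomes
#' Habitat 1 (high-enhancement cellular) and the other Habitat 2
#' (low-enhancement cellular). The voxel partition is untouched; only the
#' label names change. If the maximal-ADC cluster also has the strictly
#' maximal T1-CE centroid (a "high enhancement, high ADC" configuration not
#' expected in these tumors), a warning is issued and the same rule is
#' still applied.
#'
#' @param map a `habitat_map` with `k = 3`.
#' @return The relabeled `habitat_map` (labels 1, 2, 3 are habitat numbers).
#' @export
assign_habitats <- function(map) {
  if (!inherits(map, "habitat_map")) stop("`map` must be a habitat_map", call. = FALSE)
  if (map$k != 3L) stop("habitat assignment requires k = 3", call. = FALSE)
  cen <- map$centroids
  h3 <- which.max(cen[, "adc"])
  if (cen[h3, "t1ce"] > max(cen[-h3, "t1ce"])) {
    warning("maximal-ADC cluster also has the maximal T1-CE centroid ",
            "(high-enhancement / high-ADC configuration); labeling rule applied as-is")
  }
  rest <- setdiff(1:3, h3)
  h1 <- rest[which.max(cen[rest, "t1ce"])]
  h2 <- setdiff(rest, h1)
  perm <- integer(3)          # perm[old cluster] -> habitat number
  perm[c(h1, h2, h3)] <- 1:3
  map$labels <- perm[map$labels]
  ord <- order(perm)          # reorder centroid rows to habitat order
  map$centroids <- cen[ord, , drop = FALSE]
  map$centroids_feature <- map$centroids_feature[ord, , drop = FALSE]
  rownames(map$centroids) <- rownames(map$centroids_feature) <-
    paste0("habitat", 1:3)
  map$habitats_assigned <- TRUE
  map
}

#' Habitat voxel fractions
#'
#' Fraction of tumor voxels in each habitat: `f_h = |habitat h| / |tumor|`.
#'
#' @param map a `habitat_map` (after [assign_habitats()] for the canonical
#'   ordering).
#' @return Named numeric vector `c(f1, f2, f3)` (or length `k`) summing to 1.
#' @export
habitat_fractions <- function(map) {
  if (!inherits(map, "habitat_map")) stop("`map` must be a habitat_map", call. = FALSE)
  n <- length(map$labels)
  if (n == 0) stop("empty tumor", call. = FALSE)
  counts <- tabulate(map$labels, nbins = map$k)
  stats::setNames(counts / n, paste0("f", seq_len(map$k)))
}

#' Render a habitat map as a labeled voxel grid
#'
#' @param map a `habitat_map`.
#' @return A `voxel_grid` with habitat labels inside the tumor and 0 outside.
#' @export
habitat_label_grid <- function(map) {
  vals <- array(0, map$dim)
  vals[map$voxel_idx] <- map$labels
  voxel_grid(vals, spacing = map$spacing)
}
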