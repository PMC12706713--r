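# Shared in-code fixtures for the test suite.

# A tiny grid with the given values recycled into shape.
make_grid <- function(values, shape = c(4, 4, 2), spacing = c(1, 1, 1)) {
  voxel_grid(array(values, dim = shape), spacing = spacing)
}

# Masks with explicit voxel counts: tumor fills the first `n_tumor` voxels
# (in storage order), edema the next `n_edema`, reference the last 8.
make_counted_masks <- function(n_tumor, n_edema, shape = c(16, 16, 10),
                               spacing = c(1, 1, 1)) {
  total <- prod(shape)
  stopifnot(n_tumor + n_edema + 8 <= total)
  t <- numeric(total); t[seq_len(n_tumor)] <- 1
  e <- numeric(total); if (n_edema > 0) e[n_tumor + seq_len(n_edema)] <- 1
  r <- numeric(total); r[total - 7:0] <- 1
  segmentation_masks(
    tumor = voxel_grid(array(t, shape), spacing),
    edema = voxel_grid(array(e, shape), spacing),
    reference = voxel_grid(array(r, shape), spacing)
  )
}

# Digitized sphere mask of radius r_mm centred in the grid.
make_sphere_mask <- function(r_mm, shape, spacing) {
  cx <- (seq_len(shape[1]) - 0.5) * spacing[1]
  cy <- (seq_len(shape[2]) - 0.5) * spacing[2]
  cz <- (seq_len(shape[3]) - 0.5) * spacing[3]
  cen <- shape * spacing / 2
  r2 <- outer(outer((cx - cen[1])^2, (cy - cen[2])^2, "+"), (cz - cen[3])^2, "+")
  voxel_grid(array(as.numeric(r2 <= r_mm^2), shape), spacing)
}

# Exhaustive k-means oracle: the global minimum within-cluster SSE over all
# label assignments of n points into at most k groups.
brute_force_kmeans_sse <- function(x, k) {
  n <- nrow(x)
  stopifnot(n <= 8)
  labels <- rep(1L, n)
  best <- Inf
  repeat {
    sse <- 0
    for (j in unique(labels)) {
      pts <- x[labels == j, , drop = FALSE]
      sse <- sse + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    if (sse < best) best <- sse
    # next assignment in base-k counting
    i <- 1L
    while (i <= n) {
      labels[i] <- labels[i] + 1L
      if (labels[i] <= k) break
      labels[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}

# Brute-force AUC over all positive-negative pairs (ties count 1/2).
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# A truth row suitable for phantom rendering (all habitats present).
make_truth <- function(f = c(0.4, 0.45, 0.15), ei = 1.6, radc = 1.2,
                       ref = 850) {
  data.frame(patient_id = "T001", class = 0L,
             f1 = f[1], f2 = f[2], f3 = f[3], EI = ei,
             radc_mean_target = radc, reference_adc = ref, adc_scale = NA,
             habitat_adc1 = NA, habitat_adc2 = NA, habitat_adc3 = NA,
             discrete_vm_density = 5, endothelial_density = 20,
             continuous_vm_prob = 0.2)
}
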