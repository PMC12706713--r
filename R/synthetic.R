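#' Default synthetic-cohort configuration
#'
#' Returns the configuration of the synthetic study population. The
#' class-conditional parameters are calibrated to the published cohort
#' summary of 61 atypical GBM and 64 PCNSL patients: habitat-fraction
#' Dirichlet means (39.5/52.5/8.0% vs 54.3/41.5/4.2%) with concentrations
#' matched to the reported habitat-1 SDs (14.2% and 17.7%); edema index
#' modeled as 1 + lognormal with medians 2.008 and 3.445 (log-SDs from the
#' reported quartiles); rADCmean lognormal with medians 1.201 and 0.968;
#' age normal (50.6 +/- 15.0 vs 56.9 +/- 12.7); tumor diameter lognormal
#' with medians 47.3 and 31.1 mm; sex/headache/midline probabilities from
#' the reported counts. Vasculogenic-mimicry couplings are linear in the
#' habitat fractions and class, with signs matching the reported habitat
#' regressions (discrete-VM density increasing in f1 and decreasing in f2;
#' continuous-VM positivity decreasing in f3) and magnitudes that reproduce
#' the reported group levels (discrete VM medians ~1.6 vs ~9.1 vessels/mm^2,
#' endothelial means ~24.3 vs ~20.4, continuous positivity ~10% vs ~30%).
#'
#' @param n_patients cohort size (default 125).
#' @param rng_seed integer seed.
#' @return A `synthetic_config` list; see source for the field dictionary.
#' @export
default_config <- function(n_patients = 125L, rng_seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    prevalence_pcnsl = 64 / 125,
    rng_seed = as.integer(rng_seed),
    classes = list(
      GBM = list(
        habitat_mean = c(0.395, 0.525, 0.080),
        habitat_concentration = 10.85,
        ei_median = 2.008, ei_logsd = 1.39,
        radc_mean_median = 1.201, radc_mean_logsd = 0.231,
        age_mean = 50.6, age_sd = 15.0,
        diameter_median = 47.3, diameter_logsd = 0.407,
        p_male = 33 / 61, p_headache = 30 / 61, p_midline = 30 / 61
      ),
      PCNSL = list(
        habitat_mean = c(0.543, 0.415, 0.042),
        habitat_concentration = 6.93,
        ei_median = 3.445, ei_logsd = 0.95,
        radc_mean_median = 0.968, radc_mean_logsd = 0.194,
        age_mean = 56.9, age_sd = 12.7,
        diameter_median = 31.1, diameter_logsd = 0.600,
        p_male = 30 / 64, p_headache = 26 / 64, p_midline = 38 / 64
      )
    ),
    imaging = list(
      reference_adc = 850,                  # NAWM mean, 1e-6 mm^2/s
      adc_base = c(800, 900, 1800),         # habitat ADC shape (H1, H2, H3)
      t1ce_mean = c(180, 80, 60),           # habitat T1-CE signatures, 0-255
      t1ce_background = 80, t1ce_texture_amp = 50, t1ce_edema = 45,
      adc_background = 850, adc_edema = 1400,
      t1ce_noise_sd = 10, adc_noise_sd = 50
    ),
    vm = list(
      # linear couplings: intercept, f1, f2, f3, class (PCNSL = 1)
      discrete = c(intercept = 0, f1 = 33.95, f2 = -22.49, f3 = 0, class = 0),
      discrete_noise_sd = 2,
      endothelial = c(intercept = 2.6, f1 = 55, f2 = 0, f3 = 0, class = -12.1),
      endothelial_noise_sd = 2.5,
      # logit-scale coupling for continuous-VM positivity
      continuous = c(intercept = -1.025, f1 = 0, f2 = 0, f3 = -26, class = 0.778),
      continuous_noise_sd = 0.25,
      box_area_mm2 = 0.275, n_boxes = 10L, n_observers = 3L
    )
  )
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

#' Validate a synthetic configuration
#' @param cfg a `synthetic_config` list.
#' @return `cfg` invisibly; stops with a configuration error otherwise.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("configuration error: ", msg, call. = FALSE)
  chk(cfg$n_patients >= 2, "n_patients must be >= 2")
  chk(cfg$prevalence_pcnsl >= 0 && cfg$prevalence_pcnsl <= 1,
      "prevalence must be a probability")
  if (cfg$n_patients >= 10) {
    chk(cfg$prevalence_pcnsl > 0 && cfg$prevalence_pcnsl < 1,
        "both classes need nonzero prevalence for n >= 10")
  }
  for (nm in names(cfg$classes)) {
    cl <- cfg$classes[[nm]]
    chk(abs(sum(cl$habitat_mean) - 1) < 1e-8,
        paste0(nm, ": habitat means must sum to 1"))
    chk(all(cl$habitat_mean >= 0), paste0(nm, ": habitat means nonnegative"))
    chk(cl$habitat_concentration > 0, paste0(nm, ": concentration positive"))
    chk(cl$ei_median >= 1, paste0(nm, ": EI median must be >= 1"))
    for (f in c("ei_logsd", "radc_mean_logsd", "age_sd", "diameter_logsd")) {
      chk(cl[[f]] >= 0, paste0(nm, ": ", f, " must be nonnegative"))
    }
    for (f in c("p_male", "p_headache", "p_midline")) {
      chk(cl[[f]] >= 0 && cl[[f]] <= 1, paste0(nm, ": ", f, " must be in [0,1]"))
    }
  }
  chk(cfg$imaging$reference_adc > 0, "reference ADC must be positive")
  chk(all(cfg$imaging$adc_base > 0), "habitat ADC bases must be positive")
  for (f in c("discrete_noise_sd", "endothelial_noise_sd", "continuous_noise_sd")) {
    chk(cfg$vm[[f]] >= 0, paste0(f, " must be nonnegative"))
  }
  invisible(cfg)
}

#' Read / write a synthetic configuration as YAML
#' @param cfg a `synthetic_config`.
#' @param path YAML file path.
#' @return `read_config()` returns a validated `synthetic_config`.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  # yaml drops names on atomic vectors; store the couplings as maps
  for (nm in c("discrete", "endothelial", "continuous")) {
    out$vm[[nm]] <- as.list(out$vm[[nm]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml flattens named vectors to lists; restore the numeric couplings
  for (nm in c("discrete", "endothelial", "continuous")) {
    v <- unlist(cfg$vm[[nm]])
    if (is.null(names(v))) names(v) <- c("intercept", "f1", "f2", "f3", "class")
    cfg$vm[[nm]] <- v
  }
  for (cl in names(cfg$classes)) {
    cfg$classes[[cl]]$habitat_mean <- unlist(cfg$classes[[cl]]$habitat_mean)
  }
  for (nm in c("adc_base", "t1ce_mean")) {
    cfg$imaging[[nm]] <- unlist(cfg$imaging[[nm]])
  }
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

# Dirichlet draw via gamma normalization; infinite concentration or zero
# log-SDs give the degenerate (point-mass) limits so exact-mean cohorts can
# be generated for testing.
rdirichlet1 <- function(mean, concentration) {
  if (!is.finite(concentration)) return(mean / sum(mean))
  g <- stats::rgamma(length(mean), shape = mean * concentration)
  if (sum(g) == 0) return(mean / sum(mean))
  g / sum(g)
}

vm_linpred <- function(beta, f, cls) {
  beta["intercept"] + beta["f1"] * f[1] + beta["f2"] * f[2] +
    beta["f3"] * f[3] + beta["class"] * cls
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws `n_patients` patients from the class-conditional distributions of
#' the configuration: diagnosis, demographics, habitat fractions (Dirichlet),
#' edema index (1 + lognormal), rADC targets (lognormal median), tumor
#' diameter, and vasculogenic-mimicry levels from the linear couplings plus
#' Gaussian noise truncated at zero. Per-habitat ADC means are scaled so
#' that the habitat mixture reproduces each patient's rADCmean target over
#' the configured reference ADC. Deterministic given `cfg$rng_seed`.
#'
#' @param cfg a `synthetic_config` (default [default_config()]).
#' @return A list with `records` (one row per patient: the observable
#'   cohort table) and `truth` (the latent generative values).
#' @export
gen_cohort <- function(cfg = default_config()) {
  validate_config(cfg)
  n <- cfg$n_patients
  im <- cfg$imaging
  # class-conditional parameter lookup, vectorized over patients
  par <- function(field) {
    g <- cfg$classes$GBM[[field]]; p <- cfg$classes$PCNSL[[field]]
    function(cls) ifelse(cls == 1, p, g)
  }
  out <- withr::with_seed(cfg$rng_seed, {
    cls <- stats::rbinom(n, 1, cfg$prevalence_pcnsl)  # 1 = PCNSL
    f <- t(vapply(cls, function(ci) {
      cl <- cfg$classes[[if (ci == 1) "PCNSL" else "GBM"]]
      rdirichlet1(cl$habitat_mean, cl$habitat_concentration)
    }, numeric(3)))
    ei_med <- par("ei_median")(cls)
    ei <- ifelse(ei_med > 1,
                 1 + stats::rlnorm(n, log(pmax(ei_med - 1, 1e-12)),
                                   par("ei_logsd")(cls)),
                 1)
    radc_mean <- stats::rlnorm(n, log(par("radc_mean_median")(cls)),
                               par("radc_mean_logsd")(cls))
    age <- stats::rnorm(n, par("age_mean")(cls), par("age_sd")(cls))
    diam <- stats::rlnorm(n, log(par("diameter_median")(cls)),
                          par("diameter_logsd")(cls))
    sex <- stats::rbinom(n, 1, par("p_male")(cls))
    headache <- stats::rbinom(n, 1, par("p_headache")(cls))
    midline <- stats::rbinom(n, 1, par("p_midline")(cls))
    s <- radc_mean * im$reference_adc / as.numeric(f %*% im$adc_base)
    habitat_adc <- s %o% im$adc_base                 # n x 3
    adc_present <- habitat_adc
    adc_present[f <= 0] <- NA
    radc_max <- apply(adc_present, 1, max, na.rm = TRUE) / im$reference_adc
    radc_min <- apply(adc_present, 1, min, na.rm = TRUE) / im$reference_adc
    vm <- cfg$vm
    lin <- function(beta) {
      beta[["intercept"]] + f %*% c(beta[["f1"]], beta[["f2"]], beta[["f3"]]) +
        beta[["class"]] * cls
    }
    d_dens <- pmax(0, lin(vm$discrete) + stats::rnorm(n, 0, vm$discrete_noise_sd))
    e_dens <- pmax(0, lin(vm$endothelial) + stats::rnorm(n, 0, vm$endothelial_noise_sd))
    c_prob <- stats::plogis(lin(vm$continuous) + stats::rnorm(n, 0, vm$continuous_noise_sd))
    list(cls = cls, f = f, ei = ei, radc_mean = radc_mean, age = age,
         diam = diam, sex = sex, headache = headache, midline = midline,
         s = s, habitat_adc = habitat_adc, radc_max = radc_max,
         radc_min = radc_min, d_dens = as.numeric(d_dens),
         e_dens = as.numeric(e_dens), c_prob = as.numeric(c_prob))
  })
  ids <- sprintf("P%04d", seq_len(n))
  records <- data.frame(
    patient_id = ids,
    diagnosis = ifelse(out$cls == 1, "PCNSL", "GBM"),
    class = out$cls,
    age = out$age, sex = ifelse(out$sex == 1, "M", "F"),
    headache = out$headache, midline = out$midline,
    diameter_mm = out$diam,
    f1 = out$f[, 1], f2 = out$f[, 2], f3 = out$f[, 3],
    EI = out$ei,
    rADCmean = out$radc_mean, rADCmax = out$radc_max, rADCmin = out$radc_min,
    rADCdif = out$radc_max - out$radc_min,
    discrete_vm_density = out$d_dens,
    endothelial_density = out$e_dens,
    continuous_vm_prob = out$c_prob
  )
  truth <- data.frame(
    patient_id = ids,
    class = out$cls,
    f1 = out$f[, 1], f2 = out$f[, 2], f3 = out$f[, 3],
    EI = out$ei, radc_mean_target = out$radc_mean,
    reference_adc = im$reference_adc,
    adc_scale = out$s,
    habitat_adc1 = out$habitat_adc[, 1], habitat_adc2 = out$habitat_adc[, 2],
    habitat_adc3 = out$habitat_adc[, 3],
    discrete_vm_density = out$d_dens,
    endothelial_density = out$e_dens,
    continuous_vm_prob = out$c_prob
  )
  list(records = records, truth = truth)
}

#' Render a two-channel 3-D phantom for one patient
#'
#' Builds an ellipsoidal (spherical in physical coordinates) tumor whose
#' voxels are partitioned into the three habitats with voxel counts matching
#' the target fractions by largest-remainder rounding; an edema shell of
#' `(EI - 1) * tumor volume` voxels (nearest voxel) grown outward from the
#' tumor; and a cuboid reference region whose mean ADC equals the reference
#' value. T1-CE and ADC intensities are the per-habitat signatures (H1 high
#' T1-CE / low ADC, H2 low/low, H3 low/high) plus Gaussian noise. The
#' per-habitat ADC means are scaled to the *realized* voxel counts so a
#' noiseless phantom passed through the pipeline returns the generative
#' fractions, EI and rADC values exactly.
#'
#' @param truth one-row data frame (or named list) with `f1`, `f2`, `f3`,
#'   `EI`, `radc_mean_target` (as produced by [gen_cohort()]`$truth`).
#' @param shape grid dimensions (default `c(48, 48, 20)`).
#' @param spacing voxel spacing in mm (default `c(1, 1, 3)`).
#' @param seed integer RNG seed for the intensity noise / speckled layout.
#' @param layout `"shells"` (H1 rim, H2 middle, H3 core) or `"speckled"`
#'   (random assignment) habitat geometry.
#' @param t1ce_noise_sd,adc_noise_sd intensity noise SDs; 0 gives a
#'   noiseless phantom.
#' @param tumor_radius_mm tumor radius; default is sized so tumor plus
#'   edema fit inside the grid.
#' @param imaging intensity parameter list (defaults to
#'   `default_config()$imaging`).
#' @return A list with `t1ce`, `adc` (voxel grids), `masks`
#'   (`segmentation_masks`), `habitat_truth` (voxel grid of generative
#'   labels), and `realized` (voxel-exact fractions, EI and rADC values).
#' @export
render_phantom <- function(truth, shape = c(48, 48, 20), spacing = c(1, 1, 3),
                           seed = 1L, layout = c("shells", "speckled"),
                           t1ce_noise_sd = 0, adc_noise_sd = 0,
                           tumor_radius_mm = NULL,
                           imaging = default_config()$imaging) {
  layout <- match.arg(layout)
  truth <- as.list(truth)
  f <- c(truth$f1, truth$f2, truth$f3)
  if (abs(sum(f) - 1) > 1e-6 || any(f < 0)) {
    stop("habitat fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  ei <- truth$EI
  if (is.null(ei) || ei < 1) stop("EI must be >= 1", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  extent <- shape * spacing
  centre <- extent / 2
  if (is.null(tumor_radius_mm)) {
    # size so that the edema shell (total volume EI * tumor volume) fits
    tumor_radius_mm <- 0.7 * min(centre) / max(ei, 1)^(1 / 3)
  }
  if (tumor_radius_mm < 2 * min(spacing)) {
    stop("sizing error: tumor radius too small for this grid", call. = FALSE)
  }
  # voxel-centre coordinates
  cx <- (seq_len(shape[1]) - 0.5) * spacing[1]
  cy <- (seq_len(shape[2]) - 0.5) * spacing[2]
  cz <- (seq_len(shape[3]) - 0.5) * spacing[3]
  dx2 <- (cx - centre[1])^2
  dy2 <- (cy - centre[2])^2
  dz2 <- (cz - centre[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  tumor <- r2 <= tumor_radius_mm^2
  n_tumor <- sum(tumor)
  if (n_tumor < 3) stop("sizing error: tumor smaller than 3 voxels", call. = FALSE)
  n_edema <- as.integer(round((ei - 1) * n_tumor))
  outside <- which(!tumor)
  if (n_edema > length(outside)) {
    stop("sizing error: requested EI does not fit in the grid", call. = FALSE)
  }
  edema_idx <- outside[order(r2[outside])][seq_len(n_edema)]
  edema <- array(FALSE, shape)
  edema[edema_idx] <- TRUE
  # reference region: cuboid in the first corner; must avoid tumor + edema
  ref <- array(FALSE, shape)
  rx <- 2:min(6, shape[1]); ry <- 2:min(6, shape[2]); rz <- 2:min(3, shape[3])
  ref[rx, ry, rz] <- TRUE
  if (any(ref & (tumor | edema))) {
    stop("sizing error: no room for the reference region", call. = FALSE)
  }

  counts <- largest_remainder(f, n_tumor)
  tumor_idx <- which(tumor)
  out <- withr::with_seed(seed, {
    if (layout == "shells") {
      ord <- order(r2[tumor_idx], decreasing = TRUE)  # rim first
    } else {
      ord <- sample.int(n_tumor)
    }
    labels <- integer(n_tumor)
    pos <- 1L
    for (h in 1:3) {
      if (counts[h] > 0) {
        labels[ord[pos:(pos + counts[h] - 1L)]] <- h
        pos <- pos + counts[h]
      }
    }
    # ADC scale anchored to realized counts so rADCmean recovers exactly
    fr <- counts / n_tumor
    s <- truth$radc_mean_target * imaging$reference_adc / sum(fr * imaging$adc_base)
    habitat_adc <- s * imaging$adc_base

    # pseudo-anatomical background texture: smooth intensity structure that
    # stands in for grey/white/CSF contrast so gradient-anchored
    # normalization sees tissue edges spanning the intensity range (flat
    # backgrounds would anchor the window to noise)
    amp <- if (is.null(imaging$t1ce_texture_amp)) 0 else imaging$t1ce_texture_amp
    tex <- outer(outer(sin(cx / 4), sin(cy / 5), "*"), sin(cz / 6), "*")
    t1 <- array(imaging$t1ce_background + amp * tex, shape)
    ad <- array(imaging$adc_background, shape)
    t1[edema] <- imaging$t1ce_edema
    ad[edema] <- imaging$adc_edema
    t1[tumor_idx] <- imaging$t1ce_mean[labels]
    ad[tumor_idx] <- habitat_adc[labels]
    ad[ref] <- imaging$reference_adc
    if (t1ce_noise_sd > 0) t1 <- t1 + array(stats::rnorm(length(t1), 0, t1ce_noise_sd), shape)
    if (adc_noise_sd > 0) {
      noise <- array(stats::rnorm(length(ad), 0, adc_noise_sd), shape)
      noise[ref] <- noise[ref] - mean(noise[ref])  # keep the reference mean exact
      ad <- ad + noise
    }
    list(t1 = t1, ad = ad, labels = labels, fr = fr, habitat_adc = habitat_adc,
         s = s)
  })

  present <- counts > 0
  realized <- list(
    counts = counts,
    fractions = out$fr,
    n_tumor = n_tumor, n_edema = n_edema,
    ei = (n_tumor + n_edema) / n_tumor,
    radc_mean = sum(out$fr * out$habitat_adc) / imaging$reference_adc,
    radc_max = max(out$habitat_adc[present]) / imaging$reference_adc,
    radc_min = min(out$habitat_adc[present]) / imaging$reference_adc
  )
  lab_grid <- array(0L, shape)
  lab_grid[tumor_idx] <- out$labels
  masks <- segmentation_masks(
    tumor = voxel_grid(array(as.numeric(tumor), shape), spacing),
    edema = voxel_grid(array(as.numeric(edema), shape), spacing),
    reference = voxel_grid(array(as.numeric(ref), shape), spacing)
  )
  list(
    t1ce = voxel_grid(out$t1, spacing),
    adc = voxel_grid(out$ad, spacing),
    masks = masks,
    habitat_truth = voxel_grid(lab_grid, spacing),
    realized = realized
  )
}

#' Generate a VM counting sheet for one patient
#'
#' Per-box vessel counts are Poisson with mean `density * box_area`; the
#' continuous-VM flag of each area is Bernoulli at the patient's positivity
#' probability (shared across observers, who recount the same boxes with
#' independent Poisson noise).
#'
#' @param truth one-row data frame / named list with `patient_id`,
#'   `discrete_vm_density`, `endothelial_density`, `continuous_vm_prob`.
#' @param seed integer RNG seed.
#' @param n_boxes boxes per slide (default 10).
#' @param n_observers independent counters (default 3).
#' @param box_area_mm2 box area (default 0.275 = 550 x 500 um).
#' @return A sheet data frame (patient, box, observer, discrete_vm,
#'   endothelial, continuous_flag).
#' @export
gen_vm_counts <- function(truth, seed = 1L, n_boxes = 10L, n_observers = 3L,
                          box_area_mm2 = 0.275) {
  truth <- as.list(truth)
  dd <- truth$discrete_vm_density
  ed <- truth$endothelial_density
  cp <- truth$continuous_vm_prob
  if (dd < 0 || ed < 0) stop("densities must be nonnegative", call. = FALSE)
  withr::with_seed(seed, {
    flags <- stats::rbinom(n_boxes, 1, cp)
    do.call(rbind, lapply(seq_len(n_observers), function(ob) {
      data.frame(
        patient = if (is.null(truth$patient_id)) "P001" else truth$patient_id,
        box = seq_len(n_boxes),
        observer = ob,
        discrete_vm = stats::rpois(n_boxes, dd * box_area_mm2),
        endothelial = stats::rpois(n_boxes, ed * box_area_mm2),
        continuous_flag = flags
      )
    }))
  })
}

#' Write a full synthetic study to disk
#'
#' Materializes a synthetic cohort in the package's on-disk layout: the
#' cohort and ground-truth tables as CSV, VM counting sheets as CSV, the
#' configuration as YAML, and (optionally) per-patient NIfTI phantoms with
#' their masks.
#'
#' @param cfg a `synthetic_config`.
#' @param out_dir output directory (created if needed).
#' @param render_phantoms logical or integer: `FALSE` for tables only,
#'   `TRUE` for all patients, or a count of patients to render.
#' @param phantom_shape,phantom_spacing phantom geometry.
#' @param noise_sds list with `t1ce` and `adc` intensity noise SDs.
#' @return The output directory, invisibly.
#' @export
simulate_study <- function(cfg = default_config(), out_dir,
                           render_phantoms = FALSE,
                           phantom_shape = c(48, 48, 20),
                           phantom_spacing = c(1, 1, 3),
                           noise_sds = list(t1ce = 0, adc = 0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- gen_cohort(cfg)
  utils::write.csv(coh$records, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(coh$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  sheets <- do.call(rbind, lapply(seq_len(nrow(coh$truth)), function(i) {
    gen_vm_counts(coh$truth[i, ], seed = cfg$rng_seed + i,
                  n_boxes = cfg$vm$n_boxes, n_observers = cfg$vm$n_observers,
                  box_area_mm2 = cfg$vm$box_area_mm2)
  }))
  utils::write.csv(sheets, file.path(out_dir, "vm_sheets.csv"), row.names = FALSE)
  n_render <- if (isTRUE(render_phantoms)) nrow(coh$truth)
              else if (is.numeric(render_phantoms)) min(render_phantoms, nrow(coh$truth))
              else 0L
  for (i in seq_len(n_render)) {
    pid <- coh$truth$patient_id[i]
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    ph <- render_phantom(coh$truth[i, ], shape = phantom_shape,
                         spacing = phantom_spacing, seed = cfg$rng_seed + i,
                         t1ce_noise_sd = noise_sds$t1ce,
                         adc_noise_sd = noise_sds$adc,
                         imaging = cfg$imaging)
    write_voxel_grid(ph$t1ce, file.path(pdir, "t1ce.nii.gz"))
    write_voxel_grid(ph$adc, file.path(pdir, "adc.nii.gz"))
    write_voxel_grid(ph$masks$tumor, file.path(pdir, "mask_tumor.nii.gz"))
    write_voxel_grid(ph$masks$edema, file.path(pdir, "mask_edema.nii.gz"))
    write_voxel_grid(ph$masks$reference, file.path(pdir, "mask_reference.nii.gz"))
  }
  invisible(out_dir)
}
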