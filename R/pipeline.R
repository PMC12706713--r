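#' Pipeline configuration
#'
#' Collects every knob of the full analysis into one validated list.
#'
#' @param input_dir directory with per-patient subdirectories
#'   (`t1ce.nii.gz`, `adc.nii.gz`, `mask_tumor.nii.gz`, `mask_edema.nii.gz`,
#'   `mask_reference.nii.gz`) and a `cohort.csv` covariate table.
#' @param output_dir where stage outputs and the manifest are written.
#' @param spacing analysis grid spacing in mm (default `c(1, 1, 3)`).
#' @param k clusters per tumor (default 3).
#' @param cluster_seed,n_restarts K-means determinism controls.
#' @param split_ratio,split_seed train/validation split controls.
#' @param hl_groups Hosmer-Lemeshow bins (default 10).
#' @param bootstrap_B calibration resamples (default 1000).
#' @param dca_grid decision-curve threshold grid.
#' @param screen_alpha univariable screening level.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            spacing = c(1, 1, 3), k = 3L,
                            cluster_seed = 1L, n_restarts = 10L,
                            split_ratio = 0.7, split_seed = 1L,
                            hl_groups = 10L, bootstrap_B = 1000L,
                            dca_grid = seq(0.05, 0.95, by = 0.01),
                            screen_alpha = 0.05) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir, call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (!(split_ratio > 0 && split_ratio < 1)) stop("split_ratio must be in (0,1)", call. = FALSE)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 spacing = spacing, k = as.integer(k),
                 cluster_seed = as.integer(cluster_seed),
                 n_restarts = as.integer(n_restarts),
                 split_ratio = split_ratio, split_seed = as.integer(split_seed),
                 hl_groups = as.integer(hl_groups),
                 bootstrap_B = as.integer(bootstrap_B),
                 dca_grid = dca_grid, screen_alpha = screen_alpha),
            class = "pipeline_config")
}

#' Process one patient's volumes into habitat fractions and metrics
#'
#' The per-patient core of the pipeline: resample all grids to the analysis
#' spacing (linear for intensities, nearest for masks), normalize T1-CE to
#' 0-255 with the gradient-anchored window, cluster tumor voxels into
#' habitats, and compute EI, rADC statistics and tumor diameter.
#'
#' @param t1ce,adc intensity `voxel_grid`s.
#' @param masks a `segmentation_masks` object.
#' @param spacing analysis spacing.
#' @param k,seed,n_restarts clustering controls.
#' @return A list with `fractions`, `metrics`, `habitat_map`, and the
#'   resampled grids.
#' @export
process_patient <- function(t1ce, adc, masks, spacing = c(1, 1, 3),
                            k = 3L, seed = 1L, n_restarts = 10L) {
  t1r <- resample(t1ce, spacing, "linear")
  adr <- resample(adc, spacing, "linear")
  mk <- segmentation_masks(
    tumor = resample(masks$tumor, spacing, "nearest"),
    edema = resample(masks$edema, spacing, "nearest"),
    reference = resample(masks$reference, spacing, "nearest")
  )
  t1n <- gradient_normalize(t1r)
  map <- cluster_voxels(t1n, adr, mk$tumor, k = k, seed = seed,
                        n_restarts = n_restarts)
  if (k == 3L) map <- assign_habitats(map)
  list(fractions = habitat_fractions(map),
       metrics = imaging_metrics(adr, mk),
       habitat_map = map,
       t1ce = t1n, adc = adr, masks = mk)
}

#' Run the full habitat-analysis pipeline
#'
#' Executes the stages in order — per-patient preprocessing and habitat
#' segmentation, imaging metrics, cohort-level group statistics, and the
#' diagnostic model (univariable screening, backward-AIC selection,
#' nomogram, Hosmer-Lemeshow, bootstrap calibration, decision curve) — and
#' writes the stage outputs plus a JSON run manifest (seeds, parameters,
#' package version) under `config$output_dir`. Input validation names the
#' first patient whose files are missing or misaligned before any
#' computation starts.
#'
#' @param config a `pipeline_config`.
#' @return A report list (cohort table with fractions and metrics, stats
#'   tables, the selected model, calibration and DCA tables), invisibly
#'   written to disk.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  cov_path <- file.path(config$input_dir, "cohort.csv")
  if (!file.exists(cov_path)) stop("validation error: missing cohort.csv", call. = FALSE)
  covars <- utils::read.csv(cov_path)
  patients <- covars$patient_id
  needed <- c("t1ce.nii.gz", "adc.nii.gz", "mask_tumor.nii.gz",
              "mask_edema.nii.gz", "mask_reference.nii.gz")
  for (pid in patients) {
    pdir <- file.path(config$input_dir, pid)
    miss <- needed[!file.exists(file.path(pdir, needed))]
    if (length(miss)) {
      stop("validation error: patient ", pid, " is missing ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  per_patient <- lapply(patients, function(pid) {
    pdir <- file.path(config$input_dir, pid)
    res <- tryCatch({
      masks <- segmentation_masks(
        tumor = read_voxel_grid(file.path(pdir, "mask_tumor.nii.gz")),
        edema = read_voxel_grid(file.path(pdir, "mask_edema.nii.gz")),
        reference = read_voxel_grid(file.path(pdir, "mask_reference.nii.gz"))
      )
      process_patient(
        read_voxel_grid(file.path(pdir, "t1ce.nii.gz")),
        read_voxel_grid(file.path(pdir, "adc.nii.gz")),
        masks, spacing = config$spacing, k = config$k,
        seed = config$cluster_seed, n_restarts = config$n_restarts
      )
    }, error = function(e) {
      stop("stage `habitats` failed for patient ", pid, ": ",
           conditionMessage(e), call. = FALSE)
    })
    write_voxel_grid(habitat_label_grid(res$habitat_map),
                     file.path(config$output_dir, paste0(pid, "_habitats.nii.gz")))
    c(list(patient_id = pid), as.list(res$fractions), as.list(res$metrics))
  })
  feat <- do.call(rbind, lapply(per_patient, function(x) as.data.frame(x)))
  cohort <- merge(covars[, setdiff(names(covars),
                                   c("f1", "f2", "f3", "EI", "rADCmean",
                                     "rADCmax", "rADCmin", "rADCdif",
                                     "diameter_mm"))],
                  feat, by = "patient_id", sort = TRUE)
  utils::write.csv(cohort, file.path(config$output_dir, "cohort_features.csv"),
                   row.names = FALSE)

  # cohort-level statistics (cohort-table style)
  y <- as.integer(cohort$diagnosis == "PCNSL")
  cont_vars <- intersect(c("age", "diameter_mm", "f1", "f2", "f3", "EI",
                           "rADCmean", "rADCmax", "rADCmin", "rADCdif"),
                         names(cohort))
  stats_tab <- do.call(rbind, lapply(cont_vars, function(v) {
    cg <- compare_groups(cohort[[v]][y == 0], cohort[[v]][y == 1])
    data.frame(variable = v, test = cg$test$test, p = cg$test$p,
               GBM = cg$summary_x, PCNSL = cg$summary_y)
  }))
  utils::write.csv(stats_tab, file.path(config$output_dir, "group_stats.csv"),
                   row.names = FALSE)

  split <- split_cohort(y, ratio = config$split_ratio, seed = config$split_seed)
  train <- cohort[split$train, ]
  ytr <- y[split$train]
  screen <- univariable_screen(train, ytr, cont_vars, alpha = config$screen_alpha)
  model <- NULL; roc_train <- NULL; hl <- NULL; calib <- NULL; dca <- NULL
  if (length(screen$significant) >= 1 && length(unique(ytr)) == 2) {
    model <- select_model(train, ytr, screen$significant)
    probs <- predict(model)
    roc_train <- roc_youden(probs, ytr)
    hl <- tryCatch(hosmer_lemeshow(probs, ytr, config$hl_groups),
                   error = function(e) NULL)
    calib <- calibration_curve(train, ytr, model$predictors,
                               B = config$bootstrap_B, seed = config$split_seed)
    dca <- decision_curve(probs, ytr, config$dca_grid)
    utils::write.csv(model$coefficients_table,
                     file.path(config$output_dir, "model_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(dca, file.path(config$output_dir, "decision_curve.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "habitatdx",
    version = as.character(utils::packageVersion("habitatdx")),
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("input_dir", "output_dir"))],
    n_patients = nrow(cohort),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, group_stats = stats_tab, split = split,
                 screening = screen, model = model, roc_train = roc_train,
                 hosmer_lemeshow = hl, calibration = calib,
                 decision_curve = dca))
}
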