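#' Vessel density from box counts
#'
#' Mean vessels per mm^2 over the ten counting boxes placed on a slide:
#' `mean(counts) / box_area`. The default box is 550 x 500 um, i.e.
#' 0.275 mm^2.
#'
#' @param counts integer vector of per-box vessel counts (length `n_boxes`).
#' @param box_area_mm2 box area in mm^2 (default 0.275).
#' @param n_boxes required number of boxes (default 10).
#' @return Density in vessels/mm^2.
#' @export
vm_density <- function(counts, box_area_mm2 = 0.275, n_boxes = 10L) {
  if (length(counts) != n_boxes) {
    stop("expected ", n_boxes, " box counts, got ", length(counts), call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (box_area_mm2 <= 0) stop("box area must be positive", call. = FALSE)
  mean(counts) / box_area_mm2
}

#' Continuous-VM positivity proportion
#'
#' Fraction of the ten counting areas in which continuous vasculogenic
#' mimicry (cross-linked channels, closed loops, networks) is present.
#'
#' @param flags logical (or 0/1) vector, one per counting area.
#' @param n_boxes required number of areas (default 10).
#' @return Proportion in `[0, 1]`.
#' @export
continuous_positivity <- function(flags, n_boxes = 10L) {
  if (length(flags) != n_boxes) {
    stop("expected ", n_boxes, " area flags", call. = FALSE)
  }
  mean(as.numeric(flags) > 0)
}

#' Summarize a VM counting sheet into per-patient measures
#'
#' A counting sheet has one row per (patient, box, observer) with columns
#' `patient`, `box`, `observer`, `discrete_vm`, `endothelial`,
#' `continuous_flag`. Counts are averaged across observers per box before
#' the density computation; the continuous flag is treated as positive if
#' the majority of observers marked it.
#'
#' @param sheet data frame in the sheet format.
#' @param box_area_mm2 box area in mm^2.
#' @return Data frame with one row per patient: `discrete_vm_density`,
#'   `endothelial_density`, `continuous_positivity`,
#'   `continuous_positive_any` (1 if any area positive).
#' @export
summarize_vm_sheet <- function(sheet, box_area_mm2 = 0.275) {
  needed <- c("patient", "box", "observer", "discrete_vm", "endothelial",
              "continuous_flag")
  if (!all(needed %in% names(sheet))) {
    stop("sheet must have columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  per_box <- stats::aggregate(
    sheet[, c("discrete_vm", "endothelial", "continuous_flag")],
    by = list(patient = sheet$patient, box = sheet$box), FUN = mean)
  out <- do.call(rbind, lapply(split(per_box, per_box$patient), function(pb) {
    pb <- pb[order(pb$box), ]
    data.frame(
      patient = pb$patient[1],
      discrete_vm_density = vm_density(pb$discrete_vm, box_area_mm2,
                                       n_boxes = nrow(pb)),
      endothelial_density = vm_density(pb$endothelial, box_area_mm2,
                                       n_boxes = nrow(pb)),
      continuous_positivity = mean(pb$continuous_flag >= 0.5),
      continuous_positive_any = as.numeric(any(pb$continuous_flag >= 0.5))
    )
  }))
  rownames(out) <- NULL
  out
}

#' Habitat-fraction vs vasculature multiple linear regression
#'
#' Ordinary least squares of one habitat voxel fraction on the three
#' vasculature measures (discrete-VM density, endothelial density,
#' continuous-VM positivity). Reports standardized coefficients (computed
#' on z-scored response and predictors; their t statistics equal the
#' unstandardized ones), the overall F statistic, adjusted R^2, and the
#' Durbin-Watson statistic `sum(diff(e)^2) / sum(e^2)` on residuals in
#' input order.
#'
#' @param response numeric vector (habitat fraction per patient).
#' @param predictors data frame or matrix of predictor columns.
#' @return An object of class `vm_regression`: `$table` (term, beta_std, t,
#'   p), `$r_squared`, `$adj_r_squared`, `$f_statistic`, `$f_p`,
#'   `$durbin_watson`, `$n`.
#' @export
habitat_vm_regression <- function(response, predictors) {
  X <- as.data.frame(predictors)
  n <- length(response)
  p <- ncol(X)
  if (n != nrow(X)) stop("response and predictors differ in length", call. = FALSE)
  if (n <= p + 1) stop("need n > predictors + 1", call. = FALSE)
  if (qr(scale(as.matrix(X), scale = FALSE))$rank < p) {
    stop("predictor matrix is rank deficient (collinear predictors)", call. = FALSE)
  }
  df <- cbind(.y = response, X)
  fml <- stats::as.formula(paste(".y ~", paste(names(X), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  cf <- sm$coefficients[-1, , drop = FALSE]
  beta_std <- cf[, "Estimate"] * vapply(X, stats::sd, numeric(1)) / stats::sd(response)
  e <- stats::residuals(fit)
  dw <- sum(diff(e)^2) / sum(e^2)
  fstat <- sm$fstatistic
  structure(list(
    table = data.frame(term = rownames(cf), beta_std = unname(beta_std),
                       t = unname(cf[, "t value"]),
                       p = unname(cf[, "Pr(>|t|)"]), row.names = NULL),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(fstat[1]),
    f_p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    durbin_watson = dw,
    n = n, fit = fit
  ), class = "vm_regression")
}

#' @export
print.vm_regression <- function(x, ...) {
  cat("<vm_regression> n = ", x$n,
      ", adj R^2 = ", format(x$adj_r_squared, digits = 3),
      ", F = ", format(x$f_statistic, digits = 4),
      ", D-W = ", format(x$durbin_watson, digits = 4), "\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}
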