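#' Stratified train/validation split
#'
#' Randomly partitions a cohort into training and validation sets. The
#' training size is `ceiling(ratio * n)`; with stratification the training
#' slots are apportioned across outcome classes by largest-remainder
#' rounding, so a 7:3 split of 125 patients yields 88 training cases.
#'
#' @param class vector of class labels (one per patient).
#' @param ratio training fraction in (0, 1); default 0.7.
#' @param seed integer RNG seed.
#' @param stratify stratify by `class` (default TRUE).
#' @return A list with `train` (logical vector), `ratio`, `seed`,
#'   `n_train`, `n_validation`.
#' @export
split_cohort <- function(class, ratio = 0.7, seed = 1L, stratify = TRUE) {
  n <- length(class)
  if (n < 2) stop("need at least 2 patients", call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)", call. = FALSE)
  n_train <- as.integer(ceiling(ratio * n))
  train <- logical(n)
  withr::with_seed(seed, {
    if (stratify) {
      cls <- as.factor(class)
      counts <- table(cls)
      per_class <- largest_remainder(as.numeric(counts), n_train)
      for (ci in seq_along(levels(cls))) {
        members <- which(cls == levels(cls)[ci])
        take <- min(per_class[ci], length(members))
        train[sample(members, take)] <- TRUE
      }
    } else {
      train[sample.int(n, n_train)] <- TRUE
    }
  })
  list(train = train, ratio = ratio, seed = seed,
       n_train = sum(train), n_validation = n - sum(train))
}

#' Fit a logistic regression with reporting columns
#'
#' Maximum-likelihood logistic regression (IRLS via `glm`) reporting, per
#' term, the log-odds coefficient B, its standard error, the odds ratio
#' `exp(B)` with Wald 95% CI `exp(B +/- 1.96 SE)`, the Wald p-value, and for
#' multi-predictor models the collinearity diagnostics tolerance and
#' VIF = 1/tolerance (from the R^2 of regressing each predictor on the
#' others). Outcome coding: the positive class (PCNSL in the intended
#' application) is 1.
#'
#' @param data data frame containing the predictors.
#' @param outcome 0/1 vector (or name of a column in `data`).
#' @param predictors character vector of predictor column names.
#' @return An object of class `habitat_logit`: the `glm` fit plus a
#'   coefficient table (`$coefficients_table`), `$aic`, `$collinearity`.
#' @export
fit_logistic <- function(data, outcome, predictors) {
  if (is.character(outcome) && length(outcome) == 1) {
    yname <- outcome
    y <- data[[outcome]]
  } else {
    yname <- ".outcome"
    y <- outcome
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)
  if (nrow(data) <= length(predictors) + 1) {
    stop("need n > number of terms + 1", call. = FALSE)
  }
  for (p in predictors) {
    if (stats::var(as.numeric(data[[p]])) == 0) {
      stop("zero-variance predictor: ", p, call. = FALSE)
    }
  }
  df <- data[, predictors, drop = FALSE]
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("aliased (exactly collinear) predictor(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)
  if (separation) {
    warning("possible (quasi-)separation: diverging coefficients detected")
  }
  cf <- summary(fit)$coefficients
  tab <- data.frame(
    term = rownames(cf),
    B = cf[, "Estimate"],
    SE = cf[, "Std. Error"],
    OR = exp(cf[, "Estimate"]),
    CI_low = exp(cf[, "Estimate"] - 1.96 * cf[, "Std. Error"]),
    CI_high = exp(cf[, "Estimate"] + 1.96 * cf[, "Std. Error"]),
    p = cf[, "Pr(>|z|)"],
    row.names = NULL
  )
  coll <- NULL
  if (length(predictors) >= 2) {
    tol <- vapply(predictors, function(p) {
      r2 <- summary(stats::lm(
        stats::as.formula(paste(p, "~", paste(setdiff(predictors, p), collapse = " + "))),
        data = df))$r.squared
      1 - r2
    }, numeric(1))
    coll <- data.frame(term = predictors, tolerance = tol, VIF = 1 / tol,
                       row.names = NULL)
  }
  structure(list(fit = fit, coefficients_table = tab, aic = stats::AIC(fit),
                 collinearity = coll, predictors = predictors,
                 outcome = yname, separation = separation),
            class = "habitat_logit")
}

#' @export
print.habitat_logit <- function(x, ...) {
  cat("<habitat_logit> ", length(x$predictors), " predictor(s), AIC = ",
      format(x$aic, digits = 6), "\n", sep = "")
  print(x$coefficients_table, digits = 4)
  invisible(x)
}

#' Predicted probabilities from a fitted diagnostic model
#' @param object a `habitat_logit`.
#' @param newdata data frame with the model's predictor columns.
#' @param ... unused.
#' @return Numeric vector of predicted probabilities.
#' @export
predict.habitat_logit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    as.numeric(stats::fitted(object$fit))
  } else {
    as.numeric(stats::predict(object$fit, newdata = newdata, type = "response"))
  }
}

#' Univariable screening of candidate predictors
#'
#' Fits one single-predictor logistic model per candidate and returns the
#' combined coefficient table; candidates with Wald p below `alpha` form
#' the significant set passed on to multivariable selection.
#'
#' @inheritParams fit_logistic
#' @param candidates character vector of candidate predictor names.
#' @param alpha screening level (default 0.05).
#' @return A list with `table` (one row per candidate) and `significant`
#'   (character vector).
#' @export
univariable_screen <- function(data, outcome, candidates, alpha = 0.05) {
  rows <- lapply(candidates, function(p) {
    m <- fit_logistic(data, outcome, p)
    m$coefficients_table[m$coefficients_table$term == p, ]
  })
  tab <- do.call(rbind, rows)
  list(table = tab, significant = tab$term[tab$p < alpha])
}

#' Backward AIC model selection
#'
#' Starting from the full multivariable logistic model on the candidate set
#' (conventionally the univariably significant predictors), repeatedly
#' removes the term whose deletion most decreases the AIC until no deletion
#' decreases it; ties are broken by removing the term with the larger Wald
#' p-value. The returned model is refitted on the retained terms and carries
#' tolerance/VIF diagnostics. Exactly collinear (aliased) candidates — e.g.
#' a difference of two other candidates — are dropped with a warning before
#' elimination starts.
#'
#' @inheritParams fit_logistic
#' @param candidates character vector of candidate predictors (>= 1).
#' @return A `habitat_logit` for the selected model, with attribute
#'   `$selection_path` recording each removal and the AIC trace.
#' @export
select_model <- function(data, outcome, candidates) {
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  # drop exactly collinear (aliased) candidates up front, keeping the
  # earliest-listed representative of each dependent set
  X <- as.matrix(data[, candidates, drop = FALSE])
  qrX <- qr(cbind(1, X))
  keep_cols <- sort(qrX$pivot[seq_len(qrX$rank)])
  keep_cols <- keep_cols[keep_cols > 1] - 1
  dropped <- setdiff(candidates, candidates[keep_cols])
  if (length(dropped)) {
    warning("dropping aliased candidate(s) before selection: ",
            paste(dropped, collapse = ", "))
  }
  current <- candidates[keep_cols]
  path <- list(list(terms = current, aic = fit_logistic(data, outcome, current)$aic))
  repeat {
    m0 <- fit_logistic(data, outcome, current)
    if (length(current) == 1) break
    drops <- vapply(current, function(p) {
      fit_logistic(data, outcome, setdiff(current, p))$aic
    }, numeric(1))
    best_aic <- min(drops)
    if (best_aic >= m0$aic - 1e-12) break
    cand <- current[drops <= best_aic + 1e-9]
    if (length(cand) > 1) {
      wp <- m0$coefficients_table$p[match(cand, m0$coefficients_table$term)]
      cand <- cand[which.max(wp)]
    }
    current <- setdiff(current, cand[1])
    path <- c(path, list(list(terms = current, removed = cand[1], aic = best_aic)))
  }
  final <- fit_logistic(data, outcome, current)
  final$selection_path <- path
  final
}

#' Build a nomogram point scale from a logistic model
#'
#' Converts a fitted logistic model into the familiar points representation:
#' for predictor j with coefficient B_j over display range
#' `[lo_j, hi_j]`, the reference value is the range end with the lowest
#' risk, and points at value x are `100 * B_j (x - ref_j) * sign / S` with
#' `S = max_j |B_j| * (hi_j - lo_j)`, so the widest-effect predictor spans
#' exactly 0-100 points. Total points map back to predicted probability
#' through the reconstructed linear predictor, so the nomogram reproduces
#' the model's probabilities exactly.
#'
#' @param model a `habitat_logit`.
#' @param ranges named list of length-2 numeric ranges, one per predictor
#'   (defaults to the observed range in the training data).
#' @return An object of class `nomogram_spec` with per-predictor scales and
#'   functions `points_for(predictor, x)` and `prob_for_total(points)`.
#' @export
build_nomogram <- function(model, ranges = NULL) {
  if (!inherits(model, "habitat_logit")) stop("`model` must be a habitat_logit", call. = FALSE)
  preds <- model$predictors
  if (length(preds) < 1) stop("model has no predictors", call. = FALSE)
  B <- stats::coef(model$fit)
  intercept <- B[1]
  B <- B[-1]
  if (is.null(ranges)) {
    mf <- model$fit$model
    ranges <- lapply(preds, function(p) range(mf[[p]]))
    names(ranges) <- preds
  }
  lo <- vapply(preds, function(p) ranges[[p]][1], numeric(1))
  hi <- vapply(preds, function(p) ranges[[p]][2], numeric(1))
  if (any(hi <= lo)) stop("zero-width display range", call. = FALSE)
  ref <- ifelse(B > 0, lo, hi)   # lowest-risk end of the range
  scale_max <- max(abs(B) * (hi - lo))
  spec <- structure(list(
    predictors = preds, B = B, intercept = intercept,
    lo = lo, hi = hi, ref = ref, scale = scale_max
  ), class = "nomogram_spec")
  spec
}

#' Points for a predictor value on a nomogram scale
#' @param spec a `nomogram_spec`.
#' @param predictor predictor name.
#' @param x predictor value(s).
#' @return Points (>= 0) on the 0-100 scale.
#' @export
nomogram_points <- function(spec, predictor, x) {
  j <- match(predictor, spec$predictors)
  if (is.na(j)) stop("unknown predictor: ", predictor, call. = FALSE)
  100 * (spec$B[j] * x - spec$B[j] * spec$ref[j]) / spec$scale
}

#' Predicted probability from total nomogram points
#' @param spec a `nomogram_spec`.
#' @param total total points summed over all predictor scales.
#' @return Predicted probability of the positive class.
#' @export
nomogram_probability <- function(spec, total) {
  lp <- spec$intercept + sum(spec$B * spec$ref) + spec$scale / 100 * total
  stats::plogis(lp)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping: observations are binned by quantiles of the
#' predicted probability with tied probabilities kept in one bin (which can
#' reduce the number of bins and hence the degrees of freedom);
#' `chi^2 = sum (O - E)^2 / (E (1 - E/n_g))` over bins, df = bins - 2.
#'
#' @param probs predicted probabilities.
#' @param outcomes 0/1 outcomes.
#' @param groups requested number of bins (default 10).
#' @return A list with `statistic`, `df`, `p`, `groups_used`.
#' @export
hosmer_lemeshow <- function(probs, outcomes, groups = 10L) {
  n <- length(probs)
  if (groups < 3) stop("need at least 3 groups", call. = FALSE)
  if (n < groups) stop("fewer observations than groups", call. = FALSE)
  outcomes <- as.numeric(outcomes)
  breaks <- unique(stats::quantile(probs, seq(0, 1, length.out = groups + 1),
                                   names = FALSE))
  if (length(breaks) < 3) stop("predicted probabilities too tied to form bins", call. = FALSE)
  bin <- cut(probs, breaks = breaks, include.lowest = TRUE)
  O <- tapply(outcomes, bin, sum)
  E <- tapply(probs, bin, sum)
  ng <- tapply(outcomes, bin, length)
  keep <- !is.na(O)
  O <- O[keep]; E <- E[keep]; ng <- ng[keep]
  if (any(E <= 0) || any(E >= ng)) {
    stop("degenerate bin with expected count 0 (or n)", call. = FALSE)
  }
  stat <- sum((O - E)^2 / (E * (1 - E / ng)))
  df <- length(O) - 2L
  list(statistic = unname(stat), df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       groups_used = length(O))
}

#' Bootstrap optimism-corrected calibration
#'
#' Harrell's optimism bootstrap for the calibration slope and intercept of
#' a logistic model: the model formula is refitted on each bootstrap
#' resample, the resample model is evaluated on the original data, and the
#' average optimism (apparent minus test performance) is subtracted from
#' the apparent values. The apparent calibration slope of a model evaluated
#' on its own training data is 1 by the logistic score equations; the
#' corrected slope shrinks toward 0 in overfitted models. Resamples whose
#' outcome collapses to a single class are skipped and counted.
#'
#' @param data training data frame.
#' @param outcome 0/1 outcome vector or column name.
#' @param predictors character vector of predictors.
#' @param B number of bootstrap resamples (>= 1; 1000 in the intended use).
#' @param seed integer RNG seed.
#' @param groups bins for the reported calibration curve points.
#' @return An object of class `calibration_report`: apparent and corrected
#'   slope/intercept, the binned apparent curve, `B_used`, `B_skipped`.
#' @export
calibration_curve <- function(data, outcome, predictors, B = 1000L, seed = 1L,
                              groups = 10L) {
  if (B < 1) stop("B_resamples must be >= 1", call. = FALSE)
  model <- fit_logistic(data, outcome, predictors)
  y <- model$fit$model$.y
  lp_app <- as.numeric(stats::predict(model$fit))
  slope_app <- 1      # logistic score identity on the training data
  intercept_app <- 0
  n <- nrow(data)
  opt_slope <- numeric(0); opt_int <- numeric(0); skipped <- 0L
  refit_slope <- function(yv, lp) {
    f <- suppressWarnings(stats::glm(yv ~ lp, family = stats::binomial()))
    stats::coef(f)
  }
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      ii <- sample.int(n, n, replace = TRUE)
      yb <- y[ii]
      if (length(unique(yb)) < 2) { skipped <- skipped + 1L; next }
      mb <- tryCatch(fit_logistic(data[ii, , drop = FALSE], y[ii], predictors),
                     error = function(e) NULL)
      if (is.null(mb)) { skipped <- skipped + 1L; next }
      lp_orig <- as.numeric(stats::predict(mb$fit, newdata = data))
      cf_test <- tryCatch(refit_slope(y, lp_orig), error = function(e) c(NA, NA))
      if (any(is.na(cf_test))) { skipped <- skipped + 1L; next }
      opt_slope <- c(opt_slope, 1 - cf_test[2])
      opt_int <- c(opt_int, 0 - cf_test[1])
    }
  })
  bins <- unique(stats::quantile(stats::plogis(lp_app),
                                 seq(0, 1, length.out = groups + 1), names = FALSE))
  bl <- cut(stats::plogis(lp_app), breaks = bins, include.lowest = TRUE)
  curve <- data.frame(
    predicted = as.numeric(tapply(stats::plogis(lp_app), bl, mean)),
    observed = as.numeric(tapply(y, bl, mean)),
    n = as.numeric(tapply(y, bl, length))
  )
  structure(list(
    slope_apparent = slope_app, intercept_apparent = intercept_app,
    slope_corrected = slope_app - mean(opt_slope),
    intercept_corrected = intercept_app - mean(opt_int),
    curve = curve[!is.na(curve$predicted), ],
    B_used = length(opt_slope), B_skipped = skipped, seed = seed
  ), class = "calibration_report")
}

#' Decision-curve analysis
#'
#' Net benefit of acting on the model at each threshold probability p_t:
#' `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)`, where patients with
#' predicted probability >= p_t are treated. Returned alongside the
#' treat-all curve (`prev - (1 - prev) * p_t/(1 - p_t)`) and the treat-none
#' curve (identically 0).
#'
#' @param probs predicted probabilities.
#' @param outcomes 0/1 outcomes.
#' @param thresholds vector of threshold probabilities in (0, 1).
#' @return A data frame with columns `threshold`, `net_benefit`,
#'   `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probs, outcomes, thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (length(thresholds) == 0) stop("empty threshold grid", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  outcomes <- as.numeric(outcomes)
  if (length(unique(outcomes)) < 2) stop("both classes must be present", call. = FALSE)
  n <- length(outcomes)
  prev <- mean(outcomes)
  nb <- vapply(thresholds, function(pt) {
    treat <- probs >= pt
    tp <- sum(outcomes == 1 & treat)
    fp <- sum(outcomes == 0 & treat)
    tp / n - fp / n * pt / (1 - pt)
  }, numeric(1))
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb, treat_all = ta,
             treat_none = 0)
}
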