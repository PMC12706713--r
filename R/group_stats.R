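#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction (df = 1), the variant
#' used for the cohort's sex / location / symptom comparisons.
#'
#' @param table 2x2 matrix of nonnegative counts (rows: group, cols: level).
#' @return A list with `statistic`, `df`, `p`, `test`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("expected a 2x2 table", call. = FALSE)
  if (any(table < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, test = "pearson_chi2")
}

#' Welch two-sample t-test from samples or summaries
#'
#' Two-sided Welch t-test. Give either two raw sample vectors `x` and `y`,
#' or two summary lists/vectors `c(mean =, sd =, n =)` so that printed
#' summary statistics can be tested directly.
#'
#' @param x,y numeric sample vectors, or length-3 numeric vectors / lists
#'   with elements `mean`, `sd`, `n`.
#' @return A list with `statistic`, `df`, `p`, `test`.
#' @export
two_sample_t <- function(x, y) {
  as_summary <- function(v) {
    if (is.list(v) || (!is.null(names(v)) && all(c("mean", "sd", "n") %in% names(v)))) {
      v <- unlist(v)
      c(mean = unname(v["mean"]), sd = unname(v["sd"]), n = unname(v["n"]))
    } else NULL
  }
  sx <- as_summary(x); sy <- as_summary(y)
  if (xor(is.null(sx), is.null(sy))) {
    stop("give both arguments as samples or both as summaries", call. = FALSE)
  }
  if (is.null(sx)) {
    if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group", call. = FALSE)
    ht <- stats::t.test(x, y)
    return(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, test = "welch_t"))
  }
  if (sx["n"] < 2 || sy["n"] < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sx["sd"] <= 0 || sy["sd"] <= 0) stop("summary SDs must be positive", call. = FALSE)
  v1 <- sx["sd"]^2 / sx["n"]; v2 <- sy["sd"]^2 / sy["n"]
  tstat <- (sx["mean"] - sy["mean"]) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (sx["n"] - 1) + v2^2 / (sy["n"] - 1))
  list(statistic = unname(tstat), df = unname(df),
       p = unname(2 * stats::pt(-abs(tstat), df)), test = "welch_t")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For combined sample size <= `exact_max` the
#' p-value is computed by exact enumeration of all group labelings (tie-safe
#' via midranks; two-sided p = min(1, 2 * min(lower tail, upper tail))).
#' For larger samples the continuity-corrected normal approximation with
#' tie correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max combined-size cutoff for exact enumeration (default 12).
#' @return A list with `statistic` (U for `x`), `p`, `exact`, `test`.
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, nx)
    us <- apply(combos, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
    lo <- mean(us <= u_obs + 1e-9)
    hi <- mean(us >= u_obs - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    return(list(statistic = u_obs, p = p, exact = TRUE, test = "mann_whitney"))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = u_obs, p = ht$p.value, exact = FALSE, test = "mann_whitney")
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped; for up to `exact_max` nonzero pairs the null distribution is
#' enumerated over all 2^m sign patterns (midranks handle tied magnitudes);
#' otherwise the continuity-corrected normal approximation with tie
#' correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max nonzero-pair cutoff for exact enumeration (default 15).
#' @return A list with `statistic` (V, positive-rank sum), `p`, `exact`,
#'   `test`.
#' @export
wilcoxon_paired <- function(d, exact_max = 15L) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (m <= exact_max) {
    # enumerate all sign patterns: distribution of sum of ranks with + sign
    vs <- 0
    for (j in seq_len(m)) {
      vs <- c(vs, vs + r[j])  # grows to 2^m totals
    }
    lo <- mean(vs <= v_obs + 1e-9)
    hi <- mean(vs >= v_obs - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    return(list(statistic = v_obs, p = p, exact = TRUE, test = "wilcoxon_signed_rank"))
  }
  ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  list(statistic = v_obs, p = ht$p.value, exact = FALSE, test = "wilcoxon_signed_rank")
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC curve (AUC by the Mann-Whitney estimator with ties counted
#' one half), DeLong 95% confidence interval, and the operating point that
#' maximizes the Youden index J = sensitivity + specificity - 1. Candidate
#' cutoffs are midpoints between adjacent observed scores; when several
#' cutoffs tie on J, the one with the higher sensitivity is reported.
#'
#' @param scores numeric predictor values.
#' @param labels 0/1 (or two-level) outcome; 1 is the positive class.
#' @param direction `">"` if higher scores indicate the positive class
#'   (default), `"<"` otherwise.
#' @return A list with `auc`, `ci` (length 2), `sensitivity`, `specificity`,
#'   `cutoff`, `youden`.
#' @export
roc_youden <- function(scores, labels, direction = c(">", "<")) {
  direction <- match.arg(direction)
  labels <- as.integer(as.factor(labels)) - 1L
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  # pROC's direction: "<" means controls have lower scores than cases
  proc_dir <- if (direction == ">") "<" else ">"
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = proc_dir, quiet = TRUE)
  ci <- as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[is.finite(co$threshold), , drop = FALSE]
  j <- co$sensitivity + co$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(co$sensitivity[best])]
  list(auc = as.numeric(pROC::auc(r)), ci = ci[c(1, 3)],
       sensitivity = co$sensitivity[best], specificity = co$specificity[best],
       cutoff = co$threshold[best], youden = j[best])
}

#' Intraclass correlation coefficient for absolute agreement
#'
#' Single-measure, two-way random-effects, absolute-agreement ICC (Shrout &
#' Fleiss ICC(2,1)) from the standard mean-squares decomposition; the
#' consistency variant ICC(3,1) is reported alongside.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns.
#' @return A list with `icc` (absolute agreement), `icc_consistency`,
#'   `variant`, `n`, `k`.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  if (stats::var(as.vector(ratings)) == 0) {
    stop("ratings are constant: ICC undefined", call. = FALSE)
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc31 <- (msr - mse) / (msr + (k - 1) * mse)
  list(icc = icc21, icc_consistency = icc31, variant = "ICC(2,1)",
       n = n, k = k)
}

#' Table-style group comparison for one continuous variable
#'
#' Applies the reporting convention used for cohort tables: Shapiro-Wilk on
#' each group at alpha = 0.05 decides between the Welch t-test
#' (mean +/- SD row) and the Mann-Whitney test (median (P25, P75) row,
#' linear-interpolation quantiles).
#'
#' @param x,y numeric samples for the two groups.
#' @param alpha Shapiro-Wilk significance level for the normality gate.
#' @return A list with the chosen `test` result, `normal` flag, and the
#'   per-group summary strings.
#' @export
compare_groups <- function(x, y, alpha = 0.05) {
  normal <- stats::shapiro.test(x)$p.value >= alpha &&
    stats::shapiro.test(y)$p.value >= alpha
  summ <- function(v) {
    if (normal) {
      sprintf("%.3g +/- %.3g", mean(v), stats::sd(v))
    } else {
      q <- stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
      sprintf("%.3g (%.3g, %.3g)", q[1], q[2], q[3])
    }
  }
  res <- if (normal) two_sample_t(x, y) else mann_whitney(x, y)
  list(test = res, normal = normal, summary_x = summ(x), summary_y = summ(y))
}
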