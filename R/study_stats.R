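#' Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided signed-rank test on the differences `b - a`. Zero differences
#' are dropped (the classical convention); the exact distribution is used
#' for up to 25 tie-free nonzero differences and the normal approximation
#' with tie correction otherwise. All-zero differences give `p = 1` with a
#' warning rather than an error.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return List: `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n_used` (nonzero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p_value = 1, n_used = 0L, method = "degenerate"))
  }
  exact <- n <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", mu = 0,
                       exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n_used = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Paired t-test
#'
#' Standard paired t on `b - a` with `n - 1` df, two-sided. Zero-variance
#' nonzero differences (every difference equal) return the infinite-t
#' sentinel with `p = 0` and a warning; all-zero differences return
#' `t = 0`, `p = 1`.
#'
#' @inheritParams wilcoxon_signed_rank
#' @return List: `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  d <- b - a
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1L, p_value = 1, mean_difference = 0))
    warning("zero-variance nonzero differences; t is infinite", call. = FALSE)
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p_value = 0,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Cohen's kappa for two raters
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` over the shared category set.
#' When both raters use a single identical category throughout, chance
#' agreement is 1 and kappa is undefined (`NA` with a warning).
#'
#' @param r1,r2 equal-length vectors of ordinal/categorical ratings.
#' @return List: `kappa`, `p_observed`, `p_expected`, `table`.
#' @export
cohen_kappa <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) >= 1L)
  lev <- sort(unique(c(r1, r2)))
  tab <- table(factor(r1, levels = lev), factor(r2, levels = lev))
  p <- tab / sum(tab)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (pe == 1) {
    warning("single shared category; kappa undefined", call. = FALSE)
    return(list(kappa = NA_real_, p_observed = po, p_expected = pe, table = tab))
  }
  list(kappa = (po - pe) / (1 - pe), p_observed = po, p_expected = pe,
       table = tab)
}

#' Kendall's tau-b and tau-c
#'
#' Concordant/discordant pair counting with the variant's tie
#' normalization: tau-b divides by the geometric mean of the tie-corrected
#' pair counts; tau-c applies the rectangular `m`-category correction
#' `2 m (C - D) / (n^2 (m - 1))` with `m` the smaller number of distinct
#' values. Constant input on either side yields `NA` with a warning.
#'
#' @param r1,r2 equal-length numeric/ordinal vectors.
#' @param variant `"b"` or `"c"`.
#' @return The tau value.
#' @export
kendall_tau <- function(r1, r2, variant = c("b", "c")) {
  variant <- match.arg(variant)
  stopifnot(length(r1) == length(r2))
  n <- length(r1)
  if (length(unique(r1)) < 2L || length(unique(r2)) < 2L) {
    warning("constant ratings; tau undefined", call. = FALSE)
    return(NA_real_)
  }
  s1 <- sign(outer(r1, r1, `-`)); s2 <- sign(outer(r2, r2, `-`))
  up <- upper.tri(s1)
  conc <- sum(s1[up] * s2[up] == 1)
  disc <- sum(s1[up] * s2[up] == -1)
  if (variant == "b") {
    n0 <- n * (n - 1) / 2
    t1 <- sum(choose(table(r1), 2))
    t2 <- sum(choose(table(r2), 2))
    (conc - disc) / sqrt((n0 - t1) * (n0 - t2))
  } else {
    m <- min(length(unique(r1)), length(unique(r2)))
    2 * m * (conc - disc) / (n^2 * (m - 1))
  }
}

#' Within-participant coefficient of variation
#'
#' Per subject (row), `CV = SD / mean * 100` across the `k` columns
#' (methods, sequences, detectors); the summary is the mean of per-subject
#' CVs. Subjects with non-positive mean are excluded with a warning.
#'
#' @param table numeric matrix or data.frame, subjects x methods (k >= 2).
#' @return List: `per_subject` (CV %, `NA` for excluded rows),
#'   `summary` (mean CV %), `n_used`.
#' @export
within_participant_cv <- function(table) {
  m <- as.matrix(table)
  stopifnot(ncol(m) >= 2L, nrow(m) >= 1L)
  mu <- rowMeans(m)
  cv <- apply(m, 1L, stats::sd) / mu * 100
  bad <- mu <= 0
  if (any(bad)) {
    warning(sum(bad), " subject(s) with non-positive mean excluded from CV",
            call. = FALSE)
    cv[bad] <- NA_real_
  }
  list(per_subject = cv, summary = mean(cv, na.rm = TRUE), n_used = sum(!bad))
}

#' Two-way mixed-effects intraclass correlation
#'
#' Computes the four conventional two-way mixed ICC forms from the
#' two-way ANOVA mean squares of a complete subjects x raters table
#' (`MSR` rows, `MSC` columns, `MSE` residual):
#' single-measure consistency `(MSR - MSE) / (MSR + (k-1) MSE)`,
#' average-measure consistency `(MSR - MSE) / MSR`,
#' single-measure agreement `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' average-measure agreement `(MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#' Consistency ignores systematic column offsets; absolute agreement
#' penalizes them. No subject variance (`MSR = 0`) leaves the forms
#' undefined (`NA` with a warning).
#'
#' @param table complete numeric matrix/data.frame, n subjects x k raters,
#'   n >= 3, k >= 2, no missing cells.
#' @return List of class `icc_result`: the four ICCs, `ms` (MSR, MSC, MSE),
#'   `n`, `k`.
#' @export
icc_two_way_mixed <- function(table) {
  m <- as.matrix(table)
  if (anyNA(m)) stop("ICC requires a complete table (no missing cells)", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  stopifnot(n >= 3L, k >= 2L)
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0) {
    warning("no between-subject variance; ICC undefined", call. = FALSE)
    icc <- rep(NA_real_, 4)
  } else {
    icc <- c((msr - mse) / (msr + (k - 1) * mse),
             (msr - mse) / msr,
             (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
             (msr - mse) / (msr + (msc - mse) / n))
  }
  structure(list(icc_single_consistency = icc[1],
                 icc_avg_consistency = icc[2],
                 icc_single_agreement = icc[3],
                 icc_avg_agreement = icc[4],
                 ms = c(MSR = msr, MSC = msc, MSE = mse),
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> n=%d k=%d\n", x$n, x$k))
  cat(sprintf("  consistency: single %.4f  average %.4f\n",
              x$icc_single_consistency, x$icc_avg_consistency))
  cat(sprintf("  agreement:   single %.4f  average %.4f\n",
              x$icc_single_agreement, x$icc_avg_agreement))
  invisible(x)
}

#' Cross-detector agreement report for edge features
#'
#' Given per-subject edge-feature results for all three detectors, computes
#' for each feature (steepness, width, contrast) the within-participant CV
#' and the four two-way mixed ICC forms across detectors. Subjects missing
#' any detector are dropped with a message.
#'
#' @param features named list: for each subject, a named list of
#'   `edge_feature_result`s keyed by detector.
#' @param detectors detector names required per subject.
#' @return Data.frame with one row per feature: `feature`, `cv_percent`,
#'   the four ICC columns, `n_subjects`.
#' @export
detector_agreement_report <- function(features,
                                      detectors = c("roberts", "sobel", "canny")) {
  keep <- vapply(features, function(f) all(detectors %in% names(f)), logical(1))
  if (any(!keep))
    message(sum(!keep), " subject(s) dropped: incomplete detector coverage")
  features <- features[keep]
  if (length(features) < 3L)
    stop("need >= 3 subjects with full detector coverage", call. = FALSE)
  pull <- function(field) {
    t(vapply(features,
             function(f) vapply(detectors, function(d) f[[d]][[field]],
                                numeric(1)),
             numeric(length(detectors))))
  }
  feats <- c(steepness = "mean_steepness", width = "mean_width_px",
             contrast = "mean_contrast")
  rows <- lapply(names(feats), function(nm) {
    tab <- pull(feats[[nm]])
    cv <- within_participant_cv(tab)
    icc <- icc_two_way_mixed(tab)
    data.frame(feature = nm, cv_percent = cv$summary,
               icc_single_consistency = icc$icc_single_consistency,
               icc_avg_consistency = icc$icc_avg_consistency,
               icc_single_agreement = icc$icc_single_agreement,
               icc_avg_agreement = icc$icc_avg_agreement,
               n_subjects = nrow(tab))
  })
  do.call(rbind, rows)
}
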