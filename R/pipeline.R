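#' Parse and compare protocol acquisition times
#'
#' `parse_min_sec` converts `"m:ss"` strings to seconds.
#' `time_reduction_pct` gives the percentage of acquisition time saved by
#' the accelerated arm, `100 * (1 - sum(accel) / sum(conv))`, rounded to
#' whole percent as protocol tables print it.
#'
#' @param x character vector of `"m:ss"` durations.
#' @return `parse_min_sec`: seconds (numeric). `time_reduction_pct`: percent.
#' @export
parse_min_sec <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) stop("expected \"m:ss\", got: ", paste(p, collapse = ":"),
                              call. = FALSE)
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, numeric(1))
}

#' @rdname parse_min_sec
#' @param conventional,accelerated `"m:ss"` durations (summed if vectors).
#' @export
time_reduction_pct <- function(conventional, accelerated) {
  tc <- sum(parse_min_sec(conventional))
  ta <- sum(parse_min_sec(accelerated))
  if (tc <= 0) stop("conventional time must be positive", call. = FALSE)
  round(100 * (1 - ta / tc))
}

#' Acquisition times of the four-sequence orbital TSE protocol
#'
#' The per-sequence acquisition times of the orbital protocol the package's
#' report layout mirrors: axial and coronal T2-weighted and
#' contrast-enhanced fat-saturated T1-weighted TSE, each acquired
#' conventionally and as an accelerated deep-learning-reconstructed
#' variant. Shipped as plain CSV in `inst/extdata/scan_times.csv`.
#'
#' @return Data.frame: `sequence`, `plane`, `cr_time`, `dlr_time` ("m:ss").
#' @export
orbital_scan_times <- function() {
  utils::read.csv(system.file("extdata", "scan_times.csv",
                              package = "orbitsharp"),
                  colClasses = "character")
}

#' Read a paired-study manifest
#'
#' CSV with columns `subject_id`, `sequence`, `plane`, `cr_path`,
#' `dlr_path`. All paths must resolve and (subject, sequence, plane) rows
#' must be unique.
#'
#' @param path manifest CSV path.
#' @param check_paths verify all image paths exist (default TRUE).
#' @return The manifest data.frame.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  man <- utils::read.csv(path, colClasses = "character")
  needed <- c("subject_id", "sequence", "plane", "cr_path", "dlr_path")
  if (!all(needed %in% names(man)))
    stop("manifest must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  key <- paste(man$subject_id, man$sequence, man$plane)
  if (anyDuplicated(key))
    stop("duplicate (subject, sequence, plane) rows in manifest", call. = FALSE)
  if (check_paths) {
    missing <- c(man$cr_path, man$dlr_path)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      stop("unresolvable image paths: ", paste(utils::head(missing, 3),
                                               collapse = ", "), call. = FALSE)
  }
  man
}

#' Run the full paired-comparison study pipeline
#'
#' End-to-end batch analysis of reference/comparison image pairs: for every
#' manifest row it computes the reference metrics (SSIM, MS-SSIM, SNR,
#' PSNR, blur percentage; conventional arm as reference), the no-reference
#' metrics (PSI, perceptual blur metric) on both arms, and the three edge
#' features for each detector on both arms. Outputs mirror the layout of a
#' paired reconstruction-comparison report: a per-pair table, a
#' per-sequence mean +/- SD summary, paired tests (Wilcoxon and paired t)
#' per metric, and a cross-detector agreement table. Deterministic given
#' the manifest (all metrics are deterministic; `seed` is recorded for
#' provenance of any upstream phantom generation).
#'
#' @param manifest data.frame as from [read_manifest()], or a path to one.
#' @param detectors edge detectors to run (default all three).
#' @param out_dir optional directory for CSV outputs (`pairs.csv`,
#'   `summary.csv`, `paired_tests.csv`, `detector_agreement.csv`,
#'   `run_log.json`).
#' @param seed integer recorded in the run log.
#' @param params list of parameter overrides passed to
#'   [summarize_edge_features()] (elements `steep_win`, `contrast_win`,
#'   `half_length`, `spacing`, `contrast_floor`, `detector_params`).
#' @param images optional list of preloaded pairs (`list(cr =, dlr =)` of
#'   normalized [gray_image]s) keyed by manifest row, bypassing file I/O.
#' @return List of class `study_report`: `pairs`, `summary`,
#'   `paired_tests`, `detector_agreement`, `skipped`, `run_log`.
#' @export
run_study <- function(manifest, detectors = c("roberts", "sobel", "canny"),
                      out_dir = NULL, seed = 1L, params = list(),
                      images = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  p <- utils::modifyList(list(steep_win = 3L, contrast_win = 11L,
                              half_length = 5, spacing = 0.25,
                              contrast_floor = 0.05, detector_params = list()),
                         params)
  rows <- list(); skipped <- character(0); feat_by_subj <- list()
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i, ]
    pair <- tryCatch({
      if (!is.null(images)) images[[i]]
      else list(cr = normalize_intensity(load_image(mrow$cr_path)),
                dlr = normalize_intensity(load_image(mrow$dlr_path)))
    }, error = function(e) e)
    if (inherits(pair, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", mrow$subject_id, conditionMessage(pair)))
      next
    }
    res <- analyze_pair(pair$cr, pair$dlr, detectors, p)
    feat_by_subj[[mrow$subject_id]] <- res$features_dlr_cr
    rows[[length(rows) + 1L]] <- cbind(
      mrow[c("subject_id", "sequence", "plane")], res$metrics,
      row.names = NULL)
  }
  if (!length(rows)) stop("no analyzable pairs in manifest", call. = FALSE)
  pairs <- do.call(rbind, rows)

  metric_cols <- setdiff(names(pairs), c("subject_id", "sequence", "plane"))
  summarize <- function(df) {
    data.frame(metric = metric_cols,
               mean = vapply(metric_cols, function(cn) mean(df[[cn]][is.finite(df[[cn]])]),
                             numeric(1)),
               sd = vapply(metric_cols, function(cn) stats::sd(df[[cn]][is.finite(df[[cn]])]),
                           numeric(1)),
               row.names = NULL)
  }
  summary_tab <- do.call(rbind, lapply(split(pairs, pairs$sequence), function(df) {
    cbind(sequence = df$sequence[1], summarize(df))
  }))
  rownames(summary_tab) <- NULL

  paired_tests <- paired_test_table(pairs, detectors)
  agreement <- cross_detector_agreement(feat_by_subj, detectors)

  run_log <- list(n_pairs = nrow(pairs), n_skipped = length(skipped),
                  detectors = detectors, params = p, seed = seed,
                  timestamp_free = TRUE)
  report <- structure(list(pairs = pairs, summary = summary_tab,
                           paired_tests = paired_tests,
                           detector_agreement = agreement,
                           skipped = skipped, run_log = run_log),
                      class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Metrics + edge features for a single CR/DLR pair.
analyze_pair <- function(cr, dlr, detectors, p) {
  met <- data.frame(
    ssim = ssim(cr, dlr),
    ms_ssim = suppressWarnings(ms_ssim(cr, dlr)),
    snr = snr_ref(cr, dlr),
    psnr = psnr(cr, dlr),
    blur_pct = blur_percentage(cr, dlr),
    psi_cr = psi(cr)$value,
    psi_dlr = psi(dlr)$value,
    blur_metric_cr = perceptual_blur_metric(cr),
    blur_metric_dlr = perceptual_blur_metric(dlr))
  feats <- list()
  for (d in detectors) {
    for (arm in c("cr", "dlr")) {
      img <- if (arm == "cr") cr else dlr
      f <- summarize_edge_features(img, d, params = p$detector_params,
                                   steep_win = p$steep_win,
                                   contrast_win = p$contrast_win,
                                   half_length = p$half_length,
                                   spacing = p$spacing,
                                   contrast_floor = p$contrast_floor,
                                   keep_per_pixel = FALSE)
      feats[[paste0(d, "_", arm)]] <- f
      met[[paste0("steepness_", d, "_", arm)]] <- f$mean_steepness
      met[[paste0("width_", d, "_", arm)]] <- f$mean_width_px
      met[[paste0("contrast_", d, "_", arm)]] <- f$mean_contrast
    }
  }
  list(metrics = met, features_dlr_cr = feats)
}

paired_test_table <- function(pairs, detectors) {
  specs <- list(c("psi_cr", "psi_dlr"),
                c("blur_metric_cr", "blur_metric_dlr"))
  for (d in detectors)
    for (f in c("steepness", "width", "contrast"))
      specs[[length(specs) + 1L]] <- paste0(f, "_", d, c("_cr", "_dlr"))
  rows <- lapply(specs, function(sp) {
    a <- pairs[[sp[1]]]; b <- pairs[[sp[2]]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L) return(NULL)
    wt <- suppressWarnings(wilcoxon_signed_rank(a[ok], b[ok]))
    tt <- suppressWarnings(paired_t(a[ok], b[ok]))
    data.frame(metric = sub("_cr$", "", sp[1]), n = sum(ok),
               mean_cr = mean(a[ok]), mean_dlr = mean(b[ok]),
               mean_difference = tt$mean_difference,
               p_wilcoxon = wt$p_value, t = tt$t, p_paired_t = tt$p_value)
  })
  do.call(rbind, rows)
}

cross_detector_agreement <- function(feat_by_subj, detectors) {
  if (length(feat_by_subj) < 3L) return(NULL)
  out <- list()
  for (arm in c("cr", "dlr")) {
    per_subj <- lapply(feat_by_subj, function(f) {
      res <- f[paste0(detectors, "_", arm)]
      names(res) <- detectors
      res
    })
    rep <- tryCatch(detector_agreement_report(per_subj, detectors),
                    error = function(e) NULL)
    if (!is.null(rep)) out[[arm]] <- cbind(arm = arm, rep)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) ifelse(is.finite(col), col,
                                  ifelse(is.nan(col), "nan",
                                         ifelse(is.na(col), "nan", "inf")))
      else col
    })
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(report$pairs, "pairs.csv")
  wcsv(report$summary, "summary.csv")
  if (!is.null(report$paired_tests)) wcsv(report$paired_tests, "paired_tests.csv")
  if (!is.null(report$detector_agreement))
    wcsv(report$detector_agreement, "detector_agreement.csv")
  jsonlite::write_json(report$run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d pairs, %d skipped\n",
              nrow(x$pairs), length(x$skipped)))
  cat("paired tests:\n")
  print(x$paired_tests, digits = 4)
  invisible(x)
}
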