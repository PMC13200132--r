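test_that("Wilcoxon signed-rank: conventions and the exact five-pair enumeration", {
  expect_warning(res <- wilcoxon_signed_rank(c(3, 3, 3), c(3, 3, 3)), "zero")
  expect_equal(res$p_value, 1)

  # five positive differences: one-sided tail 1/32, two-sided 0.0625
  res5 <- wilcoxon_signed_rank(rep(0, 5), 1:5)
  expect_equal(res5$p_value, 0.0625)
  expect_equal(res5$statistic, 15)
  expect_equal(res5$method, "exact")
})

test_that("Wilcoxon matches full sign-flip enumeration on random tie-free data", {
  # independent oracle: enumerate all 2^n sign assignments of |d|
  brute_wilcoxon <- function(d) {
    n <- length(d)
    rk <- rank(abs(d))
    v_obs <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% rk
    p_ge <- mean(v_all >= v_obs); p_le <- mean(v_all <= v_obs)
    min(1, 2 * min(p_ge, p_le))
  }
  set.seed(11)
  for (i in 1:5) {
    d <- round(rnorm(8), 3)
    while (any(duplicated(abs(d))) || any(d == 0)) d <- round(rnorm(8), 3)
    got <- wilcoxon_signed_rank(rep(0, 8), d)
    expect_equal(got$p_value, brute_wilcoxon(d), tolerance = 1e-12)
  }
})

test_that("paired t handles degenerate differences and matches the closed form", {
  expect_warning(res <- paired_t(c(1, 2, 3), c(2, 3, 4)), "infinite")
  expect_identical(res$t, Inf); expect_identical(res$p_value, 0)

  sym <- paired_t(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(sym$t, 0); expect_equal(sym$p_value, 1)

  set.seed(2)
  a <- rnorm(25); b <- a + rnorm(25, 0.3, 0.5)
  d <- b - a
  res2 <- paired_t(a, b)
  expect_equal(res2$t, mean(d) / (sd(d) / sqrt(25)))
  expect_equal(res2$df, 24)
})

test_that("Cohen's kappa matches closed forms and the chance-agreement limit", {
  expect_equal(cohen_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))$kappa, 1)

  # 2x2 confusion {{40,10},{10,40}}: po 0.8, pe 0.5, kappa 0.6
  r1 <- rep(c(1, 1, 2, 2), c(40, 10, 10, 40))
  r2 <- rep(c(1, 2, 1, 2), c(40, 10, 10, 40))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$p_observed, 0.8); expect_equal(k$p_expected, 0.5)
  expect_equal(k$kappa, 0.6)

  set.seed(4)
  u1 <- sample(1:5, 1e4, TRUE); u2 <- sample(1:5, 1e4, TRUE)
  expect_lt(abs(cohen_kappa(u1, u2)$kappa), 0.05)

  expect_warning(k1 <- cohen_kappa(c(2, 2, 2), c(2, 2, 2)), "undefined")
  expect_true(is.na(k1$kappa))
})

test_that("Kendall tau-b/c equal brute-force pair counting and R's tau-b", {
  expect_equal(kendall_tau(1:6, 1:6, "b"), 1)
  expect_equal(kendall_tau(1:6, 6:1, "b"), -1)
  expect_warning(expect_true(is.na(kendall_tau(c(1, 1, 1), c(1, 2, 3)))), "constant")

  brute_tau_b <- function(x, y) {
    n <- length(x); conc <- disc <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
    n0 <- n * (n - 1) / 2
    t1 <- sum(choose(table(x), 2)); t2 <- sum(choose(table(y), 2))
    (conc - disc) / sqrt((n0 - t1) * (n0 - t2))
  }
  set.seed(6)
  for (i in 1:10) {
    x <- sample(1:4, 8, TRUE); y <- sample(1:4, 8, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y, "b"), brute_tau_b(x, y))
    expect_equal(kendall_tau(x, y, "b"), cor(x, y, method = "kendall"))
  }

  # tau-c rectangular correction on a small tied table
  x <- c(1, 1, 2, 2, 3, 3); y <- c(1, 2, 1, 3, 2, 3)
  m <- 3; n <- 6
  conc <- 0; disc <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  expect_equal(kendall_tau(x, y, "c"), 2 * m * (conc - disc) / (n^2 * (m - 1)))
})

test_that("within-participant CV matches hand values and aggregates identically", {
  expect_equal(within_participant_cv(rbind(c(5, 5, 5)))$summary, 0)

  res <- within_participant_cv(rbind(c(4, 6)))
  expect_equal(res$summary, sqrt(2) / 5 * 100, tolerance = 1e-9)

  rows <- matrix(rep(c(4, 6), each = 10), 10, 2)
  expect_equal(within_participant_cv(rows)$summary, sqrt(2) / 5 * 100,
               tolerance = 1e-9)

  expect_warning(bad <- within_participant_cv(rbind(c(-2, 2), c(4, 6))), "excluded")
  expect_equal(bad$n_used, 1)
})

test_that("two-way mixed ICC matches an independent ANOVA oracle", {
  aov_icc <- function(m) {
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                     rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
    ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    n <- nrow(m); k <- ncol(m)
    c((msr - mse) / (msr + (k - 1) * mse),
      (msr - mse) / msr,
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
      (msr - mse) / (msr + (msc - mse) / n))
  }
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rnorm(30, mean = 3), 10, 3)
    got <- icc_two_way_mixed(m)
    want <- aov_icc(m)
    expect_equal(c(got$icc_single_consistency, got$icc_avg_consistency,
                   got$icc_single_agreement, got$icc_avg_agreement),
                 want, tolerance = 1e-8)
  }
})

test_that("ICC distinguishes consistency from absolute agreement", {
  set.seed(10)
  base <- rnorm(12, 5)
  ident <- cbind(base, base, base)
  r1 <- icc_two_way_mixed(ident)
  expect_equal(unname(c(r1$icc_single_consistency, r1$icc_avg_consistency,
                        r1$icc_single_agreement, r1$icc_avg_agreement)),
               rep(1, 4), tolerance = 1e-12)

  shifted <- cbind(base, base + 2)
  r2 <- icc_two_way_mixed(shifted)
  expect_equal(r2$icc_single_consistency, 1, tolerance = 1e-12)
  expect_lt(r2$icc_single_agreement, 1)
  expect_lt(r2$icc_avg_agreement, 1)

  expect_warning(bad <- icc_two_way_mixed(matrix(2, 5, 3)), "variance")
  expect_true(is.na(bad$icc_single_consistency))
  expect_error(icc_two_way_mixed(cbind(c(1, NA, 3), c(1, 2, 3))), "complete")
})

test_that("agreement statistics are invariant to subject permutation", {
  set.seed(12)
  m <- matrix(rnorm(24, 4), 8, 3)
  perm <- sample(8)
  a <- icc_two_way_mixed(m); b <- icc_two_way_mixed(m[perm, ])
  expect_equal(a$icc_single_agreement, b$icc_single_agreement)
  x <- rnorm(8); y <- x + rnorm(8, 0.2)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(x[perm], y[perm])$p_value)
})

test_that("detector agreement report separates offsets from inconsistency", {
  mk_feat <- function(st, wd, ct) {
    structure(list(mean_steepness = st, mean_width_px = wd, mean_contrast = ct),
              class = "edge_feature_result")
  }
  # identical detectors: CV 0, ICC 1
  subj <- lapply(1:6, function(i) {
    f <- mk_feat(0.1 * i, 3 + 0.1 * i, 0.5)
    list(roberts = f, sobel = f, canny = f)
  })
  rep1 <- suppressWarnings(detector_agreement_report(subj))
  expect_equal(rep1$cv_percent, rep(0, 3))
  expect_equal(rep1$icc_single_consistency[1], 1, tolerance = 1e-12)

  # scaled copies of a varying subject effect: consistent but offset
  set.seed(13)
  base <- runif(10, 0.1, 0.4)
  subj2 <- lapply(seq_along(base), function(i)
    list(roberts = mk_feat(base[i], 3, 0.5),
         sobel = mk_feat(0.9 * base[i], 3, 0.5),
         canny = mk_feat(0.8 * base[i], 3, 0.5)))
  rep2 <- suppressWarnings(detector_agreement_report(subj2))
  st_row <- rep2[rep2$feature == "steepness", ]
  expect_gt(st_row$icc_single_consistency, 0.9)
  expect_lt(st_row$icc_single_agreement, st_row$icc_single_consistency)

  # incomplete coverage is dropped with a message
  subj3 <- c(subj, list(list(roberts = mk_feat(0.2, 3, 0.5))))
  expect_message(rep3 <- suppressWarnings(detector_agreement_report(subj3)), "dropped")
  expect_equal(rep3$n_subjects[1], 6)
})
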