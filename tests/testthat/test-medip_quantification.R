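# library scaling, CNV, calibration, beta estimation, PCA, concordance

test_that("library factors follow the counts-per-million convention", {
  cnt <- cbind(A = c(1e6, 1e6), B = c(2e6, 0), C = c(0, 0))
  expect_error(estimate_library_factors(cnt), "C")
  s <- estimate_library_factors(cnt[, 1:2])
  expect_equal(unname(s), c(2, 2))
  # equal totals give equal factors; after scaling, flat samples match
  grid <- flat_grid(5000, cpg = 4)
  tr <- make_truth(grid, baseline_beta = 0.5, cgi_beta = 0.5, seed = 1)
  cal <- make_calibrations(tr$samples$sample_id, s = c(1, 2, 1, 3),
                           dispersion = 0)
  cnt2 <- simulate_medip_counts(tr, cal, seed = 2)
  s2 <- estimate_library_factors(cnt2)
  norm_means <- colMeans(cnt2) / s2
  expect_lt(max(norm_means) / min(norm_means) - 1, 0.01)
})

test_that("CNV factors recover relative copy number from CpG-free windows", {
  # grid with CpG-free windows in every 1 Mb bin
  n <- 12000
  cpg <- rep(c(0, 3, 4, 0, 5, 2), length.out = n)
  grid <- window_grid(rep("chr1", n), (seq_len(n) - 1L) * 250,
                      seq_len(n) * 250, cpg)
  # uniform coverage: all factors 1
  cnt <- matrix(5L, n, 2, dimnames = list(NULL, c("A", "B")))
  trk <- estimate_cnv(cnt, grid)
  expect_true(all(trk$A$factor == 1))
  expect_false(any(trk$A$flagged))
  # one bin at exactly double the median CpG-free coverage
  cnt2 <- cnt
  bin2 <- grid$start >= 1e6 & grid$start < 2e6
  cnt2[bin2 & grid$cpg_count == 0, "A"] <- 10L
  trk2 <- estimate_cnv(cnt2, grid)
  expect_equal(trk2$A$factor[trk2$A$start == 1e6], 2)
  expect_equal(median(trk2$A$factor), 1)
  # error when the grid has no CpG-free windows
  g2 <- flat_grid(100, cpg = 3)
  expect_error(estimate_cnv(matrix(1L, 100, 1,
                                   dimnames = list(NULL, "A")), g2),
               "no CpG-free windows")
})

test_that("a simulated 1.5x copy gain is recovered within 0.1", {
  n <- 12000
  grid <- generate_window_grid(c(chr1 = n * 250), 250,
                               list(background_mean = 3), seed = 3)
  tr <- make_truth(grid, baseline_beta = 0.7, cgi_beta = 0.7, seed = 4)
  cn <- rep(1, n)
  gain <- grid$start >= 1e6 & grid$start < 2e6
  cn[gain] <- 1.5
  cal <- make_calibrations(tr$samples$sample_id, dispersion = 0.05,
                           cnv_factors = cn)
  cnt <- simulate_medip_counts(tr, cal, depth = 30, seed = 5)
  trk <- estimate_cnv(cnt, grid)
  est <- trk$X1$factor[trk$X1$start == 1e6]
  expect_lt(abs(est - 1.5), 0.1)
})

test_that("calibration selects windows by reference mean and variance", {
  n <- 4000
  grid <- generate_window_grid(c(chr1 = n * 250), 250,
                               list(background_mean = 3), seed = 6)
  tr <- make_truth(grid, baseline_beta = 0.95, cgi_beta = 0.95, seed = 7)
  cal_true <- make_calibrations(tr$samples$sample_id, s = 1, o = 2,
                                f_max = 30, k = 10, dispersion = 0.05)
  mu <- medip_expected_counts(tr$beta, grid, cal_true)
  ref <- data.frame(mean = rowMeans(tr$beta), var = 0.01)
  # mean 0.95 var 0.01 windows are eligible; inflating the variance of all
  # windows beyond the cutoff removes them and triggers the count error
  ref_bad <- ref
  ref_bad$var <- 0.06
  expect_error(calibrate_enrichment(mu, ref_bad, grid),
               "too few calibration windows")
  ref_low <- ref
  ref_low$mean <- 0.5
  expect_error(calibrate_enrichment(mu, ref_low, grid),
               "too few calibration windows")
  # single CpG-count bin: profile underdetermined
  g1 <- flat_grid(400, cpg = c(0, 4))
  ref1 <- data.frame(mean = 0.95, var = 0.01)[rep(1, 400), ]
  cnt1 <- matrix(10, 400, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(calibrate_enrichment(cnt1, ref1, g1), "underdetermined")
})

test_that("noiseless calibration recovers the generating profile within 2%", {
  n <- 6000
  grid <- generate_window_grid(c(chr1 = n * 250), 250,
                               list(background_mean = 3), seed = 8)
  tr <- make_truth(grid, baseline_beta = 0.95, cgi_beta = 0.95, seed = 9)
  cal_true <- make_calibrations(tr$samples$sample_id, s = 1, o = 2,
                                f_max = 30, k = 10, dispersion = 0.05)
  mu <- medip_expected_counts(tr$beta, grid, cal_true)
  ref <- data.frame(mean = rowMeans(tr$beta), var = 0.001)
  cal_fit <- calibrate_enrichment(mu, ref, grid)
  prof <- cal_fit$N1$profile
  truef <- profile_eval(cal_true$N1$profile, prof$cpg)
  # the fitted calibration lives on the CPM scale (s = totals / 1e6), so
  # rescale by the fitted library factor before comparing to the generator
  shat <- cal_fit$N1$s
  expect_lt(max(abs(prof$f * shat - truef) / truef), 0.02)
  expect_lt(abs(cal_fit$N1$o * shat - 2), 0.02)
  # fitted profile is monotone non-decreasing
  expect_true(all(diff(prof$f) >= -1e-9))
})

test_that("methylation estimation inverts the mean model", {
  g <- flat_grid(3, cpg = c(5, 5, 0))
  cal <- list(A = structure(list(sample_id = "A", s = 1, o = 2,
                                 dispersion = 0.05,
                                 profile = list(type = "knots", cpg = 5,
                                                f = 20),
                                 cnv_factors = NULL),
              class = "sample_calibration"))
  cnt <- matrix(c(12, 1, 7), 3, 1, dimnames = list(NULL, "A"))
  b <- estimate_methylation(cnt, cal, g)
  expect_equal(as.numeric(b[1, "A"]), 0.5)          # (12 - 2) / 20
  expect_equal(as.numeric(b[2, "A"]), 0)            # below background, clamped
  expect_true(is.na(b[3, "A"]))         # CpG-free window
  # zero profile with CpGs present: NA with warning
  cal0 <- cal
  cal0$A$profile$f <- 0
  expect_warning(b0 <- estimate_methylation(cnt, cal0, g), "zero")
  expect_true(all(is.na(b0[1:2, ])))
})

test_that("beta estimates are monotone in raw count and CNV-neutral", {
  g <- flat_grid(60, cpg = 6)
  cal <- make_calibrations("A", s = 1, o = 2, dispersion = 0.05)
  cnt <- matrix(seq(0, 118, by = 2), 60, 1, dimnames = list(NULL, "A"))
  b <- estimate_methylation(cnt, cal, g)
  expect_true(all(diff(b[, 1]) >= 0))
  # doubling one sample's counts is absorbed by the library factor
  n <- 4000
  grid <- generate_window_grid(c(chr1 = n * 250), 250,
                               list(background_mean = 3), seed = 10)
  tr <- make_truth(grid, baseline_beta = 0.9, baseline_sd = 0.05,
                   cgi_beta = 0.1, seed = 11)
  cal4 <- make_calibrations(tr$samples$sample_id, dispersion = 0.05)
  cnt4 <- simulate_medip_counts(tr, cal4, depth = 30, seed = 12)
  ref <- data.frame(mean = rowMeans(tr$beta), var = 0.001)
  fit1 <- calibrate_enrichment(cnt4, ref, grid)
  b1 <- estimate_methylation(cnt4, fit1, grid)
  cnt5 <- cnt4
  cnt5[, "X1"] <- 2L * cnt5[, "X1"]
  fit2 <- calibrate_enrichment(cnt5, ref, grid)
  b2 <- estimate_methylation(cnt5, fit2, grid)
  expect_equal(b1[, "X1"], b2[, "X1"], tolerance = 1e-10)
})

test_that("promoter PCA matches a direct eigen-decomposition", {
  set.seed(13)
  meth <- matrix(runif(20 * 5), 20, 5,
                 dimnames = list(NULL, paste0("S", 1:5)))
  res <- pca_promoter_methylation(meth, rep(TRUE, 20), n_top = 20)
  x <- scale(t(meth), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(x))
  pc1 <- x %*% eig$vectors[, 1]
  # equality up to sign
  expect_lt(min(max(abs(res$coords[, 1] - pc1)),
                max(abs(res$coords[, 1] + pc1))), 1e-8)
  expect_true(all(res$var_explained >= 0))
  expect_lte(sum(res$var_explained), 1 + 1e-12)
  # identical samples land on identical coordinates
  meth2 <- cbind(meth[, c(1, 1)], meth[, 2:4])
  colnames(meth2) <- paste0("S", 1:5)
  res2 <- pca_promoter_methylation(meth2, rep(TRUE, 20), n_top = 20)
  expect_equal(res2$coords[1, ], res2$coords[2, ], tolerance = 1e-10)
  expect_error(pca_promoter_methylation(meth[1:2, ] * NA, rep(TRUE, 2)),
               "fewer than 2")
})

test_that("bisulfite concordance averages covered CpGs within windows", {
  g <- flat_grid(4, cpg = 5)
  cpgs <- data.frame(chrom = "chr1", pos = c(10, 100, 300, 600, 900),
                     meth = c(0.8, 0.6, 0.5, 0.4, 0.9),
                     coverage = c(25, 30, 19, 40, 21))
  meth <- matrix(c(0.7, 0.45, 0.42, 0.88), 4, 1,
                 dimnames = list(NULL, "S1"))
  res <- summarize_bs_concordance(cpgs, g, meth)
  wm <- res$window_means
  expect_equal(wm$bs_mean[wm$window == 1], 0.7)       # mean of 0.8, 0.6
  expect_false(2 %in% wm$window)                      # coverage 19 excluded
  expect_equal(nrow(wm), 3L)
  expect_equal(res$spearman, 1)
  expect_error(summarize_bs_concordance(cpgs, g, meth * NA), "jointly")
})

test_that("concordance is high when both assays see the same methylome", {
  n <- 3000
  grid <- generate_window_grid(c(chr1 = n * 250), 250,
                               list(background_mean = 3, cgi_rate = 0.01),
                               seed = 14)
  tr <- make_truth(grid, baseline_beta = 0.6, baseline_sd = 0.15,
                   noise_sd = 0.02, seed = 15)
  cal <- make_calibrations(tr$samples$sample_id, dispersion = 0.001)
  cnt <- simulate_medip_counts(tr, cal, depth = 400, seed = 16)
  b <- estimate_methylation(cnt, attr(cnt, "calibrations"), grid)
  set.seed(17)
  keep <- grid$cpg_count > 0
  cpgs <- data.frame(chrom = "chr1", pos = grid$start[keep] + 10L,
                     meth = clamp(tr$beta[keep, "X1"] +
                                    rnorm(sum(keep), 0, 0.02)),
                     coverage = 30L)
  res <- summarize_bs_concordance(cpgs, grid, b, sample_id = "X1")
  expect_gte(res$spearman, 0.9)
})
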