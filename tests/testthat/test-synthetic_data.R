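# synthetic data generators: grids, methylomes, phenotypes, counts,
# expression, validation cohorts

test_that("window grid tiling covers chromosomes and truncates remainders", {
  g <- generate_window_grid(c(chr1 = 2500), 250, seed = 1)
  expect_equal(nrow(g), 10L)
  expect_equal(g$start[1], 0L)
  expect_equal(g$end[10], 2500L)
  # trailing 100 bp dropped
  g2 <- generate_window_grid(c(chr1 = 2600), 250, seed = 1)
  expect_equal(nrow(g2), 10L)
  expect_equal(max(g2$end), 2500L)
  expect_error(generate_window_grid(c(chr1 = -5), 250),
               "invalid genome specification")
  expect_error(generate_window_grid(c(chr1 = 1e4), 10), "window_size")
  # invariants: sorted, disjoint, fixed width
  g3 <- generate_window_grid(c(b = 5000, a = 2500), 250, seed = 2)
  expect_silent(validate_window_grid(g3))
})

test_that("CpG model: zero CGI rate gives background-only counts", {
  mu <- 2
  g <- generate_window_grid(c(chr1 = 10000 * 250), 250,
                            list(background_mean = mu, cgi_rate = 0),
                            seed = 3)
  expect_false(any(g$is_cgi))
  se <- sqrt(mu / nrow(g))
  expect_lt(abs(mean(g$cpg_count) - mu), 3 * se)
  # islands appear at designated loci
  g4 <- generate_window_grid(c(chr1 = 1e5), 250,
                             list(background_mean = 2, cgi_mean = 16,
                                  cgi_len = 4,
                                  cgi_loci = data.frame(chrom = "chr1",
                                                        pos = 50000)),
                             seed = 3)
  expect_true(any(g4$is_cgi))
  expect_gt(mean(g4$cpg_count[g4$is_cgi]), mean(g4$cpg_count[!g4$is_cgi]))
})

test_that("methylome generator plants effects exactly (noiseless)", {
  grid <- flat_grid(12000)  # 3 Mb
  lhb <- data.frame(chrom = "chr1", start = 5e5, end = 25e5, delta = -0.25)
  tr <- make_truth(grid, lhb = lhb, seed = 4)
  ww <- tr$lhb_windows
  d <- mean(tr$beta[ww, c("X1", "X2")]) - mean(tr$beta[ww, c("N1", "N2")])
  expect_equal(d, -0.25, tolerance = 1e-12)
  # zero effects, zero noise: PDX identical to normal
  tr0 <- make_truth(grid, seed = 4)
  expect_identical(tr0$beta[, "X1"], unname(tr0$beta[, "N1"]))
  # bounds and bookkeeping
  expect_true(all(tr$beta >= 0 & tr$beta <= 1))
  expect_equal(sort(tr$lhb_windows),
               which(grid$start >= 5e5 & grid$end <= 25e5))
  expect_error(make_truth(grid,
                          lhb = data.frame(chrom = "chr1", start = 0,
                                           end = 4e6, delta = -0.3)),
               "exceeds chromosome bounds")
  expect_error(make_truth(grid,
                          lhb = data.frame(chrom = "chr1", start = 0,
                                           end = 5e5, delta = -0.3)),
               "at least 1 Mb")
})

test_that("response coupling follows clamp(b0 + slope * log T/C)", {
  grid <- flat_grid(10)
  tc <- stats::setNames(exp(0:4), paste0("X", 1:5))
  tr <- make_truth(grid, n_pdx = 5, seed = 5,
                   rdmr = list(windows = 3L, b0 = 0.3, slope = 0.05),
                   t_over_c = tc)
  b <- tr$beta[3L, paste0("X", 1:5)]
  expect_equal(unname(b), 0.3 + 0.05 * (0:4), tolerance = 1e-12)
  expect_equal(diff(range(b)), 0.2, tolerance = 1e-12)
})

test_that("generators are deterministic given (parameters, seed)", {
  g1 <- generate_window_grid(c(chr1 = 1e5), 250,
                             list(background_mean = 2, cgi_rate = 0.01),
                             seed = 7)
  g2 <- generate_window_grid(c(chr1 = 1e5), 250,
                             list(background_mean = 2, cgi_rate = 0.01),
                             seed = 7)
  expect_identical(g1, g2)
  tr1 <- make_truth(g1, noise_sd = 0.05, seed = 8)
  tr2 <- make_truth(g1, noise_sd = 0.05, seed = 8)
  expect_identical(tr1$beta, tr2$beta)
  tr3 <- make_truth(g1, noise_sd = 0.05, seed = 9)
  expect_false(identical(tr1$beta, tr3$beta))
})

test_that("tumor volume formula and response classification", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_error(tumor_volume(-1, 5), "positive")
  # T/C definition: treated 50 over control 500 is 10%
  expect_equal(100 * 50 / 500, 10)
  expect_equal(as.character(classify_response(5)), "strong")
  expect_equal(as.character(classify_response(20)), "intermediate")
  expect_equal(as.character(classify_response(100)), "non_responder")
  # half-open category boundaries
  expect_equal(as.character(classify_response(c(9, 30, 78))),
               c("intermediate", "weak", "non_responder"))
  expect_error(classify_response(0), "positive")
})

test_that("phenotype simulation is consistent with the volume formula", {
  ph <- generate_phenotypes(8, seed = 10)
  growth <- attr(ph, "growth")
  expect_equal(growth$volume,
               tumor_volume(growth$length, growth$width), tolerance = 1e-12)
  pdx <- ph[ph$tissue == "pdx", ]
  expect_true(all(pdx$relative_tumor_volume > 0))
  expect_equal(pdx$response_category,
               as.character(classify_response(pdx$relative_tumor_volume)))
  # every PDX paired with a normal sample of the same patient
  expect_setequal(pdx$patient_id, ph$patient_id[ph$tissue == "normal"])
  # forcing all T/C above 78 labels everyone non-responder
  ph2 <- generate_phenotypes(6, list(log_tc_mean = log(120), log_tc_sd = 0.1,
                                     tc_range = c(80, 150)), seed = 11)
  expect_true(all(ph2$response_category[ph2$tissue == "pdx"] ==
                    "non_responder"))
})

test_that("count forward model has the stated moments", {
  n <- 10000
  grid <- flat_grid(n, cpg = 4)
  tr <- make_truth(grid, baseline_beta = 0, cgi_beta = 0, seed = 12)
  cal <- make_calibrations(tr$samples$sample_id, s = 1, o = 2,
                           dispersion = 0.05)
  cnt <- simulate_medip_counts(tr, cal, seed = 13)
  # beta = 0, s = 1, c = 1: mean count per window ~ o
  se <- sqrt((2 + 0.05 * 4) / n)
  expect_lt(abs(mean(cnt[, "N1"]) - 2), 3 * se)
  # doubling s doubles the expected count
  cal2 <- make_calibrations(tr$samples$sample_id, s = 2, o = 2,
                            dispersion = 0.05)
  cnt2 <- simulate_medip_counts(tr, cal2, seed = 13)
  expect_equal(mean(cnt2) / mean(cnt), 2, tolerance = 0.03)
  # Poisson mode: variance/mean ratio ~ 1 (constant mu across windows)
  tr5 <- make_truth(grid, baseline_beta = 0.5, cgi_beta = 0.5, seed = 12)
  cal0 <- make_calibrations(tr5$samples$sample_id, s = 1, o = 2,
                            dispersion = 0)
  cnt0 <- simulate_medip_counts(tr5, cal0, seed = 14)
  expect_equal(var(cnt0[, "N1"]) / mean(cnt0[, "N1"]), 1, tolerance = 0.05)
  # counts are integral and non-negative, reproducible
  expect_true(all(cnt >= 0))
  expect_identical(cnt, simulate_medip_counts(tr, cal, seed = 13))
})

test_that("expression generator couples genes to promoter methylation", {
  grid <- flat_grid(4, cpg = 12, is_cgi = TRUE)
  tc <- stats::setNames(c(1, 100), c("X1", "X2"))
  tr <- make_truth(grid, seed = 15,
                   rdmr = list(windows = 2L, b0 = 0.2, slope = 0.5 / log(100)),
                   t_over_c = tc)
  gm <- data.frame(gene = "G1", window = 2L, coupled = TRUE)
  # promoter beta 0.2 vs 0.7, coupling -2: expected drop of 1.0 log2 units
  ex <- generate_expression(tr, gm, coupling = -2, noise_sd = 0, seed = 16)
  expect_equal(ex["G1", "X2"] - ex["G1", "X1"], -1, tolerance = 1e-10)
  # zero coupling, zero noise: constant per gene
  gm0 <- data.frame(gene = "G1", window = 2L, coupled = FALSE)
  ex0 <- generate_expression(tr, gm0, coupling = 0, noise_sd = 0, seed = 16)
  expect_equal(var(as.numeric(ex0["G1", ])), 0)
  expect_error(generate_expression(tr, data.frame(gene = "G1", window = 99L,
                                                  coupled = TRUE)),
               "unmapped gene")
})

test_that("coupled expression is anti-correlated with methylation", {
  grid <- window_grid("chr1", 0, 250, 10, is_cgi = TRUE)
  ids <- paste0("X", 1:18)
  neg <- 0
  for (r in 1:100) {
    set.seed(2000 + r)
    tc <- stats::setNames(exp(stats::runif(18, 0, 5)), ids)
    tr <- generate_methylomes(grid, list(
      normal_ids = c("N1", "N2"), pdx_ids = ids, baseline_sd = 0,
      noise_sd = 0, rdmr = list(windows = 1L, b0 = 0.2, slope = 0.1),
      t_over_c = tc), seed = r)
    ex <- generate_expression(tr, data.frame(gene = "G1", window = 1L,
                                             coupled = TRUE),
                              coupling = -2, noise_sd = 0.1, seed = r)
    neg <- neg + (stats::cor(ex["G1", ids], tr$beta[1L, ids],
                             method = "spearman") < 0)
  }
  expect_gte(neg, 95)
})

test_that("validation cohort has the declared structure", {
  co <- generate_validation_cohort(10, group_means = c(7.4, 13.9),
                                   group_sd = 0, seed = 17)
  expect_equal(nrow(co), 20L)
  expect_true(all(co$qmsp_pct >= 0 & co$qmsp_pct <= 100))
  expect_true(all(co$os_time > 0))
  # each matched pair holds exactly one responder
  expect_true(all(tapply(co$responder, co$matched_pair_id, sum) == 1L))
  # sd 0 separates the groups perfectly: any threshold in (7.4, 13.9) works
  expect_true(all(co$qmsp_pct[!co$responder] > co$qmsp_pct[co$responder]))
  cls <- select_threshold(co$qmsp_pct, !co$responder)
  expect_equal(cls$sensitivity, 1)
  expect_equal(cls$specificity, 1)
  # raw signal inverts through control normalization
  expect_equal(normalize_qmsp(co$qmsp_raw, co$control_level), co$qmsp_pct)
  expect_error(generate_validation_cohort(2), "n_pairs")
  # no censoring when censor_rate = 0
  co0 <- generate_validation_cohort(5, censor_rate = 0, seed = 18)
  expect_true(all(co0$os_event))
})

test_that("null survival simulation gives a calibrated log-rank statistic", {
  chis <- vapply(1:40, function(r) {
    co <- generate_validation_cohort(30, hazard_ratio = 1, censor_rate = 0,
                                     seed = 3000 + r)
    logrank(co$os_time[co$responder], co$os_event[co$responder],
            co$os_time[!co$responder], co$os_event[!co$responder])$chi_square
  }, numeric(1))
  # chi-square(1) mean is 1; gross inflation would push this far above
  expect_lt(mean(chis), 2)
})
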