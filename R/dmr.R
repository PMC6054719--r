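# Window-wise negative-binomial GLM likelihood-ratio machinery.
#
# The mean model is linear in beta for every window:
#   mu_i(beta) = s_i * c_i * (o_i + beta * f_i(cpg))  =  k1_i + beta * k2_i
# so per-window likelihood maximization reduces to a bounded 1-D (group
# model) or clamped 2-D (quantitative model) search.

# per-sample constant parts of the mean model, for all windows at once
dmr_mean_parts <- function(grid, calibrations, sample_ids) {
  n_w <- nrow(grid)
  k1 <- k2 <- matrix(0, n_w, length(sample_ids),
                     dimnames = list(NULL, sample_ids))
  for (id in sample_ids) {
    cal <- calibrations[[id]]
    f <- profile_eval(cal$profile, grid$cpg_count)
    cw <- cal$cnv_factors %||% 1
    k1[, id] <- cal$s * cw * cal$o
    k2[, id] <- cal$s * cw * f
  }
  list(k1 = k1, k2 = k2)
}

# log-likelihood of counts y at mean mu (NB with var = mu + phi mu^2;
# Poisson at phi = 0); mu floored to keep the likelihood finite
nb_ll <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi <= 0) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
}

# maximize sum nb_ll over beta in [0, 1] for one window / sample subset:
# vectorized coarse grid, then stats::optimize in the bracketing interval
max_ll_beta <- function(y, k1, k2, phi, grid_n = 26L) {
  betas <- seq(0, 1, length.out = grid_n)
  mu <- pmax(outer(k1, rep(1, grid_n)) + outer(k2, betas), 1e-10)
  ll <- if (phi <= 0) colSums(stats::dpois(y, mu, log = TRUE))
        else colSums(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
  i <- which.max(ll)
  lo <- betas[max(i - 1L, 1L)]; hi <- betas[min(i + 1L, grid_n)]
  opt <- stats::optimize(function(b) nb_ll(y, k1 + b * k2, phi),
                         c(lo, hi), maximum = TRUE, tol = 1e-7)
  if (opt$objective >= ll[i]) c(opt$maximum, opt$objective)
  else c(betas[i], ll[i])
}

#' Group differential methylation test (NB-GLM likelihood ratio)
#'
#' Per CpG-containing window, the null model fits a single shared
#' methylation level beta maximizing the NB likelihood of all samples under
#' the calibrated mean model; the alternative fits one beta per group. The
#' likelihood-ratio statistic is referred to a chi-square with 1 df and
#' Benjamini-Hochberg FDR is computed across all tested windows.
#'
#' `delta_beta` is `beta(second level) - beta(first level)` of `groups`;
#' with levels `(normal, pdx)` positive values are PDX hypermethylation.
#'
#' @param counts windows x samples integer count matrix.
#' @param grid the [window_grid].
#' @param calibrations named list of `sample_calibration`; the dataset
#'   dispersion is the median of the per-sample `dispersion` fields.
#' @param groups two-level factor along `colnames(counts)` (>= 2 samples per
#'   level).
#' @return data.frame with one row per tested window: `window`, `chrom`,
#'   `start`, `end`, `delta_beta`, `log2fc`, `lrt_stat`, `p_value`, `fdr`,
#'   `direction`; attribute `"skipped"` records untested windows and the
#'   reason (`no_cpg` or `all_zero`).
#' @export
test_group_dmr <- function(counts, grid, calibrations, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L))
    stop("each group must contain at least 2 samples")
  ids <- colnames(counts)
  parts <- dmr_mean_parts(grid, calibrations, ids)
  phi <- stats::median(vapply(calibrations[ids], `[[`, numeric(1), "dispersion"))
  ia <- which(groups == levels(groups)[1L])
  ib <- which(groups == levels(groups)[2L])

  no_cpg <- grid$cpg_count == 0
  all_zero <- rowSums(counts) == 0
  test_idx <- which(!no_cpg & !all_zero)
  skipped <- data.frame(
    window = which(no_cpg | all_zero),
    reason = ifelse(no_cpg[no_cpg | all_zero], "no_cpg", "all_zero"))

  res <- matrix(NA_real_, length(test_idx), 4,
                dimnames = list(NULL, c("ba", "bb", "b0", "lrt")))
  for (r in seq_along(test_idx)) {
    w <- test_idx[r]
    y <- counts[w, ]; k1 <- parts$k1[w, ]; k2 <- parts$k2[w, ]
    h0 <- max_ll_beta(y, k1, k2, phi)
    ha <- max_ll_beta(y[ia], k1[ia], k2[ia], phi)
    hb <- max_ll_beta(y[ib], k1[ib], k2[ib], phi)
    lrt <- max(2 * (ha[2] + hb[2] - h0[2]), 0)
    res[r, ] <- c(ha[1], hb[1], h0[1], lrt)
  }
  p <- stats::pchisq(res[, "lrt"], df = 1, lower.tail = FALSE)
  delta <- res[, "bb"] - res[, "ba"]
  # enrichment-rate log fold change at the window's mean profile value
  fmat <- vapply(ids, function(id)
    profile_eval(calibrations[[id]]$profile, grid$cpg_count[test_idx]),
    numeric(length(test_idx)))
  fbar <- rowMeans(matrix(fmat, nrow = length(test_idx)))
  obar <- mean(vapply(calibrations[ids], `[[`, numeric(1), "o"))
  log2fc <- log2(pmax(obar + res[, "bb"] * fbar, 1e-10) /
                   pmax(obar + res[, "ba"] * fbar, 1e-10))
  out <- data.frame(
    window = test_idx, chrom = grid$chrom[test_idx],
    start = grid$start[test_idx], end = grid$end[test_idx],
    delta_beta = delta, log2fc = log2fc, lrt_stat = res[, "lrt"],
    p_value = p, fdr = adjust_fdr(p),
    direction = ifelse(delta >= 0, "hyper", "hypo"),
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

# clamped-linear quantitative model log-likelihood over a (b0, b1) grid,
# vectorized; returns list(ll matrix, grids)
rdmr_grid_ll <- function(y, k1, k2, phi, x, b0s, b1s) {
  n <- length(y)
  combos <- expand.grid(b0 = b0s, b1 = b1s)
  beta <- clamp(outer(rep(1, n), combos$b0) + outer(x, combos$b1))
  mu <- pmax(k1 + beta * k2, 1e-10)
  ll <- if (phi <= 0) colSums(matrix(stats::dpois(y, mu, log = TRUE), n))
        else colSums(matrix(stats::dnbinom(y, mu = mu, size = 1 / phi,
                                           log = TRUE), n))
  list(ll = ll, combos = combos)
}

#' Quantitative response-DMR test (methylation vs log relative tumor volume)
#'
#' Alternative model: `beta_i = clamp(b0 + b1 * x_i, 0, 1)` with
#' `x = log(T/C percent)` (T/C floored at 0.1% to avoid -Inf); null model:
#' `b1 = 0` (shared beta). The LRT is referred to chi-square with 1 df.
#' `delta_beta` carries the fitted slope `b1` (methylation change per
#' natural-log unit of relative tumor volume); `direction` is `hyper` when
#' methylation rises with tumor volume, i.e. with resistance.
#'
#' @param counts windows x samples count matrix (>= 4 samples).
#' @param grid the [window_grid].
#' @param calibrations named list of `sample_calibration`.
#' @param t_over_c named vector of relative tumor volume in percent, one per
#'   column of `counts`; must not be constant.
#' @param tc_floor floor for T/C before taking logs (percent).
#' @return data.frame as in [test_group_dmr] with `delta_beta` = b1 and an
#'   extra column `b0`; attribute `"skipped"` as there. Attribute
#'   `"predictor"` records the transformed predictor used.
#' @export
test_quantitative_rdmr <- function(counts, grid, calibrations, t_over_c,
                                   tc_floor = 0.1) {
  ids <- colnames(counts)
  x <- log(pmax(t_over_c[ids], tc_floor))
  if (sum(is.finite(x)) < 4L) stop("need >= 4 samples with finite predictor")
  if (stats::var(x) == 0) stop("predictor is constant")
  parts <- dmr_mean_parts(grid, calibrations, ids)
  phi <- stats::median(vapply(calibrations[ids], `[[`, numeric(1), "dispersion"))

  no_cpg <- grid$cpg_count == 0
  all_zero <- rowSums(counts) == 0
  test_idx <- which(!no_cpg & !all_zero)
  skipped <- data.frame(
    window = which(no_cpg | all_zero),
    reason = ifelse(no_cpg[no_cpg | all_zero], "no_cpg", "all_zero"))

  b1max <- 2 / diff(range(x))
  b0s <- seq(0, 1, length.out = 9L)
  b1s <- seq(-b1max, b1max, length.out = 9L)
  res <- matrix(NA_real_, length(test_idx), 3,
                dimnames = list(NULL, c("b0", "b1", "lrt")))
  for (r in seq_along(test_idx)) {
    w <- test_idx[r]
    y <- counts[w, ]; k1 <- parts$k1[w, ]; k2 <- parts$k2[w, ]
    h0 <- max_ll_beta(y, k1, k2, phi)
    g <- rdmr_grid_ll(y, k1, k2, phi, x, b0s, b1s)
    i <- which.max(g$ll)
    fn <- function(p) nb_ll(y, k1 + clamp(p[1] + p[2] * x) * k2, phi)
    opt <- stats::optim(c(g$combos$b0[i], g$combos$b1[i]), fn,
                        method = "Nelder-Mead",
                        control = list(fnscale = -1, reltol = 1e-8,
                                       maxit = 150))
    ll1 <- max(opt$value, g$ll[i], h0[2])
    par <- if (opt$value >= g$ll[i]) opt$par
           else c(g$combos$b0[i], g$combos$b1[i])
    if (ll1 == h0[2] && opt$value < h0[2] && g$ll[i] < h0[2])
      par <- c(h0[1], 0)
    res[r, ] <- c(par[1], par[2], max(2 * (ll1 - h0[2]), 0))
  }
  p <- stats::pchisq(res[, "lrt"], df = 1, lower.tail = FALSE)
  out <- data.frame(
    window = test_idx, chrom = grid$chrom[test_idx],
    start = grid$start[test_idx], end = grid$end[test_idx],
    delta_beta = res[, "b1"], b0 = res[, "b0"], log2fc = NA_real_,
    lrt_stat = res[, "lrt"], p_value = p, fdr = adjust_fdr(p),
    direction = ifelse(res[, "b1"] >= 0, "hyper", "hypo"),
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "predictor") <-
    list(x = x, transform = "natural log of T/C percent", floor = tc_floor)
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' @param p_values vector of p-values in \[0, 1\]; `NA`/`NaN` are rejected.
#' @return BH step-up adjusted values.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Filter DMR records by FDR and effect size
#'
#' @param records data.frame with `fdr` and `delta_beta`.
#' @param fdr_max keep `fdr < fdr_max` (default 1e-4).
#' @param min_abs_delta keep `|delta_beta| > min_abs_delta` (default 0.20).
#' @return the kept subset, with attribute `"n_by_direction"`.
#' @export
filter_dmrs <- function(records, fdr_max = 1e-4, min_abs_delta = 0.20) {
  keep <- records$fdr < fdr_max & abs(records$delta_beta) > min_abs_delta
  out <- records[keep, , drop = FALSE]
  attr(out, "n_by_direction") <-
    c(hyper = sum(out$direction == "hyper"),
      hypo = sum(out$direction == "hypo"))
  out
}

#' Call large hypomethylated blocks (LHBs)
#'
#' Aggregates window-level methylation into tiles (default 100 kb), computes
#' per tile the difference `mean(second-group betas) - mean(first-group
#' betas)`, merges maximal runs of consecutive tiles whose difference is at
#' most `-min_drop`, and reports merged runs spanning at least `min_size`.
#' The mean difference of each block is recomputed over its constituent
#' windows. With `groups` levels `(normal, pdx)` this is the canonical
#' ">= 1 Mb with >= 20% reduced methylation in tumor" definition.
#'
#' @param meth windows x samples beta matrix.
#' @param grid the [window_grid].
#' @param groups two-level factor along `colnames(meth)`.
#' @param tile_size aggregation tile in bp (default 1e5).
#' @param min_size minimum block span in bp (default 1e6).
#' @param min_drop minimum mean methylation reduction (default 0.20).
#' @return data.frame `chrom`, `start`, `end`, `mean_delta`, `n_windows`
#'   (possibly empty).
#' @export
call_lhbs <- function(meth, grid, groups, tile_size = 1e5, min_size = 1e6,
                      min_drop = 0.20) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  ia <- groups == levels(groups)[1L]
  ib <- groups == levels(groups)[2L]
  tile_idx <- floor(grid$start / tile_size)
  key <- paste0(grid$chrom, ":", tile_idx)
  defined <- rowSums(!is.na(meth)) > 0
  tiles <- unique(key[defined])
  mean_a <- vapply(tiles, function(tk)
    mean(meth[key == tk & defined, ia], na.rm = TRUE), numeric(1))
  mean_b <- vapply(tiles, function(tk)
    mean(meth[key == tk & defined, ib], na.rm = TRUE), numeric(1))
  delta <- mean_b - mean_a
  t_chrom <- sub(":[0-9]+$", "", tiles)
  t_idx <- as.integer(sub("^.*:", "", tiles))
  ord <- order(t_chrom, t_idx)
  t_chrom <- t_chrom[ord]; t_idx <- t_idx[ord]; delta <- delta[ord]

  hit <- is.finite(delta) & delta <= -min_drop
  blocks <- list()
  r <- 1L
  while (r <= length(hit)) {
    if (!hit[r]) { r <- r + 1L; next }
    q <- r
    while (q < length(hit) && hit[q + 1L] && t_chrom[q + 1L] == t_chrom[r] &&
           t_idx[q + 1L] == t_idx[q] + 1L) q <- q + 1L
    bstart <- t_idx[r] * tile_size
    bend <- (t_idx[q] + 1L) * tile_size
    chrom_end <- max(grid$end[grid$chrom == t_chrom[r]])
    bend <- min(bend, chrom_end)
    if (bend - bstart >= min_size) {
      w <- grid$chrom == t_chrom[r] & grid$start >= bstart & grid$end <= bend
      md <- mean(meth[w, ib], na.rm = TRUE) - mean(meth[w, ia], na.rm = TRUE)
      blocks[[length(blocks) + 1L]] <-
        data.frame(chrom = t_chrom[r], start = bstart, end = bend,
                   mean_delta = md, n_windows = sum(w),
                   stringsAsFactors = FALSE)
    }
    r <- q + 1L
  }
  if (!length(blocks))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mean_delta = numeric(0),
                      n_windows = integer(0)))
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Compare LHB intensity between response classes
#'
#' Descriptive only: per block, the mean methylation drop (class mean minus
#' normal mean over the block's windows) is reported for each response
#' class, plus the difference between the two classes when exactly two are
#' present.
#'
#' @param lhbs result of [call_lhbs].
#' @param meth windows x samples beta matrix.
#' @param grid the [window_grid].
#' @param normal_ids reference (normal) sample names.
#' @param response_classes named list mapping class name -> PDX sample
#'   names; empty classes are dropped with a warning.
#' @return data.frame with one row per block and one `delta_<class>` column
#'   per class (plus `difference` when two classes are given).
#' @export
compare_lhb_intensity <- function(lhbs, meth, grid, normal_ids,
                                  response_classes) {
  sizes <- vapply(response_classes, length, integer(1))
  if (any(sizes == 0L)) {
    warning("omitting empty response class(es): ",
            paste(names(response_classes)[sizes == 0L], collapse = ", "))
    response_classes <- response_classes[sizes > 0L]
  }
  out <- lhbs[, c("chrom", "start", "end"), drop = FALSE]
  for (cls in names(response_classes)) {
    ids <- response_classes[[cls]]
    out[[paste0("delta_", cls)]] <- vapply(seq_len(nrow(lhbs)), function(i) {
      w <- grid$chrom == lhbs$chrom[i] & grid$start >= lhbs$start[i] &
        grid$end <= lhbs$end[i]
      mean(meth[w, ids, drop = FALSE], na.rm = TRUE) -
        mean(meth[w, normal_ids, drop = FALSE], na.rm = TRUE)
    }, numeric(1))
  }
  if (length(response_classes) == 2L)
    out$difference <- out[[4L]] - out[[5L]]
  out
}
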