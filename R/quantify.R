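#' Library size factors
#'
#' Counts-per-million convention: `s_i` = total fragments of sample i / 1e6,
#' so that `count / s` is on the CPM scale per window.
#'
#' @param counts windows x samples integer matrix with column names.
#' @return named positive vector of factors.
#' @export
estimate_library_factors <- function(counts) {
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[tot <= 0], collapse = ", "))
  tot / 1e6
}

#' Copy-number tracks from CpG-free window coverage
#'
#' MeDIP fragments without any CpG cannot be enriched by the antibody, so
#' their coverage tracks copy number rather than methylation. Coverage of
#' CpG-free windows is averaged in large genomic bins (default 1 Mb) and
#' scaled to the sample median; bins with no CpG-free window inherit a
#' neutral factor of 1 and are flagged.
#'
#' @param counts windows x samples count matrix.
#' @param grid [window_grid] with `cpg_count` (CpG-free windows required).
#' @param bin_size bin width in bp.
#' @return named list (per sample) of data.frames `chrom`, `start`, `end`,
#'   `factor`, `flagged`.
#' @export
estimate_cnv <- function(counts, grid, bin_size = 1e6) {
  free <- grid$cpg_count == 0
  if (!any(free))
    stop("CNV cannot be estimated: no CpG-free windows in the grid")
  bin <- window_bin_id(grid, bin_size)
  bins <- unique(bin)
  bin_chrom <- sub(":[0-9]+$", "", bins)
  bin_idx <- as.integer(sub("^.*:", "", bins))
  bin_start <- as.integer(bin_idx * bin_size)
  bin_end <- vapply(seq_along(bins),
                    function(b) max(grid$end[bin == bins[b]]), integer(1))
  out <- lapply(colnames(counts), function(id) {
    cov <- vapply(bins, function(b) {
      w <- free & bin == b
      if (any(w)) mean(counts[w, id]) else NA_real_
    }, numeric(1))
    med <- stats::median(cov, na.rm = TRUE)
    if (!is.finite(med) || med <= 0)
      stop("CNV cannot be estimated for sample ", id,
           ": median CpG-free coverage is not positive")
    fac <- cov / med
    flagged <- is.na(fac)
    fac[flagged] <- 1
    data.frame(chrom = bin_chrom, start = bin_start, end = bin_end,
               factor = fac, flagged = flagged, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  names(out) <- colnames(counts)
  out
}

#' Expand a binned CNV track to per-window factors
#'
#' @param track one element of [estimate_cnv]'s result.
#' @param grid the [window_grid].
#' @param bin_size the bin width used for the track.
#' @return windows-long numeric vector of copy factors.
#' @export
cnv_window_factors <- function(track, grid, bin_size = 1e6) {
  key <- paste0(track$chrom, ":", floor(track$start / bin_size))
  fac <- track$factor[match(window_bin_id(grid, bin_size), key)]
  fac[is.na(fac)] <- 1
  fac
}

# method-of-moments NB dispersion on normalized counts y = count/s:
# var(y) = m/s + phi m^2 (m = mean of y), so phi = (v - m/s) / m^2 with
# 1/s averaged over samples; dataset median over windows with normalized
# mean >= 5, floored at 1e-6
estimate_dispersion <- function(norm_counts, s = 1, mean_min = 5,
                                floor = 1e-6) {
  inv_s <- mean(1 / s)
  m <- rowMeans(norm_counts)
  v <- apply(norm_counts, 1L, stats::var)
  keep <- is.finite(m) & m >= mean_min
  if (!any(keep)) return(floor)
  phi <- (v[keep] - m[keep] * inv_s) / m[keep]^2
  max(stats::median(phi, na.rm = TRUE), floor)
}

#' Calibrate per-sample enrichment profiles against reference methylation
#'
#' Transforms relative MeDIP enrichment into absolute methylation by fitting,
#' per sample, the mean model `E[count / (s c)] = o + beta * f(cpg)`.
#' Calibration windows are those whose reference methylation (e.g. from a
#' bisulfite-array compendium) has mean > `mean_min` and variance <
#' `var_max`; there beta is approximated by the reference mean, so the
#' normalized count determines `f` at that window's CpG count. Windows are
#' binned by CpG count (bins of width `bin_width`, merged rightwards until
#' each holds at least `min_bin_n` windows), a robust (median) profile value
#' is taken per bin, and monotonicity is enforced by pooling adjacent
#' violators (PAVA). The background rate `o` is the mean CNV-corrected
#' normalized count of CpG-free windows; the NB dispersion is a
#' method-of-moments estimate shared across the dataset.
#'
#' @param counts windows x samples count matrix.
#' @param reference_betas data.frame aligned to the grid with columns `mean`
#'   and `var` of the reference methylation per window.
#' @param grid the [window_grid].
#' @param cnv optional result of [estimate_cnv]; estimated internally when
#'   `NULL`.
#' @param mean_min,var_max calibration-window selection thresholds
#'   (defaults 0.90 and 0.05).
#' @param min_windows,min_bins minimum number of calibration windows and of
#'   distinct CpG-count bins required.
#' @param bin_width,min_bin_n CpG binning parameters for the profile fit.
#' @return named list of `sample_calibration` objects (fields `s`, `o`,
#'   `dispersion`, `profile` with fitted knots, `cnv_factors`).
#' @export
calibrate_enrichment <- function(counts, reference_betas, grid, cnv = NULL,
                                 mean_min = 0.90, var_max = 0.05,
                                 min_windows = 50, min_bins = 5,
                                 bin_width = 2, min_bin_n = 20) {
  stopifnot(nrow(reference_betas) == nrow(grid))
  eligible <- which(reference_betas$mean > mean_min &
                      reference_betas$var < var_max & grid$cpg_count > 0)
  if (length(eligible) < min_windows)
    stop("too few calibration windows: ", length(eligible),
         " eligible, need >= ", min_windows)
  cpg_cal <- grid$cpg_count[eligible]
  edges <- seq(min(cpg_cal), max(cpg_cal) + bin_width, by = bin_width)
  raw_bin <- findInterval(cpg_cal, edges)
  if (length(unique(raw_bin)) < min_bins)
    stop("enrichment profile underdetermined: calibration windows span only ",
         length(unique(raw_bin)), " CpG-count bins (need >= ", min_bins, ")")
  # merge sparse bins rightwards until every bin holds >= min_bin_n windows
  tab <- table(raw_bin)
  merged <- integer(0)
  acc <- 0L
  bin_of <- integer(max(raw_bin))
  cur <- 1L
  for (b in sort(unique(raw_bin))) {
    bin_of[b] <- cur
    acc <- acc + tab[[as.character(b)]]
    if (acc >= min_bin_n) { cur <- cur + 1L; acc <- 0L }
  }
  if (acc > 0L) bin_of[bin_of == cur] <- max(cur - 1L, 1L)  # fold remainder left
  bin_id <- bin_of[raw_bin]

  s <- estimate_library_factors(counts)
  if (is.null(cnv)) cnv <- estimate_cnv(counts, grid)
  free <- grid$cpg_count == 0

  out <- lapply(colnames(counts), function(id) {
    cw <- cnv_window_factors(cnv[[id]], grid)
    y <- counts[, id] / (s[[id]] * cw)
    o <- if (any(free)) mean(y[free]) else 0
    z <- (y[eligible] - o) / reference_betas$mean[eligible]
    knot_f <- tapply(z, bin_id, stats::median)
    # median CpG count, not the mean: for a monotone profile the median of
    # f(cpg) within a bin is attained at the median cpg, so the knot is
    # consistent even for coarse heterogeneous bins
    knot_cpg <- tapply(cpg_cal, bin_id, stats::median)
    knot_n <- tapply(z, bin_id, length)
    ord <- order(knot_cpg)
    prof <- pava_nondecreasing(as.numeric(knot_f[ord]), as.numeric(knot_n[ord]))
    structure(list(sample_id = id, s = s[[id]], o = o,
                   dispersion = NA_real_,
                   profile = list(type = "knots",
                                  cpg = as.numeric(knot_cpg[ord]),
                                  f = pmax(prof, 0)),
                   cnv_factors = cw),
              class = "sample_calibration")
  })
  names(out) <- colnames(counts)
  norm <- counts / rep(s, each = nrow(counts))
  phi <- estimate_dispersion(norm, s)
  for (id in names(out)) out[[id]]$dispersion <- phi
  out
}

# pool-adjacent-violators for a non-decreasing fit (weighted means)
pava_nondecreasing <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- y; wt <- w; idx <- as.list(seq_len(n))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L] + 1e-12) {
      nw <- wt[i] + wt[i + 1L]
      nv <- (val[i] * wt[i] + val[i + 1L] * wt[i + 1L]) / nw
      val[i] <- nv; wt[i] <- nw; idx[[i]] <- c(idx[[i]], idx[[i + 1L]])
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; idx[(i + 1L)] <- NULL
      i <- max(i - 1L, 1L)
    } else i <- i + 1L
  }
  out <- numeric(n)
  for (k in seq_along(val)) out[idx[[k]]] <- val[k]
  out
}

#' Absolute methylation estimates from calibrated counts
#'
#' Inverts the mean model per window and sample:
#' `beta = clamp((count / (s c) - o) / f(cpg), 0, 1)`.
#' Windows without CpGs carry no methylation estimate (`NA`); windows where
#' the profile evaluates to zero despite `cpg > 0` are set `NA` with a
#' warning.
#'
#' @param counts windows x samples count matrix (expected counts are also
#'   accepted, e.g. for closed-loop checks).
#' @param calibrations named list of `sample_calibration`.
#' @param grid the [window_grid].
#' @return windows x samples beta matrix in \[0, 1\] with `NA` where
#'   undefined.
#' @export
estimate_methylation <- function(counts, calibrations, grid) {
  beta <- matrix(NA_real_, nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  zero_profile <- FALSE
  for (id in colnames(counts)) {
    cal <- calibrations[[id]]
    f <- profile_eval(cal$profile, grid$cpg_count)
    cw <- cal$cnv_factors %||% 1
    y <- counts[, id] / (cal$s * cw)
    b <- clamp((y - cal$o) / f)
    bad <- grid$cpg_count > 0 & f <= 0
    if (any(bad)) { zero_profile <- TRUE; b[bad] <- NA_real_ }
    b[grid$cpg_count == 0] <- NA_real_
    beta[, id] <- b
  }
  if (zero_profile)
    warning("enrichment profile is zero for some CpG-containing windows; ",
            "their methylation is set to NA")
  beta
}

#' PCA of promoter-window methylation
#'
#' Restricts to promoter-overlapping windows with defined beta in all
#' samples, keeps the `n_top` most variable across samples, column-centres,
#' and decomposes. Mirrors the common QC view in enrichment-based methylome
#' studies (samples on the first two components).
#'
#' @param meth windows x samples beta matrix.
#' @param promoter_windows logical vector or integer indices of promoter
#'   windows.
#' @param n_top number of most-variable windows to keep (default 1000).
#' @return list with `coords` (samples x 2), `var_explained` (all component
#'   variance fractions), `windows_used` (grid row indices).
#' @export
pca_promoter_methylation <- function(meth, promoter_windows, n_top = 1000) {
  if (ncol(meth) < 2L) stop("need at least 2 samples")
  idx <- if (is.logical(promoter_windows)) which(promoter_windows)
         else as.integer(promoter_windows)
  sub <- meth[idx, , drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  idx <- idx[complete]
  sub <- sub[complete, , drop = FALSE]
  if (nrow(sub) < 2L)
    stop("fewer than 2 promoter windows with complete methylation")
  v <- apply(sub, 1L, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(sub)))]
  x <- t(sub[keep, , drop = FALSE])           # samples x windows
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  ev <- sv$d^2 / sum(sv$d^2)
  coords <- x %*% sv$v[, 1:2, drop = FALSE]
  colnames(coords) <- c("PC1", "PC2")
  list(coords = coords, var_explained = ev, windows_used = idx[keep])
}

#' Bisulfite concordance of MeDIP-derived methylation
#'
#' Averages per-CpG bisulfite methylation calls within grid windows
#' (excluding CpGs below the coverage cutoff) and reports the Spearman rank
#' correlation against MeDIP beta estimates over jointly defined windows.
#'
#' @param cpg_level data.frame `chrom`, `pos` (0-based), `meth` in \[0, 1\],
#'   `coverage`.
#' @param grid the [window_grid].
#' @param meth windows x samples beta matrix (or one column).
#' @param sample_id column of `meth` to compare (default first).
#' @param min_coverage minimum read coverage per CpG (default 20).
#' @return list with `window_means` (data.frame `window`, `bs_mean`,
#'   `medip_beta`) and `spearman`.
#' @export
summarize_bs_concordance <- function(cpg_level, grid, meth, sample_id = NULL,
                                     min_coverage = 20) {
  b <- if (is.matrix(meth)) meth[, sample_id %||% colnames(meth)[1L]] else meth
  keep <- cpg_level$coverage >= min_coverage
  cl <- cpg_level[keep, , drop = FALSE]
  win <- rep(NA_integer_, nrow(cl))
  for (ch in unique(cl$chrom)) {
    gi <- which(grid$chrom == ch)
    if (!length(gi)) next
    ci <- which(cl$chrom == ch)
    pos <- cl$pos[ci]
    j <- findInterval(pos, grid$start[gi])
    ok <- j >= 1L & pos < grid$end[gi][pmax(j, 1L)]
    win[ci[ok]] <- gi[j[ok]]
  }
  cl <- cl[!is.na(win), , drop = FALSE]
  win <- win[!is.na(win)]
  bs_mean <- tapply(cl$meth, win, mean)
  w_idx <- as.integer(names(bs_mean))
  joint <- !is.na(b[w_idx])
  if (!any(joint)) stop("no jointly defined windows between the two assays")
  df <- data.frame(window = w_idx[joint], bs_mean = as.numeric(bs_mean)[joint],
                   medip_beta = b[w_idx][joint])
  list(window_means = df,
       spearman = stats::cor(df$bs_mean, df$medip_beta, method = "spearman"))
}
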