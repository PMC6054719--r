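#' Synthetic paired normal/PDX methylomes with planted effects
#'
#' Builds the ground-truth methylation matrix (windows x samples) that the
#' rest of the pipeline is tested against. Normal samples have a high
#' baseline methylation outside CpG islands and low methylation inside them,
#' the canonical somatic pattern. PDX samples additionally carry three
#' planted tumor features:
#'
#' * large hypomethylated blocks (LHBs): contiguous regions of >= 1 Mb whose
#'   mean methylation is reduced by `delta` (<= -0.20) relative to normal;
#' * focal promoter/CGI hypermethylation: designated window sets whose PDX
#'   methylation is shifted upwards;
#' * response-coupled windows (rDMRs): PDX methylation follows
#'   `clamp(b0 + slope * log(T/C), 0, 1)`, so methylation rises with relative
#'   tumor volume (i.e. with carboplatin resistance).
#'
#' Independent Gaussian noise is added per cell and the result clamped to
#' \[0, 1\].
#'
#' @param grid a [window_grid].
#' @param design list with elements:
#'   \describe{
#'   \item{normal_ids, pdx_ids}{sample names (>= 2 each).}
#'   \item{baseline_beta, cgi_beta}{normal-tissue methylation outside/inside
#'     CGIs (defaults 0.8 / 0.1).}
#'   \item{baseline_sd}{per-window SD of the baseline, shared across samples
#'     (default 0); positive values create the near-fully-methylated windows
#'     that enrichment calibration selects on.}
#'   \item{lhb}{data.frame `chrom`, `start`, `end`, `delta` of planted blocks
#'     (delta <= -0.20, span >= 1 Mb).}
#'   \item{focal_hyper}{data.frame `window` (grid row index), `delta`.}
#'   \item{rdmr}{list `windows` (grid row indices), `b0`, `slope`.}
#'   \item{t_over_c}{named vector of relative tumor volume (T/C, percent),
#'     one entry per PDX sample.}
#'   \item{noise_sd}{per-cell Gaussian noise SD (default 0.03).}
#'   }
#' @param seed integer seed.
#' @return a list of class `methylome_truth` with elements `grid`, `beta`
#'   (windows x samples), `samples` (sample sheet), `lhb_regions`,
#'   `focal_dmrs`, `rdmr_windows`, `coupling_slope`, `rdmr_b0`, `t_over_c`.
#' @export
generate_methylomes <- function(grid, design, seed = 1L) {
  d <- utils::modifyList(list(baseline_beta = 0.8, cgi_beta = 0.1,
                              baseline_sd = 0, lhb = NULL, focal_hyper = NULL,
                              rdmr = NULL, t_over_c = NULL, noise_sd = 0.03),
                         design)
  if (length(d$normal_ids) < 2L || length(d$pdx_ids) < 2L)
    stop("design must name at least 2 normal and 2 PDX samples")
  n_w <- nrow(grid)
  samples <- c(d$normal_ids, d$pdx_ids)
  tissue <- rep(c("normal", "pdx"), c(length(d$normal_ids), length(d$pdx_ids)))

  base <- ifelse(grid$is_cgi, d$cgi_beta, d$baseline_beta)
  if (d$baseline_sd > 0) {
    # per-window baseline heterogeneity, shared across samples (so zero-noise
    # PDX and normal methylomes stay identical absent planted effects); this
    # also yields near-fully-methylated windows usable for calibration
    set.seed(derive_seed(seed, 7L))
    base <- clamp(base + stats::rnorm(n_w, 0, d$baseline_sd))
  }
  beta <- matrix(base, n_w, length(samples), dimnames = list(NULL, samples))

  lhb_windows <- integer(0)
  if (!is.null(d$lhb) && nrow(d$lhb)) {
    for (i in seq_len(nrow(d$lhb))) {
      b <- d$lhb[i, ]
      if (b$end - b$start < 1e6)
        stop("planted LHB intervals must span at least 1 Mb")
      on_chr <- grid$chrom == b$chrom
      if (!any(on_chr) || b$start < min(grid$start[on_chr]) ||
          b$end > max(grid$end[on_chr]))
        stop("planted region exceeds chromosome bounds: ",
             b$chrom, ":", b$start, "-", b$end)
      w <- which(on_chr & grid$start >= b$start & grid$end <= b$end)
      beta[w, tissue == "pdx"] <- beta[w, tissue == "pdx"] + b$delta
      lhb_windows <- union(lhb_windows, w)
    }
  }
  if (!is.null(d$focal_hyper) && nrow(d$focal_hyper)) {
    w <- d$focal_hyper$window
    if (any(w < 1L | w > n_w)) stop("focal window index out of range")
    beta[w, tissue == "pdx"] <- beta[w, tissue == "pdx"] + d$focal_hyper$delta
  }
  rdmr_windows <- integer(0)
  slope <- 0
  b0 <- NA_real_
  if (!is.null(d$rdmr) && length(d$rdmr$windows)) {
    if (is.null(d$t_over_c)) stop("rdmr coupling requires design$t_over_c")
    if (!all(d$pdx_ids %in% names(d$t_over_c)))
      stop("t_over_c must be named for every PDX sample")
    if (!is.null(d$focal_hyper) &&
        length(intersect(d$rdmr$windows, d$focal_hyper$window)))
      stop("rdmr windows must be disjoint from focal control windows")
    rdmr_windows <- as.integer(d$rdmr$windows)
    slope <- d$rdmr$slope
    b0 <- d$rdmr$b0
    x <- log(d$t_over_c[d$pdx_ids])
    beta[rdmr_windows, tissue == "pdx"] <-
      matrix(clamp(rep(b0, each = length(rdmr_windows)) +
                     slope * rep(x, each = length(rdmr_windows))),
             length(rdmr_windows), length(d$pdx_ids))
  }
  beta <- clamp(beta)
  if (d$noise_sd > 0) {
    set.seed(derive_seed(seed, 2L))
    beta <- clamp(beta + matrix(stats::rnorm(length(beta), 0, d$noise_sd),
                                nrow(beta), ncol(beta)))
  }
  structure(list(grid = grid, beta = beta,
                 samples = data.frame(sample_id = samples, tissue = tissue,
                                      stringsAsFactors = FALSE),
                 lhb_regions = d$lhb, lhb_windows = lhb_windows,
                 focal_dmrs = d$focal_hyper, rdmr_windows = rdmr_windows,
                 coupling_slope = slope, rdmr_b0 = b0,
                 t_over_c = d$t_over_c),
            class = "methylome_truth")
}

#' Tumor volume from caliper measurements
#'
#' `V = 1/2 * length * width^2`, the standard formula for subcutaneous
#' xenograft volume from two caliper axes.
#'
#' @param length,width caliper measurements in mm (positive).
#' @return volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("length and width must be positive")
  0.5 * length * width^2
}

#' Classify carboplatin response from relative tumor volume
#'
#' Treated-to-control (T/C) relative tumor volume in percent is mapped to
#' the four response categories with half-open boundaries:
#' strong `[0, 9)`, intermediate `[9, 30)`, weak `[30, 78)`,
#' non_responder `[78, Inf)`.
#'
#' @param t_over_c T/C in percent (> 0).
#' @return factor with levels strong, intermediate, weak, non_responder.
#' @export
classify_response <- function(t_over_c) {
  if (any(!is.finite(t_over_c)) || any(t_over_c <= 0))
    stop("t_over_c must be positive and finite")
  cut(t_over_c, breaks = c(0, 9, 30, 78, Inf), right = FALSE,
      labels = c("strong", "intermediate", "weak", "non_responder"))
}

#' Simulate PDX chemosensitivity phenotypes
#'
#' For each PDX model a control and a treated tumor are simulated: caliper
#' length and width are drawn for the control arm, the target T/C is drawn
#' from a log-normal response distribution, and the treated tumor is scaled
#' isometrically so that the volume ratio (via [tumor_volume]) reproduces the
#' target. T/C is then recomputed from the two volumes and classified with
#' [classify_response]. Every PDX sample is paired with a normal sample from
#' the same patient.
#'
#' @param n_models number of PDX models (>= 2).
#' @param response_distribution list with `log_tc_mean`, `log_tc_sd` (natural
#'   log of T/C percent) and `tc_range` (clamp bounds in percent). Defaults
#'   give a cohort spread across all four response classes.
#' @param seed integer seed.
#' @return data.frame of class `phenotype_table` with one row per sample
#'   (`sample_id`, `patient_id`, `tissue`, `relative_tumor_volume`,
#'   `response_category`) and attribute `growth` holding the per-arm caliper
#'   records (`model`, `arm`, `length`, `width`, `volume`).
#' @export
generate_phenotypes <- function(n_models,
                                response_distribution = list(), seed = 1L) {
  if (n_models < 2L) stop("n_models must be >= 2")
  rd <- utils::modifyList(list(log_tc_mean = log(25), log_tc_sd = 1.1,
                               tc_range = c(0.5, 150)),
                          response_distribution)
  set.seed(derive_seed(seed, 3L))
  tc <- clamp(exp(stats::rnorm(n_models, rd$log_tc_mean, rd$log_tc_sd)),
              rd$tc_range[1], rd$tc_range[2])
  len_c <- stats::runif(n_models, 10, 16)
  wid_c <- len_c * stats::runif(n_models, 0.55, 0.8)
  vol_c <- tumor_volume(len_c, wid_c)
  scale <- (tc / 100)^(1 / 3)
  len_t <- len_c * scale
  wid_t <- wid_c * scale
  vol_t <- tumor_volume(len_t, wid_t)
  tc_obs <- 100 * vol_t / vol_c

  model <- sprintf("M%02d", seq_len(n_models))
  pheno <- rbind(
    data.frame(sample_id = paste0(model, "_N"), patient_id = model,
               tissue = "normal", relative_tumor_volume = NA_real_,
               response_category = NA_character_, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(model, "_X"), patient_id = model,
               tissue = "pdx", relative_tumor_volume = tc_obs,
               response_category = as.character(classify_response(tc_obs)),
               stringsAsFactors = FALSE))
  pheno <- pheno[order(pheno$patient_id, pheno$tissue), ]
  rownames(pheno) <- NULL
  attr(pheno, "growth") <- data.frame(
    model = rep(model, 2L), arm = rep(c("control", "treated"), each = n_models),
    length = c(len_c, len_t), width = c(wid_c, wid_t),
    volume = c(vol_c, vol_t), stringsAsFactors = FALSE)
  class(pheno) <- c("phenotype_table", "data.frame")
  pheno
}

#' Per-sample enrichment calibration parameters
#'
#' Convenience constructor for the calibration objects consumed by the
#' forward count model and the estimation/testing routines. The enrichment
#' profile is a saturating function of CpG density,
#' `f(cpg) = f_max * cpg / (cpg + k)`, reflecting antibody-capture
#' saturation; `f(0) = 0` so CpG-free windows carry background signal only.
#'
#' @param sample_ids sample names.
#' @param s library size factor (counts-per-million convention).
#' @param o background rate: expected normalized count at beta = 0.
#' @param f_max,k saturating profile parameters.
#' @param dispersion NB dispersion phi with `var = mu + phi * mu^2`;
#'   `phi = 0` selects the exact Poisson mode.
#' @param cnv_factors optional windows-long relative copy factor vector
#'   (recycled per sample), default 1 everywhere.
#' @return named list of `sample_calibration` objects.
#' @export
make_calibrations <- function(sample_ids, s = 1, o = 2, f_max = 30, k = 10,
                              dispersion = 0.05, cnv_factors = NULL) {
  stopifnot(all(s > 0), all(o >= 0), dispersion >= 0, f_max > 0, k > 0)
  s <- rep_len(s, length(sample_ids))
  o <- rep_len(o, length(sample_ids))
  out <- lapply(seq_along(sample_ids), function(i) {
    structure(list(sample_id = sample_ids[i], s = s[i], o = o[i],
                   dispersion = dispersion,
                   profile = list(type = "saturating", f_max = f_max, k = k),
                   cnv_factors = cnv_factors),
              class = "sample_calibration")
  })
  names(out) <- sample_ids
  out
}

#' Evaluate an enrichment profile at given CpG counts
#'
#' @param profile either `list(type = "saturating", f_max, k)` or
#'   `list(type = "knots", cpg, f)` (linear interpolation through `(0, 0)`
#'   and the knots, constant beyond the last knot).
#' @param cpg vector of CpG counts.
#' @return expected normalized count increment at beta = 1.
#' @export
profile_eval <- function(profile, cpg) {
  switch(profile$type,
         saturating = profile$f_max * cpg / (cpg + profile$k),
         knots = stats::approx(x = c(0, profile$cpg), y = c(0, profile$f),
                               xout = cpg, rule = 2)$y,
         stop("unknown profile type: ", profile$type))
}

#' Expected MeDIP fragment counts under the forward model
#'
#' `mu(i, w) = s_i * c_{i,w} * (o_i + beta(w, i) * f_i(cpg_w))`.
#'
#' @param beta windows x samples methylation matrix.
#' @param grid the [window_grid].
#' @param calibrations named list of `sample_calibration` (see
#'   [make_calibrations]); names must cover `colnames(beta)`.
#' @return windows x samples matrix of expected counts.
#' @export
medip_expected_counts <- function(beta, grid, calibrations) {
  mu <- matrix(NA_real_, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  for (i in seq_len(ncol(beta))) {
    cal <- calibrations[[colnames(beta)[i]]]
    f <- profile_eval(cal$profile, grid$cpg_count)
    cw <- cal$cnv_factors %||% 1
    mu[, i] <- cal$s * cw * (cal$o + beta[, i] * f)
  }
  mu
}

#' Simulate MeDIP-seq window counts
#'
#' Draws negative-binomial counts around [medip_expected_counts]:
#' `var = mu + phi * mu^2` with per-dataset dispersion `phi` taken from the
#' calibrations (`phi = 0` draws Poisson counts). When `depth` is given, the
#' library factors are rescaled so each sample's mean expected count per
#' window equals `depth`; the effective calibrations are attached as
#' attribute `"calibrations"`.
#'
#' @param truth a `methylome_truth` object.
#' @param calibrations named list of `sample_calibration`.
#' @param depth optional target mean fragment count per window.
#' @param seed integer seed.
#' @return integer windows x samples count matrix with attribute
#'   `"calibrations"`.
#' @export
simulate_medip_counts <- function(truth, calibrations, depth = NULL, seed = 1L) {
  beta <- truth$beta
  if (!is.null(depth)) {
    for (id in colnames(beta)) {
      cal <- calibrations[[id]]
      f <- profile_eval(cal$profile, truth$grid$cpg_count)
      cw <- cal$cnv_factors %||% 1
      base <- mean(cw * (cal$o + beta[, id] * f))
      calibrations[[id]]$s <- depth / base
    }
  }
  mu <- medip_expected_counts(beta, truth$grid, calibrations)
  set.seed(derive_seed(seed, 4L))
  counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  for (i in seq_len(ncol(mu))) {
    phi <- calibrations[[colnames(mu)[i]]]$dispersion
    counts[, i] <- if (phi <= 0) stats::rpois(nrow(mu), mu[, i])
                   else stats::rnbinom(nrow(mu), mu = mu[, i], size = 1 / phi)
  }
  attr(counts, "calibrations") <- calibrations
  counts
}

#' Simulate gene expression anti-correlated with promoter methylation
#'
#' For genes flagged as coupled, log2 expression decreases linearly with the
#' sample's promoter methylation: `expr = baseline + coupling * beta_prom`
#' (coupling < 0 gives the canonical promoter-silencing direction).
#' Uncoupled genes are baseline plus noise.
#'
#' @param truth `methylome_truth`.
#' @param gene_map data.frame `gene`, `window` (grid row index of a promoter
#'   window; multiple rows per gene allowed), `coupled` (logical; constant
#'   per gene).
#' @param coupling log2-expression change per unit promoter beta (e.g. -4).
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param samples which samples to emit (default all in `truth`).
#' @param seed integer seed.
#' @return genes x samples matrix of log2 expression values.
#' @export
generate_expression <- function(truth, gene_map, coupling = -4, noise_sd = 0.1,
                                samples = truth$samples$sample_id, seed = 1L) {
  if (any(gene_map$window < 1L | gene_map$window > nrow(truth$grid)))
    stop("unmapped gene: promoter window index outside the grid")
  genes <- unique(gene_map$gene)
  set.seed(derive_seed(seed, 5L))
  baseline <- stats::runif(length(genes), 6, 10)
  names(baseline) <- genes
  expr <- matrix(rep(baseline, length(samples)), length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (g in genes) {
    rows <- gene_map[gene_map$gene == g, ]
    if (isTRUE(rows$coupled[1L])) {
      bprom <- colMeans(truth$beta[rows$window, samples, drop = FALSE])
      expr[g, ] <- expr[g, ] + coupling * bprom
    }
  }
  if (noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd),
                          nrow(expr), ncol(expr))
  expr
}

#' Simulate a matched qMSP validation cohort with survival follow-up
#'
#' Generates `n_pairs` matched patient pairs (one responder = relapse-free,
#' one non-responder per pair). qMSP methylation percent is drawn per group
#' from Gaussians with the configured means/SD and clamped to \[0, 100\];
#' the raw signal is `qmsp_pct / 100 * control_level` so that control-DNA
#' normalization recovers the percent scale. Survival times are exponential;
#' the methylation-high group (the non-responders, whose group mean is
#' higher) has its hazard multiplied by `hazard_ratio`. Censoring is an
#' independent exponential time calibrated so that roughly `censor_rate` of
#' baseline-group patients are censored.
#'
#' @param n_pairs number of matched pairs (>= 3).
#' @param group_means c(responder, non_responder) qMSP percent means.
#' @param group_sd within-group SD of qMSP percent.
#' @param hazard_ratio relative event hazard of the methylation-high group.
#' @param censor_rate approximate censored fraction in the baseline group.
#' @param control_level qMSP signal of fully methylated control DNA.
#' @param baseline_median_years median survival of the baseline group.
#' @param seed integer seed.
#' @return data.frame of class `validation_cohort`: `patient_id`,
#'   `matched_pair_id`, `responder`, `qmsp_raw`, `control_level`, `qmsp_pct`,
#'   `os_time`, `os_event`, `pfs_time`, `pfs_event`.
#' @export
generate_validation_cohort <- function(n_pairs, group_means = c(7.4, 13.9),
                                       group_sd = 4, hazard_ratio = 3,
                                       censor_rate = 0.3, control_level = 0.5,
                                       baseline_median_years = 4, seed = 1L) {
  if (n_pairs < 3L) stop("n_pairs must be >= 3")
  if (any(group_means < 0 | group_means > 100))
    stop("group means must be within [0, 100]")
  set.seed(derive_seed(seed, 6L))
  n <- 2L * n_pairs
  responder <- rep(c(TRUE, FALSE), n_pairs)
  pair <- rep(seq_len(n_pairs), each = 2L)
  mu <- ifelse(responder, group_means[1], group_means[2])
  pct <- clamp(stats::rnorm(n, mu, group_sd), 0, 100)
  lambda0 <- log(2) / baseline_median_years
  lambda <- lambda0 * ifelse(responder, 1, hazard_ratio)
  os_t <- stats::rexp(n, lambda)
  pfs_t <- stats::rexp(n, lambda * 1.4)
  if (censor_rate > 0) {
    lc <- lambda0 * censor_rate / (1 - censor_rate)
    cens <- stats::rexp(n, lc)
  } else cens <- rep(Inf, n)
  out <- data.frame(
    patient_id = sprintf("V%02d", seq_len(n)),
    matched_pair_id = pair, responder = responder,
    qmsp_raw = pct / 100 * control_level, control_level = control_level,
    qmsp_pct = pct,
    os_time = pmin(os_t, cens), os_event = os_t <= cens,
    pfs_time = pmin(pfs_t, cens), pfs_event = pfs_t <= cens,
    stringsAsFactors = FALSE)
  class(out) <- c("validation_cohort", "data.frame")
  out
}
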