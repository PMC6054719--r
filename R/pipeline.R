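# End-to-end orchestration: simulate -> quantify -> DMR/rDMR -> LHB ->
# enrichment -> triage -> validation. Every stage reads and writes plain
# files under one output directory, so each is re-runnable in isolation.

default_config <- function() {
  list(
    genome = list(chromosomes = list(chr1 = 3e6, chr2 = 1.2e6),
                  window_size = 250,
                  cpg = list(background_mean = 3, cgi_mean = 16, cgi_len = 4)),
    genes = list(n_genes = 30, n_coupled = 4, n_focal = 4, chrom = "chr2",
                 offset = 20000, spacing = 30000, promoter_flank = 2000,
                 body_length = 5000, exon_length = 300, n_exons = 3),
    methylome = list(baseline_beta = 0.8, cgi_beta = 0.1, baseline_sd = 0.08,
                     noise_sd = 0.03, focal_hyper_delta = 0.45,
                     rdmr_b0 = 0.15, coupling_slope = 0.05,
                     lhb = list(list(chrom = "chr1", start = 5e5,
                                     end = 17e5, delta = -0.30))),
    cohort = list(n_models = 22,
                  response = list(log_tc_mean = log(25), log_tc_sd = 1.1)),
    counts = list(depth = 30, o = 2, f_max = 30, k = 10, dispersion = 0.05),
    expression = list(coupling = -4, noise_sd = 0.1),
    validation = list(n_pairs = 18, group_means = c(7.4, 13.9), group_sd = 4,
                      hazard_ratio = 3, censor_rate = 0.3),
    thresholds = list(dmr_fdr = 1e-4, dmr_delta = 0.20, rdmr_p = 0.01,
                      corr_p = 0.05, lhb_tile = 1e5, lhb_min_size = 1e6,
                      lhb_min_drop = 0.20),
    seed = 17L)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' YAML with sections `genome`, `genes`, `methylome`, `cohort`, `counts`,
#' `expression`, `validation`, `thresholds`, `seed`; omitted entries fall
#' back to the packaged defaults (see the bundled
#' `inst/extdata/demo_config.yaml`).
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  th <- cfg$thresholds
  stopifnot(th$dmr_fdr > 0, th$dmr_fdr < 1, th$rdmr_p > 0, th$rdmr_p < 1,
            th$corr_p > 0, th$corr_p < 1, th$dmr_delta >= 0,
            th$lhb_min_size > 0, th$lhb_min_drop > 0, th$lhb_min_drop < 1)
  cfg
}

# gene annotation implied by the config: TSS table plus exon/intron ROIs
config_gene_tables <- function(cfg) {
  g <- cfg$genes
  tss <- data.frame(
    gene = sprintf("G%03d", seq_len(g$n_genes)), chrom = g$chrom,
    position = g$offset + (seq_len(g$n_genes) - 1L) * g$spacing,
    strand = rep(c("+", "-"), length.out = g$n_genes),
    stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(g$n_genes), function(i) {
    starts <- tss$position[i] +
      (seq_len(g$n_exons) - 1L) * floor(g$body_length / g$n_exons)
    data.frame(chrom = g$chrom, start = starts,
               end = starts + g$exon_length, stringsAsFactors = FALSE)
  }))
  bodies <- data.frame(chrom = g$chrom, start = tss$position,
                       end = tss$position + g$body_length,
                       stringsAsFactors = FALSE)
  list(tss = tss, exons = exons, bodies = bodies)
}

# contiguous CGI runs of the grid as an roi_set
cgi_roi_from_grid <- function(grid) {
  r <- rle(paste0(grid$chrom, "_", grid$is_cgi))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- grid$is_cgi[starts]
  iv <- data.frame(chrom = grid$chrom[starts[keep]],
                   start = grid$start[starts[keep]],
                   end = grid$end[ends[keep]], stringsAsFactors = FALSE)
  roi_set("CGI", iv)
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config, outdir) {
  cfg <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  gt <- config_gene_tables(cfg)
  grid <- generate_window_grid(
    unlist(cfg$genome$chromosomes), cfg$genome$window_size,
    utils::modifyList(cfg$genome$cpg,
                      list(cgi_loci = data.frame(chrom = gt$tss$chrom,
                                                 pos = gt$tss$position))),
    seed = seed)

  pheno <- generate_phenotypes(cfg$cohort$n_models, cfg$cohort$response, seed)
  pdx <- pheno$sample_id[pheno$tissue == "pdx"]
  normals <- pheno$sample_id[pheno$tissue == "normal"]
  t_over_c <- stats::setNames(
    pheno$relative_tumor_volume[pheno$tissue == "pdx"], pdx)

  promoters <- build_promoters(gt$tss, cfg$genes$promoter_flank)
  prom_flags <- annotate_windows(grid, promoters)[, 1L]
  gene_map <- do.call(rbind, lapply(seq_len(nrow(promoters$intervals)),
    function(i) {
      iv <- promoters$intervals[i, ]
      w <- which(grid$chrom == iv$chrom & grid$start < iv$end &
                   grid$end > iv$start)
      if (!length(w)) return(NULL)
      data.frame(gene = iv$gene, window = w, stringsAsFactors = FALSE)
    }))
  genes <- sort(unique(gene_map$gene))
  coupled <- genes[seq_len(cfg$genes$n_coupled)]
  focal <- genes[cfg$genes$n_coupled + seq_len(cfg$genes$n_focal)]
  rdmr_windows <- gene_map$window[gene_map$gene %in% coupled]
  focal_windows <- gene_map$window[gene_map$gene %in% focal]

  lhb <- do.call(rbind, lapply(cfg$methylome$lhb, as.data.frame))
  design <- list(
    normal_ids = normals, pdx_ids = pdx,
    baseline_beta = cfg$methylome$baseline_beta,
    cgi_beta = cfg$methylome$cgi_beta,
    baseline_sd = cfg$methylome$baseline_sd,
    noise_sd = cfg$methylome$noise_sd, lhb = lhb,
    focal_hyper = if (length(focal_windows))
      data.frame(window = focal_windows,
                 delta = cfg$methylome$focal_hyper_delta),
    rdmr = if (length(rdmr_windows))
      list(windows = rdmr_windows, b0 = cfg$methylome$rdmr_b0,
           slope = cfg$methylome$coupling_slope),
    t_over_c = t_over_c)
  truth <- generate_methylomes(grid, design, seed)

  cal <- make_calibrations(truth$samples$sample_id, o = cfg$counts$o,
                           f_max = cfg$counts$f_max, k = cfg$counts$k,
                           dispersion = cfg$counts$dispersion)
  counts <- simulate_medip_counts(truth, cal, depth = cfg$counts$depth,
                                  seed = seed)

  # reference compendium emulating a 450k tumor+normal cohort: windows that
  # vary with tumor state (LHBs, focal/response DMRs) get a high variance and
  # are excluded by the calibration filter, as in the real reference
  ref <- data.frame(mean = rowMeans(truth$beta),
                    var = apply(truth$beta, 1L, stats::var))

  gm <- gene_map
  gm$coupled <- gm$gene %in% coupled
  expr <- generate_expression(truth, gm, cfg$expression$coupling,
                              cfg$expression$noise_sd, seed = seed)
  cohort <- generate_validation_cohort(
    cfg$validation$n_pairs, unlist(cfg$validation$group_means),
    cfg$validation$group_sd, cfg$validation$hazard_ratio,
    cfg$validation$censor_rate, seed = seed)

  write_grid_bed(grid, file.path(outdir, "grid.bed"))
  write_tsv(data.frame(window = window_key(grid), is_cgi = grid$is_cgi,
                       promoter = prom_flags),
            file.path(outdir, "window_annotation.tsv"))
  write_matrix_tsv(counts, grid, file.path(outdir, "counts.tsv"))
  write_tsv(as.data.frame(pheno), file.path(outdir, "phenotypes.tsv"))
  write_tsv(data.frame(window = window_key(grid), ref),
            file.path(outdir, "reference_betas.tsv"))
  write_tsv(gt$tss, file.path(outdir, "tss.tsv"))
  write_tsv(gt$exons, file.path(outdir, "exons.tsv"))
  write_tsv(gt$bodies, file.path(outdir, "gene_bodies.tsv"))
  write_tsv(gm, file.path(outdir, "gene_map.tsv"))
  write_matrix_tsv(truth$beta, grid, file.path(outdir, "truth_beta.tsv"))
  write_tsv(data.frame(window = rdmr_windows),
            file.path(outdir, "truth_rdmr_windows.tsv"))
  if (!is.null(lhb)) write_tsv(lhb, file.path(outdir, "truth_lhb.tsv"))
  write_tsv(data.frame(gene = coupled), file.path(outdir, "truth_genes.tsv"))
  write_tsv(data.frame(gene = rownames(expr), expr, check.names = FALSE),
            file.path(outdir, "expression.tsv"))
  write_tsv(cohort, file.path(outdir, "cohort.tsv"))
  invisible(list(grid = grid, truth = truth, counts = counts, pheno = pheno,
                 cohort = cohort))
}

read_stage_grid <- function(outdir)
  read_grid_bed(file.path(outdir, "grid.bed"))

read_stage_pheno <- function(outdir)
  read_tsv(file.path(outdir, "phenotypes.tsv"))

#' @rdname run_pipeline
#' @export
stage_quantify <- function(outdir) {
  grid <- read_stage_grid(outdir)
  counts <- read_matrix_tsv(file.path(outdir, "counts.tsv"))
  ref <- read_tsv(file.path(outdir, "reference_betas.tsv"))
  cal <- calibrate_enrichment(counts, ref, grid)
  meth <- estimate_methylation(counts, cal, grid)
  write_calibrations(cal, file.path(outdir, "calibration"), grid)
  write_matrix_tsv(meth, grid, file.path(outdir, "methylation.tsv"))
  ann <- read_tsv(file.path(outdir, "window_annotation.tsv"))
  pca <- pca_promoter_methylation(meth, which(ann$promoter))
  write_tsv(data.frame(sample = rownames(pca$coords), pca$coords,
                       var1 = pca$var_explained[1L],
                       var2 = pca$var_explained[2L]),
            file.path(outdir, "pca.tsv"))
  invisible(meth)
}

#' @rdname run_pipeline
#' @export
stage_dmr <- function(outdir, thresholds = default_config()$thresholds) {
  grid <- read_stage_grid(outdir)
  counts <- read_matrix_tsv(file.path(outdir, "counts.tsv"))
  cal <- read_calibrations(file.path(outdir, "calibration"))
  pheno <- read_stage_pheno(outdir)
  groups <- factor(pheno$tissue[match(colnames(counts), pheno$sample_id)],
                   levels = c("normal", "pdx"))
  dmr <- test_group_dmr(counts, grid, cal, groups)
  filt <- filter_dmrs(dmr, thresholds$dmr_fdr, thresholds$dmr_delta)
  write_dmr_bed(dmr, file.path(outdir, "dmr.tsv"))
  write_dmr_bed(filt, file.path(outdir, "dmr_filtered.tsv"))
  write_tsv(attr(dmr, "skipped"), file.path(outdir, "dmr_skipped.tsv"))
  invisible(filt)
}

#' @rdname run_pipeline
#' @export
stage_rdmr <- function(outdir, thresholds = default_config()$thresholds) {
  grid <- read_stage_grid(outdir)
  counts <- read_matrix_tsv(file.path(outdir, "counts.tsv"))
  cal <- read_calibrations(file.path(outdir, "calibration"))
  pheno <- read_stage_pheno(outdir)
  pdx <- pheno$sample_id[pheno$tissue == "pdx"]
  tc <- stats::setNames(pheno$relative_tumor_volume[pheno$tissue == "pdx"],
                        pdx)
  rdmr <- test_quantitative_rdmr(counts[, pdx, drop = FALSE], grid,
                                 cal[pdx], tc)
  keep <- rdmr[rdmr$p_value < thresholds$rdmr_p, , drop = FALSE]
  out <- rdmr
  out$b0 <- NULL
  write_dmr_bed(out, file.path(outdir, "rdmr.tsv"))
  write_dmr_bed(keep, file.path(outdir, "rdmr_candidates.tsv"))
  write_tsv(attr(rdmr, "skipped"), file.path(outdir, "rdmr_skipped.tsv"))
  invisible(rdmr)
}

#' @rdname run_pipeline
#' @export
stage_lhb <- function(outdir, thresholds = default_config()$thresholds) {
  grid <- read_stage_grid(outdir)
  meth <- read_matrix_tsv(file.path(outdir, "methylation.tsv"))
  pheno <- read_stage_pheno(outdir)
  groups <- factor(pheno$tissue[match(colnames(meth), pheno$sample_id)],
                   levels = c("normal", "pdx"))
  lhbs <- call_lhbs(meth, grid, groups, thresholds$lhb_tile,
                    thresholds$lhb_min_size, thresholds$lhb_min_drop)
  write_tsv(lhbs, file.path(outdir, "lhb.tsv"))
  pdx <- pheno[pheno$tissue == "pdx", ]
  classes <- split(pdx$sample_id, pdx$response_category)
  classes <- classes[lengths(classes) > 0]
  if (nrow(lhbs) && length(classes) >= 1L) {
    cmp <- compare_lhb_intensity(lhbs, meth, grid,
                                 pheno$sample_id[pheno$tissue == "normal"],
                                 classes)
    write_tsv(cmp, file.path(outdir, "lhb_by_response.tsv"))
  }
  invisible(lhbs)
}

#' @rdname run_pipeline
#' @export
stage_enrich <- function(outdir) {
  grid <- read_stage_grid(outdir)
  ann0 <- read_tsv(file.path(outdir, "window_annotation.tsv"))
  grid$is_cgi <- ann0$is_cgi[match(window_key(grid), ann0$window)]
  tss <- read_tsv(file.path(outdir, "tss.tsv"))
  exons <- read_tsv(file.path(outdir, "exons.tsv"))
  bodies <- read_tsv(file.path(outdir, "gene_bodies.tsv"))
  promoters <- build_promoters(tss)
  rois <- list(promoters, cgi_roi_from_grid(grid),
               roi_set("exon", exons), roi_set("gene_body", bodies))
  flags <- annotate_windows(grid, rois)
  dmr <- read_tsv(file.path(outdir, "dmr_filtered.tsv"))
  n_w <- nrow(grid)
  key <- window_key(grid)
  dmr_idx <- match(paste0(dmr$chrom, ":", dmr$start, "-", dmr$end), key)
  dirs <- list(
    hyper = seq_len(n_w) %in% dmr_idx[dmr$direction == "hyper"],
    hypo = seq_len(n_w) %in% dmr_idx[dmr$direction == "hypo"])
  enr <- compute_enrichment(dirs, flags[, c("promoter", "CGI")])
  write_tsv(enr, file.path(outdir, "enrichment.tsv"))

  rdmr <- read_tsv(file.path(outdir, "rdmr_candidates.tsv"))
  r_idx <- match(paste0(rdmr$chrom, ":", rdmr$start, "-", rdmr$end), key)
  ann <- cbind(promoter = flags[, "promoter"], exon = flags[, "exon"],
               intron = flags[, "gene_body"] & !flags[, "exon"])
  dist <- genomic_distribution(r_idx, ann)
  write_tsv(data.frame(category = names(dist), fraction = as.numeric(dist),
                       count = attr(dist, "counts")),
            file.path(outdir, "rdmr_distribution.tsv"))
  invisible(enr)
}

#' @rdname run_pipeline
#' @export
stage_triage <- function(outdir, thresholds = default_config()$thresholds) {
  meth <- read_matrix_tsv(file.path(outdir, "methylation.tsv"))
  gene_map <- read_tsv(file.path(outdir, "gene_map.tsv"))
  rdmr <- read_tsv(file.path(outdir, "rdmr.tsv"))
  grid <- read_stage_grid(outdir)
  rdmr$window <- match(paste0(rdmr$chrom, ":", rdmr$start, "-", rdmr$end),
                       window_key(grid))
  pheno <- read_stage_pheno(outdir)
  pdx <- pheno$sample_id[pheno$tissue == "pdx"]
  tc <- stats::setNames(pheno$relative_tumor_volume[pheno$tissue == "pdx"],
                        pdx)
  expr_df <- read_tsv(file.path(outdir, "expression.tsv"))
  expr <- as.matrix(expr_df[, -1L, drop = FALSE])
  rownames(expr) <- expr_df$gene
  ders <- compute_ders(expr, pheno$sample_id[pheno$tissue == "normal"])
  cand <- triage_candidates(rdmr, meth, gene_map, ders, tc,
                            p_rdmr = thresholds$rdmr_p,
                            p_meth = thresholds$corr_p,
                            p_expr = thresholds$corr_p)
  write_tsv(cand, file.path(outdir, "candidates.tsv"))
  sc <- attr(cand, "stage_counts")
  write_tsv(data.frame(stage = names(sc), n = as.integer(sc)),
            file.path(outdir, "triage_stages.tsv"))
  invisible(cand)
}

#' @rdname run_pipeline
#' @export
stage_validate <- function(outdir) {
  cohort <- read_tsv(file.path(outdir, "cohort.tsv"))
  pct <- normalize_qmsp(cohort$qmsp_raw, cohort$control_level)
  mw <- compare_groups(pct, ifelse(cohort$responder, "responder",
                                   "non_responder"))
  cls <- select_threshold(pct, !cohort$responder)
  high <- pct >= cls$threshold
  km_lo <- km_estimate(cohort$os_time[!high], cohort$os_event[!high])
  km_hi <- km_estimate(cohort$os_time[high], cohort$os_event[high])
  lr_os <- logrank(cohort$os_time[!high], cohort$os_event[!high],
                   cohort$os_time[high], cohort$os_event[high])
  lr_pfs <- logrank(cohort$pfs_time[!high], cohort$pfs_event[!high],
                    cohort$pfs_time[high], cohort$pfs_event[high])
  write_tsv(data.frame(
    threshold = cls$threshold, tp = cls$tp, fn = cls$fn, tn = cls$tn,
    fp = cls$fp, sensitivity = cls$sensitivity,
    specificity = cls$specificity, accuracy = cls$accuracy,
    mw_U = mw$U, mw_p = mw$p_value,
    logrank_os_chisq = lr_os$chi_square, logrank_os_p = lr_os$p_value,
    logrank_pfs_chisq = lr_pfs$chi_square, logrank_pfs_p = lr_pfs$p_value),
    file.path(outdir, "validation_summary.tsv"))
  write_tsv(rbind(cbind(group = "meth_low", as.data.frame(km_lo)),
                  cbind(group = "meth_high", as.data.frame(km_hi))),
            file.path(outdir, "km_os.tsv"))
  invisible(list(classifier = cls, mann_whitney = mw, logrank_os = lr_os,
                 logrank_pfs = lr_pfs))
}

#' Run the full biomarker discovery pipeline
#'
#' Executes simulate (optional when inputs already exist) -> quantify ->
#' DMR -> rDMR -> LHB -> enrichment -> triage -> validation, writing all
#' tabular outputs under `outdir` and a YAML run report. Each `stage_*`
#' function is independently re-runnable from the serialized files.
#'
#' @param config configuration list from [read_pipeline_config].
#' @param outdir output directory.
#' @param simulate generate synthetic inputs first (default TRUE).
#' @return the run report (invisibly), also written to `run_report.yaml`.
#' @export
run_pipeline <- function(config = read_pipeline_config(), outdir,
                         simulate = TRUE) {
  warnings_seen <- character(0)
  stage_names <- c(if (simulate) "simulate", "quantify", "dmr", "rdmr",
                   "lhb", "enrich", "triage", "validate")
  report <- list(seed = config$seed, thresholds = config$thresholds,
                 stages = list())
  for (st in stage_names) {
    res <- withCallingHandlers(
      tryCatch(switch(st,
        simulate = stage_simulate(config, outdir),
        quantify = stage_quantify(outdir),
        dmr = stage_dmr(outdir, config$thresholds),
        rdmr = stage_rdmr(outdir, config$thresholds),
        lhb = stage_lhb(outdir, config$thresholds),
        enrich = stage_enrich(outdir),
        triage = stage_triage(outdir, config$thresholds),
        validate = stage_validate(outdir)),
        error = function(e)
          stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
               call. = FALSE)),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(st, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    n <- if (is.data.frame(res)) nrow(res)
         else if (is.matrix(res)) nrow(res)
         else length(res)
    report$stages[[st]] <- list(records = n)
  }
  report$warnings <- warnings_seen
  yaml::write_yaml(report, file.path(outdir, "run_report.yaml"))
  invisible(report)
}
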