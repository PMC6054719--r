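#' Collapse probe-level expression to gene level
#'
#' Probes below the quality threshold are removed first, probes without a
#' gene mapping are dropped (count reported via attribute), and for each
#' gene the surviving probe with the highest mean expression across samples
#' is retained; ties go to the lexicographically smallest probe id.
#'
#' @param probe_matrix probes x samples log2 expression matrix with probe
#'   ids as rownames.
#' @param probe_annotation data.frame `probe`, `gene`, `quality`.
#' @param keep_grades quality grades retained (default perfect/good).
#' @return genes x samples matrix with attributes `"n_dropped_quality"`,
#'   `"n_dropped_unmapped"` and `"probe_used"` (named by gene).
#' @export
collapse_probes <- function(probe_matrix, probe_annotation,
                            keep_grades = c("perfect", "good")) {
  ann <- probe_annotation[match(rownames(probe_matrix), probe_annotation$probe), ]
  good <- !is.na(ann$quality) & ann$quality %in% keep_grades
  n_bad_q <- sum(!good)
  mapped <- good & !is.na(ann$gene) & nzchar(ann$gene)
  n_unmapped <- sum(good & !mapped)
  pm <- probe_matrix[mapped, , drop = FALSE]
  genes <- ann$gene[mapped]
  means <- rowMeans(pm)
  ord <- order(genes, -means, rownames(pm))
  first <- !duplicated(genes[ord])
  pick <- ord[first]
  out <- pm[pick, , drop = FALSE]
  rownames(out) <- genes[pick]
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "n_dropped_quality") <- n_bad_q
  attr(out, "n_dropped_unmapped") <- n_unmapped
  attr(out, "probe_used") <-
    stats::setNames(rownames(pm)[pick][order(genes[pick])], sort(genes[pick]))
  out
}

#' Differential expression ratios versus the normal median
#'
#' `DER(g, s) = expr(g, s) - median(expr(g, normals))` on the log2 scale,
#' one value per gene and tumor sample.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param normal_ids names of the normal reference samples (>= 1).
#' @return genes x tumor-samples matrix of log2 ratios.
#' @export
compute_ders <- function(expr, normal_ids) {
  normal_ids <- intersect(normal_ids, colnames(expr))
  if (!length(normal_ids)) stop("no normal samples available")
  med <- apply(expr[, normal_ids, drop = FALSE], 1L, stats::median)
  tumor <- setdiff(colnames(expr), normal_ids)
  expr[, tumor, drop = FALSE] - med
}

#' Spearman correlation with exact small-sample p-value
#'
#' Average-rank Spearman rho. For n <= 8 the two-sided p-value is exact by
#' full enumeration of the n! pairings; for larger n the usual
#' t-approximation with n - 2 df is used.
#'
#' @param x,y paired finite observations, n >= 4; constant vectors are an
#'   error (rho undefined).
#' @return list `rho`, `p_value`, `n`, `method`.
#' @export
spearman_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired finite observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("rho undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_perms(n)
    rxs <- as.numeric(scale(rx))
    rys <- as.numeric(scale(ry))
    rho_perm <- (matrix(rys[perms], nrow(perms), n) %*% rxs) / (n - 1)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    t <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

#' Three-stage predictive biomarker triage
#'
#' Reproduces the candidate-gene cascade:
#' \enumerate{
#' \item genes with at least one promoter window tested as a response DMR at
#'   uncorrected `p < p_rdmr` (default 0.01);
#' \item of these, genes whose promoter methylation is Spearman-correlated
#'   with relative tumor volume at `p < p_meth` (default 0.05);
#' \item of these, genes whose expression ratio (DER) is correlated with
#'   tumor volume at `p < p_expr` (default 0.05) with sign opposite to the
#'   methylation correlation.
#' }
#' Promoter methylation per gene is the mean beta over the gene's promoter
#' windows with defined values (`meth_level = "gene"`); with
#' `meth_level = "window"` the most significant single window is used
#' instead.
#'
#' @param promoter_rdmrs result of [test_quantitative_rdmr] restricted to
#'   promoter windows (or the full table; only windows present in
#'   `gene_map` are considered).
#' @param meth windows x samples beta matrix.
#' @param gene_map data.frame `gene`, `window` (grid row index).
#' @param ders genes x samples DER matrix from [compute_ders].
#' @param t_over_c named relative-tumor-volume vector (percent) over the
#'   samples shared by `meth` and `ders` (>= 6 required).
#' @param p_rdmr,p_meth,p_expr stage thresholds.
#' @param meth_level `"gene"` (default) or `"window"`.
#' @return data.frame of candidates ordered by expression p-value
#'   (`gene`, `rdmr_p`, `meth_rho`, `meth_p`, `expr_rho`, `expr_p`,
#'   `opposite_sign`), with attribute `"stage_counts"` (`stage1`, `stage2`,
#'   `stage3`).
#' @export
triage_candidates <- function(promoter_rdmrs, meth, gene_map, ders, t_over_c,
                              p_rdmr = 0.01, p_meth = 0.05, p_expr = 0.05,
                              meth_level = c("gene", "window")) {
  meth_level <- match.arg(meth_level)
  samples <- intersect(names(t_over_c), colnames(meth))
  samples <- intersect(samples, colnames(ders))
  if (length(samples) < 6L)
    stop("need >= 6 samples with methylation, expression and response data")
  tc <- t_over_c[samples]

  rp <- promoter_rdmrs[promoter_rdmrs$window %in% gene_map$window, ]
  gene_of <- split(gene_map$window, gene_map$gene)
  min_p <- vapply(gene_of, function(w) {
    p <- rp$p_value[rp$window %in% w]
    if (length(p)) min(p) else NA_real_
  }, numeric(1))
  stage1 <- names(gene_of)[!is.na(min_p) & min_p < p_rdmr]

  rows <- list()
  stage2 <- character(0)
  for (g in stage1) {
    w <- gene_of[[g]]
    mg <- if (meth_level == "gene") {
      colMeans(meth[w, samples, drop = FALSE], na.rm = TRUE)
    } else {
      pw <- rp[rp$window %in% w, ]
      wbest <- pw$window[which.min(pw$p_value)]
      meth[wbest, samples]
    }
    if (all(!is.finite(mg)) || stats::var(mg, na.rm = TRUE) == 0) next
    mres <- tryCatch(spearman_with_p(mg, tc), error = function(e) NULL)
    if (is.null(mres) || mres$p_value >= p_meth) next
    stage2 <- c(stage2, g)
    if (!g %in% rownames(ders)) next
    eres <- tryCatch(spearman_with_p(ders[g, samples], tc),
                     error = function(e) NULL)
    if (is.null(eres) || eres$p_value >= p_expr) next
    if (sign(eres$rho) != -sign(mres$rho)) next
    rows[[g]] <- data.frame(
      gene = g, rdmr_p = min_p[[g]], meth_rho = mres$rho,
      meth_p = mres$p_value, expr_rho = eres$rho, expr_p = eres$p_value,
      opposite_sign = TRUE, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(0), rdmr_p = numeric(0),
                         meth_rho = numeric(0), meth_p = numeric(0),
                         expr_rho = numeric(0), expr_p = numeric(0),
                         opposite_sign = logical(0))
  out <- out[order(out$expr_p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- c(stage1 = length(stage1),
                                 stage2 = length(stage2),
                                 stage3 = nrow(out))
  out
}
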