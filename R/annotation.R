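#' Region-of-interest sets
#'
#' A named collection of genomic intervals (0-based half-open), e.g.
#' promoters, CpG islands, a transcription-factor binding-site track, or
#' lamina-associated domains.
#'
#' @param name set name.
#' @param intervals data.frame `chrom`, `start`, `end` (and optional
#'   metadata columns such as `gene`).
#' @return list of class `roi_set`.
#' @export
roi_set <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("roi intervals must satisfy start < end")
  structure(list(name = name, intervals = intervals), class = "roi_set")
}

#' Promoter intervals from a TSS table
#'
#' Promoters are the symmetric flank `[TSS - flank, TSS + flank)` (default
#' 2 kb each side), clipped at chromosome bounds, with the intervals of all
#' transcripts of one gene merged.
#'
#' @param tss_table data.frame `gene`, `chrom`, `position` (0-based TSS),
#'   `strand` (kept for bookkeeping; the flank is symmetric).
#' @param flank bp on each side of the TSS.
#' @param chrom_lengths optional named vector for right-clipping.
#' @return a [roi_set] named `"promoter"` whose intervals carry `gene`.
#' @export
build_promoters <- function(tss_table, flank = 2000, chrom_lengths = NULL) {
  iv <- data.frame(chrom = tss_table$chrom,
                   start = pmax(tss_table$position - flank, 0),
                   end = tss_table$position + flank,
                   gene = tss_table$gene, stringsAsFactors = FALSE)
  if (!is.null(chrom_lengths))
    iv$end <- pmin(iv$end, chrom_lengths[iv$chrom])
  merged <- lapply(split(iv, iv$gene), function(g) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(start = g$start + 1L, end = g$end)))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr), gene = g$gene[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  roi_set("promoter", out)
}

#' Flag windows overlapping regions of interest
#'
#' A window is flagged for a set when it overlaps any of its intervals by at
#' least 1 bp under half-open semantics. ROI intervals on chromosomes absent
#' from the grid are dropped with a warning.
#'
#' @param grid the [window_grid].
#' @param rois a single [roi_set] or a list of them.
#' @return logical matrix, windows x roi sets.
#' @export
annotate_windows <- function(grid, rois) {
  if (inherits(rois, "roi_set")) rois <- list(rois)
  gw <- grid_to_granges(grid)
  flags <- matrix(FALSE, nrow(grid), length(rois))
  colnames(flags) <- vapply(rois, `[[`, character(1), "name")
  for (j in seq_along(rois)) {
    iv <- rois[[j]]$intervals
    unknown <- !(iv$chrom %in% grid$chrom)
    if (any(unknown)) {
      warning(sum(unknown), " interval(s) of ROI set '", rois[[j]]$name,
              "' on chromosomes absent from the grid were dropped")
      iv <- iv[!unknown, , drop = FALSE]
    }
    if (!nrow(iv)) next
    gr <- GenomicRanges::GRanges(iv$chrom,
                                 IRanges::IRanges(start = iv$start + 1L,
                                                  end = iv$end))
    hits <- GenomicRanges::findOverlaps(gw, gr)
    flags[unique(S4Vectors::queryHits(hits)), j] <- TRUE
  }
  flags
}

#' DMR enrichment in regions of interest (genome-wide background)
#'
#' For each ROI set and DMR direction the fraction of windows that are DMRs
#' inside the ROI (`p1`) is compared to the genome-wide DMR fraction
#' (`p2`, ROI included): `odds_ratio = [p1/(1-p1)] / [p2/(1-p2)]`. A
#' two-sided Fisher exact p-value is computed on the 2x2 table
#' (in-ROI / out-ROI) x (DMR / non-DMR).
#'
#' @param dmr_flags named list of logical windows-long vectors (e.g.
#'   `list(hyper = ..., hypo = ...)`), or a single logical vector.
#' @param roi_flags logical windows x roi matrix from [annotate_windows].
#' @return data.frame `roi`, `direction`, `dmr_in_roi`, `windows_in_roi`,
#'   `dmr_total`, `windows_total`, `odds_ratio`, `fisher_p`. ROI sets
#'   covering zero windows are omitted with a warning.
#' @export
compute_enrichment <- function(dmr_flags, roi_flags) {
  if (!is.list(dmr_flags)) dmr_flags <- list(dmr = dmr_flags)
  n <- nrow(roi_flags)
  rows <- list()
  for (roi in colnames(roi_flags)) {
    in_roi <- roi_flags[, roi]
    n_roi <- sum(in_roi)
    if (n_roi == 0L) {
      warning("ROI set '", roi, "' covers no windows; omitted")
      next
    }
    for (dir in names(dmr_flags)) {
      dmr <- dmr_flags[[dir]]
      a <- sum(dmr & in_roi)
      m <- sum(dmr)
      p1 <- a / n_roi
      p2 <- m / n
      or <- if (p1 >= 1) Inf
            else if (p2 <= 0 || p2 >= 1) NA_real_
            else (p1 / (1 - p1)) / (p2 / (1 - p2))
      tab <- matrix(c(a, n_roi - a, m - a, n - n_roi - (m - a)), 2L, 2L)
      fp <- stats::fisher.test(tab)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, direction = dir, dmr_in_roi = a, windows_in_roi = n_roi,
        dmr_total = m, windows_total = n, odds_ratio = or, fisher_p = fp,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic distribution of DMR windows
#'
#' Assigns each DMR window exactly one category with priority
#' promoter > exon > intron > intergenic and reports the category fractions
#' (always summing to 1).
#'
#' @param dmr_windows logical windows-long vector or integer indices.
#' @param annotation logical windows x category matrix with columns
#'   `promoter`, `exon`, `intron`.
#' @return named vector of fractions with attribute `"counts"`.
#' @export
genomic_distribution <- function(dmr_windows, annotation) {
  idx <- if (is.logical(dmr_windows)) which(dmr_windows)
         else as.integer(dmr_windows)
  cat <- rep("intergenic", length(idx))
  cat[annotation[idx, "intron"]] <- "intron"
  cat[annotation[idx, "exon"]] <- "exon"
  cat[annotation[idx, "promoter"]] <- "promoter"
  lev <- c("promoter", "exon", "intron", "intergenic")
  counts <- vapply(lev, function(l) sum(cat == l), integer(1))
  frac <- if (length(idx)) counts / length(idx) else counts * NA_real_
  attr(frac, "counts") <- counts
  frac
}
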