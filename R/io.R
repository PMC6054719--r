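# Plain-text serialization: TSV for tables/matrices, BED for intervals.

#' @rdname xenomark_io
#' @param df data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Tabular and interval I/O
#'
#' TSV with a header row; matrices gain a leading `window` key column
#' (`chrom:start-end`); grids are BED4 (`chrom`, `start`, `end`,
#' `cpg_count`, 0-based half-open).
#'
#' @name xenomark_io
#' @param path file path.
#' @return the read object, or (for writers) the path invisibly.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname xenomark_io
#' @param grid a [window_grid].
#' @export
write_grid_bed <- function(grid, path) {
  utils::write.table(grid[, c("chrom", "start", "end", "cpg_count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname xenomark_io
#' @param window_size window width of the stored grid.
#' @export
read_grid_bed <- function(path, window_size = NULL) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "cpg_count"),
                         stringsAsFactors = FALSE)
  window_grid(b$chrom, b$start, b$end, b$cpg_count,
              window_size = window_size %||% unique(b$end - b$start)[1L])
}

#' @rdname xenomark_io
#' @param m windows x samples matrix.
#' @param grid the aligned [window_grid].
#' @export
write_matrix_tsv <- function(m, grid, path) {
  df <- data.frame(window = window_key(grid), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname xenomark_io
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$window
  m
}

#' @rdname xenomark_io
#' @param calibrations named list of `sample_calibration`.
#' @param dir directory receiving `calibration.tsv`, `profile_knots.tsv`
#'   and `cnv_factors.tsv`.
#' @export
write_calibrations <- function(calibrations, dir, grid = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  main <- do.call(rbind, lapply(calibrations, function(cal)
    data.frame(sample = cal$sample_id, s = cal$s, o = cal$o,
               dispersion = cal$dispersion, profile_type = cal$profile$type,
               f_max = cal$profile$f_max %||% NA_real_,
               k = cal$profile$k %||% NA_real_, stringsAsFactors = FALSE)))
  write_tsv(main, file.path(dir, "calibration.tsv"))
  knots <- do.call(rbind, lapply(calibrations, function(cal) {
    if (cal$profile$type != "knots") return(NULL)
    data.frame(sample = cal$sample_id, cpg = cal$profile$cpg,
               f = cal$profile$f, stringsAsFactors = FALSE)
  }))
  if (!is.null(knots)) write_tsv(knots, file.path(dir, "profile_knots.tsv"))
  cnv <- do.call(rbind, lapply(calibrations, function(cal) {
    if (is.null(cal$cnv_factors)) return(NULL)
    data.frame(sample = cal$sample_id,
               window = if (!is.null(grid)) window_key(grid)
                        else seq_along(cal$cnv_factors),
               factor = cal$cnv_factors, stringsAsFactors = FALSE)
  }))
  if (!is.null(cnv)) write_tsv(cnv, file.path(dir, "cnv_factors.tsv"))
  invisible(dir)
}

#' @rdname xenomark_io
#' @export
read_calibrations <- function(dir) {
  main <- read_tsv(file.path(dir, "calibration.tsv"))
  knot_path <- file.path(dir, "profile_knots.tsv")
  knots <- if (file.exists(knot_path)) read_tsv(knot_path) else NULL
  cnv_path <- file.path(dir, "cnv_factors.tsv")
  cnv <- if (file.exists(cnv_path)) read_tsv(cnv_path) else NULL
  out <- lapply(seq_len(nrow(main)), function(i) {
    id <- main$sample[i]
    prof <- if (main$profile_type[i] == "saturating")
      list(type = "saturating", f_max = main$f_max[i], k = main$k[i])
    else {
      kn <- knots[knots$sample == id, ]
      list(type = "knots", cpg = kn$cpg, f = kn$f)
    }
    structure(list(sample_id = id, s = main$s[i], o = main$o[i],
                   dispersion = main$dispersion[i], profile = prof,
                   cnv_factors = if (!is.null(cnv)) cnv$factor[cnv$sample == id]),
              class = "sample_calibration")
  })
  names(out) <- main$sample
  out
}

#' @rdname xenomark_io
#' @param records DMR record data.frame.
#' @export
write_dmr_bed <- function(records, path) {
  cols <- intersect(c("chrom", "start", "end", "delta_beta", "lrt_stat",
                      "p_value", "fdr", "direction"), names(records))
  write_tsv(records[, cols, drop = FALSE], path)
}
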