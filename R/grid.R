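#' Genome window grids
#'
#' The analysis operates on an ordered, disjoint tiling of the genome into
#' fixed-width windows (default 250 bp, matching typical MeDIP fragment
#' lengths). Each window carries the number of CpG dinucleotides it contains;
#' CpG-free windows are used for copy-number and background estimation, CpG
#' island (CGI) windows model promoter-associated islands.
#'
#' Coordinates are 0-based half-open throughout the package.
#'
#' @param chrom,start,end,cpg_count,is_cgi parallel vectors of window fields.
#' @param window_size the fixed window width in bp.
#' @return a `data.frame` of class `window_grid` with columns `chrom`,
#'   `start`, `end`, `cpg_count`, `is_cgi` and attribute `window_size`.
#' @export
window_grid <- function(chrom, start, end, cpg_count,
                        is_cgi = rep(FALSE, length(chrom)),
                        window_size = unique(end - start)) {
  g <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), cpg_count = as.integer(cpg_count),
                  is_cgi = as.logical(is_cgi), stringsAsFactors = FALSE)
  attr(g, "window_size") <- as.integer(window_size[1L])
  class(g) <- c("window_grid", "data.frame")
  validate_window_grid(g)
  g
}

#' @rdname window_grid
#' @param grid object to validate.
#' @export
validate_window_grid <- function(grid) {
  stopifnot(is.data.frame(grid),
            all(c("chrom", "start", "end", "cpg_count") %in% names(grid)))
  if (any(grid$cpg_count < 0)) stop("cpg_count must be non-negative")
  ws <- attr(grid, "window_size")
  if (!is.null(ws) && any(grid$end - grid$start != ws))
    stop("all windows must have width equal to the configured window size")
  ord <- order(grid$chrom, grid$start)
  if (!identical(ord, seq_len(nrow(grid))))
    stop("windows must be sorted by (chrom, start)")
  by_chr <- split(grid, grid$chrom)
  for (g in by_chr) {
    if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
      stop("windows must be disjoint within each chromosome")
  }
  invisible(grid)
}

#' Generate a synthetic genome window grid
#'
#' Tiles each chromosome with fixed-width windows (a trailing remainder
#' shorter than one window is dropped) and draws per-window CpG counts from a
#' two-component model: a CpG-poor Poisson background, plus CpG-rich
#' CGI-like islands spanning `cgi_len` consecutive windows. Islands are
#' either placed at designated loci (`cgi_loci`, e.g. promoters) or seeded at
#' random with per-window start probability `cgi_rate`.
#'
#' @param genome_spec named numeric vector of chromosome lengths in bp.
#' @param window_size window width in bp (>= 50).
#' @param cpg_model list with elements `background_mean` (mean CpGs of a
#'   background window), `cgi_rate` (island start probability per window),
#'   `cgi_mean` (mean CpGs of an island window), `cgi_len` (island length in
#'   windows), and optionally `cgi_loci` (data.frame with `chrom`, `pos`;
#'   islands are centred on these positions and `cgi_rate` is ignored for
#'   placement when supplied together with `cgi_rate = 0`).
#' @param seed integer seed.
#' @return a [window_grid].
#' @export
generate_window_grid <- function(genome_spec, window_size = 250,
                                 cpg_model = list(), seed = 1L) {
  if (length(genome_spec) == 0L || any(!is.finite(genome_spec)) || any(genome_spec <= 0))
    stop("invalid genome specification: chromosome lengths must be positive")
  if (window_size < 50) stop("window_size must be >= 50")
  m <- utils::modifyList(list(background_mean = 2, cgi_rate = 0,
                              cgi_mean = 15, cgi_len = 4, cgi_loci = NULL),
                         cpg_model)
  if (is.null(names(genome_spec)))
    names(genome_spec) <- paste0("chr", seq_along(genome_spec))
  set.seed(derive_seed(seed, 1L))

  pieces <- lapply(names(genome_spec), function(ch) {
    n <- floor(genome_spec[[ch]] / window_size)
    if (n == 0L) return(NULL)
    start <- as.integer((seq_len(n) - 1L) * window_size)
    data.frame(chrom = ch, start = start, end = start + as.integer(window_size),
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, pieces)
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  rownames(g) <- NULL

  is_cgi <- rep(FALSE, nrow(g))
  if (!is.null(m$cgi_loci)) {
    for (i in seq_len(nrow(m$cgi_loci))) {
      ch <- m$cgi_loci$chrom[i]
      w0 <- which(g$chrom == ch & g$start <= m$cgi_loci$pos[i] &
                    m$cgi_loci$pos[i] < g$end)
      if (length(w0)) {
        half <- floor(m$cgi_len / 2)
        idx <- (w0 - half):(w0 - half + m$cgi_len - 1L)
        idx <- idx[idx >= 1L & idx <= nrow(g)]
        idx <- idx[g$chrom[idx] == ch]
        is_cgi[idx] <- TRUE
      }
    }
  }
  if (m$cgi_rate > 0) {
    starts <- which(stats::runif(nrow(g)) < m$cgi_rate)
    for (w0 in starts) {
      idx <- w0:min(w0 + m$cgi_len - 1L, nrow(g))
      idx <- idx[g$chrom[idx] == g$chrom[w0]]
      is_cgi[idx] <- TRUE
    }
  }
  cpg <- stats::rpois(nrow(g), m$background_mean)
  if (any(is_cgi))
    cpg[is_cgi] <- 1L + stats::rpois(sum(is_cgi), m$cgi_mean - 1)
  window_grid(g$chrom, g$start, g$end, cpg, is_cgi, window_size = window_size)
}

# map windows to genomic bins of bin_size; returns "chrom:bin" ids
window_bin_id <- function(grid, bin_size) {
  paste0(grid$chrom, ":", floor(grid$start / bin_size))
}

# GRanges view of the grid (1-based closed, as GenomicRanges expects)
grid_to_granges <- function(grid) {
  GenomicRanges::GRanges(grid$chrom,
                         IRanges::IRanges(start = grid$start + 1L, end = grid$end))
}
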