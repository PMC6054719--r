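# Shared fixture builders: everything is generated in code, no files.

# uniform single-chromosome grid with constant CpG count
flat_grid <- function(n, cpg = 3, ws = 250, chrom = "chr1", is_cgi = FALSE) {
  window_grid(rep(chrom, n), (seq_len(n) - 1L) * ws, seq_len(n) * ws,
              rep(cpg, length.out = n), rep(is_cgi, length.out = n),
              window_size = ws)
}

# paired-design truth with configurable planted effects
make_truth <- function(grid, n_normal = 2, n_pdx = 2, seed = 1, ...) {
  ids_n <- paste0("N", seq_len(n_normal))
  ids_x <- paste0("X", seq_len(n_pdx))
  design <- utils::modifyList(
    list(normal_ids = ids_n, pdx_ids = ids_x, noise_sd = 0), list(...))
  generate_methylomes(grid, design, seed)
}

# promoter-array grid for triage experiments: n_genes promoters of
# `wpg` windows each, CpG-rich island in the middle
promoter_array <- function(n_genes, wpg = 16) {
  cpg_unit <- c(rep(3, (wpg - 4) / 2), rep(c(12, 16, 16, 12), 1),
                rep(3, (wpg - 4) / 2))
  cpg <- rep(cpg_unit, n_genes)
  n_w <- n_genes * wpg
  list(grid = window_grid(rep("chr1", n_w), (seq_len(n_w) - 1L) * 250,
                          seq_len(n_w) * 250, cpg, cpg > 8),
       gene_map = data.frame(gene = rep(sprintf("G%02d", seq_len(n_genes)),
                                        each = wpg),
                             window = seq_len(n_w),
                             stringsAsFactors = FALSE))
}

# brute-force maximized NB log-likelihood over a beta grid (oracle)
grid_search_ll <- function(y, k1, k2, phi, step = 0.001) {
  betas <- seq(0, 1, by = step)
  best <- -Inf
  for (b in betas) {
    mu <- pmax(k1 + b * k2, 1e-10)
    ll <- if (phi <= 0) sum(dpois(y, mu, log = TRUE))
          else sum(dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
    if (ll > best) best <- ll
  }
  best
}

# two-sided Fisher exact p by hypergeometric enumeration (oracle)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# scaled-down pipeline configuration for end-to-end tests
test_pipeline_config <- function(seed = 5) {
  cfg <- read_pipeline_config()
  cfg$genome$chromosomes <- list(chr1 = 1.6e6, chr2 = 6e5)
  cfg$genes$n_genes <- 12
  cfg$genes$n_coupled <- 3
  cfg$genes$n_focal <- 3
  cfg$genes$spacing <- 30000
  cfg$methylome$lhb <- list(list(chrom = "chr1", start = 2e5, end = 13e5,
                                 delta = -0.30))
  cfg$cohort$n_models <- 16
  cfg$validation$n_pairs <- 12
  cfg$seed <- seed
  cfg
}
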