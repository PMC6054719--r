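# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Generators consume named sub-streams of one master seed so that adding a
#' stage never perturbs the random numbers of another stage. The derived seed
#' always stays below 2^31.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer offset identifying the sub-stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(offset) * 104729) %% 2147483587)
}

# all permutations of 1:n as an (n! x n) index matrix; n <= 8 only
all_perms <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

# window key "chrom:start-end" used in all tabular outputs
window_key <- function(grid) paste0(grid$chrom, ":", grid$start, "-", grid$end)
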