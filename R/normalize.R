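with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Downsample a repertoire to a fixed number of UMI-labeled molecules
#'
#' Draws `n_molecules` molecules uniformly *without replacement* from the
#' multiset of UMI-labeled cDNA molecules (per-clonotype counts are
#' jointly multivariate hypergeometric). Clonotypes reduced to zero are
#' dropped and frequencies recomputed. The draw is bit-reproducible given
#' `seed`. Repertoires smaller than the target are refused: the sampling
#' depth is meant to be the cohort's lower bound (16,000 molecules in the
#' motivating study).
#'
#' @param rep a [repertoire()]
#' @param n_molecules target molecule count (default 16000)
#' @param seed integer RNG seed, or NULL to use the current RNG stream
#' @param replacement sample with replacement instead (multinomial
#'   approximation, for sensitivity analyses only). Default FALSE.
#' @return downsampled repertoire with `total_count(rep) == n_molecules`
#' @export
downsample_umis <- function(rep, n_molecules = 16000L, seed = NULL,
                            replacement = FALSE) {
  n_molecules <- as.integer(n_molecules)
  tot <- total_count(rep)
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (tot < n_molecules)
    stop(sprintf("repertoire has %d molecules, fewer than n_molecules = %d; refusing to upsample",
                 tot, n_molecules))
  counts <- rep$count
  newc <- with_seed(seed, {
    if (replacement) {
      as.vector(stats::rmultinom(1L, n_molecules, counts / tot))
    } else {
      idx <- sample.int(tot, n_molecules)  # molecule labels 1..tot
      cl <- findInterval(idx, cumsum(counts), left.open = TRUE) + 1L
      tabulate(cl, nbins = length(counts))
    }
  })
  keep <- newc > 0L
  out <- rep[keep, , drop = FALSE]
  out$count <- as.numeric(newc[keep])
  recompute_frequencies(new_repertoire_like(out, rep))
}

#' Truncate a repertoire to its top-N most frequent clonotypes
#'
#' Keeps the `min(n, size)` clonotypes of highest count; ties at the
#' cutoff are broken lexicographically on (v_gene, cdr3nt) so the result
#' is deterministic. Frequencies are recomputed over the retained set.
#'
#' @param rep a [repertoire()]
#' @param n number of clonotypes to keep (default 20000)
#' @return truncated repertoire
#' @export
top_n_clonotypes <- function(rep, n = 20000L) {
  if (n < 1L) stop("n must be >= 1")
  if (!nrow(rep)) return(rep)
  o <- order(-rep$count, rep$v_gene, rep$cdr3nt, method = "radix")
  keep <- sort(o[seq_len(min(n, nrow(rep)))])
  recompute_frequencies(new_repertoire_like(rep[keep, , drop = FALSE], rep))
}
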