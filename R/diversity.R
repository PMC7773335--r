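#' Observed diversity
#'
#' Number of distinct clonotypes with count >= 1. Meant to be computed on
#' depth-normalized clonesets (see [downsample_umis()]); comparing raw
#' clonesets of different sizes conflates richness with sequencing depth.
#'
#' @param rep a [repertoire()]
#' @return integer clonotype count
#' @export
observed_diversity <- function(rep) sum(rep$count >= 1)

#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))`, where
#' `f1` and `f2` are the numbers of singleton and doubleton clonotypes.
#' The `+1` in the denominator keeps the estimator defined when no
#' doubletons are observed (common repertoire-tool practice); set
#' `bias_corrected = FALSE` for the classical `f1^2 / (2 * f2)` form.
#'
#' @param rep a [repertoire()] with integer counts
#' @param bias_corrected default TRUE
#' @return estimated richness (>= observed)
#' @export
chao1 <- function(rep, bias_corrected = TRUE) {
  s_obs <- observed_diversity(rep)
  f1 <- sum(rep$count == 1)
  f2 <- sum(rep$count == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / 2
}

#' Normalized Shannon-Wiener index
#'
#' `H / log(S_obs)` with `H = -sum(p_i * log(p_i))`, i.e. Shannon entropy
#' of the clonotype frequency distribution divided by its maximum for the
#' observed richness. 1 = perfectly even; values near 0 indicate
#' domination by clonal expansions. Defined as 0 for a single-clonotype
#' repertoire.
#'
#' @param rep a [repertoire()]
#' @return value in \[0, 1\]
#' @export
normalized_shannon_wiener <- function(rep) {
  s <- nrow(rep)
  if (s <= 1L) return(0)
  p <- rep$count / sum(rep$count)
  p <- p[p > 0]
  -sum(p * log(p)) / log(s)
}

#' Diversity statistics at fixed sampling depth
#'
#' Optionally downsamples to `n_molecules` UMIs (seeded), then reports
#' observed diversity, Chao1 and the normalized Shannon-Wiener index.
#'
#' @param rep a [repertoire()]
#' @param n_molecules depth to normalize to, or NULL to use the
#'   repertoire as given
#' @param seed RNG seed for the downsample
#' @return data.frame with columns `observed`, `chao1`,
#'   `normalized_shannon_wiener`, `n_molecules`
#' @export
diversity_stats <- function(rep, n_molecules = NULL, seed = NULL) {
  if (!is.null(n_molecules)) rep <- downsample_umis(rep, n_molecules, seed)
  data.frame(observed = observed_diversity(rep),
             chao1 = chao1(rep),
             normalized_shannon_wiener = normalized_shannon_wiener(rep),
             n_molecules = total_count(rep))
}
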