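hamming1_keys <- function(strings) {
  # one-position wildcard masks, length-stratified: two equal-length
  # strings are at Hamming distance <= 1 iff they share a mask
  lens <- nchar(strings)
  id <- rep.int(seq_along(strings), lens)
  pos <- sequence(lens)
  s <- strings[id]
  masked <- paste0(substr(s, 1L, pos - 1L), "\x01",
                   substring(s, pos + 1L))
  list(id = id, key = paste0(lens[id], ":", pos, ":", masked))
}

#' Count strings with a near-identical partner in another set
#'
#' Number of strings in `set_a` having at least one partner in `set_b` at
#' Hamming distance <= 1 (identical length, at most one substitution).
#' Each string in `set_a` is counted once regardless of how many partners
#' it has. Implemented by length-bucketed wildcard-mask hashing: the
#' index is built in O(N * L) and a 20,000 x 20,000 comparison completes
#' in seconds, returning exactly the brute-force nested-loop count.
#'
#' @param set_a,set_b character vectors of unique CDR3 amino-acid
#'   sequences (deduplicate clonesets first; see [publicity_matrix()])
#' @return integer count, directional (a matched in b)
#' @export
hamming1_match_count <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) return(0L)
  ka <- hamming1_keys(set_a)
  kb <- hamming1_keys(set_b)
  hit <- ka$key %in% kb$key
  length(unique(ka$id[hit]))
}

#' Cross-donor publicity of a subset's CDR3 repertoire
#'
#' For every unordered pair of donors, counts amino-acid-defined CDR3
#' variants shared with at most one mismatch between the two donors'
#' clonesets, each first truncated to its `top_n` most frequent
#' clonotypes and deduplicated on `cdr3aa` (publicity counts sequence
#' *variants*, not clonotypes). Because the directional counts can
#' differ, both are reported and `n_public` is their mean.
#'
#' @param reps named list of repertoires of one subset, one per donor
#'   (names default to donor ids)
#' @param top_n truncation depth, default 20000
#' @param max_mismatch 0 for exact matching, 1 (default) for the
#'   one-mismatch-tolerant count
#' @return data.frame: `subset`, `donor_a`, `donor_b`, `n_ab`, `n_ba`,
#'   `n_public`
#' @export
publicity_matrix <- function(reps, top_n = 20000L, max_mismatch = 1L) {
  if (length(reps) < 2L) stop("need at least 2 donors")
  if (is.null(names(reps)))
    names(reps) <- vapply(reps, attr, "", "donor_id")
  subset <- unique(vapply(reps, attr, "", "subset"))
  sets <- lapply(reps, function(r) unique(top_n_clonotypes(r, top_n)$cdr3aa))
  pairs <- utils::combn(length(sets), 2L)
  out <- apply(pairs, 2L, function(ij) {
    a <- sets[[ij[1L]]]; b <- sets[[ij[2L]]]
    if (max_mismatch == 0L) {
      nab <- sum(a %in% b); nba <- sum(b %in% a)
    } else {
      nab <- hamming1_match_count(a, b)
      nba <- hamming1_match_count(b, a)
    }
    data.frame(subset = paste(subset, collapse = "/"),
               donor_a = names(sets)[ij[1L]], donor_b = names(sets)[ij[2L]],
               n_ab = nab, n_ba = nba, n_public = (nab + nba) / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
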