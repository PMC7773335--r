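clonotype_key <- function(rep) paste(rep$v_gene, rep$cdr3nt, sep = "\r")

#' Clonotypes shared between two repertoires
#'
#' Nucleotide-level sharing: clonotypes match when both the V gene segment
#' and the CDR3 nucleotide sequence are identical.
#'
#' @param a,b repertoires of the same chain
#' @return data.frame with columns `v_gene`, `cdr3nt`, `freq_a`, `freq_b`
#' @export
shared_clonotypes <- function(a, b) {
  if (!identical(attr(a, "chain"), attr(b, "chain")))
    stop("chain mismatch: ", attr(a, "chain"), " vs ", attr(b, "chain"))
  ka <- clonotype_key(a); kb <- clonotype_key(b)
  ia <- which(ka %in% kb)
  m <- match(ka[ia], kb)
  data.frame(v_gene = a$v_gene[ia], cdr3nt = a$cdr3nt[ia],
             freq_a = a$freq[ia], freq_b = b$freq[m],
             stringsAsFactors = FALSE)
}

#' F2 overlap metric
#'
#' Frequency-weighted repertoire overlap: the sum over shared clonotypes
#' of the geometric mean of their frequencies,
#' `sum(sqrt(freq_a * freq_b))`. Equals 1 for identical (renormalized)
#' repertoires and 0 for disjoint ones. Typically computed after top-N
#' truncation (see [top_n_clonotypes()]).
#'
#' @param a,b repertoires of the same chain with normalized frequencies
#' @return value in \[0, 1\]
#' @export
overlap_f2 <- function(a, b) {
  sh <- shared_clonotypes(a, b)
  if (!nrow(sh)) return(0)
  sum(sqrt(sh$freq_a * sh$freq_b))
}

#' D overlap metric
#'
#' Relative overlap richness: the number of shared nucleotide-defined
#' clonotypes divided by the product of the two cloneset sizes,
#' `n_shared / (S_a * S_b)`. A small relative quantity, usually reported
#' in scientific notation.
#'
#' @param a,b nonempty repertoires of the same chain
#' @return nonnegative value
#' @export
overlap_d <- function(a, b) {
  if (!nrow(a) || !nrow(b)) stop("empty repertoire")
  nrow(shared_clonotypes(a, b)) / (nrow(a) * nrow(b))
}

#' Pairwise overlap over a set of repertoires
#'
#' Truncates every repertoire to its top `top_n` clonotypes, then reports
#' both overlap metrics for every unordered pair. Intended for the
#' subsets of one donor and one chain.
#'
#' @param reps named list of repertoires (names used as sample ids;
#'   defaults to their subset labels)
#' @param top_n truncation depth, default 20000
#' @return data.frame: `sample_a`, `sample_b`, `n_shared`, `f2`, `d`
#' @export
repertoire_overlap <- function(reps, top_n = 20000L) {
  if (length(reps) < 2L) stop("need at least 2 repertoires")
  if (is.null(names(reps)))
    names(reps) <- vapply(reps, attr, "", "subset")
  tr <- lapply(reps, top_n_clonotypes, n = top_n)
  pairs <- utils::combn(length(tr), 2L)
  out <- apply(pairs, 2L, function(ij) {
    a <- tr[[ij[1L]]]; b <- tr[[ij[2L]]]
    sh <- shared_clonotypes(a, b)
    data.frame(sample_a = names(tr)[ij[1L]], sample_b = names(tr)[ij[2L]],
               n_shared = nrow(sh),
               f2 = if (nrow(sh)) sum(sqrt(sh$freq_a * sh$freq_b)) else 0,
               d = nrow(sh) / (nrow(a) * nrow(b)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Clonotype-sharing network across the subsets of one donor
#'
#' After truncating each subset's cloneset to its `top_n` most frequent
#' clonotypes, builds the bubble-plot network: one node per clonotype
#' instance (subset, clonotype, frequency), with clonotypes present in
#' two or more subsets forming "clouds" — their instances are connected
#' pairwise and carry the arithmetic mean frequency across the maternal
#' subsets. With `focal` set, only clouds containing the focal subset are
#' retained (plus that subset's private nodes), mirroring
#' "only clonotypes shared with X" displays.
#'
#' @param reps list of >= 2 repertoires, same donor and chain
#' @param top_n per-subset truncation depth, default 2000
#' @param focal optional subset label to filter clouds on
#' @return list with `nodes` (id, subset, v_gene, cdr3nt, freq, shared,
#'   cloud_freq) and `edges` (source, target, v_gene, cdr3nt) data.frames,
#'   importable by common graph tools
#' @export
build_sharing_network <- function(reps, top_n = 2000L, focal = NULL) {
  if (length(reps) < 2L) stop("need at least 2 repertoires")
  subsets <- unname(vapply(reps, attr, "", "subset"))
  if (anyDuplicated(subsets)) stop("duplicate subset labels")
  chains <- unique(vapply(reps, attr, "", "chain"))
  donors <- unique(vapply(reps, attr, "", "donor_id"))
  if (length(chains) > 1L || length(donors) > 1L)
    stop("sharing network expects one donor and one chain")
  if (!is.null(focal) && !focal %in% subsets)
    stop("focal subset '", focal, "' not among repertoires")

  tr <- lapply(reps, top_n_clonotypes, n = top_n)
  nodes <- do.call(rbind, lapply(seq_along(tr), function(i) {
    r <- tr[[i]]
    data.frame(subset = subsets[i], v_gene = r$v_gene, cdr3nt = r$cdr3nt,
               freq = r$freq, stringsAsFactors = FALSE)
  }))
  key <- paste(nodes$v_gene, nodes$cdr3nt, sep = "\r")
  # cloud frequency = arithmetic mean across the subsets carrying the clonotype
  mean_by_key <- tapply(nodes$freq, key, mean)
  nodes$shared <- as.vector(table(key)[key]) >= 2L
  nodes$cloud_freq <- ifelse(nodes$shared, as.vector(mean_by_key[key]),
                             nodes$freq)
  nodes$id <- paste(nodes$subset, nodes$v_gene, nodes$cdr3nt, sep = "|")

  if (!is.null(focal)) {
    focal_keys <- key[nodes$subset == focal]
    keep <- nodes$subset == focal | (nodes$shared & key %in% focal_keys)
    nodes <- nodes[keep, , drop = FALSE]
    key <- key[keep]
    nodes$shared <- as.vector(table(key)[key]) >= 2L
  }

  edges <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), key), function(ix) {
    if (length(ix) < 2L) return(NULL)
    pr <- utils::combn(ix, 2L)
    data.frame(source = nodes$id[pr[1L, ]], target = nodes$id[pr[2L, ]],
               v_gene = nodes$v_gene[ix[1L]], cdr3nt = nodes$cdr3nt[ix[1L]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        v_gene = character(), cdr3nt = character(),
                        stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes[, c("id", "subset", "v_gene", "cdr3nt", "freq",
                         "shared", "cloud_freq")],
       edges = edges)
}
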