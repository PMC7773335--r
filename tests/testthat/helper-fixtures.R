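# Fixtures and independent brute-force oracles shared across test files.

NT <- c("A", "C", "G", "T")

random_nt <- function(n_codons) {
  paste(sample(NT, 3 * n_codons, replace = TRUE), collapse = "")
}

# a small well-formed repertoire with distinct in-frame clonotypes
make_rep <- function(counts, donor = "D1", subset = "Tfh", chain = "TRB",
                     seed = NULL, aa_len = 13L) {
  build <- function() {
    n <- length(counts)
    aa <- character(n); nt <- character(n)
    seen <- character()
    for (i in seq_len(n)) {
      repeat {
        s <- random_nt(aa_len)
        a <- tcrsubsets::translate_nt(s)
        if (!grepl("\\*", a) && !(s %in% seen)) break
      }
      seen <- c(seen, s)
      nt[i] <- s; aa[i] <- a
    }
    repertoire(data.frame(count = counts, cdr3nt = nt, cdr3aa = aa,
                          v_gene = sprintf("TRBV-sim-%02d", (seq_len(n) %% 7) + 1),
                          j_gene = "TRBJ-sim-01",
                          stringsAsFactors = FALSE),
               donor_id = donor, subset = subset, chain = chain) |>
      recompute_frequencies()
  }
  if (is.null(seed)) build() else with_seed_test(seed, build())
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# O(n*m) nested-loop sharing oracle on (v_gene, cdr3nt)
brute_shared <- function(a, b) {
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$v_gene[i] == b$v_gene[j] && a$cdr3nt[i] == b$cdr3nt[j]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# O(n*m*L) pairwise Hamming<=1 oracle (equal lengths only); character
# splits are precomputed once so the quadratic loop stays affordable
brute_hamming1_count <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  sa <- strsplit(set_a, ""); sb <- strsplit(set_b, "")
  lb <- lengths(sb)
  count <- 0L
  for (i in seq_along(sa)) {
    ca <- sa[[i]]
    found <- FALSE
    for (j in which(lb == length(ca))) {
      if (sum(ca != sb[[j]]) <= 1L) { found <- TRUE; break }
    }
    if (found) count <- count + 1L
  }
  count
}

random_aa_set <- function(n, len_range = 8:16) {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  unique(vapply(seq_len(n), function(i) {
    paste(sample(aas, sample(len_range, 1L), replace = TRUE), collapse = "")
  }, character(1)))
}
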