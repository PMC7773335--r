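#' @importFrom stats rpois runif rnorm sd shapiro.test t.test wilcox.test
#'   kruskal.test oneway.test prcomp rlnorm uniroot setNames rbinom
#' @importFrom utils head write.table
NULL

CLONOTYPE_COLUMNS <- c("count", "freq", "cdr3nt", "cdr3aa",
                       "v_gene", "d_gene", "j_gene",
                       "v_end", "d_start", "d_end", "j_start")

#' Construct a TCR repertoire
#'
#' A repertoire is an ordered cloneset for one (donor, subset, chain)
#' combination: a data.frame of clonotypes carrying UMI-derived molecule
#' counts, relative frequencies, CDR3 nucleotide and amino-acid sequences,
#' V/D/J segment calls and 0-based junction markers within the CDR3
#' nucleotide sequence (-1 meaning undefined).
#'
#' Duplicate (v_gene, cdr3nt) rows are merged by summing counts so that
#' nucleotide-defined clonotypes are unique within a repertoire; a message
#' reports how many rows were merged.
#'
#' @param clonotypes data.frame with at least columns `count`, `cdr3nt`,
#'   `cdr3aa`, `v_gene`. Missing optional columns (`freq`, `d_gene`,
#'   `j_gene`, junction markers) are filled with defaults. Extra columns
#'   are preserved.
#' @param donor_id,subset,chain repertoire metadata. `chain` is usually
#'   "TRA" or "TRB".
#' @param merge_duplicates merge rows sharing (v_gene, cdr3nt)? Default TRUE.
#' @return object of class `tcr_repertoire` (a data.frame).
#' @seealso [validate_repertoire()], [read_clonotype_table()]
#' @export
repertoire <- function(clonotypes, donor_id = "", subset = "", chain = "TRB",
                       merge_duplicates = TRUE) {
  df <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  need <- c("count", "cdr3nt", "cdr3aa", "v_gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clonotype table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$freq)) df$freq <- NA_real_
  if (is.null(df$d_gene)) df$d_gene <- ""
  if (is.null(df$j_gene)) df$j_gene <- ""
  for (m in c("v_end", "d_start", "d_end", "j_start"))
    if (is.null(df[[m]])) df[[m]] <- -1L
  df$count <- as.numeric(df$count)
  extra <- setdiff(names(df), CLONOTYPE_COLUMNS)
  df <- df[, c(CLONOTYPE_COLUMNS, extra), drop = FALSE]

  if (merge_duplicates && nrow(df)) {
    key <- paste(df$v_gene, df$cdr3nt, sep = "\r")
    if (anyDuplicated(key)) {
      ndup <- sum(duplicated(key))
      first <- !duplicated(key)
      agg <- rowsum(df$count, key, reorder = FALSE)
      out <- df[first, , drop = FALSE]
      out$count <- as.numeric(agg[match(key[first], rownames(agg)), 1L])
      df <- out
      message("merged ", ndup, " duplicate (v_gene, cdr3nt) row(s)")
    }
  }
  rownames(df) <- NULL
  structure(df,
            donor_id = as.character(donor_id),
            subset = as.character(subset),
            chain = as.character(chain),
            class = c("tcr_repertoire", "data.frame"))
}

new_repertoire_like <- function(df, template) {
  rownames(df) <- NULL
  structure(as.data.frame(df),
            donor_id = attr(template, "donor_id"),
            subset = attr(template, "subset"),
            chain = attr(template, "chain"),
            class = c("tcr_repertoire", "data.frame"))
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> donor=%s subset=%s chain=%s: %d clonotypes, %s molecules\n",
              attr(x, "donor_id"), attr(x, "subset"), attr(x, "chain"),
              nrow(x), format(total_count(x), big.mark = ",")))
  if (nrow(x)) print(head(as.data.frame(x), 6L), ...)
  invisible(x)
}

#' Total molecule count of a repertoire
#' @param rep a `tcr_repertoire`
#' @return sum of clonotype counts
#' @export
total_count <- function(rep) sum(rep$count)

#' Recompute clonotype frequencies
#'
#' Sets `freq_i = count_i / sum(count)`. Idempotent.
#'
#' @param rep a `tcr_repertoire` with positive total count
#' @return the repertoire with frequencies summing to 1
#' @export
recompute_frequencies <- function(rep) {
  if (!nrow(rep)) stop("cannot recompute frequencies of an empty repertoire")
  tot <- sum(rep$count)
  if (tot <= 0) stop("total count must be positive")
  rep$freq <- rep$count / tot
  rep
}

#' Translate CDR3 nucleotide sequences
#'
#' Standard-genetic-code translation implemented as a codon-table lookup
#' (the table is `Biostrings::GENETIC_CODE`). Sequences whose length is
#' not a multiple of 3 give `NA`.
#'
#' @param nt character vector of DNA sequences over A/C/G/T
#' @return character vector of amino-acid sequences ('*' = stop)
#' @export
translate_nt <- function(nt) {
  gc_tab <- Biostrings::GENETIC_CODE
  vapply(nt, function(s) {
    n <- nchar(s)
    if (is.na(s) || n == 0L || n %% 3L != 0L) return(NA_character_)
    cod <- substring(toupper(s), seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- gc_tab[cod]
    if (anyNA(aa)) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_in_frame <- function(rep) {
  nchar(rep$cdr3nt) %% 3L == 0L & !grepl("[*_]", rep$cdr3aa, perl = TRUE)
}

#' Validate a repertoire against the type invariants
#'
#' Checks, without throwing: counts >= 1; frequencies in \[0,1\] and summing
#' to 1 (tolerance 1e-6); junction marker ordering
#' `v_end <= d_start <= d_end <= j_start` when all four are defined and
#' marker ranges within the CDR3 nucleotide sequence; uniqueness of
#' (v_gene, cdr3nt); and, for in-frame records, agreement between the
#' translated `cdr3nt` and `cdr3aa`.
#'
#' @param rep a `tcr_repertoire`
#' @return data.frame with columns `index` (clonotype row, NA for
#'   repertoire-level issues), `rule`, `message`; zero rows iff valid.
#' @export
validate_repertoire <- function(rep) {
  issues <- list()
  add <- function(index, rule, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      index = index, rule = rule, message = msg, stringsAsFactors = FALSE)
  if (!nrow(rep))
    return(data.frame(index = integer(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))

  bad <- which(is.na(rep$count) | rep$count < 1)
  for (i in bad) add(i, "count", "count must be >= 1")
  bad <- which(!is.na(rep$freq) & (rep$freq < 0 | rep$freq > 1))
  for (i in bad) add(i, "freq_range", "freq outside [0, 1]")
  fs <- sum(rep$freq)
  if (is.na(fs) || abs(fs - 1) > 1e-6)
    add(NA_integer_, "frequency normalization",
        sprintf("frequencies sum to %.6g, expected 1", fs))

  key <- paste(rep$v_gene, rep$cdr3nt, sep = "\r")
  for (i in which(duplicated(key)))
    add(i, "duplicate_key", "duplicate (v_gene, cdr3nt)")

  m <- rep[, c("v_end", "d_start", "d_end", "j_start")]
  alldef <- rowSums(m >= 0) == 4L
  ord_bad <- which(alldef &
                   !(m$v_end <= m$d_start & m$d_start <= m$d_end &
                     m$d_end <= m$j_start))
  for (i in ord_bad) add(i, "marker_order",
                         "junction markers violate v_end <= d_start <= d_end <= j_start")
  ntlen <- nchar(rep$cdr3nt)
  rng_bad <- which(apply(m, 1L, max) >= ntlen | (m$j_start >= 0 & m$j_start >= ntlen))
  rng_bad <- which((pmax(m$v_end, m$d_start, m$d_end, m$j_start) >= ntlen))
  for (i in rng_bad) add(i, "marker_range", "junction marker beyond cdr3nt length")

  inf <- is_in_frame(rep)
  if (any(inf)) {
    tr <- translate_nt(rep$cdr3nt[inf])
    mism <- which(inf)[!is.na(tr) & tr != rep$cdr3aa[inf]]
    for (i in mism) add(i, "translation mismatch",
                        "translated cdr3nt differs from cdr3aa")
  }
  if (!length(issues))
    return(data.frame(index = integer(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
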