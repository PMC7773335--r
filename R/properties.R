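the <- new.env(parent = emptyenv())

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Amino-acid property table
#'
#' Returns the packaged table of amino-acid property scales used for CDR3
#' middle-region scoring: the ten Kidera factors (`kf1`..`kf10`),
#' contact-energy-derived `strength` and `mjenergy`, interface/conformation
#' propensities (`core`, `rim`, `surface`, `alpha`, `beta`, `turn`,
#' `disorder`), residue `volume`, `polarity`, `charge` at pH 7 and
#' Kyte-Doolittle `hydropathy`. Rows are the 20 standard amino acids.
#'
#' Column provenance is recorded in the commented header of the shipped
#' resource (`inst/extdata/aa_property_table.tsv`). Note that `core`,
#' `rim` and `surface` are synthetic stand-ins for interface propensities
#' whose published source was not available when the resource was built;
#' see the package vignette.
#'
#' @return data.frame with rownames A..V and one column per scale
#' @export
aa_property_table <- function() {
  if (is.null(the$prop_table)) {
    path <- system.file("extdata", "aa_property_table.tsv",
                        package = "tcrsubsets", mustWork = TRUE)
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             comment.char = "#", stringsAsFactors = FALSE)
    rownames(tab) <- tab$aa
    tab$aa <- NULL
    stopifnot(all(AA20 %in% rownames(tab)), !anyNA(tab))
    the$prop_table <- tab[AA20, , drop = FALSE]
  }
  the$prop_table
}

#' Middle region of a CDR3 amino-acid sequence
#'
#' For sequences of length >= k, the contiguous substring of length `k`
#' starting at offset `floor((len - k) / 2)` (left-biased when the
#' overhang is odd); shorter sequences are returned whole rather than
#' dropped. These central residues dominate TCR contacts with the peptide
#' component of peptide-MHC.
#'
#' @param cdr3aa character vector of amino-acid sequences
#' @param k window length, default 5
#' @return character vector of middle regions
#' @export
middle_region <- function(cdr3aa, k = 5L) {
  if (any(is.na(cdr3aa) | cdr3aa == ""))
    stop("empty or NA CDR3 amino-acid sequence")
  bad <- regexpr(sprintf("[^%s*_]", paste(AA20, collapse = "")), cdr3aa)
  if (any(bad > 0L))
    stop(sprintf("non-standard character at position %d of '%s'",
                 bad[bad > 0L][1L], cdr3aa[bad > 0L][1L]))
  len <- nchar(cdr3aa)
  start <- ifelse(len >= k, (len - k) %/% 2L + 1L, 1L)
  substr(cdr3aa, start, start + pmin(len, k) - 1L)
}

#' Per-clonotype physicochemical property of the CDR3 middle region
#'
#' Arithmetic mean of the named scale over the residues of
#' `middle_region(cdr3aa, k)`.
#'
#' @param cdr3aa character vector of CDR3 amino-acid sequences
#' @param scale scale name, a column of `table`
#' @param table property table, default [aa_property_table()]
#' @param k middle-region length, default 5
#' @return numeric vector of property scores
#' @export
clonotype_property <- function(cdr3aa, scale, table = aa_property_table(),
                               k = 5L) {
  if (!scale %in% colnames(table))
    stop("unknown scale '", scale, "'; available: ",
         paste(colnames(table), collapse = ", "))
  vals <- setNames(table[[scale]], rownames(table))
  mid <- middle_region(cdr3aa, k)
  chars <- strsplit(mid, "", fixed = TRUE)
  lens <- nchar(mid)
  v <- vals[unlist(chars, use.names = FALSE)]
  grp <- rep.int(seq_along(mid), lens)
  as.vector(rowsum(v, grp, reorder = TRUE) / lens)
}

#' Repertoire-averaged CDR3 property
#'
#' Frequency-weighted (default) or unweighted average of
#' [clonotype_property()] over a repertoire. The weighted form,
#' `sum(freq_i * x_i)`, equals the per-molecule mean.
#'
#' @param rep a [repertoire()]
#' @param scale scale name
#' @param table property table
#' @param weighted weight by clonotype frequency? Default TRUE.
#' @param k middle-region length
#' @return a single numeric value
#' @export
repertoire_property_average <- function(rep, scale,
                                        table = aa_property_table(),
                                        weighted = TRUE, k = 5L) {
  if (!nrow(rep)) stop("empty repertoire")
  x <- clonotype_property(rep$cdr3aa, scale, table, k)
  if (weighted) {
    w <- rep$count / sum(rep$count)
    sum(w * x)
  } else mean(x)
}
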