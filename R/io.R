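VDJTOOLS_COLUMNS <- c("count", "freq", "cdr3nt", "cdr3aa",
                      "v", "d", "j", "VEnd", "DStart", "DEnd", "JStart")
AIRR_COLUMNS <- c("sequence_id", "duplicate_count", "freq",
                  "junction", "junction_aa",
                  "v_call", "d_call", "j_call",
                  "v_end", "d_start", "d_end", "j_start")

norm_gene <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "."] <- ""
  x
}
norm_marker <- function(x) {
  x <- suppressWarnings(as.integer(as.character(x)))
  x[is.na(x)] <- -1L
  x
}

#' Read a clonotype table
#'
#' Reads one tab-separated clonotype table in either the VDJtools-style
#' dialect (columns `count freq cdr3nt cdr3aa v d j VEnd DStart DEnd
#' JStart`) or AIRR Rearrangement TSV (columns `junction`, `junction_aa`,
#' `v_call`, `d_call`, `j_call`, `duplicate_count`, plus optional custom
#' junction-marker columns written by [write_clonotype_table()]).
#'
#' Records with an empty CDR3 nucleotide sequence are dropped with a
#' message. Missing segment calls encoded as "." or "" and missing markers
#' are normalized to `""` / `-1`. Row order in the file is preserved;
#' duplicate (v_gene, cdr3nt) rows are merged by summing counts.
#'
#' @param path file path
#' @param dialect `"vdjtools"` or `"airr"`
#' @param donor_id,subset,chain metadata attached to the repertoire
#' @return a [repertoire()]
#' @export
read_clonotype_table <- function(path, dialect = c("vdjtools", "airr"),
                                 donor_id = "", subset = "", chain = "TRB") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  req <- if (dialect == "vdjtools")
    c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j")
  else c("duplicate_count", "junction", "junction_aa",
         "v_call", "d_call", "j_call")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("format error (", dialect, "): missing required column(s): ",
         paste(miss, collapse = ", "))

  if (dialect == "vdjtools") {
    cnt_raw <- dt$count
    df <- data.frame(count = suppressWarnings(as.numeric(as.character(cnt_raw))),
                     freq = suppressWarnings(as.numeric(as.character(dt$freq))),
                     cdr3nt = toupper(as.character(dt$cdr3nt)),
                     cdr3aa = as.character(dt$cdr3aa),
                     v_gene = norm_gene(dt$v), d_gene = norm_gene(dt$d),
                     j_gene = norm_gene(dt$j),
                     v_end = if ("VEnd" %in% names(dt)) norm_marker(dt$VEnd) else -1L,
                     d_start = if ("DStart" %in% names(dt)) norm_marker(dt$DStart) else -1L,
                     d_end = if ("DEnd" %in% names(dt)) norm_marker(dt$DEnd) else -1L,
                     j_start = if ("JStart" %in% names(dt)) norm_marker(dt$JStart) else -1L,
                     stringsAsFactors = FALSE)
    extra <- setdiff(names(dt), VDJTOOLS_COLUMNS)
  } else {
    cnt_raw <- dt$duplicate_count
    df <- data.frame(count = suppressWarnings(as.numeric(as.character(cnt_raw))),
                     freq = if ("freq" %in% names(dt))
                       suppressWarnings(as.numeric(as.character(dt$freq))) else NA_real_,
                     cdr3nt = toupper(as.character(dt$junction)),
                     cdr3aa = as.character(dt$junction_aa),
                     v_gene = norm_gene(dt$v_call), d_gene = norm_gene(dt$d_call),
                     j_gene = norm_gene(dt$j_call),
                     v_end = if ("v_end" %in% names(dt)) norm_marker(dt$v_end) else -1L,
                     d_start = if ("d_start" %in% names(dt)) norm_marker(dt$d_start) else -1L,
                     d_end = if ("d_end" %in% names(dt)) norm_marker(dt$d_end) else -1L,
                     j_start = if ("j_start" %in% names(dt)) norm_marker(dt$j_start) else -1L,
                     stringsAsFactors = FALSE)
    extra <- setdiff(names(dt), AIRR_COLUMNS)
  }
  badcnt <- which(is.na(df$count) & !is.na(cnt_raw) & cnt_raw != "")
  if (length(badcnt))
    stop("non-numeric count at data line(s): ",
         paste(head(badcnt, 5L), collapse = ", "))
  for (e in extra) df[[e]] <- dt[[e]]

  empty <- is.na(df$cdr3nt) | df$cdr3nt == ""
  if (any(empty)) {
    message("dropped ", sum(empty), " record(s) with empty CDR3")
    df <- df[!empty, , drop = FALSE]
  }
  rp <- repertoire(df, donor_id = donor_id, subset = subset, chain = chain)
  if (all(is.na(rp$freq))) rp <- recompute_frequencies(rp)
  rp
}

#' Write a clonotype table
#'
#' Serializes a repertoire back to TSV in the requested dialect with a
#' fixed column order. Counts are written losslessly and frequencies at
#' full double precision (>= 15 significant digits), so
#' `read_clonotype_table()` on the result reproduces the repertoire.
#'
#' @param rep a [repertoire()]
#' @param path output file path
#' @param dialect `"vdjtools"` or `"airr"`
#' @export
write_clonotype_table <- function(rep, path, dialect = c("vdjtools", "airr")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(rep)
  extra <- setdiff(names(df), CLONOTYPE_COLUMNS)
  if (dialect == "vdjtools") {
    out <- data.frame(count = df$count, freq = df$freq,
                      cdr3nt = df$cdr3nt, cdr3aa = df$cdr3aa,
                      v = df$v_gene, d = df$d_gene, j = df$j_gene,
                      VEnd = df$v_end, DStart = df$d_start,
                      DEnd = df$d_end, JStart = df$j_start,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(sequence_id = if (nrow(df))
                        sprintf("clonotype-%06d", seq_len(nrow(df))) else character(),
                      duplicate_count = df$count, freq = df$freq,
                      junction = df$cdr3nt, junction_aa = df$cdr3aa,
                      v_call = df$v_gene, d_call = df$d_gene,
                      j_call = df$j_gene,
                      v_end = df$v_end, d_start = df$d_start,
                      d_end = df$d_end, j_start = df$j_start,
                      stringsAsFactors = FALSE)
  }
  for (e in extra) out[[e]] <- df[[e]]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n",
                     showProgress = FALSE)
  invisible(path)
}
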