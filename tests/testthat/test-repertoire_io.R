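test_that("repertoire construction enforces the data model", {
  df <- data.frame(count = c(6, 3, 1),
                   cdr3nt = c("TGTGCCAGCAGCTTC", "TGTGCCAGCAGCTTT",
                              "TGTGCCAGTAGCTTC"),
                   cdr3aa = c("CASSF", "CASSF", "CASSF"),
                   v_gene = c("V1", "V2", "V3"))
  r <- recompute_frequencies(repertoire(df))
  expect_s3_class(r, "tcr_repertoire")
  expect_equal(total_count(r), 10)
  expect_equal(r$freq, c(0.6, 0.3, 0.1))
  expect_equal(r$v_end, rep(-1L, 3))
  expect_identical(nrow(validate_repertoire(r)), 0L)

  expect_error(repertoire(data.frame(count = 1)), "required column")

  # duplicate (v_gene, cdr3nt) rows merge by summing counts
  dup <- df
  dup$v_gene <- "V1"
  dup$cdr3nt <- dup$cdr3nt[1]
  expect_message(r2 <- repertoire(dup), "merged 2")
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$count, 10)
})

test_that("translation follows the standard genetic code (61 sense codons)", {
  codons <- apply(expand.grid(NT, NT, NT), 1, paste, collapse = "")
  oracle <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAStringSet(cd),
                                       no.init.codon = TRUE)),
    character(1), USE.NAMES = FALSE)
  sense <- oracle != "*"
  expect_equal(translate_nt(codons[sense]), oracle[sense])
  expect_equal(sum(sense), 61L)
  # multi-codon and frame handling
  expect_equal(translate_nt("TGTGCCAGCAGCTTC"), "CASSF")
  expect_true(is.na(translate_nt("TGTG")))
})

test_that("validation flags broken invariants without throwing", {
  r <- make_rep(c(5, 3, 2), seed = 11)
  bad <- r
  bad$freq <- bad$freq * 0.8
  iss <- validate_repertoire(bad)
  expect_true("frequency normalization" %in% iss$rule)

  bad2 <- r
  bad2$cdr3aa[2] <- paste0(substr(bad2$cdr3aa[2], 1, nchar(bad2$cdr3aa[2]) - 1), "W")
  iss2 <- validate_repertoire(bad2)
  expect_true(any(iss2$rule == "translation mismatch" & iss2$index == 2))

  bad3 <- r
  bad3$count[1] <- 0
  expect_true("count" %in% validate_repertoire(bad3)$rule)

  bad4 <- r
  bad4$v_end <- 5L; bad4$d_start <- 3L; bad4$d_end <- 8L; bad4$j_start <- 12L
  expect_true("marker_order" %in% validate_repertoire(bad4)$rule)
})

test_that("vdjtools dialect round-trips and preserves order", {
  r <- make_rep(c(9, 7, 7, 2, 1), seed = 21)
  r$v_end <- c(3L, 4L, 5L, -1L, 3L)
  r$j_start <- c(10L, 11L, 12L, -1L, 9L)
  r$extra_note <- letters[1:5]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(r, f, "vdjtools")
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr[1:11], c("count", "freq", "cdr3nt", "cdr3aa", "v", "d",
                                "j", "VEnd", "DStart", "DEnd", "JStart"))
  r2 <- read_clonotype_table(f, "vdjtools", donor_id = "D1", subset = "Tfh")
  expect_equal(as.data.frame(r2), as.data.frame(r), ignore_attr = TRUE)
  # second round trip is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(r2, f2, "vdjtools")
  expect_identical(readLines(f), readLines(f2))
})

test_that("airr dialect maps Rearrangement columns onto the model", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tduplicate_count\tjunction\tjunction_aa\tv_call\td_call\tj_call",
               "c1\t6\tTGTGCCAGCAGCTTC\tCASSF\tTRBV9\t\tTRBJ1-1",
               "c2\t4\tTGTGCCAGCAGCTTT\tCASSF\tTRBV9\t.\tTRBJ1-2"), f)
  r <- read_clonotype_table(f, "airr")
  expect_equal(r$cdr3nt, c("TGTGCCAGCAGCTTC", "TGTGCCAGCAGCTTT"))
  expect_equal(r$cdr3aa, c("CASSF", "CASSF"))
  expect_equal(r$count, c(6, 4))
  expect_equal(r$freq, c(0.6, 0.4))
  expect_equal(r$d_gene, c("", ""))  # "." and empty both normalize

  r2 <- make_rep(c(5, 4, 1), seed = 31)
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(r2, fa, "airr")
  hdr <- strsplit(readLines(fa, n = 1), "\t")[[1]]
  expect_true(all(c("duplicate_count", "junction", "junction_aa", "v_call",
                    "d_call", "j_call") %in% hdr))
  r3 <- read_clonotype_table(fa, "airr")
  expect_equal(r3$cdr3nt, r2$cdr3nt)
  expect_equal(r3$count, r2$count)
  expect_equal(r3$v_end, r2$v_end)
})

test_that("reader errors and record dropping behave as specified", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("count\tfreq\tcdr3aa\tv\td\tj", "1\t1\tCASSF\tV1\t\tJ1"), f)
  expect_error(read_clonotype_table(f, "vdjtools"), "cdr3nt")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("count\tfreq\tcdr3nt\tcdr3aa\tv\td\tj",
               "6\t0.6\tTGTGCCAGCAGCTTC\tCASSF\tV1\t\tJ1",
               "oops\t0.4\tTGTGCCAGCAGCTTT\tCASSF\tV2\t\tJ1"), f2)
  expect_error(read_clonotype_table(f2, "vdjtools"), "non-numeric count")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("count\tfreq\tcdr3nt\tcdr3aa\tv\td\tj",
               "6\t0.6\tTGTGCCAGCAGCTTC\tCASSF\tV1\t\tJ1",
               "4\t0.4\t\t\tV2\t\tJ1"), f3)
  expect_message(r <- read_clonotype_table(f3, "vdjtools"), "dropped 1")
  expect_equal(nrow(r), 1L)

  # empty repertoire writes a header-only file
  e <- make_rep(c(2, 1), seed = 41)[0, ]
  fe <- withr::local_tempfile(fileext = ".tsv")
  write_clonotype_table(repertoire(e), fe, "vdjtools")
  expect_length(readLines(fe), 1L)
})
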