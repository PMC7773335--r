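toy_scale <- local({
  tab <- data.frame(row.names = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  tab$toy <- 0
  tab["L", "toy"] <- 1; tab["G", "toy"] <- 2; tab["Q", "toy"] <- 3
  tab["A", "toy"] <- 4; tab["Y", "toy"] <- 5
  tab
})

test_that("middle_region uses the left-biased floor convention", {
  expect_equal(middle_region("CASSLGQAYEQYF"), "LGQAY")   # len 13
  expect_equal(middle_region("CASSLGQAYEQF"), "SLGQA")    # len 12, offset 3
  expect_equal(middle_region("CASF"), "CASF")             # shorter than k
  expect_equal(middle_region("CASSF", k = 5), "CASSF")
  expect_equal(middle_region(c("CASSLGQAYEQYF", "CASF")), c("LGQAY", "CASF"))
  expect_error(middle_region("CASBX"), "position 4")
  expect_error(middle_region(""), "empty")
})

test_that("clonotype_property averages the middle-region residues", {
  expect_equal(clonotype_property("LGQAY", "toy", toy_scale), 3.0)
  # homopolymer returns the residue value on any scale
  tab <- aa_property_table()
  for (s in c("kf4", "strength", "volume")) {
    expect_equal(clonotype_property("AAAAAAA", s, tab), tab["A", s])
  }
  # value depends only on the middle region: mutate the flanks
  expect_equal(clonotype_property("CASSLGQAYEQYF", "toy", toy_scale),
               clonotype_property("WWWWLGQAYWWWW", "toy", toy_scale))
  expect_error(clonotype_property("CASSF", "nope", toy_scale), "available")
})

test_that("repertoire averages match the per-molecule brute-force oracle", {
  df <- data.frame(count = c(3, 1),
                   cdr3nt = c("TGT", "TGT"), cdr3aa = c("LLLLL", "YYYYY"),
                   v_gene = c("V1", "V2"))
  r <- recompute_frequencies(repertoire(df, merge_duplicates = FALSE))
  # freqs .75/.25, values 1/5 on toy scale
  expect_equal(repertoire_property_average(r, "toy", toy_scale), 2.0)
  expect_equal(repertoire_property_average(r, "toy", toy_scale,
                                           weighted = FALSE), 3.0)

  big <- make_rep(sample(1:20, 300, replace = TRUE), seed = 13)
  tab <- aa_property_table()
  for (s in c("kf1", "strength", "hydropathy")) {
    oracle <- mean(rep(clonotype_property(big$cdr3aa, s, tab), big$count))
    expect_equal(repertoire_property_average(big, s, tab), oracle)
  }
  # invariant under reordering and count rescaling
  perm <- sample(nrow(big))
  shuffled <- repertoire(as.data.frame(big)[perm, ], merge_duplicates = FALSE)
  expect_equal(repertoire_property_average(shuffled, "kf1", tab),
               repertoire_property_average(big, "kf1", tab))
  scaled <- big; scaled$count <- big$count * 7
  expect_equal(repertoire_property_average(scaled, "kf1", tab),
               repertoire_property_average(big, "kf1", tab))
  # convexity: weighted average within [min, max] of clonotype values
  vals <- clonotype_property(big$cdr3aa, "kf1", tab)
  avg <- repertoire_property_average(big, "kf1", tab)
  expect_gte(avg, min(vals)); expect_lte(avg, max(vals))
})

test_that("junction insertion arithmetic matches the marker definitions", {
  mk <- function(v_end, d_start, d_end, j_start, ntlen = 45L) {
    repertoire(data.frame(count = 1, cdr3nt = strrep("A", ntlen),
                          cdr3aa = strrep("K", ntlen / 3), v_gene = "V1",
                          v_end = v_end, d_start = d_start,
                          d_end = d_end, j_start = j_start))
  }
  ji <- junction_insertions(mk(10L, 13L, 20L, 23L))
  expect_equal(unlist(ji), c(ndn_length = 12, n_insertions = 4,
                             vdins = 2, djins = 2))
  # abutting V and J, no D
  ji2 <- junction_insertions(mk(10L, -1L, -1L, 11L))
  expect_equal(ji2$ndn_length, 0)
  expect_equal(ji2$n_insertions, 0)
  expect_true(is.na(ji2$vdins) && is.na(ji2$djins))
  # chewback overlap clamps to zero
  ji3 <- junction_insertions(mk(10L, 9L, 20L, 23L))
  expect_equal(ji3$vdins, 0)
  # undefined v_end/j_start gives missing values
  ji4 <- junction_insertions(mk(-1L, -1L, -1L, -1L))
  expect_true(all(is.na(ji4)))
  # markers beyond the sequence are a validation error
  expect_error(junction_insertions(mk(10L, 13L, 20L, 60L)), "beyond")
  # n_insertions <= ndn_length whenever D is defined
  co <- generate_cohort(generator_config(n_donors = 1, subsets = "Th1",
                                         clones_per_subset = 400, seed = 9))
  ji5 <- junction_insertions(co$repertoires[[1]])
  ok <- !is.na(ji5$vdins)
  expect_true(all(ji5$n_insertions[ok] <= ji5$ndn_length[ok]))
})

test_that("cdr3_length counts in both units", {
  r <- repertoire(data.frame(count = 1, cdr3nt = "TGTGCCAGCAGCTTC",
                             cdr3aa = "CASSF", v_gene = "V1"))
  expect_equal(cdr3_length(r, "aa"), 5L)
  expect_equal(cdr3_length(r, "nt"), 15L)
  co <- generate_cohort(generator_config(n_donors = 1, subsets = "Th1",
                                         clones_per_subset = 100, seed = 2))
  r2 <- co$repertoires[[1]]
  expect_equal(cdr3_length(r2, "nt"), 3L * cdr3_length(r2, "aa"))
})

test_that("the feature vector has 28 parameters with the stated invariances", {
  co <- generate_cohort(generator_config(n_donors = 1, subsets = "Th1",
                                         clones_per_subset = 200, seed = 4))
  r <- co$repertoires[[1]]
  fv <- feature_vector(r)
  expect_length(fv, 28L)
  expect_true(all(is.finite(fv)))
  expect_named(fv, tcrsubsets:::FEATURE_NAMES)

  # one clonotype: the vector equals the clonotype's raw parameters
  one <- repertoire(as.data.frame(r)[1, ], merge_duplicates = FALSE)
  fv1 <- feature_vector(recompute_frequencies(one))
  expect_equal(fv1[["cdr3_length"]], nchar(one$cdr3nt))
  expect_equal(fv1[["kf4"]], clonotype_property(one$cdr3aa, "kf4"))

  # doubling every count leaves the vector unchanged
  dbl <- r; dbl$count <- r$count * 2
  expect_equal(feature_vector(recompute_frequencies(dbl)), fv)

  # identical repertoires give identical vectors
  expect_equal(feature_vector(r), fv)
})
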