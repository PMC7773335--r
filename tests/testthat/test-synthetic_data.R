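test_that("generator configuration is validated", {
  expect_error(generator_config(sharing_matrix = matrix(0, 2, 2)),
               "square subset x subset")
  sm <- matrix(0.5, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(generator_config(subsets = c("A", "B"), sharing_matrix = sm),
               "diagonal")
  expect_error(generator_config(public_fraction = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(composition_bias = list(Zz = c(kf4 = 1))),
               "unknown subset")
  expect_error(generator_config(subsets = c("A", "B"), public_fraction = 0.5,
                                public_pool_size = 2,
                                clones_per_subset = 1000) |> generate_cohort(),
               "infeasible")
})

test_that("the cohort is deterministic given the seed", {
  cfg <- generator_config(n_donors = 2, subsets = c("Tfh", "Treg"),
                          clones_per_subset = 150, public_fraction = 0.1,
                          seed = 33)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  # and writes byte-identical tables
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_clonotype_table(c1$repertoires[[1]], f1, "vdjtools")
  write_clonotype_table(c2$repertoires[[1]], f2, "vdjtools")
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- generator_config(n_donors = 2, subsets = c("Tfh", "Treg"),
                           clones_per_subset = 150, public_fraction = 0.1,
                           seed = 34)
  expect_false(identical(generate_cohort(cfg2), c1))
})

test_that("generated repertoires satisfy all io invariants", {
  co <- generate_cohort(generator_config(n_donors = 2,
                                         subsets = c("Th1", "Th22"),
                                         clones_per_subset = 250,
                                         sharing_matrix = matrix(c(0, .1, .1, 0), 2,
                                           dimnames = list(c("Th1", "Th22"),
                                                           c("Th1", "Th22"))),
                                         public_fraction = 0.05, seed = 17))
  for (r in co$repertoires) {
    expect_identical(nrow(validate_repertoire(r)), 0L)
    expect_true(all(is_in_frame <- nchar(r$cdr3nt) %% 3 == 0))
    expect_equal(translate_nt(r$cdr3nt), r$cdr3aa)
  }
})

test_that("nothing planted means nothing found", {
  co <- generate_cohort(generator_config(n_donors = 2,
                                         subsets = c("Tfh", "Treg"),
                                         clones_per_subset = 200, seed = 21))
  r <- co$repertoires
  expect_equal(nrow(co$ledger$shared), 0L)
  expect_equal(nrow(co$ledger$public), 0L)
  # within-donor sharing is absent (random 13-mers virtually never collide,
  # and the generator plants none)
  expect_equal(nrow(shared_clonotypes(r[["D1|Tfh"]], r[["D1|Treg"]])), 0L)
  # and exact-match cross-donor publicity is zero
  pub <- publicity_matrix(list(D1 = r[["D1|Tfh"]], D2 = r[["D2|Tfh"]]),
                          max_mismatch = 0L)
  expect_equal(pub$n_public, 0)
})

test_that("planted sharing and publicity are recovered from the ledger", {
  subsets <- c("Th17", "Th22")
  sm <- matrix(c(0, 0.2, 0, 0), 2, byrow = TRUE,
               dimnames = list(subsets, subsets))
  co <- generate_cohort(generator_config(n_donors = 2, subsets = subsets,
                                         clones_per_subset = 300,
                                         sharing_matrix = sm,
                                         public_fraction = 0.15, seed = 22))
  led <- co$ledger$shared
  expect_gt(nrow(led), 0L)
  for (d in c("D1", "D2")) {
    sh <- shared_clonotypes(co$repertoires[[paste0(d, "|Th17")]],
                            co$repertoires[[paste0(d, "|Th22")]])
    planted <- led[led$donor_id == d, ]
    # every planted copy is recovered by shared_clonotypes
    expect_true(all(paste(planted$v_gene, planted$cdr3nt) %in%
                    paste(sh$v_gene, sh$cdr3nt)))
  }
  # planted public variants match exactly across donors (distance 0)
  pub <- co$ledger$public
  expect_gt(nrow(pub), 0L)
  a1 <- pub$cdr3aa[pub$donor_id == "D1" & pub$subset == "Th17"]
  r2 <- unique(co$repertoires[["D2|Th17"]]$cdr3aa)
  common_pool <- intersect(a1, pub$cdr3aa[pub$donor_id == "D2" &
                                          pub$subset == "Th17"])
  expect_true(all(common_pool %in% r2))
  expect_gte(hamming1_match_count(unique(a1), r2), length(common_pool))
})

test_that("composition bias shifts the middle-5 property mean by delta", {
  delta <- 0.5
  co <- generate_cohort(generator_config(
    n_donors = 1, subsets = c("Tfh", "Treg"), clones_per_subset = 3000,
    composition_bias = list(Treg = c(strength = delta)), seed = 23))
  tab <- aa_property_table()
  m_tfh <- repertoire_property_average(co$repertoires[["D1|Tfh"]], "strength")
  m_trg <- repertoire_property_average(co$repertoires[["D1|Treg"]], "strength")
  tgt <- co$ledger$property_targets
  expect_equal(tgt$expected_mean - co$ledger$base_property_means[["strength"]],
               delta, tolerance = 1e-9)
  # wide tolerance here; the 20-seed 3-SE recovery lives in the acceptance suite
  expect_equal(m_trg - m_tfh, delta, tolerance = 0.2)
})

test_that("tilt_weights hits the requested mean exactly and monotonically", {
  tab <- aa_property_table()
  s <- setNames(tab$strength, rownames(tab))
  for (d in c(-0.8, -0.2, 0.3, 1.0)) {
    tw <- tilt_weights(s, d)
    expect_equal(sum(tw$weights * s), mean(s) + d, tolerance = 1e-9)
    expect_equal(sum(tw$weights), 1)
  }
  expect_gt(tilt_weights(s, 0.6)$beta, tilt_weights(s, 0.1)$beta)
  expect_error(tilt_weights(s, 100), "outside the achievable range")
})

test_that("plant_expansion reshapes frequencies as requested", {
  r <- make_rep(rep(10, 1000), seed = 24)
  ex <- plant_expansion(r, k = 1L, mass = 0.5)
  expect_equal(max(ex$freq), 0.5, tolerance = 2e-3)  # 0.5 + residual share
  expect_lt(normalized_shannon_wiener(ex), normalized_shannon_wiener(r))
  # continuity: vanishing mass leaves the repertoire essentially unchanged
  tiny <- plant_expansion(r, k = 1L, mass = 1e-7)
  expect_lt(max(abs(tiny$freq - 1 / 1000)), 1e-6)
  expect_error(plant_expansion(r, k = 1L, mass = 1), "\\(0, 1\\)")
  # evenness drops across seeds whenever the planted mass dominates
  for (s in 25:29) {
    rr <- make_rep(sample(5:15, 300, replace = TRUE), seed = s)
    expect_lt(normalized_shannon_wiener(plant_expansion(rr, 3L, 0.6)),
              normalized_shannon_wiener(rr))
  }
})
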