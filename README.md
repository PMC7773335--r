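# tcrsubsets

Repertoire-level comparison of T-cell receptor (TCR) clonesets across
flow-sorted T-cell subsets and donors.

## The problem

High-throughput TCR sequencing of sorted CD4+ T-cell subsets (Tfh, Th1,
Th17, Th22, Th2, Tregs, ...) produces one clonotype table per (donor,
subset, chain): UMI-derived molecule counts, CDR3 nucleotide and
amino-acid sequences, V/D/J calls and junction markers. The scientific
questions — do subsets select physicochemically distinct TCRs? how clonal
is each subset? which subsets exchange clonotypes? which carry public
TCRs? — all reduce to a handful of repertoire statistics that must be
computed on *depth-normalized* clonesets to be comparable. `tcrsubsets`
implements that analysis stack end to end, for immunologists and
computational biologists working with VDJtools-style or AIRR
Rearrangement TSV clonotype tables.

## What it computes

* **Normalization** — downsampling to a fixed number of UMI-labeled
  molecules (multivariate hypergeometric, seeded; default n = 16,000) and
  truncation to the top-N most frequent clonotypes (default N = 20,000;
  N = 2,000 for networks).
* **CDR3 middle-region physicochemistry** — for each clonotype, the mean
  of a property scale over the five central residues of the CDR3 (the
  residues that dominate peptide contact), then the frequency-weighted
  repertoire average. Shipped scales: Kidera factors kf1–kf10 (kf4 =
  inverted hydrophobicity), contact-energy-derived interaction
  `strength` and `mjenergy`, `volume` (bulky residues W, Y, F, R, K score
  highest), `surface`, `charge`, `polarity`, `hydropathy`, helix/sheet/
  turn propensities and `disorder`.
* **Junction statistics** — NDN length, total N insertions, `vdins`,
  `djins` from the 0-based junction markers.
* **The 28-parameter feature vector** per cloneset, and correlation PCA
  over repertoires (both chains concatenated or per chain).
* **Diversity** — observed richness, bias-corrected Chao1
  `S_obs + f1(f1−1)/(2(f2+1))`, and the normalized Shannon–Wiener index
  `H/ln(S_obs)`.
* **Clonal overlap** — clonotypes matched on identical V gene + CDR3
  nucleotide sequence; weighted `F2 = Σ_shared sqrt(f_a f_b)` and
  relative `D = n_shared/(S_a·S_b)`; per-donor clonotype-sharing
  networks with shared "clouds" carrying the mean frequency across
  maternal subsets.
* **Publicity** — amino-acid-defined CDR3 variants shared between donor
  pairs with at most one mismatch (Hamming, length-stratified), counted
  on deduplicated top-20,000 clonesets via an exact wildcard-mask index.
* **Statistics** — the group-versus-mean scheme: omnibus one-way ANOVA
  (or Kruskal–Wallis after a Shapiro–Wilk gate), per-group two-sample
  Welch t (or Wilcoxon) against the pooled values, Bonferroni over
  groups, significance tiers, plus Benjamini–Hochberg FDR adjustment.
* **Synthetic cohorts** — a seeded generator with heavy-tailed clone
  sizes, tunable middle-5 physicochemical bias per subset (exponential
  tilting to an exact target shift), planted inter-subset sharing and
  cross-donor public clonotypes, with a ground-truth ledger.

## Worked example

```r
library(tcrsubsets)

subsets <- c("Tfh", "Th17", "Treg")
sharing <- matrix(0.04, 3, 3, dimnames = list(subsets, subsets))
diag(sharing) <- 0
cfg <- generator_config(n_donors = 3, subsets = subsets,
                        clones_per_subset = 2000,
                        composition_bias = list(Treg = c(strength = 0.4)),
                        sharing_matrix = sharing,
                        public_fraction = 0.05, seed = 42)
cohort <- generate_cohort(cfg)

# middle-5 interaction strength, weighted by clonotype frequency
sapply(cohort$repertoires[grep("^D1", names(cohort$repertoires))],
       repertoire_property_average, scale = "strength")
#> D1|Tfh   3.419   D1|Th17  3.398   D1|Treg  3.775
```

The Treg repertoire reads ~0.4 strength units above the unbiased
subsets: the planted shift is recovered. Diversity on a 3,000-molecule
downsample of `D1|Treg`:

```r
diversity_stats(cohort$repertoires[["D1|Treg"]], n_molecules = 3000, seed = 1)
#>   observed    chao1 normalized_shannon_wiener n_molecules
#> 1     1214 2162.356                 0.9434419        3000
```

1,214 distinct clonotypes were seen in 3,000 molecules; Chao1
extrapolates ~2,162 (the generator made 2,000-odd, most unseen at this
depth) and evenness is high (0.94: no dominant expansion). Overlap and
publicity:

```r
d1 <- cohort$repertoires[grep("^D1", names(cohort$repertoires))]
names(d1) <- sub("D1|", "", names(d1), fixed = TRUE)
repertoire_overlap(d1, top_n = 20000)
#>   sample_a sample_b n_shared         f2            d
#> 1      Tfh     Th17      172 0.05289914 3.657756e-05
#> 2      Tfh     Treg      165 0.04861587 3.517032e-05
#> 3     Th17     Treg      164 0.04995824 3.519981e-05

trg <- cohort$repertoires[grep("Treg", names(cohort$repertoires))]
names(trg) <- sub("|Treg", "", names(trg), fixed = TRUE)
publicity_matrix(trg, top_n = 20000)
#>   subset donor_a donor_b n_ab n_ba n_public
#> 1   Treg      D1      D2   15   15       15
#> 2   Treg      D1      D3   24   24       24
#> 3   Treg      D2      D3   27   27       27
```

Each subset pair shares ~165–172 of its clonotypes (the 4% planted
sharing rate × 2,000 clones, both directions, minus downsampling of the
table to unique keys), and Treg clonesets share 15–27 public amino-acid
variants per donor pair. The full pipeline — features, stats, diversity,
overlap, networks, publicity, PCA — runs with:

```r
run_pipeline(cohort$repertoires, "out/", pipeline_config(n_molecules = 3000))
```

or from the shell via the bundled CLI
(`inst/cli/tcrsubsets.R`, subcommands `simulate`, `downsample`, `topn`,
`features`, `diversity`, `overlap`, `publicity`, `run`).

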