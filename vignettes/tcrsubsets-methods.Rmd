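---
title: "Methods: repertoire-level comparison of TCR clonesets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire-level comparison of TCR clonesets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrsubsets)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the numerical choices made
where conventions were open, and what the synthetic-data tests do and do
not establish.

## The analysis model

A *repertoire* is an ordered cloneset for one (donor, subset, chain):
clonotypes defined at the nucleotide level by the pair (V gene, CDR3
nucleotide sequence), each carrying a UMI-derived molecule count. All
statistics below are computed per repertoire or per pair of repertoires;
biological claims then rest on comparing them across subsets and donors.
Two normalizations make those comparisons fair:

* **Depth normalization.** Diversity statistics are computed after
  downsampling each cloneset to a fixed number of UMI-labeled molecules
  (default `n_molecules = 16000`). Because the sampled objects are
  physical cDNA molecules, sampling is *without replacement*: the vector
  of per-clonotype counts is multivariate hypergeometric. A multinomial
  mode exists (`replacement = TRUE`) for sensitivity analysis only.
  Repertoires below the target are excluded by the pipeline, not
  upsampled — the target is meant to be the cohort's lower bound.
* **Rank normalization.** Overlap and publicity are computed on the top
  `N` most frequent clonotypes per cloneset (default 20,000; 2,000 for
  sharing networks), so clonesets of different depth contribute equally
  many candidates. Ties at the cutoff are broken lexicographically on
  (V gene, CDR3nt) — the upstream convention is unstated, and a
  deterministic rule makes runs reproducible.

## CDR3 middle-region scoring

Physicochemical comparison uses the **five middle residues** of the CDR3
loop — the residues that typically dominate contact with the peptide in
a peptide–MHC complex. For a CDR3 of length $L \ge 5$ the window starts
at offset $\lfloor (L-5)/2 \rfloor$ (left-biased for odd overhangs;
deterministic, matching common substring-centering practice). CDR3s
shorter than five residues are scored whole rather than dropped, to
avoid silently shrinking cohorts; both the window length `k` and this
rule are configurable.

A clonotype's score on a scale $s$ is the arithmetic mean of $s$ over
the window's residues; the repertoire value is the frequency-weighted
average $\sum_i f_i x_i$ (identical to the per-molecule mean), with an
unweighted mode for robustness checks. The shipped property table
(`aa_property_table()`) contains transcribed published constants — the
ten Kidera factors, Miyazawa–Jernigan diagonal contact energies
(`mjenergy`), Kyte–Doolittle hydropathy, Zamyatnin residue volumes
(bulkiest: W, Y, F, R, K), Grantham polarity, net charge at pH 7 and
Chou–Fasman/TOP-IDP conformational propensities. Two caveats are
recorded in the resource header:

* `strength` is *derived* as $-(e_{ii} + \bar e)/2$, the mean pairwise
  interaction affinity under the standard additive approximation
  $e_{ij} \approx (e_{ii}+e_{jj})/2$ to the contact-energy matrix.
* `core`, `rim` and `surface` are **synthetic stand-ins**: the published
  cross-docking interface propensities were unobtainable in the build
  environment, so these columns are monotone constructs (burial
  propensity, bulky-but-exposed, small/polar-accessibility-stable).
  Their orderings are sensible but their absolute values carry no
  provenance; none of the package's quantitative guarantees depend on
  them.

## The 28-parameter feature vector and PCA

Each cloneset is summarized by 28 frequency-weighted parameters: kf1–10,
strength, mjenergy, CDR3 length (nucleotides), NDN length, N insertions,
vdins, djins, core, rim, volume, polarity, disorder, surface, alpha,
beta, turn, charge, hydropathy. Junction counts come from the 0-based
markers: `ndn = j_start − v_end − 1`; `vdins`/`djins` are clamped at 0
when exonuclease chewback makes segments overlap; without a D call,
`n_insertions` falls back to the whole NDN stretch.

PCA is correlation PCA: parameters have incommensurate units, so columns
are z-scored (constant columns dropped with a warning) before the
eigendecomposition. Signs are fixed by making the largest-magnitude
loading of each component positive. Whether a *sample* is a
(donor, subset) with both chains' features concatenated (56 columns) or
a (donor, subset, chain) with 28 columns is genuinely ambiguous in the
source protocol — its parameter count says 28 but its top loadings mix
α- and β-chain parameters. Both layouts are supported
(`pca_input(layout=)`); concatenation is the default and is flagged as
an interpretation.

## Diversity

Three statistics, all computed on the downsampled cloneset:
observed richness; bias-corrected Chao1
$S_{obs} + f_1(f_1-1)/(2(f_2+1))$ (the $+1$ keeps the estimator defined
with no doubletons — common repertoire-tool practice; the classical form
is available); and the normalized Shannon–Wiener index $H/\ln S_{obs}$,
defined as 0 for a single clonotype. Normalizing by the $\ln S_{obs}$ of
the *same downsampled cloneset* makes the index scale-free in [0, 1].

## Overlap, networks, publicity

Nucleotide-level sharing requires identical V gene *and* CDR3nt.
`F2 = Σ_shared √(f_a f_b)` (so F2(a,a) = 1 after renormalization) and
`D = n_shared/(S_a S_b)`. D is documented as an interpretation: the
upstream tool names but does not define it, and this form matches its
use as a small per-pair relative quantity. Sharing networks connect
instances of the same clonotype across subsets within a donor; the
"cloud" bubble size is the arithmetic mean of the member frequencies
(the geometric mean is plausible but unstated upstream; arithmetic was
chosen and fixed).

Publicity counts amino-acid-defined CDR3 *variants* (deduplicated, after
top-N truncation) shared between donor pairs at Hamming distance ≤ 1 —
one substitution at equal length, not edit distance, because repertoire
comparisons are conventionally length-stratified and the tolerance is
described as a "mismatch". Matching uses a wildcard-mask index: each
string of length $L$ emits $L$ keys with one position masked; two
equal-length strings are within one substitution iff they share a key.
The index is exact (tested against a nested-loop oracle) and linear to
build. Directional counts can differ; both are reported and their mean
is the headline number, a convention chosen because the source protocol
does not specify direction.

## The statistical layer

Per-parameter subset comparisons use a two-stage scheme: an omnibus
one-way ANOVA — or Kruskal–Wallis when any group fails a per-group
Shapiro–Wilk gate at α = 0.05 — followed by a per-group two-sample Welch
t-test (or Wilcoxon) of the group against the pooled values, with
Bonferroni correction over the number of groups and star tiers at
0.05/0.01/0.001/0.0001. Benjamini–Hochberg step-up adjustment is
provided for FDR control across families of tests.

**Calibration caveat (important).** "Each group versus the mean" admits
two readings: pool *all* values including the tested group (the
convention of the upstream plotting tool, and this package's default
`pooled = "all"`), or pool only the *other* groups (`pooled = "rest"`).
Neither is well calibrated at the study's scale of 8 groups × 5 values.
Including the group makes the two samples overlap, deflating the
statistic: the acceptance script measures a type-I error of ≈ 0.040 at
nominal 0.05 (10,000-replicate null simulation). Excluding the group
leaves Welch's test at n = 5 vs 35, where the Satterthwaite
approximation is known to be liberal. The corresponding acceptance
expectation is therefore deliberately left failing rather than widened:
treat per-group stars near the threshold with caution, and prefer the
omnibus p for gatekeeping.

## The synthetic cohort generator

`generate_cohort()` stands in for deposited data and gives every
pipeline stage a ground truth:

* **Clone sizes**: log-normal (default meanlog 1, sdlog 1.2) or
  power-law — heavy-tailed, like real expanded repertoires.
* **CDR3s**: lengths 8–20 aa peaked near 14–15 (discretized normal,
  matching typical TCRβ CDR3 length distributions), canonical C...F
  anchors, uniform interior composition.
* **Physicochemical bias**: the middle-5 window of subset $s$ is drawn
  with weights $w(aa) \propto \exp(\beta\, s(aa))$, with $\beta$ solved
  by `uniroot` so the expected scale mean shifts by exactly the
  configured δ — monotone, invertible, and recorded in the ledger.
* **Junctions**: Poisson(λ = 3) insertions at each junction, a 4–10 nt
  D segment, markers constructed consistently (so `junction_insertions`
  recovers the drawn values); ~5% of clonotypes lack a D call.
* **Sharing**: a clonotype of subset *i* is copied into subset *j*
  (same V + CDR3nt, fresh count) with probability `sharing_matrix[i, j]`.
* **Publicity**: with probability `q` a clonotype's amino-acid CDR3
  comes from a cohort-shared per-subset pool; codons are redrawn per
  donor, so amino-acid publicity and nucleotide overlap stay decoupled,
  as in real data.

Everything is determined by one seed. What the generator does *not*
emulate: V(D)J generation probabilities and allelic biases, thymic
selection, sequencing error, UMI collisions, or realistic V/J usage
(segment names come from a fictional catalog — segment-usage statistics
are out of scope). A green recovery test therefore establishes that the
*estimators* are correct on a stated world, not that real repertoires
satisfy the world's assumptions.

`plant_expansion(rep, k, mass)` scales all frequencies by `1 − mass` and
returns the freed mass to the top-k block proportionally. This
formulation was chosen over literally overwriting the block's total
frequency because it is continuous at `mass → 0` and the output
majorizes the input, so evenness (normalized Shannon–Wiener) strictly
decreases for every positive mass — both properties the literal
overwrite violates. Counts are re-materialized on a 10⁹-molecule grid
(frequency error ≤ 5e-10) to keep them whole.

## Numerical and degenerate-input choices

* Downsampling below the repertoire size is refused, never padded.
* Frequencies must sum to 1 within 1e-6 for validation; recomputation is
  exact division and idempotent.
* Duplicate (V, CDR3nt) rows merge by summing counts on construction,
  with a message.
* Missing segment calls "." and "" normalize to ""; missing markers to
  −1; marker arithmetic propagates NA rather than guessing.
* Hamming matching is undefined across lengths (counts 0), by design.
* Welch statistic for two identical constant samples is defined as 0
  with p = 1 (the 0/0 limit is treated as "no evidence").
* The Chao1 `f2 + 1` denominator and the `nsw = 0` convention for
  singleton repertoires avoid division by zero without branching.

## Known limitations

Beyond the generator's scope notes above: the statistical layer tests
each parameter marginally (no multivariate inference beyond PCA); the
`core`/`rim`/`surface` scales are stand-ins; figure-level biological
results from the motivating study (subset orderings, absolute diversity
values) require the deposited cohort data and are not reproduced by the
synthetic suite — the pipeline will, however, run unchanged on such
tables supplied as VDJtools-style or AIRR TSV.
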