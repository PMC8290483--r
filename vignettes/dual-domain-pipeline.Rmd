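---
title: "Methods: dual-domain amplicon analysis of early-life gut microbiota"
author: "biomepipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-domain amplicon analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model of the data

`biomepipe` analyses paired bacterial (16S V4) and fungal (ITS2) OTU count
tables from a cross-sectional mother–infant cohort: child stool sampled in
nine age bins from the first week of life to five years, maternal stool and
breast milk sampled one and four weeks postpartum, template-free blanks per
extraction stratum, and positive controls. Everything downstream of the OTU
table is in scope; read processing, OTU clustering, and taxonomy assignment
are not. Positive controls are excluded from every analysis: they exist to
verify the sequencing run, carry no specimen information, and would distort
blank statistics if treated as either blanks or specimens.

The pipeline is organised as six numbered drivers under `analysis/`, each a
thin narrative wrapper over exported functions, so that every computation is
unit-testable in isolation and reusable on real tables read with
`read_count_table()` (TSV, or BIOM via the `biomformat` package),
`read_taxonomy()`, and `read_metadata()`.

## Blank-based decontamination

Reagent contamination is detected per stratum (stool and breast milk are
extracted and amplified separately, with their own blanks, and have
distinct blank contamination profiles). For each OTU we compute, over
blanks and over specimens separately, a dispersion score: the geometric
mean of counts plus one sample standard deviation. An OTU is

* **removed** when it is present in *strictly more than* 50% of blanks and
  its blank score exceeds its specimen score — the classic signature of a
  reagent contaminant: recurrent in blanks, weak in specimens;
* **background-subtracted** when it exceeds the prevalence threshold but
  its specimen score dominates — a genuine community member that also leaks
  into blanks. Here the arithmetic mean plus one SD of its blank counts is
  subtracted from every specimen count, floored at zero and rounded down so
  counts stay integral;
* **kept** otherwise.

Numerical choices worth stating. The geometric mean uses the pseudocount
convention `exp(mean(log(c + 1))) - 1`, which is defined for zero counts and
converges to the plain geometric mean for large ones; the SD uses the n−1
denominator and is defined as 0 for a single blank. "Present" means a count
strictly above zero, with no minimum count. The two flagged branches
partition the above-threshold OTUs exhaustively, so no flagged OTU escapes a
decision. Samples with totals strictly under 1,000 reads are dropped *after*
subtraction (subtraction can push a marginal sample below the floor, and a
sample kept on pre-subtraction reads but dominated by background would be
misleading); both totals are recorded in the report. Strata are
recombined after filtering over the union of surviving OTUs, zero-filled
where a stratum removed an OTU the other kept. A stratum without blanks
passes through with a warning rather than failing, which also makes
re-running QC on already-cleaned data a no-op.

## Alpha diversity

Observed richness and Shannon diversity (natural log) are computed after
rarefying every sample, without replacement, to a common depth. The depth
defaults to the minimum retained sample total after QC — the largest depth
that loses no sample — and is recorded in every report; a `replicates`
argument averages the metrics over independent rarefaction draws for users
who want the subsampling noise quantified. Each age bin is compared to the
week-4 mothers (the adult reference — mothers of one-month-olds) with a
two-sided Wilcoxon rank-sum test, Bonferroni-adjusted over the bins tested.
The test is exact when sample sizes permit and ties are absent, otherwise a
normal approximation with tie and continuity corrections is used (the
`stats::wilcox.test` switching rule); this keeps small-bin comparisons
exact without special-casing.

## Community composition

Bray–Curtis dissimilarities are computed on raw cleaned counts, not
rarefied ones: subsampling is prescribed only for the depth-sensitive alpha
metrics, and Bray–Curtis on proportionally complete counts uses all the
data. Users who prefer rarefied input can pass a rarefied table.

The age effect on composition is tested with a permutational variance
partition on the distance matrix, using age in days as a single continuous
covariate. With `A = d^2` and the centering matrix `J`, the Gower-centered
inner-product matrix is `G = -J A J / 2`; the model sum of squares is
`tr(H G H)` for the hat matrix `H` of the design `[1, z]`, `SS_total =
tr(G)`, and the pseudo-F is `(SS_model / 1) / (SS_res / (n - 2))`.
Significance comes from permuting the covariate: `p = (1 + #{F* >= F}) /
(1 + n_perm)` with 999 permutations by default, so p is floored at
`1/(n_perm + 1)`. When `n! <= n_perm` the implementation switches to
exhaustive enumeration of all `n!` permutations, making small-n results
deterministic. F comparisons use a `1e-12` slack so exact ties with the
observed statistic count as exceedances rather than falling to floating
point noise.

Convergence to the oldest bin is assessed by collecting each bin member's
distance to every 5-year (MOL 57-63) bin member and comparing that
distribution, per bin, to the within-reference pairwise distances with a
rank-sum test under Bonferroni correction. Repeated distances to the same
reference individuals are treated as independent observations; that
dependence inflates the effective sample size, which is a caveat of this
procedure, and the per-bin medians are reported alongside the p-values for
that reason. Ordination (NMDS) is deliberately absent: it visualises, but
the inference here does not depend on it.

## Mother–infant sharing

An OTU is "present" in a sample when its relative abundance strictly
exceeds 0.01% — strict, so a count sitting exactly on the threshold does
not count. Related pairs link a child's stool sample to its own mother's
stool or milk sample from the matching postpartum window; the candidate
unrelated pool contains every other child-by-mother combination *within the
same window and source*. Stratifying the pool this way keeps the null
comparison free of window and specimen-type composition effects. Because
the unrelated pool is much larger than the related set, each test draws an
equal-size subsample of unrelated pairs without replacement (one draw by
default, seed recorded); `n_draws > 1` reports the p-value distribution
across draws and summarises it by the median, quantifying a subsampling
variability that a single draw leaves invisible.

## Genus-level differential abundance

OTU counts are aggregated to genus labels before testing; OTUs unresolved
at genus collapse to their deepest resolved rank, prefixed by the rank
marker (`f__Lachnospiraceae`), and OTUs without any taxonomy become
`Unclassified` — aggregation therefore conserves column totals exactly, and
"classified at the genus level or above" remains countable. Each genus's
relative abundance is compared between the week-1 and week-4 maternal
groups with rank-sum tests under Benjamini–Hochberg correction across
genera. Relative abundance, not counts, is tested: the maternal groups
differ in sequencing depth, and the scientific claim is compositional.
An OTU-level negative-binomial model is out of scope here by design; this
module is the nonparametric confirmation layer.

## The synthetic study generator

The generator exists so that every stage of the pipeline can be exercised,
with known truth, on data shaped like the cohort it targets. Per specimen,
a composition is drawn from a Dirichlet centred on its bin's mean profile
(concentration 50 — enough overdispersion that replicate samples differ
visibly, not so much that bins lose identity) and reads are drawn
multinomially at a log-normal depth (median 10,000 reads for 16S, 5,000
for ITS2, matching desk-scale amplicon runs). Design features it emulates:

* **Staged bacterial succession.** Child-bin profiles are mixtures
  `(1 - t) * stage + t * adult` with the mixing weight `t` increasing over
  the nine bins (0.02 to 1). The newborn stage is Escherichia-dominated and
  taxon-poor, the infancy stage Bifidobacterium-dominated with prominent
  Bacteroides, and the adult target Prevotella-dominated and even. The `t`
  spacing is deliberately non-uniform: Bray–Curtis saturates near disjoint
  compositions and flattens near the target, so uniform spacing would bunch
  the early and late bins. The spacing used keeps the per-bin median
  distances to the 5-year bin separated by roughly equal gaps.
* **A flat mycobiome.** All stool fungal profiles are identical across bins
  (Candida-dominated); breast-milk fungi are Malassezia-dominated. A
  configurable fraction (35%) of specimens carries no fungi at all, and
  fungal depths are lower with a larger under-1,000-read fraction — so the
  fungal arm genuinely exercises the no-signal path, including heavy sample
  loss at QC.
* **Individual-specific carriage.** Each subject carries only a random
  subset (probability 0.4) of the panel's low-abundance OTUs (below 1%
  expected abundance). Without this, every mother would present the same
  OTU set and mother-specific transmission would be undetectable in
  principle; with it, rare-taxon carriage is informative, as in real
  cohorts.
* **Transmission.** Each related infant receives 30 OTUs sampled from its
  mother's realized stool composition, seeded at low abundance — above the
  0.01% presence threshold but capped at 0.2% so the infant's staged
  community still dominates. Transmission is bacterial only; the fungal arm
  deliberately carries no mother-infant signal.
* **Contamination.** Reagent-class contaminants appear in a stratum's
  blanks at Poisson means of 60–80 counts with Poisson(0.3–0.5) leakage
  into specimens — constructed to satisfy the removal rule. A second class
  is abundant in specimens (Poisson 200–300) while recurrent at low level
  in blanks, exercising the subtraction branch. Blanks also carry a trace
  (Poisson 0.01) of community carryover.

Study sizes default to 12 child samples per bin (15 in the two
mother-paired newborn bins), 15 pairs per window, four stool and two milk
blanks — roughly the per-bin scale of the cohort designs this emulates, and
small enough that a full study simulates in well under a second, so the
calibration properties in the test suite can average over 100+ studies.

What passing tests on this generator do **not** show: the profiles are
qualitative dominance patterns, not measured abundances; there is no
phylogenetic structure, no batch effects beyond the stratum split, no
compositional zero-inflation beyond the carriage and fungal-zero
mechanisms, and no strain-level variation — shared OTU presence here is
transmission by construction, which real data cannot guarantee.

## Reproducibility

Every randomized operation (rarefaction, permutations, unrelated-pair
draws, simulation) takes an explicit integer seed, restores the caller's
RNG state afterwards, and records the seed in its report. Reports are TSV
with a JSON sidecar carrying the parameters, seed, and package version in
deterministic field order, so reruns are byte-comparable.

## Known limitations

* The rank-sum test on bin-to-reference distances ignores the dependence
  among distances sharing a reference individual (stated above).
* Single-draw unrelated subsampling leaves the sharing p-value dependent on
  the draw; use `n_draws` to see the spread.
* The decontamination rule is prevalence-plus-dispersion only; it does not
  model contaminant frequency against DNA concentration, and cross-talk
  between specimen wells is not corrected, only emulated in the generator.
* Bonferroni over bins is conservative when bins are many and correlated.
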