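# biomepipe

Analysis pipeline for paired bacterial (16S) and fungal (ITS2) amplicon
surveys of mother–infant cohorts: who acquires which microbes, from whom,
and when, over the first years of life.

Starting from OTU count tables, taxonomy, and sample metadata, the package
implements the full statistical chain used in cross-sectional early-life
microbiota studies:

* **Blank-based decontamination.** An OTU present in strictly more than 50%
  of a stratum's template-free blanks is *removed* when its blank
  dispersion score — geometric mean of counts plus one SD,
  `GM(c) = exp(mean(log(c + 1))) − 1` — exceeds the same score over
  specimens, and *background-subtracted* (`max(0, ⌊c − (mean + SD of blank
  counts)⌋)`) when specimens dominate. Stool and breast milk are processed
  as separate strata with their own blanks, then recombined. Samples under
  1,000 total reads are dropped.
* **Alpha diversity.** Observed richness and Shannon index
  `H = −Σ pᵢ ln pᵢ` after without-replacement rarefaction to a common
  depth; each age bin is compared to the adult reference (week-4 mothers)
  by Wilcoxon rank-sum tests under Bonferroni correction.
* **Community composition.** Bray–Curtis dissimilarity
  `d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`; a permutational variance partition of the
  distance matrix on continuous age (Gower-centered `G = −½JAJ`, pseudo-F
  from `tr(HGH)`, permutation p with exhaustive enumeration at small n);
  and a convergence test comparing each bin's distances to the 5-year bin
  against the within-reference distances.
* **Mother–infant sharing.** OTUs present above a strict 0.01% relative
  abundance are counted per related pair and compared to equal-size random
  subsamples of unrelated pairs from the same postpartum window and
  specimen source.
* **Genus-level differential abundance.** Counts aggregated to genus (or
  deepest resolved rank), rank-sum tests on relative abundance with
  Benjamini–Hochberg correction.
* **A truth-labelled study generator.** Dirichlet-multinomial communities
  with staged genus succession (Escherichia-type newborns,
  Bifidobacterium-type infancy, Prevotella-type from the second year), a
  flat fungal arm with fungus-free samples, individual-specific carriage of
  rare taxa, tunable mother–infant transmission, spiked contaminants, and
  uneven sequencing depth — so every stage above is testable against known
  ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over a simulated cohort.
Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_decontam.R
Rscript analysis/03_alpha_diversity.R
Rscript analysis/04_beta_diversity.R
```

generates a study (9 child age bins, 15 mother–infant pairs per postpartum
window, stool and breast-milk strata, paired 16S/ITS2 tables), cleans it,
and prints, among other output:

```
[bacteria_16S] cleaned table: 83 OTUs x 172 samples
  stool: removed 3 OTU(s) [3/3 labelled contaminants], subtracted 2, dropped 2 sample(s) under 1000 reads
...
[bacteria_16S] rarefied 142 stool samples to depth 1130
  shannon: 3/10 bins differ from the adult reference (below: DOL 0-5, DOL 13-17, DOL 26-35)
...
[bacteria_16S] age explains 19.0% of community variance (pseudo-F = 25.74, p = 0.001) over 112 child samples
  median distance to the 5-year bin, by bin:
    DOL 0-5      0.849  *
    ...
    MOL 33-39    0.484
  (monotone decline: TRUE)
[fungi_ITS2] age explains 1.3% of community variance (pseudo-F = 0.79, p = 0.613) over 64 child samples
```

That is the expected signature: every spiked contaminant recovered, newborn
bacterial diversity significantly below the adult reference while fungal
diversity shows no age trend, age explaining a large share of bacterial but
not fungal community variance, and child communities converging
monotonically on the 5-year profile. `analysis/05_sharing.R` and
`analysis/06_diffabund.R` add the mother–infant sharing comparison (related
pairs share more bacterial OTUs than resampled unrelated pairs) and the
maternal week-1 vs week-4 genus shifts (Escherichia higher, Prevotella
lower in week 1). All tables land in `results/` as TSV with JSON sidecars
recording parameters and seeds.

The methods vignette (`vignettes/dual-domain-pipeline.Rmd`) documents the
statistical procedures, the generator's design, and its limitations.

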