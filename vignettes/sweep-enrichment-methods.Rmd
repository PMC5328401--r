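---
title: "Methods: testing GWAS risk alleles for selective-sweep enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing GWAS risk alleles for selective-sweep enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the analysis unit

Polygenic traits leave their association signal spread over thousands of
variants, and any recent positive selection acting on such a trait should
leave a correspondingly diffuse signature: variants more strongly associated
with the trait should, on average, sit in genomic regions carrying more
evidence of a selective sweep. `sweepenrich` tests this at three levels of
resolution — a rank correlation, a threshold-scan of enrichment odds ratios,
and an effect-direction test — followed by a gene-level over-representation
analysis of the variants driving the signal.

Because GWAS summary statistics are heavily redundant under linkage
disequilibrium (LD), the analysis unit throughout is the *clumped* variant:
after quality control (imputation info score > 0.9, minor allele frequency
> 0.02), a greedy p-value-ranked clumping pass keeps the most significant
variant of every LD cluster (500 kb window, surviving pairwise r² < 0.25).
These defaults are the standard summary-statistics pipeline for this
analysis and are all tunable via `clump_params()`. The clumping algorithm
is the usual greedy semantics: repeatedly take the unclaimed variant with
the smallest p-value as an index and claim everything within the window at
r² ≥ 0.25 with it; ties in p are broken by ascending (chromosome,
position) so results are deterministic. The major histocompatibility
complex (chr6:25–34 Mb), whose extreme LD defeats clumping, is optionally
reduced to its single most significant variant (`restrict_mhc()`).

Effect sizes are expressed per *minor* allele (`orient_to_minor()`): when
the effect allele is the major allele the odds ratio is inverted and the
alleles swapped. The operation is a projection — applying it to an
already-oriented table changes nothing — and preserves minor allele
frequency and |log OR|. A variant with eaf exactly 0.5 is left unchanged;
either choice is arbitrary, and a fixed rule keeps runs deterministic.

# Selection scores and coordinates

Selection evidence enters as a *score track*: genomic intervals each
carrying a score for one of two sweep scenarios — *incomplete* (the
favoured allele still segregates) and *complete* (it reached fixation) —
such as hierarchical-boosting classifier output. Scores are inputs;
recomputing them from selection-test statistics is out of scope.

Coordinates follow the BED convention: score regions and genes are
half-open 0-based, variant positions 1-based, and a variant at position
p overlaps [s, e) iff s ≤ p−1 < e. Chromosome names are normalized (the
`chr` prefix is stripped) at read time. Strand is ignored; alleles are
taken as reported. When several regions of one scenario cover a position
the *maximum* score is taken — window boundaries in real tracks make this
case rare, and the maximum is the conservative choice for an enrichment
test keyed to high scores. The "selected" set is the top 5% of assigned
scores over the clumped analysis set, with the cutoff defined as the
nearest-rank (ceiling) empirical quantile and membership as score ≥
cutoff; computing the quantile over the analysis set (rather than over
all genomic windows) matches the variant-level unit of every downstream
test, and `score ≥ cutoff` guarantees the top set is never empty under
ties.

# The three statistics

**Rank correlation.** `spearman_correlation()` computes rho as the
Pearson correlation of mid-ranks of (−log10 p, score), with the two-sided
t-approximation p-value. Variants without a score are dropped pairwise.
`permute_correlation()` permutes the GWAS column against the fixed score
column (default 10,000 draws) and reports the one-sided (greater)
empirical p-value with the add-one rule, p = (1 + #{rho* ≥ rho}) /
(n_perm + 1) — the question is specifically whether the observed
correlation is *higher* than chance, and the add-one convention avoids
p = 0. A two-sided variant is available by flag.

**Threshold scan.** `threshold_enrichment()` cross-classifies the scored
analysis variants by (GWAS p < t) × (score ≥ top-5% cutoff) over a grid
of thresholds t, reporting for each the odds ratio ad/bc, the Woolf
normal interval exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d)), and a two-sided
p-value from the chi-square test without continuity correction, replaced
by Fisher's exact test whenever a cell is below 5. No method for the CI
or the 2×2 p-value is canonical in this literature; Woolf and
chi-square/Fisher are the standard large-table choices and are stated
here once. Two default grids are provided (`default_thresholds()`): six
thresholds {1e−4, 1e−3, 0.01, 0.05, 0.1, 0.5} for a moderately powered
GWAS and nine (adding 5e−8, 1e−6, 1e−5) for a highly powered one; the
Bonferroni alpha is 0.05 divided by the number of thresholds scanned
(8.3×10⁻³ and 5.5×10⁻³ respectively), and the correlation stage is
likewise Bonferroni-corrected for datasets × scenarios (e.g. five
disorders × two scenarios gives 5×10⁻³). Zero margins leave the OR
undefined with an explicit reason; zero cells leave the OR at 0/∞ with
the CI undefined.

**Direction test.** For the focal set (p < 0.1 and score in the top 5%),
`direction_test()` asks whether minor-allele effects lean toward risk:
the observed statistic is the median minor-allele OR, compared to medians
of equally sized variant subsets drawn without replacement under the
null, again with the add-one empirical p.

The choice of the null pool matters more than it looks. In real summary
statistics (and in this package's generator) effect magnitude and
significance are linked through z = log(OR)/SE, so conditioning on
p < 0.1 selects variants with systematically larger |log OR|. Drawing
null subsets from the *whole* analysis set would compare the focal median
against medians of smaller-magnitude ORs — an under-dispersed null that
rejects far too often (we measured ~40% at nominal 5% under a null
generator). The default pool is therefore the *associated margin*
(variants with p < 0.1): given exchangeable scores, the focal set is a
uniformly random subset of that margin, which makes the test exactly
calibrated, and it corresponds to permuting the score track against the
GWAS results — the same permutation scheme as the correlation test. The
full-set pool (`null = "fullset"`) and a sign-flipping null
(`null = "signflip"`) are kept as labelled alternatives.

# Gene mapping and over-representation

Variants map to every gene whose interval extended by ±50 kb covers
their position (`map_genes()`); "the gene it is in and/or the nearest
genes" is read as *all* genes within the flank, with a single-nearest
mode available. A gene enters gene lists once no matter how many variants
hit it. `overrepresentation_test()` is a generic hypergeometric
upper-tail test, p = P(X ≥ k), with fold enrichment (k/n)/(K/N),
Bonferroni over the terms actually tested (those with ≥ 1 background
gene) and Benjamini–Hochberg FDR alongside. The default background is
the set of genes reachable from the clumped analysis variants — not the
whole annotation — which controls for gene length and variant density;
the whole-annotation background is available by passing it explicitly.
`enrichment_count_permutation()` re-derives the number of
Bonferroni-significant terms on random variant sets of the focal size
(default 100 permutations), validating that the count itself exceeds
chance.

# The synthetic-data generator

`simulate_bundle()` generates a complete, self-consistent study: GWAS
summary statistics, LD, score tracks for both scenarios, genes, and term
annotations, with a `truth` record of every planted membership. Its
defaults are the package's standard test conditions:

* 2,000 variants in 400 contiguous LD blocks of 5 (within-block r² = 0.9,
  cross-block 0) on one synthetic chromosome, 10 kb per block. Block LD
  makes clumping truth exactly computable; continuous r² decay is
  deliberately not modelled.
* MAF uniform on (0.02, 0.5); imputation info uniform on (0.95, 1);
  minor-allele log OR ~ Normal(0, 0.02) with SE = 1/√(2·maf·(1−maf)·n)
  at a nominal study size n = 10,000, so z = log(OR)/SE and the two-sided
  p-value link effect magnitude and significance the way real summary
  statistics do.
* 100 score regions tiling the genome, scores Normal(0, 1) per scenario.
* Coupling: for variants inside top-5% score regions, −log10 p is shifted
  by γ·score (`assoc_coupling`); the log-OR magnitude is then re-derived
  from the final p-value so the z-linkage survives the shift. γ = 0 is
  the exchangeable null underlying all calibration tests.
* Directionality: within the selected-and-associated set, the minor-allele
  risk direction is resampled to probability π (`direction_prob`;
  0.5 = null). Sign flips leave |z| and hence p unchanged.
* 150 genes tiling the genome at 70% occupancy; 50 random terms of 5–30
  genes; optionally one planted term whose overlap with the focal gene
  pool is chosen to hit a target fold enrichment, with infeasible
  (fold, size) combinations rejected before generation.

Planted-signal studies use γ = 0.45 with 250 regions at 5,000 variants —
chosen once so that the coupling is moderate: both permutation tests
reject at 5% in well over 90% of replicates while the 2×2 tables of the
threshold scan remain fully populated at the p < 0.01 threshold, where
the shift concentrates the planted enrichment. (At the looser 0.1
threshold the same coupling saturates the selected column; the scan's
evaluation point in the acceptance studies is therefore 0.01.) The
ensemble "true" OR for coverage checks is computed from one 50,000-variant
run of the same process, since the generative OR has no closed form. The
demonstration study plants its fold-3 term with 40 genes over a 400-gene
universe: at that size the planted overlap clears the Bonferroni bar
comfortably in essentially every seed, whereas a 20-gene term sits at the
edge of detectability and is recovered in only ~70% of seeds — term size,
not fold, is what separates the two regimes at these list sizes.

What the generator does *not* emulate: realistic allele-frequency spectra
and recombination maps, continuous LD decay, polygenic architecture with
a fixed heritability, strand ambiguity, or multi-allelic sites. Passing
tests certify the statistical machinery — calibration, power, oracle
equivalence, determinism — on data with the assumed coupling structure,
not the biological fidelity of any particular real dataset.

# Numerical and reproducibility choices

* Empirical p-values always use the add-one rule and so are bounded below
  by 1/(n_perm + 1) and never zero.
* Permutation streams are canonicalized (pairs sorted before permuting;
  null pools sorted before subsampling) so empirical p-values are
  invariant to analysis-set row order.
* Every stochastic stage takes an explicit seed; `run_pipeline()` fans a
  master seed out to per-stage substreams and records everything in a
  manifest (config snapshot, input file digests, per-stage row counts,
  package version). Identical config + seed reproduces byte-identical
  output tables.
* Result tables are written as plain TSV at 17 significant digits, so
  counts round-trip exactly and doubles to machine precision.
* Degenerate inputs are handled explicitly: empty score tracks warn;
  all-missing scores are a hard error; constant scores flag every
  variant; an empty focal set is a hard error in `direction_test()` and
  an explicit skip inside `run_pipeline()`.

Problem sizes in the test suite (500 null replicates at 2,000 variants
with 1,000 permutations; 200 planted replicates at 5,000 variants; 500
clumping and 200 overlap oracle instances; 1,000 hypergeometric cases)
are the package's standard verification conditions: large enough that
binomial error bands on rejection rates are tight (±3 SD ≈ ±0.03 around
0.05), small enough to run routinely.

# Known limitations

* The LD reference is an input (blocks or sparse pairs); r² is never
  computed from genotypes, and an unknown variant is treated as
  unlinked, with a warning count.
* Permutation nulls ignore residual LD between clumped variants; no
  circular-shift or LD-aware scheme is provided.
* The GO hierarchy is not used to adjust gene-set statistics; terms are
  tested independently.
* Genome-build identity between the GWAS and the score track is the
  caller's responsibility; no liftover is attempted.
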