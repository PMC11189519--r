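---
title: "relictpop: models, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{relictpop: models, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions each estimator makes, how the synthetic-cohort generator is
parameterized, and where design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The setting

The package targets cohorts like a relict island population of a crop wild
relative genotyped together with wild, landrace, and cultivar panels plus an
outgroup species: a few dozen diploid samples, a joint-called *all-sites*
VCF (invariant records retained), group labels per sample, substantial
inbreeding from partial selfing, and very unequal group sizes. Two features
dominate the analysis design:

1. **Invariant sites are data.** Per-site diversity statistics must divide
   by all callable sites, not just SNPs; a SNP-only matrix inflates π and
   dxy by orders of magnitude. `split_sites()` / `concat_sites()` /
   `filter_sites()` keep the two site classes separable and recombinable so
   the "combined VCF" workflow (filter SNPs hard, filter invariant sites
   only by depth, concatenate) is reproducible.
2. **Phase is never available.** All estimators are written in
   allele-count algebra that is exact for unphased diploids: for a site
   with `n` called alleles of which `a` are alternate, the number of
   mismatching haplotype pairs is `a(n−a)` regardless of how heterozygotes
   are phased. The testthat oracles deliberately take the other route
   (expand to pseudo-haplotypes and enumerate pairs) so that agreement is a
   genuine cross-check.

## Estimators

**π and dxy.** Window values are ratio-of-sums: Σ mismatches / Σ pairs
over sites in the window. Sites with fewer than two called haplotypes (or
an empty group) contribute nothing; windows with zero comparisons are `NA`
and stay `NA` through averaging — a window of missing data is not a window
of zero diversity. Windows are half-open, anchored at position 1, tiled to
the last observed site on each chromosome; the final partial window is kept
and flagged (`partial`). Chromosome lengths are not part of the matrix, so
trailing empty windows beyond the last site cannot be emitted; summaries are
unaffected because such windows would be `NA`. `summarize_windows()` reports
both the pooled ratio-of-sums (window-size invariant; used for headline
values) and the plain mean of window ratios, labeled, because published
tables rarely say which was used.

**Weir–Cockerham Fst.** The 1984 two-level variance components for two
populations, from called sample sizes, alternate-allele frequencies, and
observed heterozygote frequencies; window Fst is Σa / Σ(a+b+c). Sites with
fewer than two called genotypes in either group are skipped; invariant
sites contribute zeros, so including them is harmless. Negative estimates
are legitimate and not clamped. Hudson-style estimators were considered and
rejected as the default because the windowed-statistics convention this
package mirrors uses WC84.

**Heterozygosity and F_IS.** Per site, expected homozygosity uses the
small-sample correction `1 − 2p(1−p)·N/(N−1)` with `p` estimated from the
*whole cohort present in the matrix* — not per group — matching the pooled
usage in the workflow this package reproduces. Group-level tables are means
over member individuals. Consequence worth knowing: in strongly structured
cohorts the pooled `p` imports a Wahlund effect, so group F_IS values are
higher than within-group estimates would be; that is a property of the
method being mirrored, not a bug.

**Relatedness.** Yang et al.'s genotype covariance standardized by
`2p(1−p)`, averaged over polymorphic sites with both members called.

**LD.** r² is the squared Pearson correlation of dosage vectors (composite
LD) over pairwise-complete samples; monomorphic-in-context pairs are
skipped and counted rather than emitted as NaN. Pruning follows the
`--indep-pairwise` dialect with the window unit in SNP counts. The removal
tie-break — drop the lower-MAF member, then the later position — is a
documented local convention: the upstream toolkit's internal order is not
normative, and the post-condition (no retained same-window pair above the
threshold) is what the tests enforce, by exhaustive re-scan.

**PCA / IBS / NJ.** PCA standardizes by `sqrt(2p(1−p))` and decomposes the
sample covariance; coordinates are SVD scores with signs fixed by making
the first sample's loading nonnegative. Missing dosages are a precondition
violation (the mirrored workflow runs PCA only on fully-called pruned
SNPs). The neighbor-joining implementation is the package's own: standard
Q-criterion with lowest-index tie-breaking; negative branch-length
estimates are clamped to zero with the excess transferred to the sibling so
the pair's path length is preserved (alternatives — leaving negatives, or
re-estimating — make downstream display order nondeterministic). Rooting
places the root at the midpoint of the branch separating a monophyletic
outgroup. Newick output quotes labels containing metacharacters;
`read_newick()` exists because `ape::read.tree` preserves the quote
characters verbatim.

**Folded SFS and Tajima's D.** Genotypes are hard calls: the
genotype-likelihood machinery used upstream of this package operates on
BAMs, which are out of scope, so sites with any missing genotype in the
focal group are excluded entirely (the all-individuals requirement), and
minor-allele counts are folded as `min(a, n−a)`. Tajima's D uses the 1989
constants computed from `n = 2 ×` group size; `D` is `NA` when `S = 0`, and
a warning is raised for `n < 4` where the variance formula is unstable.
Sliding windows overlap (50 kbp / 10 kbp by default), so neighboring window
values are autocorrelated; that is reproduced as specified, not corrected.

**Novel alleles.** A site is *eligible* when every reference-panel
individual (wild + outgroup by default) is homozygous reference; a focal
group is *flagged* when at least one member carries the alternate. The
definition is deliberately reference-orientation-bound (no ancestral-state
polarization beyond including the outgroup in the panel). Both the total
filtered-site count and the eligible-site count are carried as attributes
because percentage denominators are ambiguous in the source convention.
The overlap table uses exactly-this-subset semantics, so it is a partition.

## The synthetic-cohort generator

`simulate_wf()` is a discrete-generation forward Wright–Fisher simulator
with infinite-sites mutation on a continuous coordinate line, Poisson
crossovers per meiosis, partial selfing, piecewise-constant deme sizes,
splits, and constant migration, compiled via Rcpp. Forward simulation was
chosen over a coalescent because selfing, migration, and arbitrary
piecewise demography compose trivially forward in time, at the price of a
burn-in (≥ 10·Ne generations, enforced). Positions fixed across every
living haplotype are purged periodically — the segregating set is what the
statistics see; the reference allele silently absorbs substitutions, which
is also what a reference assembly does. Sampling at the end is by
*individual*, keeping each sample's two haplotypes paired so that
selfing-induced homozygosity survives into `draw_diploids()`.

**Desk scaling.** All presets keep Ne ≤ 500 and inflate μ and r to hold
4Neμ and 4Ner at realistic values; times scale with Ne. The study-scale
parameters (μ = 4.56e-9 per site per year, 1-year generations) are
preserved only through these compound parameters. What a green test
establishes is therefore that the estimators recover the parameters of the
stated model at desk scale — not that the pipeline reproduces any number
computed from the real 65-genome cohort, which would need the deposited
reads and the unpublished reference.

**Presets.**

* `neutral_equilibrium` — one deme, N = 100, μ = r = 2.5e-4: θ = 0.1/site.
  At these exact values E[S] in a 10-haplotype sample of 10 kbp is
  θ·a1(10)·L ≈ 2,829, the Watterson check in the acceptance suite.
* `two_deme_island(Nm)` — two demes of N = 100. The declared `Nm` is the
  island-model *effective* migrant number: for two demes with pairwise
  migration m, coalescent theory gives T_within = 4N and
  T_between = 4N + 1/(2m), hence Fst ≈ 1/(1 + 8Nm_pair) — twice the
  infinite-island rate. The preset therefore sets m_pair = Nm/(2N) so that
  the textbook expectation E[Fst] = 1/(1 + 4Nm) applies to the declared
  parameter. This was fixed from theory (and checked against an
  independent coalescent simulator) before the package's own simulator ran.
* `domestication_series` — the full six-group cohort: wild root (N = 120,
  selfing 0.5), a deep outgroup (split 800 generations), an isolated
  island deme "MK" (split 500, N = 40, selfing 0.7), two landraces
  (split 300 through a 15-individual bottleneck to N = 40, selfing 0.75),
  and a cultivar (split 100 from LR2 through N = 6 to N = 12,
  selfing 0.9). At desk scale populations sit near mutation–drift
  equilibrium within ~2Ne generations of an event, so the diversity
  ordering wild > landraces > cultivar is carried by the ordered
  equilibrium θ_eff = 4Neμ/(1+F_selfing) values, with the bottlenecks
  supplying the transient; this is the reason the preset orders present-day
  Ne and not only bottleneck depths.
* `island_relict` — one deme: N = 150 before a crash to 20 at 100
  generations back, re-expansion to 200 at 30 back, decline to 80 at 4
  back — the study-scale crash ≈ 10,000 and expansion ≈ 3,000 years ago
  shrunk 100-fold, with 1-year generations making years and generations
  interchangeable. Most lineages coalesce in the long bottleneck, so
  post-expansion genealogies are star-like: genome-wide Tajima's D is
  negative and the folded SFS is singleton-enriched relative to the
  neutral expectation — the qualitative signature of the relict-island
  history.

**What the generator does not emulate:** sequencing reads and genotyping
error, indel/multiallelic mutation (emitted sites are biallelic SNPs;
indel and multiallelic handling is exercised by hand-built fixtures),
linked selection, gene conversion, and variable recombination. Depth
annotations are Poisson site means, enough to give depth filters teeth but
not a coverage model.

## Numerical and interface choices

* Coordinates: VCF positions are 1-based; intervals are 0-based half-open
  (BED). A site at `pos` is genic iff `start ≤ pos−1 < end`.
* MAF/MAC are computed on called genotypes only; a mac/maf threshold of 0
  disables the clause. Sites without depth annotations pass depth filters
  (synthetic data may omit depth); this is logged in the clause matrix
  attached to `filter_sites()` output.
* Half-calls (`0/.`) are missing; "invariant" means no alternate allele
  observed among called genotypes, so an ALT-listed site never observed
  alternate is invariant.
* Dosage storage collapses multiallelic genotypes to non-reference counts.
  On write, a multiallelic hom-alt is serialized `1/2` so the
  observed-allele count (and the `multiallelic` class) survives a round
  trip; a multiallelic site whose genotypes never carry two alternates
  re-reads as `snp` — a documented representational limit.
* Mean depth is written as the Float INFO field `MEANDP` (the model stores
  per-site means, not per-sample DP); `read_vcf()` prefers mean FORMAT/DP,
  then `MEANDP`, then INFO/DP divided by sample count.
* VCF parse errors are reported with file context but without line numbers
  (the underlying Bioconductor parser does not expose them); this trades
  an error-message nicety for not reimplementing a VCF parser.
* The discretization of continuous simulated positions to integer
  coordinates pushes collisions to the next free base (and pulls back at
  the chromosome edge), so emitted positions are unique and order-preserving
  as long as the variant count fits the chromosome.
* Seeds: every stochastic entry point takes an explicit seed; the C++ core
  draws from R's RNG, so `set.seed()` governs the whole chain
  (simulate → emit → read → statistics is bit-reproducible).

## Open questions resolved here

* The upstream filter preset differs between the 65-sample SNP set (with
  MAF 0.05 and depth bounds) and the 67-sample novel-allele set (without);
  both presets are provided verbatim (`filter_preset()`) and not
  harmonized.
* "Average observed heterozygosity" is read as the per-group mean of
  per-individual heterozygous proportions; `group_het_summary()` emits that
  alongside the per-individual report so the per-site variant can be formed
  by the caller.
* Whether published π tables pool or average windows is unstated;
  `summarize_windows()` reports both, labeled.
* The down-sampled LD replicates are emitted both raw (one curve per
  replicate) and as a pointwise mean, since the display convention
  ("ten lines") is not an algorithmic statement.

## Known limitations

* `het_fis()` on a structured cohort measures inbreeding relative to pooled
  frequencies (Wahlund-inflated); compute it per group if within-group
  F_IS is wanted.
* The finite-island F_IS expectation differs from s/(2−s) by O(1/N) terms;
  at the desk-scale N = 100 used in tests the identity-coefficient
  equilibrium is ≈ 0.655 for s = 0.8 rather than 0.667, well inside the
  tolerance the acceptance criterion allows but visible if tolerances were
  tightened.
* `ld_prune()` is quadratic per window and intended for the tens of
  thousands of genic SNPs of the mirrored workflow, not whole-genome SNP
  sets.
* The pipeline's stage-skip logic is by output existence, not content
  hashing of inputs; delete outputs (or the directory) to force recompute.
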