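---
title: "Panel biomarkers, survival and enrichment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel biomarkers, survival and enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelmarkers)
```

panelmarkers implements the analysis chain used to characterise a mutated
gene's phenotype in a targeted-panel tumor sequencing cohort: somatic-call
filtering, per-sample instability biomarkers (TMB, MSI, CIN), the
gene-level mutation landscape, mutation-status group comparisons, overall
survival models, and phenotype-permutation gene-set enrichment.  This
vignette documents the statistical methods, the tunable parameters, the
synthetic-cohort generator that makes every stage testable, and the design
decisions taken where the methodology is genuinely open.

## Somatic-call filtering

A call is retained iff its variant allele frequency (VAF, alt reads over
total depth) is **at least 2%** and it has **at least 5** supporting reads,
both bounds inclusive, and it matches neither the positional artifact list
nor the per-call artifact flag.  Matched-normal subtraction is assumed to
have happened upstream in the caller.  The filter is idempotent and
monotone in both thresholds; both are config values (`min_vaf`,
`min_alt_reads`).  No strand-bias or mapping-quality filtering is done
here — those belong to the caller, not this post-filter.

## Tumor mutational burden

TMB is the count of somatic, coding, nonsynonymous substitutions and
indels (classes `missense`, `nonsense`, `frameshift_indel`,
`inframe_indel`, `splice`; synonymous calls never count), excluding calls
flagged as known driver mutations, divided by the panel footprint in
megabases.  The driver list is user-supplied (the `is_known_driver`
column); the default is empty.  `panel_mb` is a required configuration
value with default 1.6 Mb, a typical footprint for a ~400-gene panel.  TMB
is stored raw (mutations/Mb); plots and Cox covariates use
`log2(TMB + 1)` via `tmb_log2()`.

## Microsatellite instability

Each of the panel's mononucleotide-repeat sites (52 by default, minimum
repeat length 15 bp) contributes a paired tumor/normal read-length
histogram.  A site with fewer than `msi_min_reads = 20` reads in either
histogram is *not evaluable*.  Otherwise tumor and normal length
distributions are compared with a chi-square test on the 2 × k table of
length bins, merging any bin whose expected count falls below 5 into its
smaller neighbour (df = k′ − 1 after merging); a two-sample
Kolmogorov–Smirnov alternative is selectable (`msi_test = "ks"`).  The
site is *unstable* iff the test rejects at `msi_alpha = 0.05`.  The choice
of test is exposed rather than hidden because "significantly differed" is
the entire published definition of site instability in assays of this
type; chi-square on pooled bins is the natural test for discrete length
histograms and KS the natural nonparametric alternative.

The sample-level MSI fraction is unstable / (unstable + stable) sites,
excluding non-evaluable ones, and the sample is called **MSI iff the
fraction strictly exceeds 40%** (`msi_threshold`): 21 unstable of 52
evaluated (0.404) is MSI, 20 of 50 (exactly 0.40) is MSS.  The continuous
fraction is also reported and used as the "MSI score" in group
comparisons — the score is not defined separately from the fraction
anywhere in the source methodology, so the fraction is the score here.

## Chromosomal instability

CIN is the proportion of copy-number segments whose log2 ratio lies
*strictly* outside ±0.2 ("exceeding 0.2 or falling below −0.2"; a segment
at exactly ±0.2 is not aberrant).  Count weighting is the default, since
the definition speaks of a proportion *of segments*; base-pair length
weighting (`cin_weighting = "length"`) is offered because many copy-number
pipelines report the genome-fraction variant of the statistic.

## Mutation landscape

The oncoprint matrix is binary gene × sample: 1 iff the sample has at
least one retained nonsynonymous call in the gene.  Pairwise
co-occurrence/mutual exclusivity uses a two-sided Fisher's exact test on
each gene pair's 2 × 2 table, Benjamini–Hochberg correction across tested
pairs, and a direction call (odds ratio > 1 co-occurring, < 1 mutually
exclusive) only at q ≤ 0.05.  Genes mutated in fewer than `min_mutated =
5` samples are not tested.  Inside the full pipeline, pairwise testing is
additionally restricted to the `landscape_top_genes = 25` most frequently
mutated genes — the depth of a typical oncoprint panel — so the quadratic
pair count stays meaningful; `pairwise_association()` itself has no such
restriction.

## Group comparisons

Continuous readouts (age, TMB, CIN, MSI fraction, cell-type scores) are
compared between mutated and wild-type samples with the two-sided
Mann–Whitney U test; sex with Fisher's exact test; the stage distribution
with a Pearson chi-square on the 2 × k table (a warning is attached when
any expected cell is below 5).  The Mann–Whitney p-value is exact — full
enumeration of label assignments, valid under ties — whenever the total
sample size is at most 12, and uses the normal approximation with tie and
continuity correction otherwise.  The mutated and wild-type patient groups
are independent, so the unpaired rank-sum test is the correct choice; a
paired signed-rank test has no valid pairing in this design.  Cell-score
comparisons are BH-adjusted across score rows (aggregate rows such as an
immune score are treated simply as additional rows), with the usual
significance tiers (&lt;0.001, &lt;0.01, &lt;0.05).

## Survival

Kaplan–Meier curves use the product-limit estimator with standard
right-censoring handling, and groups are compared with the log-rank test;
model fitting is delegated to the survival package.  Cox
proportional-hazards models (univariate per covariate, or one joint
multivariate model) use the Efron approximation for tied event times — the
accepted default under moderate ties.  Covariate encodings: sex as an
indicator of male, stage as ordinal numeric by default (categorical
optional, `stage_as_factor`), MSI as a binary indicator of MSI status, and
TMB on the `log2(TMB + 1)` scale.  A constant covariate is an error;
suspected complete separation (|log HR| > 15) is flagged as non-converged
rather than reported silently.  Two-gene stratified curves form the four
mut/wt combinations, dropping empty strata with a warning.

## Gene-set enrichment

Genes are ranked by signal-to-noise: (mean~mut~ − mean~wt~) divided by the
sum of the group standard deviations, each floored at 0.2 × |group mean|
(and at 0.2 when the mean is zero).  Both phenotype groups need at least 3
samples.  The enrichment score is the classic weighted running sum: hits
add |metric|^p^ / Σ~hits~|metric|^p^ (p = 1 by default), misses subtract
1/(N − N~hits~), and ES is the extremum by absolute value; at p = 0 this
reduces to the unweighted Kolmogorov–Smirnov statistic.  The null is built
by phenotype permutation — relabelling samples (1000 permutations by
default) and re-ranking genes each time, which preserves gene–gene
correlation.

Normalisation is sign-separated: NES = ES / mean(|same-sign null ES| of
the same set).  Each *null* ES is normalised leaving itself out of that
mean; including it shrinks exactly the extreme null values relative to the
observed one and makes tail inference anti-conservative (we verified the
effect by simulation before adopting the leave-one-out form).  The nominal
p is the same-sign tail of the set's own null.  FDR q compares the
observed NES against the pooled null NES distribution, positive and
negative sides separately.  A family-wise `fwer_p` is also reported:
|NES| against the per-permutation maximum of |null NES| over all sets,
two-sided because selecting "the most extreme set" scans both signs.
Under null simulations the top set's `fwer_p` is uniform (3.3% of 60 null
cohorts below 0.05; KS p = 0.97).

## The synthetic-cohort generator

`simulate_cohort()` generates everything the pipeline consumes, with a
programmable effect of one focal gene on every readout, and emits ground
truth (focal status, true MSI status, per-sample hazard) for recovery
testing.  Defaults describe a large colon-cancer panel cohort: 3702
samples, focal gene PKHD1 at frequency 424/3702 ≈ 11.45%, background
drivers TP53/APC/KRAS/SMAD4/PIK3CA at 73/57/40/19/20%, 59% male, age
N(60, 10), stage probabilities (0.15, 0.25, 0.35, 0.25) with a ×1.5
stage-2 enrichment among focal-mutated samples.

* **Variants.** Each mutated driver gene contributes one call flagged
  `is_known_driver` with VAF ≥ 4.5% and ≥ 5 reads.  TMB-eligible
  passenger counts are Poisson with mean `tmb_base × panel_mb` (default
  6/Mb × 1.6 Mb), times `tmb_fold = 2.5` in mutated samples — flagging
  drivers makes the Poisson count exactly the TMB numerator after driver
  exclusion.  Synonymous passengers (0.25 × that rate) and three decoy
  classes (sub-2% VAF, 1–4 supporting reads, artifact-flagged) are layered
  on top with fates guaranteed by construction, so filter recovery is
  checkable per call.
* **MSI.** A sample is truly MSI with probability 0.10 (wild-type) or
  0.35 (mutated); MSI enrichment of this size is what hypermutated
  colorectal subgroups show, and it makes the MSI contrast detectable at
  the n = 1000 scale the recovery tests use.  Site histograms are
  discretised normals around the reference repeat length (15–25 bp);
  unstable sites shift 3 bp shorter with 1.5× dispersion — deletion
  stutter.  MSI samples have each site unstable with probability 0.7, MSS
  samples 0.01.
* **Copy number.** Each of 40 segments is aberrant with probability
  `cin_mean` (0.30 wild-type / 0.20 mutated), drawn strictly outside
  ±0.2 when aberrant and strictly inside otherwise, so expected CIN
  equals the configured mean exactly.
* **Survival.** Exponential proportional hazards: baseline median 36
  months at the reference covariates, HR 2.0 for the focal mutation, 1.03
  per year of age (centred at 60), 1.6 per stage step (centred at 2).
  Administrative censoring is uniform on (0, t~max~), with t~max~ solved
  numerically so the expected censored fraction equals `censor_rate =
  0.3` given the realised hazards.
* **Expression and cell scores.** Gene means uniform on log2 3–8 with
  unit normal noise; 50 disjoint hallmark-style sets of 20 genes; the two
  interferon-response sets are shifted −1 log2 unit in mutated samples.
  Twelve xCell-style score rows, the first seven shifted +0.8 SD in
  mutated samples.

One root seed drives everything; each component derives its own
sub-stream by hashing the component name with the seed, so disabling a
component (the `components` argument) leaves the others byte-identical.
The generator emulates the *statistical structure* of such a cohort, not
its biology: mutations are independent across genes (no real
co-occurrence structure), there are no trinucleotide signatures, no
tumor-purity gradient, no germline contamination, and expression noise is
homoscedastic.  Tests passing on these cohorts therefore demonstrate that
the statistics recover programmed effects at realistic sizes and hold
their error rates — not that any particular biological claim transfers to
real data.

## Numerical and testing choices

Degenerate inputs have defined behaviour throughout: empty call sets give
TMB 0; zero evaluable MSI sites give `not_evaluable`; empty segment lists
give `NA` CIN; all-tied rank tests report p = 1; gene sets with no
overlap give `NA` results and whole-list sets are flagged degenerate.
Ties in the gene ranking break deterministically by gene identifier, so
permutation results are reproducible bit for bit under a fixed seed.

Validation sizes were chosen to make each check informative at desk
scale: exact-test oracles enumerate completely (all 2 × 2 tables to
n = 30, all rank assignments to n = 12); null calibrations use 2000
replicates (binomial SE ≈ 0.5% on a 5% rate); hazard-ratio recovery uses
500 replicates at n = 500; GSEA recovery uses 20 seeds at 200
permutations; the end-to-end direction check runs one effects cohort and
one null cohort at n = 1000 with the default 1000 permutations.

## Limitations

The MSI caller consumes per-site histograms, not BAMs, and applies no
tumor-purity correction; real low-purity samples attenuate the length
shift in a way the generator does not model.  Copy-number segmentation is
upstream of this package.  The co-occurrence analysis is pairwise
Fisher — dedicated mutual-exclusivity models (DISCOVER, CoMEt) that
condition on per-sample mutation burden are out of scope, and burden
confounding can inflate apparent co-occurrence.  Cox diagnostics stop at
convergence/separation checks; proportional-hazards testing is left to
the survival package's tooling.  xCell-style scores are inputs, never
recomputed.
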