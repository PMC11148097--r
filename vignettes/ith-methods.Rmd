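---
title: "Quantifying multi-layer intratumor heterogeneity with ithlayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-layer intratumor heterogeneity with ithlayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithlayers)
```

## The analysis model

`ithlayers` analyses cohorts in which each tumor was sampled in several
spatially separated regions (typically three, at least 0.3 cm apart)
together with one matched normal, and each region profiled on up to four
molecular layers: somatic mutations, copy number, DNA methylation and gene
expression. The pipeline starts downstream of the external callers — it
consumes MAF-like mutation tables, SEG-like segment tables, BED-like
window methylation counts and an expression matrix, never raw reads.

The core quantity is per-patient, per-layer **pairwise intratumor
heterogeneity**. For the discrete layers each region is reduced to a set of
alteration keys and region pairs are scored by the Jaccard distance
$d_J(V_i,V_j) = 1 - |V_i \cap V_j|/|V_i \cup V_j|$; a pair where both sets
are empty has no defined distance and is reported missing. For the
continuous layers each region's purity-corrected profile is sum-normalised
to a probability distribution and pairs are scored by the Jensen–Shannon
distance with base-2 logarithms,
$JSD(P_1,P_2)=\sqrt{\tfrac12[D_{KL}(P_1\|R)+D_{KL}(P_2\|R)]}$ with
$R=(P_1+P_2)/2$. Base 2 matters: only then is the distance bounded by 1
(reached exactly when the supports are disjoint). No pseudocount is added
before the divergence — the KL terms are always taken against the mixture
$R$, which is positive wherever either input is, so zeros are harmless and
$0\log 0 = 0$ applies. A per-patient summary is the arithmetic mean over
the $\binom{k}{2}$ defined pairs; the raw pairs are also exported because
cross-layer correlations are computed on pairwise values, not means.

### From call tables to variant sets

Three rules precede the mutational metrics, each with deliberately strict
inequalities (boundary values pass):

1. **Sample QC** — keep a sample iff QScore ≥ 35, contamination ≤ 0.02 and
   mean depth ≥ 30×; exclusions are logged with a reason, and a missing
   metric is itself a reason.
2. **Call filtering** — keep an SNV iff it has ≥ 6 alt-supporting reads,
   a small indel iff ≥ 8 (a call is an indel iff ref/alt lengths differ);
   drop anything above 1% population frequency as presumed germline.
3. **Cross-region rescue** — a variant that passed in one region of a
   patient and has ≥ 1 raw alt read in another region of the same patient
   is called there too. Rescue repairs the false-negative sharing that
   multi-region designs are prone to; it is monotone and idempotent, and it
   runs *after* the population-frequency filter — germline contamination is
   never rescuable. (Applying the frequency filter second would let one
   passing region resurrect a germline call everywhere; nothing in the
   analysis chain benefits from that order.) Support thresholds apply per
   region, not to pooled counts, matching how per-region call tables are
   produced.

Trunk/branch classification then operates on the post-rescue presence
matrix: a variant present in **all** tumor regions is trunk, anything else
is branch. Classifying pre-rescue would systematically deflate trunk
proportions by exactly the false negatives the rescue exists to repair. A
patient with zero variants has undefined proportions, reported missing
rather than 0/0. TMB is the missense count, optionally per megabase of a
39 Mb covered exome.

### Copy number

Arm-level calls use the >60% rule: an arm is a gain in a region iff the
amplified segments account for *strictly more than* 60% of that arm's
segments (losses analogously; both cannot exceed 60% simultaneously). The
fraction is computed over segment **counts** by default because that is the
natural reading of segment-based calling; a `by = "length"` switch weights
by genomic span instead for users whose segmentation produces very uneven
segments. An arm with no segments yields `none` with missing fractions.
Non-`none` calls become binary event keys (`"1p:gain"`) that feed the CNV
Jaccard ITH and the phylo-CNV tree, the same presence/absence
representation as mutations.

### Purity correction

A bulk region profile is modelled as a two-component linear mixture,
$\mathrm{obs} = p\,\mathrm{tumor} + (1-p)\,\mathrm{normal}$ with $p$ the
region's tumor purity, and inverted in closed form against the matched
normal profile, clamping to $[0,1]$ for beta values and $[0,\infty)$ for
expression. The linear model is the standard deconvolution identity; using
it for both methylation and expression keeps the correction exactly
invertible and therefore exactly testable — on noiseless mixtures the
correction recovers the tumor component to 1e-12. The matched patient
normal is the default reference (a pooled normal mean is a reasonable
fallback when a matched normal failed QC). Purity is carried per region:
different regions of one tumor legitimately differ in purity, and nothing
downstream requires reconciling them.

### Differential methylation

The simplified DMR caller works on windows (default 100 bp tiling,
counts pooled across CpGs and samples within each group), tests each
window's pooled methylated/unmethylated 2×2 table with Fisher's exact
test, adjusts with Benjamini–Hochberg, and calls a DMR iff
$|\Delta\beta| \ge 0.2$ **and** $q < 0.05$. BH is the conventional
q-value procedure here; the effect-size and FDR thresholds are the
substantive part of the rule and are preserved exactly. Windows with fewer
than 5 pooled reads (configurable) are dropped as low-quality.

### Trees

Per patient and layer, Euclidean distances are computed between sample
rows — binary alteration vectors (the normal sample enters as all-zero)
or purity-corrected profiles (the normal enters with its measured
profile) — and a tree is fitted by **ordinary-least-squares minimum
evolution**. Because the leaf count is tiny (4 with the standard 3+1
design), the package enumerates *every* unrooted binary topology (3 at
4 leaves, 10,395 at 8, the supported maximum), fits branch lengths by OLS
against the distance matrix, clamps negative fitted lengths to zero, and
selects the topology with the smallest total clamped length. This replaces
a heuristic tree search with an exact procedure at no practical cost; for
additive inputs it provably inverts path-distance computation, which the
tests exercise to 1e-9. Ties (e.g. star-like matrices) are broken by a
lexicographic encoding of leaf splits, which also makes the output
invariant to leaf input order. Clamping before the total-length comparison
is a presentation convention; `clamp_negative = FALSE` retains raw OLS
lengths. The tree is rooted at the normal sample for display. Concordance
between a patient's phylogenetic and phyloepigenetic trees is the
Robinson–Foulds distance on unrooted topologies, with "aligned" defined as
RF = 0 — a deliberately strict operationalisation of structural agreement,
since no branch-length-aware criterion is obviously better and RF = 0 is
reproducible.

### Cohort statistics

Cross-layer relationships are Spearman correlations on pairwise (region
pair) ITH values within each subtype; subtype contrasts are Wilcoxon
rank-sum tests on pairwise values; driver enrichment compares per-patient
trunk vs branch driver fractions (driver = annotated oncogene/TSG role,
in practice the COSMIC census), with patients lacking a side contributing
missing values. The Wilcoxon implementation uses the exact null
distribution when the combined sample size is ≤ 12 with no ties and the
tie-corrected, continuity-corrected normal approximation otherwise — the
switchover keeps exactness where it is cheap at these cohort sizes.
Survival stratification splits patients at the median of per-patient mean
ITH (strictly above the median is "high"; values equal to the median go
"low" — the tie side is arbitrary but must be fixed for determinism, and
is configurable), then compares groups per endpoint with Kaplan–Meier
estimates and the log-rank test, the standard companion of KM curves. The
KM median is the first time the curve drops to 0.5 or below, "not reached"
otherwise. Multivariate Cox modelling is deliberately left to `survival`
or any other package — the exported per-patient table carries everything
needed.

## The synthetic cohort generator

`simulation_config()` fixes the study conditions; `simulate_cohort()`
draws from them deterministically (one substream per patient derived from
the master seed, so per-patient data are stable under cohort
recomposition). The generator emulates:

- two subtypes whose clonal architecture differs sharply: mutations are
  truncal with probability 0.663 (H-like) or 0.172 (L-like), the cohort
  medians the design targets; branch mutations get a uniformly chosen
  non-empty proper subset of the 3 regions (the trunk/branch dichotomy is
  the only clone structure the statistics use, so no deeper clone tree is
  modelled);
- read counts Binomial(depth, purity/2) in carrying regions at 250×/75×
  tumor/normal depth, with purity uniform on (0.3, 0.8) — a free choice,
  as no per-patient purities are published for such cohorts;
- sporadic alt reads in non-carrying regions at rate 1e-4 per site. This
  is the residual artifact-support rate of caller-emitted candidate
  tables, not the raw per-base instrument error (~1e-3): at 250× the raw
  rate would give ≥1 supporting read at 22% of sites, converting ~14% of
  branch mutations to trunk through the rescue rule and making the
  configured trunk fractions unrecoverable by construction. At 1e-4 the
  rescue rule still sees regular traffic (~2.5% of non-carrying sites)
  while trunk-fraction recovery stays within the 0.05 the validation
  demands;
- 2% of mutations carry population frequency > 1% to exercise the
  germline filter; drivers occur at 5% baseline with trunk odds ×3;
- methylation windows with Beta(2,8) normal betas, 10% DMR windows
  shifted by ±0.3 in the tumor component with the same trunk/subset clone
  structure, observed betas purity-mixed and binomially sampled at ~300
  pooled reads per window (per-CpG coverage ~34× times roughly nine CpGs
  per targeted window);
- purity-mixed log-normal expression with fold-changes on 10% of genes;
- arm-level CNV events (Poisson mean 4) setting 80% of a carried arm's
  segments, over a 5% per-segment noise floor — recoverable by the >60%
  rule but not trivially clean;
- exponential survival whose hazard is scaled for the high-genetic-ITH
  group (the L-like, low-trunk-fraction patients), with uniform censoring
  calibrated to the target censoring fraction. Tying the hazard to a
  configured group makes survival validation a parameter-recovery
  exercise, not a biological claim.

What the generator does **not** emulate — realistic genome coordinates,
trinucleotide signature structure, CNV–VAF multiplicity consistency,
FFPE damage beyond the QC thresholds, or correlated layers beyond the
shared clone structure. Passing tests therefore demonstrate that the
statistical machinery recovers known truth under the stated generative
model, not that real tumors satisfy that model.

## Validation design and problem sizes

The test suite validates against independent oracles: a term-by-term
brute-force JSD on 1,000 random distribution pairs (agreement to 1e-9);
additive-metric round trips and an independent OLS tree builder
(`ape::fastme.ols`) for minimum evolution; a hand product-limit loop for
KM (1e-12); exact Fisher p-values for the DMR caller. Parameter recovery
uses 20 seed-swept cohorts of 20 patients × 3 regions (trunk-fraction
recovery within 0.05; mutational ITH ordered L > H in ≥90% of seeds).
Error control uses 50-seed null sweeps (DMR false positives, log-rank
type I) and a 25-seed power sweep at hazard ratio 4 with 40 patients.
These sizes keep the full suite under two minutes while leaving the
binomial/Monte-Carlo margins comfortable.

## Known limitations

- The methylation JSD uses all covered windows by default; restricting to
  DMR windows is possible upstream but changes the metric's scale.
- Exhaustive tree search stops at 8 leaves; larger designs need a
  heuristic builder and are out of scope.
- RF = 0 is a strict alignment criterion; near-concordant trees (one NNI
  apart) count as not aligned.
- The linear purity correction amplifies count noise by 1/purity; at low
  purity and shallow coverage the corrected profiles are noisier than the
  observed ones, which is why the generator's window depth pools CpGs.
- Focal CNV discovery (GISTIC-style peak calling) is not implemented;
  focal events enter, if at all, as pre-labelled event columns.
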