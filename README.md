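# ithlayers

Multi-region tumor sequencing samples several spatially separated regions
of one tumor (plus a matched normal) and asks how much the regions differ —
the tumor's **intratumor heterogeneity (ITH)**. `ithlayers` quantifies ITH
across four molecular layers from standard call tables, for cancer
genomicists analysing multi-region cohorts:

- **Mutational and CNV ITH** — each region is reduced to its set of somatic
  alterations \(V_i\) (post-rescue variant keys, or arm-level copy-number
  events), and each region pair scored by the Jaccard distance

  d_J(V_i, V_j) = 1 − |V_i ∩ V_j| / |V_i ∪ V_j|,

  0 for identical regions, 1 for disjoint ones.
- **Methylation and transcriptional ITH** — each region's tumor-purity-
  corrected profile is sum-normalised into a probability distribution and
  pairs are scored by the Jensen–Shannon distance

  JSD(P₁, P₂) = sqrt(½ [D_KL(P₁‖R) + D_KL(P₂‖R)]),  R = (P₁+P₂)/2,

  with base-2 logarithms, so JSD ∈ [0, 1].

Around these metrics the package implements the full analysis chain:
sample QC (QScore ≥ 35, contamination ≤ 0.02, depth ≥ 30×), somatic-call
filtering (SNV ≥ 6 / indel ≥ 8 supporting reads, ≤ 1% population
frequency), cross-region rescue of low-frequency calls, trunk/branch
classification (trunk = shared by *all* regions), TMB, the >60% arm-level
CNA rule, linear two-component purity correction of methylation/expression,
a simple windowed DMR caller (≥ 0.2 beta difference, BH q < 0.05),
exact minimum-evolution trees (exhaustive topology enumeration + OLS branch
lengths) rooted at the normal sample with Robinson–Foulds concordance
between phylogenetic and phyloepigenetic trees, cross-layer Spearman
correlations, and median-split Kaplan–Meier/log-rank survival
stratification. A synthetic cohort generator with known ground truth
(clone structure, purities, DMRs, hazard groups) makes every stage
testable.

## Worked example

```r
library(ithlayers)

cfg <- simulation_config(n_patients_H = 4, n_patients_L = 4, seed = 42)
sim <- simulate_cohort(cfg)
res <- run_pipeline(sim$bundle)
summary(res)
```

```
ITH analysis: 8 patients
  cnv             cohort mean ITH = 0.4127
  methylation     cohort mean ITH = 0.1848
  mutational      cohort mean ITH = 0.4309
  transcriptional cohort mean ITH = 0.1095
  phyloepigenetic trees aligned with phylogenetic: 2/8
Subtype comparison of pairwise ITH (Wilcoxon rank-sum):
           layer     mean_H    mean_L  U            p n_H n_L
      mutational 0.22995766 0.6318015  0 3.644203e-05  12  12
             cnv 0.22727273 0.6805556 30 2.182582e-02  11  12
     methylation 0.17566877 0.1939729 49 1.939309e-01  12  12
 transcriptional 0.09347463 0.1254963 26 8.615558e-03  12  12
Survival, mutational ITH median split: OS log-rank p = 0.7166
...
```

The H-subtype patients are simulated mostly truncal (trunk fraction 0.663)
and the L-subtype mostly branched (0.172), so pairwise mutational ITH is
much higher in L than H (0.63 vs 0.23; Wilcoxon p ≈ 4e-5) while the purity-
corrected methylation layer barely separates — the pattern the per-patient
trunk proportions confirm:

```r
res$report$trunk_branch
#>   patient_id n_trunk n_branch trunk_proportion
#> 1        P01      71       44        0.6173913
#> ...
#> 8        P08      14       85        0.1414141
```

`save_report(res, "out/")` writes a deterministic `report.json` (sorted
keys, full precision), per-stage TSVs and one Newick tree per patient and
layer. Cohorts round-trip through TSV tables with
`write_cohort()`/`load_cohort()`, and
`inst/cli/ithlayers.R` wraps simulation and analysis for shell use.

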