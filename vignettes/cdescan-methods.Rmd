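---
title: "Methods: detecting driver-mutation selection in CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting driver-mutation selection in CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdescan)
```

## The problem

CRISPR-Cas9 knockout cuts DNA. The double-strand break triggers a
p53-mediated damage response, so in a mixed population the cells that
already carry an inactivating driver mutation (p53, and as it turns out
other drivers such as KRAS) can tolerate editing better than their
wild-type neighbours. Knocking out *certain* genes amplifies this
difference, and those knockouts therefore *select* for pre-existing
driver-mutant cells — a safety problem for CRISPR screening and editing,
and a biological signal in its own right.

`cdescan` detects this selection signature from data:

* **CDE+ genes** — genes whose knockout leaves driver-mutant cell lines
  *more viable* than driver-WT lines in CRISPR-KO screens, while shRNA
  knockdown of the same gene shows no such differential. The
  CRISPR-specificity is the point: shRNA does not cut DNA, so a
  cut-dependent selection mechanism should vanish there.
* **CDE− genes** — the mirror image (WT more viable after knockout).
* **CRISPR-selected cancer drivers (CCDs)** — driver genes for which the
  genome-wide *count* of CDE-like genes is skewed between the CRISPR and
  shRNA modalities far beyond chance.

## The core procedure

Throughout, viability scores follow the DepMap gene-effect convention:
**lower = more essential**. Readers flip declared-inverted inputs
(`invert = TRUE`).

For one driver on a panel of cell lines profiled in both modalities:

1. **Mutation profile** (`derive_mutation_profile`). A line is mutant iff
   it carries a qualifying non-synonymous variant of the driver; silent and
   intronic variants never qualify. Three modes: `any_nonsynonymous`
   (default), `lof_only` (nonsense/frameshift/indel plus the four classic
   p53 DNA-binding-domain hotspots R248Q/R273H/R248W/R175H), and
   `gof_hotspots` (listed activating changes only; the KRAS default is
   G12D/G12V/G13D — the literature's canonical activating hotspots, kept
   configurable because no single canonical list exists).
2. **Per-gene differential essentiality** (`classify_differential`). A
   rank-sum test of post-knockout viability between mutant and WT lines per
   gene, BH-corrected across all genes of the modality, classified
   `pos`/`neg`/`ns` by q < 0.1 and the sign of the median difference
   (mutant median minus WT median). The default is a two-sided p with
   direction read from the medians; a one-sided mode (per-direction
   p-values, BH within direction) is available, since either reading is
   compatible with how such screens are analyzed in practice. Missing
   values are excluded pairwise per gene. An optional covariate mode
   regresses viability on copy number per gene first and tests the
   residuals.
3. **Copy-number confound filter** (`cn_association_filter`). Genes whose
   copy number is itself associated with the driver's mutation status
   (rank-sum, BH, q < 0.1) are removed from the CDE sets: amplification
   artifacts in CRISPR screens would otherwise masquerade as selection.
4. **CDE sets** (`identify_cde`). CDE+ = CRISPR-`pos`, not shRNA-`pos`,
   not CN-filtered. The shRNA exclusion is *same-direction* by default: a
   gene significant in shRNA in the opposite direction still counts as
   "not showing this differential essentiality". The stricter
   any-direction rule is a config option (`shrna_exclusion`).
5. **Modality skew** (`build_contingency`, `skew_test`). The 3×2 table of
   pos/neg/ns counts per modality is tested with Fisher's exact test,
   replaced by its Pearson chi-squared approximation when every cell
   exceeds 30 (`chi2_min_cell`); exact enumeration is used up to table
   totals of 500, a seeded Monte-Carlo estimate beyond.
6. **Genome-wide scan** (`ccd_scan`). Steps 1-5 for every candidate driver
   with ≥ 10 mutant lines (`min_mutant_lines`), BH across drivers on the
   skew p-values, plus a pairwise Fisher independence filter of each
   candidate's mutation profile against a reference driver (p53 by
   default) so that candidates merely co-mutated with p53 are flagged
   rather than reported. A driver is *reported* when skew q < 0.1, it has
   more than `ccd_min_cde_pos` CDE+ genes (300 at biobank scale), and it
   is not reference-correlated. Ranking is deterministic: skew q, then
   CDE+ count, then gene id.

## Statistical primitives

All stages share one set of primitives (`rank_sum_test`,
`signed_rank_test`, `bh_fdr`, `hypergeom_tail`, `fisher_rxc`,
`average_precision`, `glm_fit`), each of which records the method it used
(`exact`, `normal_approx`, `chi2_approx`, `monte_carlo`):

* Rank-sum: exact null distribution for combined n ≤ 12 without ties,
  otherwise a tie-corrected normal approximation with continuity
  correction (mid-ranks; the tie variance correction matters for the
  synthetic heavy-tail stress option, real gene-effect scores rarely tie).
  "Greater" always means the first argument's population is
  stochastically larger.
* Signed-rank: zeros dropped (count logged by callers), exact over the
  2^n sign patterns for n ≤ 15 without ties in |d|.
* Fisher r×c: the cell > 30 chi-squared switch mirrors the scan's rule.
* `glm_fit` (gaussian/binomial) drops aliased design columns with a
  warning, uses IRLS to relative tolerance 1e−8 (max 100 iterations), and
  flags probable separation as non-convergence rather than returning an
  unstable estimate.

The test suite verifies every exact path against independent
brute-force oracles (all label assignments, all sign patterns, all
fixed-margin tables, binomial-coefficient sums) to 1e−12.

## Enrichment

`overlap_enrichment` is the upper-tail hypergeometric test.
`gsea` implements the weighted Kolmogorov-Smirnov running-sum enrichment
score with a **gene-sampling null** (same-size sets drawn from the ranked
list), matching the approach of the widely used preranked implementations:
NES = ES / mean |null ES| of matching sign, empirical p within the
matching-sign half of the null, BH per sign. Consequences worth knowing:
the attainable p floor is about 2/permutations (half the null shares the
observed sign), and a gene set equal to the whole list has ES = 0 (the
complement is empty, the running sum ends at zero). The ES statistic
itself is checked against `fgsea::calcGseaStat` in the tests.

Positional gene sets use 0-based half-open arithmetic throughout
(`cfs_geneset` for common-fragile-site cytobands, `hac_rank_enrichment`
for sgRNA sites in highly accessible chromatin): a gene starting exactly
at a band's end does not overlap it, and an sgRNA at an interval's `end`
coordinate is outside. The HAC analysis ranks genes by the number of
sgRNA sites falling in accessible intervals (ties broken by total sgRNA
count then gene id), takes the top k = |CDE+| genes, and tests the
hypergeometric overlap with the CDE+ set.

## Clinical interaction model

For patient cohorts, the per-sample copy-number alteration burden of a
gene set is

GI = (1/N) Σᵢ I(|sᵢ| > 1),

with sᵢ the SCNA log-ratio of gene i (log2 assumed; the threshold is
strict, so |s| = 1 contributes nothing; missing entries leave both the
numerator and N). `compare_gi` tests whether the CDE+ set's burden is
lower than that of size-matched random control sets (100 seeded draws,
p combined by median — the choice of control genes and number of draws is
a design decision of this package) within each driver stratum.

`fit_interaction_model` is the per-gene logistic regression

logit P(driver mutant) = β₀ + Σₖ β_ct,k·cancer_typeₖ +
β_load·mutation_load + β_GI·GIᵢ + β_stage·stage + β_int·GIᵢ·stage,

with GIᵢ = |sᵢ| the gene's absolute SCNA level, stage binarized (0 =
I/II, 1 = III/IV), mutation load the per-sample non-synonymous variant
count (a log10(x+1) transform is available), and cancer-type dummies
against the first level (dropped when only one type is present). A
significantly positive β_int means high alteration of the gene accompanies
faster driver-mutation accumulation with stage; `interaction_enrichment`
asks whether CDE+ genes are over-represented among such genes
(significant set = converged fits with β_int > 0 and BH q < 0.1).

## Cas9 activity and allele-frequency expansion

`activity_scan` tests per driver whether GFP-reporter Cas9 activity is
higher in mutant lines (one-sided rank-sum, BH across drivers);
`activity_adjusted` refits the focal driver's effect as a linear model
adjusting for p53 status. `maf_expansion_scan` takes paired parental /
Cas9-expressing mutant-allele frequencies, discards cell lines with Cas9
activity strictly below 20% (a case at exactly 0.20 is retained), and
tests per driver whether the frequency increased (signed-rank, zeros
removed and counted). Intronic variants are included by default with an
exclusion flag, since both analyses are informative and the intronic
calls are the more fragile ones.

## Pooled isogenic screens

Counts are CPM-normalized per (context, modality, timepoint, replicate)
sample; sgRNAs with any raw day-0 count below 20 are removed everywhere
(raw counts, so filtering and normalization commute); fold changes are
replicate-averaged day30/day0 CPM ratios with pseudocount 0.5 (zero
handling; 0 reproduces exact ratios when all counts are positive), ranked
ascending within context (rank 1 = most depleted). Gene scores aggregate
the per-sgRNA WT-minus-mutant rank differences by mean (median available),
and the screen-difference score is the CRISPR-KO aggregate minus the
CRISPRi aggregate. CDE+ behaviour — WT-specific depletion under cutting
but not under interference — makes this score strongly *negative*, so the
k most negative genes are called CDE+-like and the k most positive
CDE−-like; k is a user choice because the fraction of the library to call
is inherently a design decision of the focused library. Genes with fewer
than two surviving sgRNAs are excluded. Note that the per-class
signed-rank tests reported alongside are computed on the same screen the
classes were called from, so on synthetic data they are confirmatory
descriptions of the calls rather than independent inference.

Screen QC ranks genes by ascending mean logFC and scores average
precision against gold-standard essential/non-essential sets (AUROC
reported alongside; the pass threshold of 0.6 applies to the AUPRC, and a
random screen on balanced gold sets scores ≈ 0.5 on both).
`competition_trend` fits percentage-of-mutant-cells on day (continuous)
with sgRNA dummies and reports the day slope ×15 with its standard error
×15, the 15-day extrapolated change.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameter records including
the seed (`withr::with_seed`), and every one returns a truth ledger from
which sensitivity and false-discovery proportions of the downstream
callers can be computed without re-reading parameters.

* `simulate_screen_pair` — the reference panel is 60 lines × 2000 genes,
  driver mutated at rate 0.5, planted classes of 120 CDE+ / 60 CDE− /
  60 shared-differential / 30 copy-number-confounded genes, effect 1.5
  viability units over unit Gaussian noise, 2% missingness. The effect
  size and noise give per-gene power > 0.99 at 30 v 30 lines, so set-level
  sensitivity is limited by the multiplicity correction and the
  exclusion rules, which is the regime worth testing. A scaled t(5) noise
  option stresses the rank tests. A few WT lines carry silent driver
  variants, exercising the non-synonymous filter. Not emulated: the
  gene-gene correlation structure of real screens, realistic mutational
  signatures, CN-expression coupling — so passing recovery tests show the
  inference machinery is correct, not that real-data effect sizes are
  detectable.
* `simulate_cohort` — forward simulation of the interaction model above;
  with a planted CDE+ set the members share a latent alteration-burden
  factor (each member's |s| = burden + noise) so that each individually
  carries interaction signal, and optionally their alterations are damped
  in driver-WT samples for the burden-comparison tests.
* `simulate_counts` — negative-binomial day-0 counts (mean 500/sgRNA,
  dispersion 0.1), 10 guides per gene, day-30 resampled at 0.3× the
  day-0 mean for planted genes in the WT context of the CRISPR-KO
  modality only.
* `simulate_maf_pairs` — parental frequencies Uniform(0.05, 0.5), the
  planted driver's Cas9 frequency shifted by `delta` (default 0.1) with
  0.03 noise, activities Uniform over the gate-relevant range.
* `simulate_annotation` — non-overlapping gene bodies on a small genome;
  fragile-site bands placed exactly over the planted genes (decoy bands
  intergenic), so the positional set recovery is exact by construction.

## Study sizes used by the tests and the acceptance script

Recovery of planted CDE genes runs at the reference 60 × 2000 panel over
20 seeds (sensitivity ≥ 0.9, mean false-discovery proportion ≤ 0.15 at
effect 1.5; mean FDP ≤ 0.12 at effect 0). The driver-scan calibration
uses 500 genes × 40 lines × 20 candidate drivers with
`ccd_min_cde_pos = 10` — the biobank-scale default of 300 would be
meaningless on a 500-gene panel — with 50 null and 50 planted
replicates. Interaction-model recovery uses n = 2000 cohorts, 100
replicates per β ∈ {0, 0.5, 1}; bias is checked per β and Wald coverage
pooled across the replicate set, because per-β coverage at 100 replicates
carries a Monte-Carlo standard error (~0.02) comparable to the width of
the acceptance band. GSEA calibration uses a 1000-gene list with
200-500 permutations.

## Known limitations

* The rank-sum normal approximation is used for every panel larger than
  12 lines; at 20-30 lines exact p-values would differ in the third
  decimal, which does not move q < 0.1 calls in practice.
* The BH family is per modality and per scan stage; a joint correction
  across modalities would be slightly more conservative.
* The gene-sampling GSEA null ignores inter-gene correlation, as does the
  preranked implementation it mirrors.
* `ccd_scan` treats drivers independently; co-mutation structure beyond
  the pairwise reference-driver filter is not modelled.
* The clinical model assumes the stage binarization and a linear
  load term; no survival modelling is included.

## A worked miniature

```{r example, message = FALSE, warning = FALSE}
sim <- simulate_screen_pair(screen_sim_params(
  n_lines = 40L, n_genes = 400L, n_cde_pos = 30L, n_cde_neg = 15L,
  n_shared_de = 10L, n_cn_confounded = 10L, seed = 7L))
profile <- derive_mutation_profile(sim$muts, sim$driver,
                                   screen_lines(sim$crispr))
de_crispr <- classify_differential(sim$crispr, profile, alpha = 0.1)
de_shrna <- classify_differential(sim$shrna, profile, alpha = 0.1)
drop <- cn_association_filter(sim$cn, profile, alpha = 0.1)
cde <- identify_cde(de_crispr, de_shrna, drop)
cde
skew_test(build_contingency(de_crispr, de_shrna))
```
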