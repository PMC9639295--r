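---
title: "Mapping condition-responsive cis-regulatory variation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping condition-responsive cis-regulatory variation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reqtlmap)
```

## The problem

Plants vary genetically in how strongly individual genes respond to abiotic
stress. Given a panel of inbred genotypes assayed by RNA-seq under a control
and a stress (heat) condition, together with genome-wide variant calls, the
questions are: which variants regulate expression in each condition (cis- and
trans-eQTL), which cis variants change their effect *between* conditions
(response eQTL, reQTL), which allele of each responsive gene reacts more
strongly and in which direction, which genes are switched on only under
stress with allele-dependent activation (heat-expressed-only eGenes), and
which candidate variants are the most plausible causal ones given
transcription-factor (TF) footprint maps from control and stressed tissue.

`reqtlmap` implements this analysis as a set of composable functions plus a
one-call orchestrator (`run_pipeline()`), and pairs it with a synthetic-cohort
generator that plants every effect class with known truth so each stage is
verifiable end to end.

## The interaction model

For one gene and one candidate cis variant, let $E_{ic}$ be the normalized
expression of genotype $i$ in condition $c \in \{0, 1\}$ (control 0, heat 1),
$d_i \in \{0, 1, 2\}$ the alt-allele dosage and $x_{i1}, \dots, x_{ik}$
sample-level covariates. The model is the linear mixed model

$$E_{ic} = \mu + \beta_d d_i + \beta_c c + \textstyle\sum_j \gamma_j x_{ij}
 + \sum_j \delta_j x_{ij} c + \theta \, d_i c + u_i + \varepsilon_{ic},$$

with a random intercept $u_i \sim N(0, \sigma_g^2)$ per genotype and
$\varepsilon_{ic} \sim N(0, \sigma_e^2)$. The reQTL test is the t test of the
genotype-by-condition interaction $\theta$ with Satterthwaite-approximated
denominator degrees of freedom, Bonferroni-adjusted across all tested
gene/variant pairs and called at adjusted $p < 0.01$.

### How the fit is computed

Each genotype contributes exactly one control and one heat observation
(incomplete pairs are dropped), so an orthonormal within-genotype
sum/difference transform makes the covariance diagonal with two variance
strata: sums have variance $\sigma_e^2 + 2\sigma_g^2$ and differences
$\sigma_e^2$. REML then reduces to a one-dimensional profile over the stratum
variance ratio $\varphi = (\sigma_e^2 + 2\sigma_g^2)/\sigma_e^2 \ge 1$,
optimized on $\log\varphi$ by golden-section search (tolerance $10^{-9}$; the
boundary $\varphi = 1$, i.e. $\sigma_g^2 = 0$, is admitted exactly).
Satterthwaite degrees of freedom use the delta method with the *expected*
REML information of the two stratum variances, which has a closed form here;
`lmerTest` (which fits the identical model and uses the observed information)
agrees with the coefficient and standard error to six decimals and with the
degrees of freedom to about one percent, and is kept as an independent
cross-check in the test suite. On a fully balanced design with
condition-invariant covariates the fit collapses exactly to ordinary least
squares of the per-genotype differences $E_{i1} - E_{i0}$ on dosage and
covariates, with $df = n - k - 2$; this closed form is the second oracle.

Aliased fixed-effect columns are dropped (with a warning) via QR rank
detection; a gene/variant pair whose interaction column itself is aliased, or
whose dosage is constant among complete pairs, returns a flagged
non-converged row with a missing p-value.

## Pipeline stages and the parameters that matter

1. **Variant QC** — MAF $\ge$ 0.1, heterozygous rate $\le$ 0.1, no missing
   calls (all boundaries inclusive); residual missing dosages mean-imputed and
   rounded to $\{0,1,2\}$ (exact ties toward 1). InDels are treated uniformly
   with SNPs; a flag can exempt them from the MAF rule.
2. **LD pruning** — windowed greedy rule (window 50 variants, step 5,
   $r^2 > 0.99$); within a violating pair the lower-MAF member is removed,
   position-later on ties. The widely used pruning tools leave the exact
   removal rule version-dependent, so a deterministic rule is fixed here and
   verified
   against an independent brute-force implementation.
3. **Population structure** — five principal components of the mean-centered
   dosage matrix (signs fixed so each component's largest-magnitude loading
   is positive).
4. **Expression** — counts-per-million with *median-of-ratios* size factors
   computed against one common reference across both conditions. A strong
   stress response moves a large mass of counts into upregulated genes, which
   deflates total-count CPM of unchanged genes; the median-of-ratios factors
   are robust to this composition shift. A gene is "expressed" in a condition
   at CPM > 1 (strict) in at least 10% of genotypes.
5. **Differential response** — paired Wilcoxon signed-rank per gene (exact
   tie-aware enumeration up to 25 non-zero differences, normal approximation
   with tie and continuity correction beyond), BH-adjusted at 0.01;
   up/down calls additionally require |median log2 ratio| > 1 with a +1
   pseudocount on both CPMs. "Consistent upregulation" requires median and
   90%-quantile (type 7) of the per-genotype log2 ratios both strictly
   positive. The quantile order is configurable: the published criterion
   pairs "median > 0" with "90% quantile > 0", which the median already
   implies; the 10% quantile is the stricter reading, and both are available
   via `quantile_q`.
6. **Hidden factors** — a PCA surrogate for probabilistic factor models:
   genes standardized, residualized on known covariates, top-$k$ sample
   scores. The study-scale analogue is $k = 25$; the default here is
   $k = 5$, matched to panels of 100-150 genotypes where more factors mostly
   fit noise.
7. **eQTL scan** — expression inverse-normal transformed per condition
   (Blom offsets $\Phi^{-1}((r - 3/8)/(n + 1/4))$, average ranks on ties),
   residualized-correlation scan equivalent to per-pair OLS; cis means
   |gene-body distance| $\le$ 1 Mb (inclusive; distance to the gene body, not
   the TSS, with upstream negative by strand); BH at 0.01 within the cis and
   trans strata separately (jointly via `bh_strata = "joint"`).
8. **Hotspots** — candidate trans variants target $\ge$ 3 genes more than
   1 Mb away; a fixed 10-kb bin is a hotspot when its candidates' target-gene
   union exceeds 10. The hotspot scan uses structure PCs only: hidden-factor
   covariates absorb exactly the broad, coherent expression signal a
   trans-regulator creates (in our simulations a 15-target hub is captured by
   a factor with $|r| > 0.8$ to its dosage and vanishes from the scan), a
   known cost of factor correction in trans-eQTL mapping.
9. **reQTL candidates** — per gene and condition the top significant cis
   variant (exact p ties broken by a seeded draw); identical tops are tested
   once, non-identical tops once if $r^2 > 0.8$ (seeded pick) and both if
   $r^2 \le 0.8$; single-condition eGenes contribute their one top.
   Covariates for the interaction model are the 5 PCs plus $k$ factors
   inferred once from the column-stacked two-condition matrix, so each
   sample-condition row carries its own factor value. When both candidates of
   a gene pass, the smaller-p pair defines the gene's reQTL.
10. **reGene classes** — heterozygotes excluded; per homozygous allele group
    $L = \log_2((\mathrm{median\ heat\ CPM} + 1)/(\mathrm{median\ control\
    CPM} + 1))$; prefix Ref/Alt by larger $|L|$, suffix Heat/Control by its
    sign; exact $|L_{ref}| = |L_{alt}|$ is ambiguous and excluded. Groups
    need $\ge$ 3 homozygotes each.
11. **heo-eGenes** — heat-only expressed genes with a significant heat cis
    hit; class by the larger median heat CPM between homozygous groups at the
    top variant.
12. **Footprints** — BED-style half-open intervals; fragment centering keeps
    fragments of 20-80 bp and reduces them to 20 bp around the middle base
    (seeded coin flip between the two middle bases of even-length fragments,
    windows clamped inside the fragment); the differential-occupancy
    surrogate is a Welch t test on log2 interval-CPM of 3+3 replicate counts
    with BH < 0.05 (pre-called statuses can be supplied instead). Enrichment
    near upregulated genes uses a one-sided Fisher test on presence of a
    heat-enriched footprint in the 2-kb flank. Top-variant prioritization
    ranks a gene's rescanned variants by raw interaction p (ties: closer to
    the TSS, then position) and asks whether any of the top 3 falls inside a
    heat-enriched footprint (1-based position converted to a 0-based point
    against the half-open interval). The inside/outside comparison pools
    $-\log_{10} p$ across a category's genes (a per-gene mode would weight
    genes equally; pooling matches the variant-level question) and applies
    the two-sided rank-sum test.

## What the synthetic cohort emulates

`sim_config()` defaults define the study conditions: 120 near-homozygous
genotypes from 4 subpopulations (Balding-Nichols, $F_{st} = 0.1$, residual
heterozygosity 2%), 6,000 variants (9% InDels) in 20-variant LD blocks
(within-block haplotype copying with switch probability $(1 - r)/2$,
$r = 0.9$) on three 5-Mb chromosomes, and 1,200 non-overlapping genes. Counts
are negative binomial (dispersion 0.1) on a log2-scale linear predictor with
library sizes uniform in 0.8-1.2 million.

Planted classes: 30% cis-only genes (equal allelic effects in both
conditions), 5% reQTL genes in four categories with per-allele responses
drawn so the stronger response is 2.5-3.5 log2 units and the weaker within
$\pm 0.5$ (interaction $|\theta| \ge 1$ per alt dose by construction), 2%
heat-expressed-only genes (baseline log2 CPM around $-5$, activation 7.5-9,
allele-dependent heat level), 5% consistently upregulated genes
(condition effect 2-3, no genetic effect), and two 15-target trans hotspots.
Causal variants are drawn from variants with empirical MAF $\ge$ 0.15 inside
the gene body $\pm$ 2 kb (or the promoter, with `placement = "promoter"`).
Three hidden factors load on 30% of genes; each gene has a genotype random
intercept of SD 0.2 matching the model's $u_i$.

Two generator choices deserve emphasis. First, reQTL genes receive *balanced*
allelic effects, $\beta_d \approx -\theta/2$ in control and $+\theta/2$ under
heat: this guarantees the gene is an eGene in both conditions (a prerequisite
for candidate selection) and keeps the per-condition genetic variance
comparable, so the per-condition rank-normal transform — which rescales each
condition to unit variance — does not compress the interaction. With
sign-aligned effects the transform can shrink even a large planted
interaction below detectability; detected reQTLs in any real panel are
implicitly biased toward the balanced regime for the same reason. Second,
footprint replicate counts emulate deep occupancy coverage (means 100-300,
near-Poisson technical noise): with only three replicates per condition the
Welch test's heavy-tailed null makes shallow counts unable to clear an FDR of
0.05 no matter how large the fold change.

Features of real data the generator does not emulate: recombination maps and
realistic LD decay (block-copying only), sequence context, read-level noise,
GC or length biases, batch structure beyond the planted factors, dominance or
epistasis, and any relationship between footprint occupancy and expression
beyond the planted causal-variant coverage. Passing tests therefore
demonstrate correctness of the statistical machinery and calibrated error
rates under the model's assumptions — not performance on a real panel.

## Numerical choices and degenerate inputs

- Exact signed-rank null by dynamic programming over doubled midranks
  (handles ties exactly); all-zero differences give $p = 1$ by convention;
  zero differences are dropped before ranking (classical convention,
  configurable).
- Exact rank-sum null via the closed-form distribution without ties, full
  enumeration with ties while feasible, otherwise normal approximation with
  tie and continuity corrections.
- Correlations are clamped to $\pm(1 - 10^{-12})$ before the t transform;
  variants whose residualized dosage is constant are skipped and counted.
- `pairwise_r2()` on a constant vector returns 0 with a warning; in LD
  pruning a constant column is treated as fully redundant ($r^2 = 1$).
- Tertile plasticity classes break ties toward the lower class via first-rank
  ordering; class sizes differ by at most one.
- Satterthwaite df fall back to the residual df ($N - p$) if the information
  matrix is numerically singular.
- Kenward-Roger is not implemented: on the balanced paired designs this
  pipeline produces it coincides with Satterthwaite.

## Problem sizes used by the test suite

The packaged tests run the full generator at its defaults (120 genotypes,
6,000 variants, 1,200 genes) once and reuse it; error-rate suites use 20
null cohorts of 250 genes with 1,000 interaction tests each; oracle
equivalences use a 50-gene x 200-variant x 60-sample scan and 100 balanced
interaction fits with 30 covariates; footprint prioritization uses 20 cohorts
of 300 genes. These sizes were chosen so each suite exercises the asymptotic
regime of its statistics while a full run remains a desk-scale computation.

## Known limitations

- The inverse-normal transform protects against outliers and distributional
  misfit but attenuates interactions for genes whose genetic variance differs
  strongly between conditions (see above); effect sizes on the transformed
  scale are not directly interpretable in log2 units.
- Bonferroni reQTL calling is conservative when candidate pairs are
  correlated through LD.
- The hotspot binning rule counts unique target genes, not independent
  signals; LD spreads a single regulator across adjacent bins, which is
  visible in the simulations and expected on real data.
- Mean-round imputation is a placeholder for haplotype-aware imputation,
  adequate only at the low missingness the QC thresholds enforce.
- The differential-occupancy surrogate uses total-count normalization across
  intervals; a large planted enrichment mass biases stable intervals toward
  apparent depletion (it cannot create spurious enrichment, which is the
  direction used downstream).
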