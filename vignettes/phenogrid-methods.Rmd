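---
title: "Colony-array phenomics with phenogrid: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony-array phenomics with phenogrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogrid)
```

## The measurement model

phenogrid analyses colony-array phenomics screens in which mutant
library strains of fission yeast are pinned at 384 positions per plate,
with a 96-colony wild-type reference grid occupying every position with
odd row and odd column of the 16 x 24 array. Two readouts are
supported: colony size (growth) and phloxine-B redness (the dye stains
dead cells, so redness is an inverse viability readout).

Raw colony size at position $(r, c)$ of plate $p$ is modelled as

$$ y_{prc} = B_p \cdot S_p(r, c) \cdot \mu_{g(p,r,c)} \cdot \varepsilon, $$

where $B_p$ is a plate/batch factor, $S_p$ a smooth multiplicative
spatial surface (nutrient and pinning gradients), $\mu_g$ the relative
growth of the strain at that position, and $\varepsilon$ multiplicative
noise. The analysis inverts this model in two steps:

1. **Reference-grid normalization** estimates the expected wild-type
   value at every position from the reference lattice and divides by
   it: fitness $= y / \hat y_{wt}$.
2. **Row/column median correction** divides each value by its row
   median, then by the column median of the row-corrected values, and
   rescales the plate median to 1, absorbing residual striping.

The redness readout receives only the row/column correction; its
spatial structure is much weaker and a multiplicative grid correction
of an intensity score is not meaningful on this scale.

### Interpolation scheme

The expected wild-type value at non-reference positions is the
bilinear interpolation over the enclosing cell of the reference
lattice. Positions beyond the outermost reference rows/columns (row 16,
column 24) use the linear extension of the nearest lattice cell. Both
choices are exact for planar gradients: on a plate whose sizes follow
$a + b\,r + c\,s$ exactly, every fitness value is exactly 1. This
exactness is a tested invariant, and is the reason bilinear
interpolation was chosen over nearest-neighbour or global polynomial
schemes.

At reference positions themselves a naive bilinear estimate would
return the colony's own value, forcing reference fitness to 1
identically and making the control CV and FUV statistics degenerate.
phenogrid therefore estimates the expected value at reference nodes
leave-one-out from lattice neighbours: the average of the two
axis-symmetric neighbours per axis in the lattice interior, and the
two-point linear extrapolation at lattice borders. These estimators
are also plane-exact, so the all-fitness-exactly-1 invariant holds on
planar plates at every position.

A missing reference colony invalidates every position whose
interpolation cell (or leave-one-out estimate) would use it; those
colonies are set absent with the flag `grid_neighbour_missing` rather
than silently normalized against a broken surface.

### Signal metrics: control CV and FUV

Plate quality is summarised by the coefficient of variation of
post-normalization reference fitness (control CV) and the fraction of
unexplained variance (FUV): the variance of post-normalization
reference fitness divided by the variance of pre-normalization
reference sizes rescaled to mean 1. Because the leave-one-out estimate
contributes its own variance, the naive ratio is inflated by the
analytically known factor $1 + \overline{\sum_k w_k^2}$ (sum of squared
estimator weights, averaged over reference nodes; 1.71875 for the
complete standard384 lattice). phenogrid divides this factor out, so a
plate of pure i.i.d. noise has FUV close to 1 and a plate whose
variation is dominated by a removable gradient has FUV close to 0.
This correction matters in overexpression mode, where plates with
FUV > 1 are failed by QC.

The control CV is reported uncorrected — it is the actual spread of
normalized control values, which is what downstream tests experience.
One consequence worth knowing: when the generator injects raw noise
with CV $c$, the post-normalization control CV is about $1.31 c$
(reference positions) and mutant-position fitness noise about
$1.19 c$. The benchmark functions `power_scan()` and
`fdr_benchmark()` therefore take their `wt_size_cv` argument on the
post-normalization scale — the scale on which plate QC reports it —
and divide out the analytic inflation before configuring the
generator.

## Quality control

Colony level: pinning failures (size 0) are set absent; colonies with
circularity below 0.85 are set absent for the size readout (shape
artifacts bias area quantification). Plate level: size plates with
control CV above 0.2 and redness plates with control CV above 0.05 are
failed entirely; overexpression mode additionally fails plates with
FUV above 1 or control CV above 0.5. QC never deletes rows — every
exclusion is a flag plus a report entry, so observation counts stay
auditable.

## Hit calling

For every strain x condition the median effect size (MES) is the ratio
of medians of colony-level fitness between the strain and its
baseline:

* benign (control) conditions — baseline is the wild-type control in
  the same condition;
* stress conditions — baseline is the same strain in the linked
  control condition (so stress MES is a relative, interaction-type
  effect);
* overexpression screens — the empty-vector control strain replaces
  the wild type, and stress-condition fitness is first divided by the
  strain's median benign-condition fitness.

Significance uses Welch's unequal-variance t-test on colony-level
values pooled across biological and technical replicates, followed by
Benjamini-Hochberg adjustment within each condition. Ratio-of-medians
(rather than median-of-ratios) is used because replicate colonies are
unpaired across plates. Pooling colonies is the default comparison
unit; this treats technical replicates as exchangeable with biological
ones for the test, which slightly overstates the effective sample
size when batch effects are present — the replicate structure is
retained in the dataset so users can aggregate first if preferred.

Hit thresholds (deletion mode): BH-adjusted p below 0.05 and
|log2 MES| above log2(1.05) for growth, log2(1.015) for redness — a 5%
(growth) or 1.5% (redness) difference, of the order of the respective
control CVs (0.050 and 0.007). Overexpression mode: adjusted p at or
below 0.01 and |MES − 1| of at least 5%. Zero-variance Welch
inputs follow a fixed convention (p = 1 for equal means, p = 0
otherwise) so that degenerate synthetic cases are deterministic.

### What the power analysis shows

`power_scan()` measures, per effect size, the fraction of seeded
synthetic screens (one injected strain among 144 on full 384 plates,
9 biological x 2 technical replicates, post-normalization control CV
0.050) in which the injected strain is called a hit. Two facts shape
the resulting curve:

* at a true effect exactly at the 5% effect-size filter, the MES
  estimate exceeds the filter only about half the time — the filter is
  a hard boundary through the centre of the sampling distribution;
* with a single true effect among 144 strains, per-condition BH is
  effectively a Bonferroni correction.

Consequently the smallest effect detected in at least 80% of runs
under these conditions is about 7%, while detection by significance
alone (`criterion = "significant"`) is already near-certain at 5%.
Both criteria are exposed; the default is the full hit definition.

## Phenotype profiles, clustering and networks

Effect sizes are converted to modified z-scores, $(\mathrm{MES} - 1) /
\mathrm{SD}_{wt}(\text{condition})$, i.e. deviations in units of
wild-type spread. Conditions probing the same stressor (e.g. dose
series) are aggregated by the signed strongest response (maximal |z|,
sign kept; equal-magnitude ties resolve to the positive value for
determinism). Profiles are discretized at ±1.5 SD into sensitive (−1),
similar (0) and resistant (+1); strains with fewer than five non-zero
responses are dropped (overexpression mode then also drops sparse
conditions) and remaining absent cells are imputed with 0.

Hierarchical clustering uses Ward linkage on Euclidean distances for
deletion screens (`hclust(method = "ward.D2")`, the same algorithm as
scipy's "ward") and complete linkage on Canberra distances for
overexpression screens, with flat clusters from a maxclust-style cut.
The overexpression discretization threshold is configurable because
the convention differs between screen types; the deletion-mode default
of 1.5 SD is the package default throughout.

The correlation network connects strains whose discretized profiles
have Pearson |r| > 0.6 with BH-adjusted p < 0.01, p-values from the
two-sided t-distribution on n − 2 degrees of freedom. The BH family is
all strain pairs tested in one run. Pairs sharing fewer than three
defined conditions are skipped and counted; constant profiles yield no
edges. Communities are detected with seeded Louvain modularity
optimisation on |r| edge weights — a standard, scriptable replacement
for interactive GUI-based community clustering. The core-condition
restriction used for screen-scale clustering is a user-supplied
whitelist (`core_conditions`), not a hard-coded list.

## Cytology and meiosis statistics

Cell-size and cell-cycle calls consume per-cell microscopy tables (63
fields per sample). Samples are first filtered on a 0-5 density score
(0 and 5 excluded). Size phenotypes compare per-cell binucleated-cell
lengths (Wilcoxon rank-sum, two-sided) with a ≥5% median fold-change
filter; cell-cycle phenotypes compare per-field binucleate percentages
with a ≥20% filter. The comparison units differ deliberately: length
is a per-cell quantity, while the binucleate fraction is only defined
per field; both interpretations are recorded here because the
convention is ambiguous in common usage. Flow-cytometry agreement is
the Pearson correlation of the microscopy binucleate fraction with the
gated G1+S population fraction (binucleated cells are in G1/S).

Mating efficiency is computed from cell-fate counts as
$\{2(z+a) + s/2\} / \{2(z+a) + s/2 + n\}$ with z zygotes, a asci, s
free spores and n non-mating cells; spore viability is colonies formed
over spores plated, pooled across plates (sum/sum) with per-plate
values also reported. The statistical test behind between-strain
viability comparisons is not standardised and is left to the user.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure the
analysis assumes: full 384 plates with the 96-colony reference grid,
one plate per condition x biological repeat (split over layout chunks
for libraries larger than 144 strains x 2 technical replicates),
multiplicative lognormal noise (default size CV 0.050, redness CV
0.007), per-plate plane-plus-Gaussian-bump surfaces, per-batch
factors, uniform random pinning failures and low-circularity
artifacts, and known injected effects returned as ground truth.
Defaults follow the screening design the pipeline targets: nine
biological repeats with two technical repeats each.

Choices worth stating:

* **Lognormal noise.** The distributional family of colony-size noise
  is a modelling choice, not an established fact; lognormal is the
  simplest strictly positive model compatible with the ratio-based
  statistics, and its sdlog is set so the CV matches the configured
  value exactly ($\sigma^2 = \log(1 + \mathrm{CV}^2)$), with the
  multiplicative median kept at 1 so injected effects are unbiased.
* **What it does not emulate**: position-autocorrelated pinning
  artifacts, edge drying effects beyond the smooth surface, agar
  batch-to-stressor interactions, or strain-specific variance. Passing
  tests therefore demonstrate correctness of the statistical pipeline
  under its own model assumptions, not robustness to every failure
  mode of real plates.
* **Sparse plates.** The row/column median correction assumes
  well-populated rows; simulated screens should fill plates (strains x
  technical replicates close to 288) as real screens do, otherwise row
  medians are estimated from a handful of colonies and strong injected
  effects leak into their rows' corrections.

`simulate_cell_samples()` uses a Poisson cells-per-field model,
lognormal lengths around the sample median (default CV 0.14, a
realistic spread for fixed fission-yeast cells), defaults of 9.7 µm
median binucleate length and 13.2% binucleated cells, and Bernoulli
nuclei counts. `simulate_meiosis_counts()` draws non-mating cells
binomially, splits completed matings multinomially between zygotes,
asci and spore-releasing meioses (four free spores each), and draws
viable colonies binomially.

## Problem sizes and determinism

Everything is seeded: a `sim_config` seed fixes the whole experiment
bit-for-bit, and the benchmark functions derive per-run seeds from one
master seed. The validation suites use problem sizes chosen to make
Monte-Carlo assertions stable at desk scale: 100 runs per effect size
for the detection-rate scan (binomial SE ≤ 0.05) and 20 repetitions of
a 500-strain x 4-stress-condition mixture (about 2500 strain-condition
tests each) for the FDR benchmark. Degenerate inputs follow explicit
conventions rather than erroring mid-pipeline: QC never throws on data
content, all-absent rows/columns stay absent through the median
corrections, and empty profile matrices propagate as explicit empty
results.

## Known limitations

* The FUV correction factor assumes i.i.d. noise at reference
  positions; under strong heteroscedasticity the corrected FUV is
  approximate.
* Stress-mode MES compares unpaired colony sets between condition
  plates; a mixed model with plate random effects would use the
  replicate structure more efficiently but is deliberately out of
  scope.
* The test statistics treat colonies as independent observations;
  residual within-plate correlation (shared interpolation cells) makes
  the tests slightly anticonservative at very small effect sizes.
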