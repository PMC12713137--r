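---
title: "Modeling the phases of somatic CAG-repeat expansion and neurodegeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the phases of somatic CAG-repeat expansion and neurodegeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagphases)
```

## The model

Huntington's disease is caused by an inherited CAG-repeat expansion in
*HTT*.  In neurons, the repeat continues to expand somatically over the
lifespan, cell by cell, and the disease process in each neuron appears to
be driven by the length its own tract has reached rather than by the
inherited length alone.  `cagphases` analyzes (and simulates) paired
single-nucleus measurements of genome-wide expression and per-cell
CAG-repeat length under a phase model of this cell-autonomous cascade:

* **Phase A** — slow, length-dependent expansion of the inherited allele.
  Repeat units accrue over decades; the rate differs strongly (up to
  ~18-fold) between molecularly defined pyramidal neuron types, and only
  weakly (~1.3-fold) between cortical areas.
* **Phase B** — once a tract passes about 90 units, expansion
  accelerates sharply, carrying a minority of cells to hundreds of units.
  The resulting length distribution is "armadillo"-shaped: a dense body
  (45–90 units) plus a long high-length tail.
* **Phase C** — beyond about 150 units, gene expression begins to change
  progressively, escalating with further expansion.  Down-regulated (C−)
  genes are disproportionately the genes that define the cell's identity.
* **Phase D** — at still-longer lengths, cells enter a discrete
  de-repression crisis: scores of normally silent genes (developmental
  transcription factors, *CDKN2A/B*) switch on.  Repeat length predicts
  *whether* a cell has entered the crisis, not how far it has progressed.
* **Phase E** — cell loss.  Fast-expanding pyramidal types are lost
  preferentially.

## Per-cell expansion statistic and its regression

For a cell with measured disease-allele length `CAG` and donor inherited
length `inh`, the phase A expansion is

```
phase_a_expansion = max(0, min(100, CAG) - inh)
```

The cap at 100 units isolates phase A kinetics from the much faster phase
B regime; the clamp sends rare contracted alleles to zero.  Cells without
a CAG measurement are excluded, never imputed.

`fit_expansion_nbr()` models these counts as negative binomial with log
link and a single shared dispersion, with donor, region, and fine
molecular identity (subcluster) as factor covariates.  Each factor is
treatment-coded against its largest level; because single coefficients
depend on that reference choice, the fit also reports each factor's
max/min ratio of exponentiated coefficients (reference included at 1), a
coding-invariant summary of the subtype and regional spans.  Factor
levels with fewer than 20 observations are dropped with their cells, and
a factor that collapses to one level (e.g. donor in a single-donor
dataset) is removed with a message.

## Per-gene models: the hinge and the de-repression covariate

Gene-level counts `E_g` are modeled as `NB(mu_g, v_g)` with

```
log(mu_g) = log(N) + beta_h * f_{m,n}(CAG) + beta_d * phaseD.prob_{S,M}
            + donor + region + subcluster
```

where `N` is the cell's total UMI count (offset with coefficient fixed at
1), and

* `f_{m,n}(CAG) = 0` below the onset `m`, then `min(CAG, n) - m` — a
  hinge that encodes "no effect until a threshold, then a continuously
  escalating effect".  Defaults `m = 150`, `n = 500`.  The onset is not
  fitted gene by gene; instead `profile_hinge_onset()` profiles the
  summed log-likelihood of a set of responsive genes over a grid of
  candidate onsets (110–200 by 10) and recovers the commencement point of
  the program.
* `phaseD.prob_{S,M}(score) = 1 / (1 + exp(-S (score - M)))`, a logistic
  transform of the cell's phase D panel score — the summed panel UMIs
  normalized to 100k (`phase_d_score()`).  We use `S = 2`, `M = 2`
  per-100k: a cell with at most 1 normalized panel UMI gets probability
  < 0.15 while a cell with 10 or more gets > 0.99, matching the observed
  bimodality of the crisis (most long-repeat cells carry 0–1 normalized
  panel UMIs; cells in crisis carry 10+).  Both parameters are exposed in
  the configuration.

Wald tests on `beta_h` and `beta_d` recognize phase C and phase D genes
respectively.  Fitting uses maximum likelihood (`MASS::glm.nb`); genes
whose dispersion diverges (essentially Poisson genes, e.g. silent panel
genes) are refitted in the Poisson limit of the model rather than
discarded.  Non-converged genes are excluded from calling and counted in
a message.

Because nearly all of the statistical signal lives in the minority of
cells with long tracts, `downsample_for_fitting()` thins the dense
mid-range before fitting: cells with lengths in `(35, 100]` are kept with
probability 0.10, while every cell above 100 — and every cell at or below
35 — is retained.  Intervals on CAG length are half-open `(lower, upper]`
throughout the package.

### Calling and summarizing

`classify_phase_genes()` applies Benjamini–Hochberg FDR separately to the
hinge and phase D p-values across all fitted genes (BH is the package's
choice of FDR procedure).  Phase C calls split by slope sign into C+ and
C−.  Phase D calls are stringent: FDR < 0.1% *and* fold-change > 10,
where the fold-change is defined as `exp(beta_d)` — the fitted change
between de-repression probability 0 and 1.

`median_fc_trajectory()` summarizes a gene set per cell as the median
fold-change relative to a low-expansion baseline (cells with lengths in
`(0, 100]`, within the cell's own subtype so type-specific expression
does not masquerade as a length effect).  Per-100k values receive a
pseudocount of 1 in numerator and denominator.  Genes detected in fewer
than 90% of the analysis cells are excluded — ratios of barely-detected
genes are dominated by sampling noise.  Note one numerical property of
this estimator: the median of noisy count ratios sits slightly below 1
even at baseline; comparisons across CAG bins (the escalation of phase C)
are unaffected because the bias cancels in relative terms.

`compare_phase_c()` pairs hinge slopes fitted in two contexts,
restricted to genes with `p < 1e-10` in at least one, and reports their
correlation and sign agreement — high concordance indicates a shared
phase C program (as between upper- and deep-layer pyramidal neurons),
scatter around independence indicates distinct programs (as between
cortex and striatum).

## Phase D analytics

A cell is *called* in phase D when its logistic probability exceeds 0.5
(strictly), i.e. when its panel score exceeds the midpoint `M`.  The call
threshold is a thresholded probability rather than a mixture-model
assignment because the logistic probability is exactly the quantity the
per-gene models regress on.  `entry_fraction_by_bin()` reports the
entered fraction by length bin (defaults `(150,250], (250,350],
(350,500], (500,Inf)`) with exact binomial intervals;
`crisis_structure()` reports the bimodal structure among long-repeat
cells (fraction with score ≤ 1; among score > 2, fraction ≥ 10; distinct
panel genes per cell); `magnitude_vs_length()` rank-correlates score with
length among entered cells with a seeded permutation test.

## Identity erosion

`specificity_scores()` computes per-gene mean per-100k expression in two
control-cell groups (canonically pyramidal neurons vs cortical
interneurons) and the pseudocounted log2 ratio.  `erosion_enrichment()`
then asks whether C− genes are disproportionately group-A identity genes
using a one-sided Wilcoxon rank-sum test of the log2 ratios, C− versus
the remaining background.  A rank test is the minimal formalization of
the overlay comparison it implements, and is invariant to monotone
transforms of expression.  The degenerate case (C− equal to the whole
background) reports shift 0 rather than an error.

## Cell survival

`relative_abundance()` normalizes each donor's per-type counts by that
donor's L5IT count — an abundant pyramidal population with modest somatic
expansion.  The ratio removes depth and dissection differences and is
more stable across control donors than fractions of all nuclei, whose
denominators drift with age-related changes in other populations
(interneurons, OPCs).  Donors with zero reference cells are excluded with
a message rather than pseudocounted.  `survival_ratios()` takes medians
per group (HD; control) and reports their ratio with a percentile
bootstrap over donors — the donor, not the cell, is the sampling unit.
`survival_vs_expansion()` rank-correlates per-type survival with
expansion propensity using a seeded permutation p-value.

## The synthetic-data generator

The generator exists so that every stage can be exercised against a known
truth.  Its defaults describe the study conditions the analysis assumes.

**Repeat lengths.**  Expansion is a discrete-time pure-birth process: in
each step (monthly by default) a tract gains one unit with probability
`rate / steps_per_year`.  The rate grows exponentially with current
length during phase A (`base_rate * length_slope^(len - inherited)`,
defaults 0.025/yr and 1.025), is multiplied by the cell type's rate
multiplier and by a per-cell log-normal frailty (`cell_rate_sd = 0.6`,
mean 1), saturates at `rate_cap = 4`/yr, and doubles (`phaseB_boost = 2`)
past the 90-unit threshold.  Two choices here are the package's own:

* The exponential length dependence is capped (at the phase B threshold,
  and by `rate_cap`): uncapped exponential growth makes the per-step
  probability diverge for any step size.  The cap bounds the per-step
  probability by construction at `rate_cap * phaseB_boost /
  steps_per_year`, and the constructor rejects parameter sets that break
  the bound with an instruction to use a finer time step.
* The per-cell frailty models stable cell-to-cell variation in expansion
  propensity (e.g. mismatch-repair activity).  It is what produces the
  armadillo shape: without it, the time of crossing into phase B is
  nearly deterministic and a fast subtype ends up entirely in the tail.
  With the defaults, an 18×-multiplier subtype at age 60 has ≈32% of
  cells beyond 100 units with tails to ~500, while a 1× subtype barely
  moves — the qualitative picture the analysis expects.

Expansion affects only the disease allele (`allele_specific = TRUE`);
lengths are absorbed at `max_cag = 600` (the longest tracts the assay
resolves).  Coefficient-recovery studies use a constant-rate variant
(`length_slope = 1`, `phaseB_boost = 1`) in which an injected
multiplicative effect acts directly on the mean expansion, so "recovery
of a 1.3-fold region effect" is well defined.

**Phase D states.**  Entry is an independent Bernoulli draw per cell with
a length-dependent hazard, supplied as a step (or any) function rather
than estimated — the analysis treats the hazard as an empirical curve.
The default steps are 0 below 150, 0.05 on (150,250], then 0.25, 0.5,
0.8.

**Expression.**  Per cell, a target library size is log-normal (median
20k UMIs, sdlog 0.35); per gene, counts are negative binomial with
dispersion drawn from U(1, 5) and mean
`N/1e5 * exp(baseline + slope * hinge + donor + region)`.  Donor and
region effects are i.i.d. normal on the log scale (SD 0.15 and 0.05).
Phase C gene slopes default to ±0.01 per unit beyond 150; phase D panel
genes are Poisson with a leak of 0.001 per-100k (silent) switching to 10
per-100k per gene in cells that have entered the crisis.  Baselines of
the null genes are rescaled per subtype so expected per-100k expression
sums to 100k — recorded `total_umis` are realized column sums, so
simulated datasets are internally consistent with the per-100k
normalization.  Effect-class genes keep fixed moderate baselines (a small
share of the transcriptome) so that their own regulation does not move
library sizes; an early version of the generator let the normalization
inflate them, and the resulting compositional drift in `log(N)` was
enough to miscalibrate null hinge tests — a useful reminder that the same
artifact can affect real data when regulated genes are a large fraction
of the measured transcriptome.

**Composition studies.**  `simulate_village_study()` draws per-donor
type counts multinomially, with HD donors' proportions reweighted by
per-type survival factors; `survival_from_multipliers()` couples survival
to expansion propensity (log-linear from 1 down to 0.45) for studies of
the survival–expansion relation.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: ambient RNA and doublets; batch and chemistry
effects; classifier-induced label structure beyond a uniform flip rate;
donor-level covariance (age, CAP score) beyond an i.i.d. donor effect;
multi-unit expansion jumps and contractions; uncertainty in the CAG
length measurement itself; and absolute calibration of kinetic rates to
human decades (only relative and ordinal behavior is asserted).

## Numerical and edge-case choices

* Ties in the cluster-to-subclass majority vote are reported as
  unmapped ("tie"), never silently broken; clusters under 10 cells are
  unmapped ("too few cells"); mapped clusters with purity ≤ 60% are
  flagged, not dropped, and can be excluded downstream.
* The profile over hinge onsets compares only grid points at which the
  same number of genes converged.
* All-zero genes are skipped; non-converged fits are flagged and never
  called.
* `phase_d_score()` refuses cells with zero total UMIs; hazards outside
  [0, 1] and overlapping length bins are errors.
* Seeded operations (`downsampling`, permutation tests, bootstrap,
  all simulators) restore the caller's RNG state (`withr::with_seed`).

## Problem sizes

The test suite exercises the stages at sizes chosen to make the
statistical assertions sharp while keeping a full run fast: 40,000 cells
for expansion-model recovery; 9,000 cells (40% beyond 100 units, echoing
the fitted-set composition) for hinge-slope recovery; 200 null genes for
calibration and 20 replicate datasets for FDR control and onset
recovery; 10,000 cells per length bin for the entry-fraction curve; 100
donors (50+50) for survival recovery; 100 replicates for the
identity-erosion null calibration.

## Limitations

Hinge parameters are profiled on a coarse grid, not jointly estimated
per gene; dispersion uncertainty is ignored in Wald tests (as is
standard); the phase D fold-change definition (`exp(beta_d)` between
probability 0 and 1) is one of several reasonable choices; and the
pipeline's identity-erosion stage requires control interneurons in the
dataset and skips itself otherwise.
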