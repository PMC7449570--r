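---
title: "Methods: power for sequencing-and-imputation GWAS designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power for sequencing-and-imputation GWAS designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqimpower)
```

`seqimpower` estimates statistical power for case-control GWAS in which
`n` participants are whole-genome sequenced (and their haplotypes added to
the imputation reference panel) and `m` participants are array-genotyped
and imputed. This vignette documents the statistical model, the estimator
and its weights, the synthetic data generator and Monte Carlo oracle used
to validate them, and the numerical and design choices a maintainer should
know about.

## Disease model and effect size

We assume a dichotomous trait under a multiplicative per-allele model: with
`g` copies of the risk allele, disease risk is proportional to `γ^g`.
Genotypes are Hardy-Weinberg at population MAF `p`. Conditioning on disease
status gives closed-form allele frequencies

\[
p_{case} = \frac{p\gamma}{1 + p(\gamma - 1)}, \qquad
p_{control} = \frac{p - K\,p_{case}}{1 - K},
\]

where `K` is prevalence. Both follow from Bayes' rule at the allele level;
a useful consequence is that case and control genotypes each remain
Hardy-Weinberg at their own allele frequency, so the within-group genotype
variances are exactly `2q(1-q)` (`genotype_variances()`); the package's
tests confirm this against enumeration of the joint genotype-by-disease
distribution. Models where the implied control frequency would be negative
(prevalence too large for the given MAF and relative risk) are rejected.

The association test we target is the allele-based two-sample comparison:
difference in mean genotype between cases and controls, standardized by the
**pooled combined-sample variance** (the standard allelic/trend test
standardization). With `s` cases per control, the pooled variance is the
case/control mixture variance, which expands to
`[(1+s)(v_case + v_control/s) + 4(p_case-p_control)^2] \cdot s/(1+s)^2`
per observation; standardizing the mean difference by it yields a statistic
with asymptotic mean `η√N` in a study of `N` participants, where

\[
\eta = \frac{2(p_{case} - p_{control})}
{\sqrt{(1+s)\left(v_{case} + \tfrac{1}{s} v_{control}\right)
 + 4(p_{case}-p_{control})^2}}.
\]

The placement of the radical — in particular, which group variance carries
the factor `1/s`, and the presence of the `4Δp²` term — was pinned by a
Monte Carlo oracle before anything was built on top of it: at
`p = 0.005, γ = 4, K = 0.01, s = 1` and `N = 20{,}000`, the mean simulated
Z statistic matches `η√N` within Monte Carlo error (about one standard
error at 20,000 replicates), whereas the alternative reading (group
variances standardized separately, no `4Δp²` term) is ~12 standard errors
off. That alternative corresponds to a Welch-style statistic; the pooled
form is what the package simulates and what `η` standardizes.

`η²` is the per-sample noncentrality of the corresponding 1-df chi-squared
test (`ncp_unit` in `effect_size()`).

## Two-stage designs and analytic power

Test statistics are computed separately in the sequenced and imputed
strata and combined with effective-sample-size weights,

\[
Z_{nm} = \sqrt{c}\,Z^{seq}_n + \sqrt{1-c}\,Z^{imp}_m,
\qquad c = \frac{n}{n + r^2 m},
\]

where `r²` is the imputation r-squared of the variant in the imputed
stratum. Under this weighting `Z_{nm}` is asymptotically
`N(η\sqrt{n + r^2 m},\, 1)`: an imputed sample contributes `r²` of a
sequenced one. Two-sided power at level `α` is

\[
\mathrm{Power} = \Phi(\lambda - z_{1-\alpha/2}) +
\Phi(-\lambda - z_{1-\alpha/2}), \qquad \lambda = \eta\sqrt{n + r^2 m},
\]

implemented in `analytic_power()` and verified against adaptive numerical
integration of \(\int_{-z}^{z}\phi(u - \lambda)\,du\) to `1e-8` across a
grid of effect sizes, effective sample sizes, and significance levels.

**Known approximation limit.** The unit-variance claim is asymptotic in a
second sense: under a strong alternative the pooled-variance statistic has
variance slightly *below* 1 (the pooled denominator absorbs part of the
between-group mean difference — the same `4Δp²` term). For `γ = 4` at MAF
0.5% the simulated standard deviation of Z is ≈ 0.85. Exactly at 50% power
this has no effect (the rejection boundary sits at the mean), but far from
midrange power the analytic value can deviate from the exact rejection rate
by a few times the Monte Carlo standard error at 20,000 replicates. The
package's Monte Carlo agreement checks therefore test strong-effect
configurations at midrange power, where the comparison is sharp for the
mean (the quantity `η` controls) and not confounded by the variance
approximation; mild-effect configurations are tested away from 0.5 as
well. This is a property of the normal approximation itself, shared by any
power formula built on it, not of the implementation.

## Empirical quality tables and the weighted estimator

Per-variant imputation quality at a given (population, array, panel size)
lives in a `quality_table`: sample MAF (minor-allele folded, fold flagged
in a provenance column), reference-panel MAC, imputation r-squared (`NA`
when the variant is absent from the panel or not imputed), and a
population-specificity flag. Tables read and write a flat TSV
(gzip-transparent); bin-aggregated tables are supported through a `weight`
column that multiplies the row's weight in all computations.

A variant is **imputable** when its panel MAC is at least 5 (the usual
panel inclusion threshold) and its r-squared is at least 0.3. One source
convention states the r-squared rule strictly (`> 0.3`), another
non-strictly (`≥ 0.3`); ties at the boundary are measure-zero in real
data, and the package follows the non-strict indicator with a
`strict_r2` flag to flip it. **Coverage** of a MAF bin is the weighted
fraction of its variants that are imputable; an empty bin raises an error
rather than returning 0, since "no data" and "nothing imputable" are
different facts.

`estimate_power()` averages per-variant analytic power over the table:

\[
\widehat{\mathrm{Power}}(m, n) =
\frac{\sum_j w^{MAF}_j w^{PS}_j\, C_{nj}\,
\mathrm{Power}(\eta, n + r_{nj}^2 m)}{\sum_j w^{MAF}_j w^{PS}_j},
\]

* `w_MAF` is the model-implied Poisson probability of the variant's sample
  MAC (mean `2N(s\,p_{case} + p_{control})/(s+1)`) divided by the empirical
  MAC proportion in the table. It converts "average over the variants we
  happened to observe" into "expectation for a variant with the specified
  MAF and effect size". The Poisson approximation to the exact
  case/control binomial-mixture MAC distribution is accurate for rare
  variants (total variation < 0.01 for MAF ≤ 1% across sample sizes
  1,000–10,000; asserted in tests with the exact distribution computed by
  convolution in `exact_mac_pmf()`).
* `w_PS` rescales population-specific versus shared variants so their
  weighted share equals the empirical probability that a variant at the
  model's MAF is population-specific, computed per MAF bin. When the
  variant's own bin has empirical fraction exactly 0 or 1 with the
  opposite flag, the ratio is undefined; such variants are impossible
  under the empirical model and receive weight 0 with a warning.
* `C` gates power: non-imputable variants contribute zero power **but keep
  their weight in the denominator**. This is what makes the weighted
  imputable probability `p_imputable` an upper bound that power approaches
  as `m → ∞` (the plateau visible in power-versus-m curves), rather than
  an average over imputable variants only.

`η` is computed once from the population MAF of the disease model, not
per-record from each variant's sample MAF: the estimator asks "what is the
power for a variant with MAF p", and the table contributes only the
imputation-quality mixture.

Two conventions were genuinely open and are exposed as options:

* The sample size `N` in the Poisson numerator of `w_MAF` defaults to the
  quality table's own evaluation sample size, so numerator and denominator
  describe the same sampling process; `gwas_N` switches the numerator to a
  planned GWAS size instead.
* The default PS-fraction bins use the conventional rare/low-frequency
  edges (0.1%, 0.25%, 0.5%, 5%, 50%) with a `[0, 0.1%)` bin prepended so
  the whole folded-MAF range is covered. If the bin containing the model's
  MAF holds no table variants, the table-wide PS fraction is used as a
  fallback (only the model's bin can be empty; every variant's own bin
  contains at least itself).

Tables are measured at discrete panel sizes; `interpolate_panel_size()`
interpolates r-squared and panel MAC linearly per variant between the two
bracketing sizes, matched by variant id, and refuses to extrapolate. A
variant missing at either bracketing size keeps a missing r-squared, while
its panel MAC interpolates from 0 — so imputability can switch on midway,
consistent with the panel actually growing. Linear interpolation is
deliberately conservative: it invents no saturation model between measured
points.

## Synthetic quality-table generator

Real quality tables come from masking experiments on sequenced cohorts;
the generator (`generate_quality_tables()`) produces tables with the same
qualitative structure so that every formula can be exercised and validated
without controlled-access data:

* Population MAFs are drawn with density ∝ 1/p on `[1e-4, 0.5]` (the
  neutral-spectrum shape); sample MACs are binomial draws in an evaluation
  sample of `N = 3412`, conditioned on being polymorphic.
* A variant is population-specific with probability
  `ps_max · exp(-maf/ps_decay)` (defaults 0.5, 0.01): rarer variants are
  more often confined to the target population.
* The effective matched panel for a shared variant is
  `panel_n + external_weight × external_panel_size` (defaults 0.05 ×
  30,000 = 1,500 effective individuals — an external panel helps, but at a
  haplotype-sharing discount); a population-specific variant sees only
  `panel_n`.
* Mean r-squared follows a saturation curve
  `r2_max(array) · x / (x + n50(maf))` with `n50(maf) = 100 + 0.3/maf`:
  rarer variants need more matched haplotypes to impute well. Array
  ceilings default to 0.90 / 0.95 / 0.97 for Core / OmniExpress / Omni2.5,
  reflecting scaffold density. Per-variant r-squared is a Beta draw around
  that mean (concentration 50).
* Panel MACs are **cumulative** binomial draws as the matched panel grows,
  and each variant's Beta quantile is drawn once and shared across panel
  sizes and arrays. Both choices make every variant's quality monotone in
  panel size and array density *by construction*, so coverage and power
  monotonicity are structural properties of the generated tables, which
  the estimator's monotonicity tests then verify end to end.

These defaults were chosen once to make the generated tables resemble
published augmented-panel behavior — external-panel-only coverage around
30% for MAF 0.1–0.25% variants rising toward ~80% with 2,000 sequenced,
near-complete coverage for common variants — and are not tuned thereafter.

What the generator does **not** emulate: linkage disequilibrium and
haplotype mosaics (r-squared is drawn, not produced by an imputation
algorithm), array-specific marker placement (arrays differ only through
the r-squared ceiling), admixture structure, and any correlation between a
variant's frequency and its imputability beyond the saturation curve.
Passing tests therefore show that the estimator, weights, and optimizer
are correct *given* a quality table; they do not certify any particular
real population's coverage numbers. For real designs, users should supply
quality tables measured on their own population (or published summary
tables) via `read_quality_table()`.

## Monte Carlo oracle

`simulate_power()` simulates the two-stage test end to end: case/control
genotypes under Hardy-Weinberg at `p_case`/`p_control`, the sequenced
stratum analyzed on true genotypes, the imputed stratum on dosages
`D = G + ε` with Gaussian noise calibrated so `cor(G, D)² = r²`
(`ε` variance `V(1-r²)/r²` with `V` the case/control mixture variance),
strata combined with `√c, √(1-c)` weights, two-sided rejection at
`z_{1-α/2}`.

Rather than materializing individual-level matrices, replicates are drawn
as sufficient statistics: genotype-class counts are multinomial, and the
noise sums `(Σε, ΣGε, Σε²)` are drawn from their exact joint conditional
distribution given the genotypes, by decomposing the iid Gaussian noise
vector along the constant direction, the centered-genotype direction, and
the orthogonal complement (two normals and an independent
`χ²_{n_g - 2}` per group). The joint law of the Z statistics is identical
to individual-level simulation — this is an exact reformulation, not an
approximation — and 20,000 replicates of a 20,000-participant design take
well under a second. Sequenced and imputed strata are drawn independently,
which is equivalent to random subsampling of who gets sequenced under this
model. Replicates where a statistic is undefined (a stratum drawn
monomorphic, possible in principle for very rare variants in small strata)
count as non-rejections and are reported in `n_undefined`.

`simulate_imputed_dosage()` is the file-facing counterpart for building
paired truth/dosage fixtures; it leaves dosages unclipped so the target
correlation is exact (clip on export if a format requires `[0, 2]`).

## Cost model and design optimization

`cost = n × seq_cost + m × array_cost`: sequenced participants incur no
array cost. This accounting is the one consistent with iso-cost lines
`m = total/array_cost − (seq_cost/array_cost)·n` in design space. Defaults
are $1,000 per genome and list prices $49 / $94 / $172 per sample for
Core / OmniExpress / Omni2.5. Costs are held in integer cents so
feasibility comparisons at budget boundaries are exact; budgets are
inclusive.

`min_cost_design()` and `max_power_design()` evaluate the full
`(array, n, m)` grid exhaustively — `n` defaults to the panel sizes
present in the supplied tables (interpolation available), `m` to a
50-participant step — and return the winner plus the entire evaluated
frontier. Ties break toward lower cost, then fewer sequenced, then fewer
imputed (cheaper logistics first). Infeasibility is an explicit result
carrying the best value found, never a silent fallback. Tests hold the
optimizer to an independently written brute-force enumeration and to
monotonicity in budget and power-target sweeps. Exhaustive search is the
point: grids of a few hundred cells evaluate in seconds, and no pruning
heuristic can then silently miss the optimum.

## Numerical choices and degenerate inputs

* `z_crit` is computed as `qnorm(α/2, lower.tail = FALSE)`; the
  `1 - α/2` form loses three digits at genome-wide `α` and would break the
  exact null identity `power = α` (at `γ = 1` the weighted estimator
  returns `α × p_imputable` to 1e-10, which the tests assert).
* The Poisson MAC pmf is truncated where cumulative mass reaches
  `1 - 1e-12`, giving finite support for weighting; MACs beyond the
  truncation get weight 0 (they are impossible under the model to that
  tolerance).
* Monomorphic inputs: a variant with zero variance on either side of a
  truth/dosage pair gets missing r-squared; `simulate_imputed_dosage()`
  refuses monomorphic genotypes; `p = 0` propagates to zero frequencies
  and `η = 0`.
* Sample MAFs above 0.5 are folded to the minor allele and flagged;
  sample MAC is recomputed as `round(2N·maf)` after folding.
* All generator and simulator functions take an explicit seed and restore
  the caller's RNG state; identical seeds give byte-identical outputs.

## Problem sizes used by the test suite

Monte Carlo checks run at 20,000 replicates (binomial SE ≈ 0.0035 at
midrange power; agreement asserted within 3 SE). The analytic-vs-
integration grid covers 5 effect sizes × 5 effective sample sizes × 3
significance levels. Synthetic tables in tests use 150–2,000 variants;
the upper-bound property is asserted over 1,000 randomized tables. The
full suite runs in well under a minute on one CPU.

## Limitations

* Power for non-imputable variants is assumed zero: no credit for LD-proxy
  tagging. This is conservative for common variants (usually well tagged)
  and realistic for rare ones.
* Binary traits under the multiplicative model only; the `model` tag in
  `disease_model()` leaves room for dominant/recessive/continuous
  extensions, and no covariate adjustment is modeled.
* Sequenced participants are assumed randomly selected; strategic
  selection to maximize panel diversity would do somewhat better, so
  results are a mild lower bound on what sequencing buys.
* The optimizer maximizes single-study power; the design that is optimal
  for one study need not maximize downstream meta-analysis power.
* Recruitment and sample-collection costs are excluded; only sequencing
  and genotyping enter the cost model, and sample size is assumed
  unconstrained.
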