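---
title: "Extreme class discrimination for paired expression data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme class discrimination for paired expression data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdselect)
library(dplyr)
```

## The problem

In tumour biomarker screens it is common to profile tumour tissue and
adjacent normal tissue from the *same* patients. Each patient then
contributes a matched pair, and the question for each of the M features
(microarray probe sets, genes, transcripts) is whether it separates the two
tissue classes *within* patients. Because each pair shares the patient's
stable characteristics — genotype, age, processing batch — a paired analysis
cancels those confounders and retains power at the small sample sizes
(a few dozen patients) typical of surgical cohorts.

`ecdselect` implements an *extreme class discrimination* (ECD) screen: it
looks for features whose per-patient differences all point the same way,
rather than features with merely a significant mean shift. A feature that
classifies every one of N patients correctly is called a **completely
discriminative signal (CDS)**; anything else is an **incomplete
discriminative signal (IDS)**. The number of minority-sign pairs is the
feature's **misclassification count**.

## The model

Write `x_ij` and `y_ij` for the normal and tumour intensities of feature
`j` in patient `i` (non-log, strictly positive values such as
MAS5-summarised microarray signal). The working model behind the paired
design is additive on the latent (log) scale:

    x_ij = mu_j + alpha_i + eps_ij,   y_ij = mu_j + theta_j + alpha_i + eps'_ij

where `mu_j` is a feature baseline, `alpha_i` a random patient effect
shared by both members of the pair, `theta_j` the disease effect, and the
residuals are independent and symmetric about zero. Within-pair
differences eliminate `alpha_i`, which is why the pipeline only ever
compares values patient by patient.

## The pipeline

1. **Cross-normalization (CN).** Each class is rescaled by the *opposite*
   class's per-feature mean: `y_cn = y / mean(x)`, `x_cn = x / mean(y)`.
   For a feature with a genuine effect this inflates tumour ratios and
   deflates normal ratios simultaneously, widening the gap between the
   classes before differences are taken. The transform is dimensionless
   and invariant to a common rescaling of all intensities. The exact
   algebra of this step is a genuine design choice: dividing by the
   opposite-class mean was adopted (over subtracting it, or dividing by
   the patient's own opposite value) because it acts on non-log
   intensities as ratios, treats the two classes symmetrically, and is
   scale-invariant; the alternatives remain available through the
   `cn_method` argument.
2. **Modified Wilcoxon test (MWT).** Per feature, the differences
   `d_ij = y_cn - x_cn` are ranked by absolute value (average ranks for
   ties; exact zeros dropped), the smaller of the positive/negative rank
   sums `r_min` is standardised by its null moments
   `n(n+1)/4` and `sqrt(n(n+1)(2n+1)/24)`, and a two-sided p-value is read
   from the normal distribution.
3. **Misclassification accounting.** `min(t_plus, t_minus)` counts the
   minority-sign pairs; zero errors with no zero differences makes the
   feature CDS.
4. **Bootstrap filter.** Patient pairs are resampled with replacement
   (default 9,999 replicates), CN and the MWT are recomputed on each
   replicate, and `p_boot` is the fraction of replicates whose p-value is
   *strictly* smaller than the observed one.
5. **Fold-change filter.** The ratio of class means, symmetrised to be at
   least 1, must exceed a floor.

The **strict** selection keeps features with zero misclassifications, MWT
p below `mwt_alpha` (0.05), `p_boot` below 0.05 and fold change above
1.35. The **relaxed** selection tolerates up to `max_errors` (default 2)
misclassified pairs, and in exchange demands `p_boot` below 0.01 and fold
change above 1.2. The sign-symmetry test (below) is reported as an
annotation justifying the error budget, not used as a filter.

## The sign-symmetry test

Under the null each pair's sign is an independent fair coin, so the
probability of at most `s` minority signs among N pairs is the binomial
lower tail `sum_{k<=s} C(N,k) 0.5^N`. Bonferroni-multiplied by the number
of features screened, this bounds how many low-error features chance
alone supplies. For the reference design — 27 pairs, 22,283 probe sets —
at most two errors gives

```{r sign-test}
sign_symmetry_test(s = 2, n_pairs = 27, m_tests = 22283)
```

an adjusted p of about 0.063 (0.062 after truncation to three decimals),
i.e. even the *relaxed* two-error criterion is globally implausible under
pure chance. Two errors in 27 pairs is a `r round(100 * 2 / 27)`% error
rate. The one-sided lower tail is used (a two-sided version would double
it); sidedness is configurable.

## Small-sample behaviour of the Z approximation

The MWT uses a normal approximation with a pluggable correction policy.
The default, `"continuity"`, moves the smaller rank sum half a unit
toward its null mean before standardising (clamped so a balanced feature
keeps Z = 0). `"none"` disables the correction and `"shrink:c"` deflates
Z by `sqrt((n-c)/n)`, a degrees-of-freedom-style factor. No single policy
is privileged by theory here, so the policy is recorded with the results.

Against the exact signed-rank distribution (full enumeration of the `2^n`
sign assignments) at `r_min = 0`, the uncorrected normal tail is accurate
to well under 0.01 from six pairs upward, but breaks down below that
(absolute error 0.019 at n = 5, 0.057 at n = 4, 0.14 at n = 3). Six pairs
is therefore the smallest sample at which the package's normal deviate
should be trusted; below that the sign-symmetry tail, which is exact, is
the appropriate reference. This floor matters for interpreting the
package's validation battery, which checks normal-vs-exact agreement over
six to twelve pairs.

## The bootstrap: what the counting rule can and cannot do

The bootstrap statistic is `p_boot = #(Pboot < Ptest) / B` with a strict
inequality, computed under pair resampling (the unit of resampling is the
patient pair, preserving the paired dependence that is the method's
premise; a sign-flip permutation mode is available via `null =
"signflip"` for users wanting a classical symmetric null). Two
consequences follow directly from the counting rule:

* it is a *stability* filter, not a significance test — it asks how often
  resampled cohorts look even more extreme than the observed one;
* a zero-misclassification feature can **never** be removed by it: its
  observed p (zero rank sum at the full pair count) is the minimum any
  replicate can attain, so `p_boot` is exactly 0. The bootstrap
  therefore only discriminates among features that already show some
  sign disagreement.

CN is recomputed inside every replicate, since the class means change
under resampling.

## Known limitation: sign coupling under cross-normalization

CN divides by *estimated* class means, which couples the signs of a
feature's differences across patients: when, by chance, one class's mean
is overestimated, all of that feature's differences shift together. Under
a pure null the chance that all N pairs share a sign is therefore higher
than the independent-coin value `2·0.5^N`. At the reference scale (27
pairs, 10,000 null features, the simulator defaults below) this
materialises as roughly one or two spurious complete separations per
10,000 null features — and because such features also inherit an inflated
fold change and are immune to the bootstrap filter (previous section),
they typically survive the strict selection. Users should regard the
strict selection's false-positive rate as "a few in 10⁴ features", not
zero, and treat borderline fold changes among zero-error features with
suspicion. On raw (non-CN) differences the independent-coin rate holds
exactly; the package's test suite pins both facts.

## The simulator

`simulate_paired()` draws data from the additive model above, then
exponentiates both classes so the output is strictly positive and
log-normal — the shape of MAS5-like intensity data. Defaults encode the
reference study conditions: 27 patient pairs; baseline `mu_j ~ N(log 500, 1)`
(500 being the conventional mean-intensity scaling target of MAS5
output); patient effect `alpha_i ~ N(0, 1)`, comparable to the baseline
spread, so stable confounders are a dominant variance component; residual
noise `eps ~ N(0, 0.5)`; a 1% effect fraction with log-scale effect size
2 and random direction. A linear-scale mode (`intensity_transform =
FALSE`) skips the exponentiation for closed-form checks of means and
variances; its output can be non-positive and is not meant for CN.

What the simulator deliberately does not emulate: probe-level noise,
batch effects, inter-feature correlation, or heavy-tailed outliers.
Passing the validation battery therefore demonstrates internal
correctness and the method's operating characteristics under its own
model — not performance on any particular real cohort.

```{r simulate}
sim <- simulate_paired(n_features = 2000, n_patients = 27,
                       effect_fraction = 0.01, seed = 7)
fit <- run_ecd(sim$data, ecd_config(n_boot = 999, seed = 7))
glance(fit)
evaluate_selection(fit, sim$truth)
```

## Baselines and overlap statistics

`paired_t_test()` and `standard_wilcoxon()` score the same data with the
classical paired tests on raw differences; `bh_fdr()`
(Benjamini–Hochberg, via `stats::p.adjust`) and `top_k()` produce
equal-size ranked lists for method comparisons; `overlap_test()` computes
the upper-tail hypergeometric probability of an observed overlap between
two lists (default universe 13,074, the number of RefSeq genes
non-redundantly represented on the U133A array), with a Fisher-style
two-sided mode.

## Numerical and design choices

* Intensities are used non-log-transformed; zero or negative cells are
  floored at a configurable epsilon (default 0.01 intensity units, with a
  warning) so CN ratios stay finite.
* Ties receive average ranks; exact-zero differences are dropped before
  ranking; a feature whose differences are all zero is flagged degenerate
  (`p = 1`) and never selected.
* Any zero difference breaks CDS status (strict signs required).
* Results tables sort by (MWT p ascending, |Z| descending, feature id) —
  fully deterministic under ties.
* The bootstrap is computed only for features surviving the error and MWT
  filters; since those filters do not depend on the bootstrap, the final
  selection is identical to bootstrapping everything.
* All randomness is scoped through `withr::with_seed`, so simulation and
  bootstrap calls are reproducible and order-independent; test and
  validation runs use 999 bootstrap replicates (the package default is
  9,999) and the problem sizes shown above.
* `evaluate_selection()` reports the false-discovery proportion as 0 for
  an empty selection, by convention.
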