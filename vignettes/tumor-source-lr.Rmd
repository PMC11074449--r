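---
title: "Likelihood ratios for tumor tissue source identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood ratios for tumor tissue source identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tumor tissue — often formalin-fixed, paraffin-embedded (FFPE) material — may
be the only sample available to decide whether tissue originated from a known
individual. Somatic alterations (additional alleles, replacement alleles,
partial or complete loss of heterozygosity) make the tumor's STR profile
deviate from the person's constitutional genotype, and FFPE DNA is degraded,
so a naive profile comparison fails exactly when it is needed most. tumorlr
treats the tumor as a DNA mixture of a normal cell population and `K - 1`
tumor subclones and reports a likelihood ratio

$$LR = \frac{P(E \mid H_p)}{P(E \mid H_d)}$$

where `E` is the observed profile, `Hp` states that normal cells and their
tumor subclones come from the person of interest, and `Hd` that they come
from an unrelated individual or, optionally, from a parent/offspring or
full sibling of that person.

## The model

**Peak heights.** The height contributed by one allele copy at mixture
weight 1 follows a gamma distribution with mean `mu` (RFU) and coefficient
of variation `omega`; all contributions share the scale `mu * omega^2`, so
independent cell-population contributions add in the gamma shape:

$$\text{shape}(a) = \frac{1}{\omega^2}\sum_{\text{pop}} w_{\text{pop}}\,
n_{a,\text{pop}}\, \varepsilon^{(\text{bp}_a - 90)/100},$$

with `n` the copy number of allele `a` in the population and `w` the mixture
weights: the normal-cell fraction `Mxn` (a pathologist's estimate, supplied
a priori) plus `K - 1` subclone weights summing to `1 - Mxn`. The
`gamma_qq_diagnostic()` quantile-quantile check against per-locus total
heights supports this assumption on simulated data.

**Degradation.** FFPE profiles decline log-linearly with fragment size
("ski-slope"). `fit_degradation()` regresses log mean locus height on mean
locus size; `exp(slope)` is the per-base probability of no strand breakage,
and the gamma mean of an allele of size `bp` is scaled by
`epsilon^((bp - 90)/100)` with `epsilon = per_base_slope^100`. Degradation
is included when `p_deg = 1 - per_base_slope > 1e-4`, and `epsilon` is then
refined jointly by maximum likelihood within `(0.1, 1]`.

**Dropout and drop-in.** An allele the genotype combination expects but the
profile does not show contributes the gamma CDF at the analytical threshold
(AT, default 175 RFU) — no separate dropout parameter is introduced, because
the gamma model already implies `P(Y < AT)`. Drop-in and stutter are not
modeled (stutter is assumed filtered per kit protocol); an observed allele
no population can produce therefore gives density exactly zero.

**Tumor genotypes (the descent prior).** Each tumor allele slot descends
from one normal allele slot and is

* retained with probability `1 - phi`,
* lost with probability `phi * loss_fraction` (pLOH/LOH states), or
* replaced by population allele `a` with probability
  `phi * (1 - loss_fraction) * f(a)` (Aadd/Anew states; replacement may
  regenerate the source allele).

`phi` is the per-locus incidence of STR variants, supplied a priori (a
colorectal table spanning [0.0775, 0.4341] is bundled; loci missing from a
table get the mean incidence). The unordered-genotype probability sums the
ordered slot-to-source assignments, so `P(g_t | g_n, phi)` is a proper
distribution — at `phi = 0` the tumor equals the somatic genotype with
probability one. `loss_fraction` defaults to 0.5: absent any published split
between loss and replacement events, variant mass is divided evenly.

**Unseen alleles.** Candidate normal alleles are the observed alleles plus
the person of interest's (under `Hp` and the kinship hypotheses) or plus the
aggregate symbol `Q` (under `Hd`), which carries the residual frequency mass
`max(0, 1 - sum f)` and, having no physical size, is assigned the locus mean
observed size for its (unobserved-peak) dropout factor. This keeps the
enumeration finite while preserving normalization.

**Kinship.** `Hd` may name a parent/offspring (IBD coefficients (0, 1, 0))
or full sibling ((1/4, 1/2, 1/4)) of the person of interest as the source;
the unknown's constitutional genotype prior is then conditioned on the
reference genotype through the usual IBD decomposition.

**Number of contributors.** The maximum allele count across loci bounds the
number of cell populations: `K = 2` when `Lmax < 3`, else
`ceiling(Lmax / 2)`.

## Nuisance maximization

`Mxn` and `phi` are a priori parameters and are never optimized. `mu`,
`omega`, `epsilon` (when included) and, for `K > 2`, the subclone weight
split are maximized separately under each hypothesis with bounded L-BFGS-B:
`log mu` in `[log(AT/10), log(1e5)]`, `omega` in `[0.05, 1.5]`, `epsilon` in
`[0.1, 1]`, subclone split parameterized by stick-breaking logits in
`[-8, 8]`. Five seeded starts (one informed by the median locus total
height and the degradation pre-fit, four quasi-random in the box) are
scored and the best two are polished; this keeps the ten-thousand-odd
optimizations of a full non-contributor experiment tractable on one CPU
while being deterministic in the seed. The per-locus enumeration is
flattened once into index vectors, so one likelihood evaluation is a few
vectorized gamma calls.

## The synthetic cohort generator

`simulate_frequency_table()` (Dirichlet frequencies over consecutive
integer designations with occasional `.3` microvariants),
`sample_reference_profile()` (Hardy-Weinberg), `simulate_tumor_profile()`
(descent-model variants, gamma heights, degradation, AT filtering, with all
applied variants recorded as truth metadata) and `make_case_suite()`
emulate the study's inputs: 21 autosomal GlobalFiler loci, `mu = 1500` RFU
and `omega = 0.2` (dropout rare at AT 175 for `Mxn >= 0.1`), per-base slope
0.996 (the middle of the cohort's fitted 0.9943-0.9985 range), and 17 cases
whose normal-cell fractions are `1 - Mxt` for tumor-cell percentages
between 30% and 90%. The simulator draws tumor genotypes from the same
descent model the likelihood integrates over — a generative/analytic
consistency that the test suite checks by chi-square.

Two variant-incidence regimes matter. The bundled colorectal survey range
([0.0775, 0.4341] per locus) is the *analysis* prior. The *realized*
alteration rate in the cohort being emulated is much lower — roughly 9% of
loci altered per sample — so cohort-emulating simulations
(`scripts/acceptance.R`) generate tumors at a per-slot incidence of 0.046,
which reproduces that fraction, while still analyzing with the survey-range
incidences. Generating instead at the survey-range incidence yields
variant-heavy profiles (about half of all loci altered) that are useful for
stress-testing the enumeration but do not resemble the cohort.

What the generator does not emulate: stutter and drop-in artifacts,
inter-locus amplification imbalance, off-ladder alleles beyond `.3`
microvariants, and FFPE chemistry beyond log-linear height decay. Passing
tests therefore validate the model's internal consistency and its behavior
on idealized electropherograms, not performance on real casework data.

## Behavior of the LR in the a priori parameters

For a true contributor the LR rises with `Mxn` (the known genotype's
mixture weight grows) and, on variant-free profiles, falls near-linearly
with the assumed `phi` (the prior increasingly discounts the shared
genotype while the alternative-source terms gain); for non-contributors the
LR falls as `Mxn` grows. These are the behaviors the acceptance tests
check on variant-free synthetic cases.

A known limitation: because the descent prior is normalized, the `(1 - phi)`
retention factor largely cancels between the `Hp` and `Hd` maxima, so the
`phi`-dependence on unaltered loci is weak (a few hundredths of a log10 unit
per locus across the survey range). On profiles that do carry realized
variants, the altered loci contribute a rising, strongly concave term
(`log(phi (1 - phi))`-shaped), which can produce a shallow interior maximum
of `log10 LR` in `phi` and weaken the linear correlation. Sweeps over
variant-heavy cases should therefore be read as sensitivity analyses rather
than as linear fits.

## Numerical choices and degenerate inputs

* Log-sum-exp is used across genotype combinations; a locus where every
  combination is impossible (an observed allele no candidate can produce)
  contributes `-Inf` and is named in a warning rather than silently dropped.
* Frequencies are floored at `5 / (2 N)` (survey size `N = 500` by default);
  flooring never lowers a stored frequency, and the generator renormalizes
  so bundled tables round-trip through disk.
* The `Mxn` confidence interval is read as an absolute `+/- 0.10`, clipped
  to `[0.01, 0.99]`, with 21 evenly spaced points; the non-contributor test
  uses its minimum, quartiles and maximum as the five groups and caches the
  `Hd` denominator per group.
* Reference profiles listing one allele at a locus are treated as
  homozygous; evidence loci whose peaks all fall below AT remain in the
  profile as total-dropout loci.
* Optimizer reproducibility is exact for a given seed; repeated runs give
  bit-identical log-likelihoods.

## Problem sizes used by the checks

The test suite works on 5-12 locus cases for engine checks and full
21-locus cases for parameter recovery; property suites use hundreds of
randomized draws. `scripts/acceptance.R` generates a 10-case cohort for the
non-contributor experiment (5 groups x 200 individuals per case) and the
`phi` sweeps, and a 17-case suite for the kinship comparisons — sizes chosen
so the whole script completes in well under half an hour on a single CPU.
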