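# tumorlr

Likelihood ratios for deciding whether tumor tissue originated from a known
individual, from STR (short tandem repeat) capillary-electrophoresis
profiles.

Tumor genomes accumulate somatic alterations — additional alleles (Aadd),
replacement alleles (Anew), partial and complete loss of heterozygosity
(pLOH/LOH) — so a tumor STR profile need not match the constitutional
genotype of the person it came from, and FFPE-derived DNA is degraded on top
of that. tumorlr is aimed at forensic geneticists and molecular pathologists
who need a quantitative strength-of-evidence statement for such samples
rather than a "cannot be excluded".

## The model

Tumor tissue is treated as a DNA mixture of a normal cell population and
`K − 1` tumor subclones. The evidence `E` is evaluated under

* `Hp`: normal cells and their `K − 1` subclones come from the person of
  interest, versus
* `Hd`: they come from an unrelated individual — or from a parent/offspring
  or full sibling of the person of interest,

and reported as `LR = P(E | Hp) / P(E | Hd)`, with

```
P(E | H) = ∏_m  Σ_{g_m ∈ G_m}  P(g_m | H, φ_m) · p(y_m | g_m, M_x, μ, ω, ε)
```

Peak heights `y_m` follow a gamma model: each allele's shape is
`(1/ω²) Σ_pop w_pop · n_{a,pop} · ε^((bp−90)/100)` with shared scale `μω²`,
weights `(M_xn, …)` given by the pathologist's normal-cell fraction,
degradation factor `ε` from a log-linear "ski-slope" fit, and dropout below
the analytical threshold (175 RFU) handled by the gamma CDF. Tumor subclone
genotypes get a descent prior: each allele slot is retained with `1 − φ`,
lost with `φ·λ`, or replaced by population allele `a` with `φ(1−λ)f(a)`,
where `φ` is the per-locus incidence of STR variants (a colorectal table
spanning [0.0775, 0.4341] is bundled). `μ`, `ω`, `ε` and the subclone weight
split are maximized separately under each hypothesis; `M_xn` and `φ` are a
priori parameters and never optimized.

See `vignettes/tumor-source-lr.Rmd` for the full account of the model,
defaults and limitations.

## Worked example

Simulate a colorectal-like case (21 GlobalFiler loci, 40% normal cells,
FFPE degradation) and test it against the patient's reference:

```r
library(tumorlr)

cfg   <- sim_config(seed = 11, mxn = 0.4, phi = 0.046)   # cohort-like variant rate
freqs <- simulate_frequency_table(cfg)
ref   <- sample_reference_profile(freqs, seed = 2, "patient1")
tumor <- simulate_tumor_profile(ref, freqs, cfg)

head(tumor, 4)
#>   sample_id  locus   allele height  size
#> 1 patient1-T D3S1358 7       1552.    78
#> 2 patient1-T D3S1358 9       1075.    86
#> 3 patient1-T vWA     12       833.   158
#> 4 patient1-T vWA     14      1439.   166

fit_degradation(tumor) |> glance()
#>   per_base_slope    p_deg
#> 1       0.997214 0.002786        # ski-slope: P(breakage)/bp ~ 0.0028

lr <- compute_lr(tumor, ref, freqs, mxn = 0.4, phi = default_phi())
lr
#> Tumor-source likelihood ratio (HP vs HD_UNRELATED)
#>   log10(LR) = 26.5256  [K = 2, Mxn = 0.4]
#>   Hp logL = -266.22226 ; Hd logL = -327.2998
```

`log10(LR) ≈ 26.5` says the profile is about 10^26 times more probable if
the tumor came from `patient1` than from an unrelated individual — decisive
support, comparable to a full random-match probability despite the mixture
and degradation modeling. `tidy(lr)` breaks that into per-locus
contributions (they sum to the total):

```r
tidy(lr) |> head(3)
#>   locus   log10_lr
#> 1 D3S1358    0.985
#> 2 vWA        0.999
#> 3 D16S539    2.85
```

`glance(lr)` adds the fitted nuisance parameters (here `μ ≈ 1433` RFU,
`ω ≈ 0.17`, `ε ≈ 0.69` — close to the generator's `μ = 1500`, `ω = 0.2`,
`0.996^100 ≈ 0.67`). Further entry points: `compute_lr(..., hd = "po"/"fs")`
for relative-as-source defenses, `grid_experiment()` and `interval_lr()`
for sensitivity over `M_xn` and `φ`, `non_contributor_test()` for Hd-true
specificity, `gamma_qq_diagnostic()` for the peak-height model check, and
`autoplot()` on any result. A command-line interface with the same
functionality ships as `inst/cli/tumorlr`.

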