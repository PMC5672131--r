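# keratopower

Paraxial corneal-power calculations for keratoconus eyes treated with
accelerated corneal collagen crosslinking (CXL), for researchers and
clinicians who need central corneal power without trusting the standard
keratometric shortcut.

## The problem

Keratometers estimate corneal power from the anterior radius alone,

    Pk = (nk − 1) / r1c,

with the fictitious keratometric index nk = 1.3375. The reference standard
is the Gaussian thick-lens power using both corneal surfaces and the
central thickness e_c,

    Pc_Gauss = P1c + P2c − (e_c/n_c)·P1c·P2c,
    P1c = (n_c − n_a)/r1c,   P2c = (n_ha − n_c)/r2c.

In post-CXL keratoconus the anterior-to-posterior radius ratio
k = r1c/r2c spans roughly 1.04–1.57, and Pk(1.3375) overestimates
Pc_Gauss by up to 3.2 D. For a given geometry the error vanishes at the
exact index nk_exact = 1 + r1c·Pc_Gauss; when the posterior radius cannot
be measured, the package provides an **adjusted keratometric index**
nk_adj(r1c): three linear functions of the anterior radius per schematic
eye model (Gullstrand, Le Grand), calibrated by an equal-error condition
at each band's posterior-radius extremes so that Pk_adj = (nk_adj − 1)/r1c
stays within ±0.8 D of the Gaussian power over the calibrated domain.

The package implements: the power equations and exact index; the band
calibration and piecewise evaluation; an exhaustive simulation sweep that
regenerates the published summary tables; a synthetic-cohort generator
emulating the published 21-eye clinical sample; and the agreement pipeline
(Bland–Altman limits, Pearson correlation, Wilcoxon/paired-t tests).

## Worked example

A cornea with r1c = 7.1 mm and r2c = 5.6 mm (the published sample means):

```r
library(keratopower)
run_adjust(7.1, 5.6, "gullstrand")
#>  r1c band nk_adj pk_adj r2c pc_gauss nk_exact delta_pc_1.3375
#>  7.1    2 1.3238   45.6 5.6       46   1.3263             1.6
```

The classical 1.3375 estimate overshoots the Gaussian power by 1.6 D; the
adjusted index (band 2, nk_adj = 1.3238) brings the single-surface
estimate to 45.6 D, within 0.4 D of the 46.0 D reference.

A full synthetic cohort run:

```r
co <- generate_synthetic_cohort(21, seed = 7)
analyze_cohort(co, "gullstrand")
#> Cohort agreement analysis (gullstrand model, nk = 1.3375, measured thickness)
#>   21 eyes analysed, 0 excluded (r1c out of domain)
#>
#>       comparison  n mean_diff sd_diff loa_low loa_high pearson_r p_wilcoxon
#> 1    pk_vs_gauss 21    1.5976   0.563   0.494     2.70     0.988   9.54e-07
#> 2    pk_vs_pkadj 21    1.6424   0.359   0.938     2.35     0.996   9.54e-07
#> 3 pkadj_vs_gauss 21   -0.0449   0.569  -1.161     1.07     0.987   8.12e-01
```

The classical index overestimates by 1.6 D on average (significant,
Wilcoxon p < 0.001) while the adjusted power is statistically
indistinguishable from the Gaussian reference (mean −0.04 D, p = 0.81).

A command-line wrapper ships in `inst/cli/keratopower` with subcommands
`simulate`, `adjust`, `cohort` and `agree`:

```sh
Rscript inst/cli/keratopower simulate --model gullstrand --format markdown
Rscript inst/cli/keratopower adjust --r1c 6.8 --r2c 4.4 --model gullstrand
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline theoretical
quantities from scratch — the point keratometric errors at the published
extreme geometries, the fitted band-algorithm slopes, and the exhaustive
banded-domain extrema of the exact index, adjusted index, Gaussian power
and adjusted power — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## See also

The methods vignette (`vignettes/adjusted-keratometric-index.Rmd`) covers
the model assumptions, the band reconstruction, rounding conventions, the
synthetic generator's realism limits, and known discrepancies.
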