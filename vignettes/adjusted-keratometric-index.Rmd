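---
title: "Corneal power after crosslinking: the adjusted keratometric index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal power after crosslinking: the adjusted keratometric index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keratopower)
```

## The problem

Keratometers and topographers estimate central corneal power from the
anterior corneal radius alone,

$$P_k = \frac{n_k - 1}{r_{1c}},$$

where the fictitious *keratometric index* $n_k$ (conventionally 1.3375)
absorbs the optical effect of the posterior corneal surface and of corneal
thickness. That shortcut is calibrated for normal corneas, where the
anterior-to-posterior radius ratio $k = r_{1c}/r_{2c}$ sits near 1.2. In
keratoconus the cornea steepens and thins, and corneal collagen
crosslinking (CXL) further remodels the posterior surface, so $k$ ranges
over roughly 1.04–1.57. There $P_k(1.3375)$ can overestimate the true
paraxial power by more than 3 D — enough to corrupt intraocular-lens power
calculation and to exaggerate the apparent flattening effect of the
surgery.

The reference standard is the Gaussian thick-lens power, which uses both
surfaces and the central thickness $e_c$:

$$P_c^{Gauss} = P_{1c} + P_{2c} - \frac{e_c}{n_c} P_{1c} P_{2c},
\qquad
P_{1c} = \frac{n_c - n_a}{r_{1c}},\quad
P_{2c} = \frac{n_{ha} - n_c}{r_{2c}},$$

with all lengths in metres. The keratometric error is
$\Delta P_c = P_k - P_c^{Gauss}$ (positive = overestimation). Setting
$\Delta P_c = 0$ defines the *exact* keratometric index of a given
geometry, which the package computes through the stable identity
$n_k^{exact} = 1 + r_{1c} \, P_c^{Gauss}$.

Since many clinics cannot measure $r_{2c}$, the package's centrepiece is an
*adjusted* keratometric index $n_k^{adj}(r_{1c})$: a piecewise-linear
function of the anterior radius alone, calibrated so that the keratometric
formula stays within ±0.8 D of the Gaussian power over the whole post-CXL
domain.

## Schematic eye models

The corneal refractive indices and nominal thickness come from the two
classical schematic eyes:

| model | $n_c$ | $n_{ha}$ | $e_c$ (mm) | classical $n_k$ |
|---|---|---|---|---|
| Gullstrand | 1.376 | 1.336 | 0.50 | 1.3315 |
| Le Grand | 1.3771 | 1.3374 | 0.55 | 1.3304 |

These constants are shipped in a plain-text key/value file
(`inst/extdata/eye_models.dcf`) and further models can be added with
`register_eye_model()`; the two built-ins are immutable. The decisive
validation of this constant choice is numerical: with them the package
reproduces every published point error, every fitted band coefficient, and
every tabulated range (see the test suite).

## The calibration

The post-CXL domain is split into three anterior-radius bands, each with
fixed posterior-radius extremes; the banding is identical for both eye
models:

```{r}
default_bands("gullstrand")[, c("band", "r1c_min", "r1c_max",
                                "r2c_lo", "r2c_hi", "k_min", "k_max")]
```

The extremes were reconstructed from the published k-ratio intervals
($r_{2c}^{lo} = r_{1c}^{max}/k_{max}$, $r_{2c}^{hi} = r_{1c}^{min}/k_{min}$);
this is the only interpretation that reproduces all published coefficients
and ranges.

For each $r_{1c}$, $n_k^{adj}$ is defined by the equal-error condition: the
keratometric error must have equal magnitude and opposite sign at the two
posterior-radius extremes of the band. Because the condition makes $P_k$
hit the midpoint of the two Gaussian powers,

$$n_k^{adj} = 1 + r_{1c}\,
\frac{P_c^{Gauss}(r_{2c}^{lo}) + P_c^{Gauss}(r_{2c}^{hi})}{2},$$

and substituting the thick-lens formula shows $n_k^{adj}$ is *exactly*
linear in $r_{1c}$: the slope is the mean posterior surface power of the
two extremes (rescaled to per-mm) and the intercept follows from the
thickness term. This is why the least-squares fits on the 0.1 mm band
grids return $R^2 = 1$ to machine precision and why the fit is
grid-independent. The adjusted power is then
$P_k^{adj} = (n_k^{adj} - 1)/r_{1c}$, evaluated piecewise by
`nk_adj_piecewise()`.

```{r}
build_table("gullstrand")[, c("band", "slope", "intercept",
                              "nk_adj_min", "nk_adj_max",
                              "pk_adj_min", "pk_adj_max",
                              "delta_pc_min", "delta_pc_max")]
```

## Numerical and design choices

**Units and rounding.** Interfaces accept millimetres (pachymetry in
micrometres); everything is converted to metres internally so powers are
dioptres. Display rounding follows the tabulated conventions: powers to
1 decimal, refractive indices to 4, slopes to 5, k ratios to 2.

**Band assignment.** The published rows live on a 0.1 mm grid; for
continuous $r_{1c}$ between rows the package uses the half-open midpoint
rule (band 1 below 6.85 mm, band 2 in [6.85, 7.25), band 3 above). Radii
outside 5.6–8.5 mm raise an error unless extrapolation is requested
explicitly, in which case the nearest band's line is extended and the
result flagged.

**Exact vs printed coefficients.** Piecewise evaluation defaults to exact
closed-form coefficients; the published 5/4-decimal roundings are available
(`use_printed = TRUE`) and can differ by one or two units in the fourth
index decimal. For the Le Grand middle band the exact intercept is 1.3782
where the published table prints 1.3781 — a table-rounding quirk the tests
tolerate at ±0.0001 without forcing agreement.

**Which sweep reproduces the published extremes.** Two domain conventions
coexist. The Cartesian (r1c, r2c) grid filtered by the k ratio (rounded to
2 decimals) is exposed by `enumerate_domain()`. But every published
extreme of the classical-index error corresponds to a *band corner* — each
band's grid of anterior radii crossed with its two posterior extremes —
and the rounded-k rectangle admits the pair (6.9, 4.4) whose error (3.3 D
at $n_k$ = 1.3375, Gullstrand) exceeds the published maximum of 3.2 D.
`delta_pc_extremes()` therefore defaults to the band-corner scheme and
offers the rectangle as an option. Tied extremes are reported as sets; the
published ties are ties at the printed 0.1 D rounding, so recovering them
needs a 0.1 D tie tolerance rather than the default 0.05 D.

**One irreproducible cell.** The published Le Grand Gaussian-power maximum
(58.6 D) cannot be reconstructed from any banding interpretation — the
band-corner evaluation gives 60.2 D at (5.6, 5.4), mirroring the
Gullstrand geometry whose published value (59.9 D) does reproduce. The
tests assert the reproducible Gullstrand values and pin the Le Grand cell
at our computed 60.2 D rather than forcing the published number.

## The synthetic cohort and what green tests establish

The original 21-eye clinical dataset is unpublished, so the clinical
pipeline runs on synthetic cohorts that emulate the published sample
summary: independent truncated-normal draws for radii, pachymetry and
asphericities, with a rejection step keeping $k$ inside the observed
1.1404–1.4719. The published per-eye statistics (mean difference 1.63 D,
its limits of agreement, the fitted clinical regression line) are *not*
reproduction targets — they depend on per-eye data nobody can access.
What the tests establish instead is distribution-level behaviour: the mean
overestimation of $P_k(1.3375)$ falls inside the reported 0.8–2.9 D
clinical envelope, the agreement machinery (Bland–Altman limits, Pearson
correlation, Wilcoxon/paired-t) is verified on hand-computed vectors, and
the adjusted power tracks the Gaussian power eye by eye.

One stated property fails honestly: per-eye $|P_k^{adj} - P_c^{Gauss}|$
does **not** stay below 0.85 D on these cohorts. Independent sampling with
only the global k constraint generates eyes whose posterior radius falls
below their band's calibration extreme (e.g. $r_{1c}$ = 7.3 mm with
$r_{2c}$ = 4.96 mm), where the ±0.8 D guarantee simply does not apply, and
the per-eye error can approach 1.6 D. The real cohort never occupied that
region — its flat-cornea eyes all had $k \le 1.30$ — but no r1c–r2c
covariance is published to emulate, and tightening the generator to force
the bound would be circular. The bound does hold, and is tested, for every
eye whose posterior radius lies within its band's extremes: by
construction the error is monotone in $r_{2c}$ and antisymmetric at the
extremes, so interior eyes are covered. Users applying the algorithm to
corneas with extreme k ratios at flat anterior radii should expect errors
above the nominal ±0.8 D.

Similarly, the common claim that $P_k(1.3375)$ *always* overestimates the
Gaussian power holds for the Gullstrand model across the whole domain but
fails for Le Grand at flat spherical corneas ($k = 1$, large $r_{1c}$),
where the thin-lens margin $(1.3375 - 1 - n_c + n_{ha})/r_{1c}$ is a tenth
of a dioptre and the thick-lens cross term overturns it.

## Limitations

Paraxial optics only: corneal asphericity is carried descriptively in the
cohort records but plays no optical role, so the powers are central
estimates, not effective optical-zone powers. The calibration is specific
to the post-CXL curvature domain; untreated keratoconus needs a different
(published, eight-band) calibration that this package deliberately does
not implement. The synthetic cohort reproduces marginal distributions and
the k constraint, not the joint curvature structure of real eyes; any
conclusion that depends on r1c–r2c covariance is outside what a green test
here can support.
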