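---
title: "Methods: from specimen measurements to regional phosphate budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from specimen measurements to regional phosphate budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosfor)
```

## The problem

Benthic foraminifera — shelled protists living in and on marine
sediments — accumulate dissolved inorganic phosphate (DIP)
intracellularly, largely as polyphosphate in acidocalcisome-like
organelles, at concentrations orders of magnitude above ambient
seawater. Summed over dense living assemblages, this intracellular pool
is a standing stock of reactive phosphorus on the seafloor that is
temporarily withdrawn from primary production. `phosfor` implements the
quantitative chain needed to size that stock: per-specimen biovolume,
per-individual phosphate content and intracellular concentration,
assemblage-based areal stocks, regional budgets against riverine
phosphorus runoff, and the EDS image transform used to localize
phosphorus-rich organelles in cryo-SEM elemental maps.

## Biovolume from 2D measurements

Specimens are photographed in plan view and measured along two (or one)
principal axes. Each species is assigned the closest simple geometric
solid; volumes follow the standard closed forms, with **all axes as
full lengths** (microscope measurements are full widths, so formulas
divide internally):

| shape | volume |
|---|---|
| sphere | $\pi d^3/6$ |
| prolate spheroid | $\pi \ell w^2/6$ |
| oblate spheroid | $\pi d^2 t/6$ |
| triaxial ellipsoid | $\pi abc/6$ |
| elliptic cone | $\pi abh/12$ |
| elliptic cylinder | $\pi abh/4$ |
| half-ellipsoid | $\pi abc/12$ |

Volumes are converted to litres ($1\,\mu\mathrm{m}^3 = 10^{-15}$ l).
Every formula is validated in the test suite against numerical
integration of elliptical cross-sections to within 0.5%.

Two morphologies hide their third dimension in plan view, and two
height rules reconstruct it:

* **fixed height** — a previously determined species mean height
  (default 133 µm for *Bolivina spissa*);
* **diameter ratio** — the mean ratio of the shortest visible diameter
  to the height (default 0.424 for *Cibicidoides wuellerstorfi*), so
  height = shortest diameter / 0.424.

The species→shape map in `foram_shape_defaults()` is an editable
configuration table. The two height rules above are well constrained;
the shape assignments for the remaining species are working defaults
that users should override with their own morphometric judgement.
Unknown species deliberately raise an error rather than falling back to
a silent default.

The cell (cytoplasm) volume is taken as a fixed fraction of the
external test volume, default 0.75: the internal test volume is assumed
completely filled with cytoplasm. Reported mean cell volumes are
treated as *internal* volumes, i.e. the 75% factor is already included;
`intracellular_concentration()` therefore divides contents by the mean
cell volume directly.

## Per-individual content and intracellular concentration

Pooled samples of 1–75 living specimens are extracted by repeated
freeze–thaw cycles into 3 ml of reverse-osmosis water and the extract
measured by segmented flow-injection analysis. The conversion chain is

$$\text{content} \;(\mathrm{pmol\,ind^{-1}}) =
  \frac{c \,(\mathrm{\mu mol\,l^{-1}}) \times V \,(\mathrm{l}) \times 10^6}{n},
\qquad
  c_{cell} \;(\mathrm{mM}) = \frac{\text{content} \times 10^{-9}}{V_{cell}\,(\mathrm{l})}.$$

Three numerical policies matter here:

* **Blank correction is off by default.** Procedural blanks in this
  workflow are run for the nitrate channel; phosphate correction is an
  explicit opt-in (`blank_correct(..., correct = TRUE)`), subtracting
  the blank mean and flooring at zero.
* **Detection limit (0.004 µmol l⁻¹) flags, never censors.** Values
  below it are retained with a `below_detection` flag; zeroing them
  would bias small species' contents low.
* **Species summaries are means of per-sample values** (mean of
  ratios), not pooled-content over pooled-volume. The two differ
  whenever cell volumes vary between samples; single-sample species are
  plain ratios and carry no standard deviation.

## Assemblage stocks, imputation and budgets

The areal DIP stock of a station's living assemblage is

$$\textstyle\sum \mathrm{DIP}_{sed} \;(\mathrm{mmol\,m^{-2}})
  = \sum_n A_n \times \text{phosphate}_n \times 10^{-9},$$

with $A_n$ the living abundance of species $n$ in ind m⁻² and
phosphate$_n$ its mean content in pmol ind⁻¹; mass stocks use the
molar mass of phosphate, configurable with default 95 g mol⁻¹.
Abundance dialects (`ind_cm2`, `ind_10cm3` per layer) are converted to
ind m⁻² explicitly, with a logged message.

Content resolution follows a three-step rule implemented in
`lookup_content()`:

1. an exact species match uses the library value (multiple regional
   entries for one species are averaged first);
2. otherwise the mean over measured congeners is imputed (genus = first
   whitespace-delimited token; a synonym table can be applied upstream);
3. otherwise the species is **excluded** and contributes zero.

*Ammonia veneta* is excluded by default because its measurements come
from laboratory culture only. Excluded species are not silently
dropped: each station reports the fraction of living abundance they
carry (`excluded_abundance_share`), which bounds the unaccounted stock
from below — exclusion can only underestimate the true stock.

Regional summaries default to the equal-weight arithmetic mean with
s.e. $= sd/\sqrt{n}$; user-supplied weights (e.g. area of influence)
switch to the weighted mean and its weighted s.e. analogue. The
equal-weight default was a genuine design choice: survey-specific
weighting schemes are dataset-dependent and cannot be encoded as a
package default.

Budgets scale the mean areal stock to a regional total
($\mathrm{t} = \mathrm{g\,m^{-2}} \times \mathrm{m^2} \times 10^{-6}$)
and express it as **buffer days** of riverine phosphorus runoff,
$\text{days} = \text{total}/\text{runoff} \times 365$. The
single-species areal extrapolation
(`areal_extrapolation()`) converts a volumetric bloom density over a
sediment layer to ind m⁻² (×10⁴ per cm² per cm of depth) before the
same mass conversion.

## EDS elemental maps

Cryo-SEM EDS count maps of low-abundance elements are dominated by
position-dependent bremsstrahlung background. Under the assumption that
the *spectral shape* of the background is the same at every pixel, the
background under an element's characteristic peak is proportional to
the background outside all peaks, estimated per pixel as CPS minus the
summed element counts. The intensity-to-noise ratio

$$R(m,n) = \frac{I_i(m,n)}{\mathrm{CPS}(m,n) - \sum_i I_i(m,n)}
  = \frac{S_i(m,n)}{B_i(m,n)} + 1$$

is flat where an element only tracks the background and rises where
genuine signal is present. Numerical policies:

* the denominator sums **all** mapped elements by default; an
  `exclude_target` flag implements the alternative reading in which the
  target's own counts stay in the denominator;
* pixels with denominator < ε (default 1 count) are masked, as are
  pixels where summed counts exceed CPS (physically inconsistent;
  masked, never clipped);
* the per-pixel background under the element's own peak is *not*
  separately estimated — $R$ as computed is the observable proxy, and
  the phantom generator encodes exactly this bookkeeping.

One-pixel median filtering (`median_filter()`, radius 1, window clipped
at borders, masked pixels excluded from the window) removes single-pixel
count noise before interpretation. A 16-colour look-up table
(`lut_quantize()`) bins the valid range linearly for display without
modifying grey values; bin edges can be fixed absolutely for cross-map
comparability. Registration against the calcium map of the calcitic
test uses a least-squares similarity transform (scale, rotation,
translation — 4 degrees of freedom, no shear or warping), solved in
closed form via complex linear regression and cross-checked in the
tests against an SVD-based Procrustes solution; resampling uses inverse
mapping with bilinear interpolation, with row 0 the top of the image
and x = columns.

When summarizing $R$ over a region (e.g. inside enrichment discs), the
package's tests use the denominator-weighted mean of pixel ratios —
equivalently, summed counts over summed background. A plain mean of
per-pixel ratios carries an $O(1/\text{counts})$ Jensen bias from the
Poisson denominator; aggregating counts before the ratio removes it.

## The synthetic generators

Each generator returns observables **and** its latent truth, so every
pipeline stage has an exact or statistical recovery test:

* `gen_specimens()` draws axes from lognormal distributions and stores
  the exact volume implied by the assigned shape — recovery is exact by
  construction.
* `gen_extractions()` applies multiplicative Gaussian noise (default
  sd = 5%) to exact pooled concentrations; multiplicative noise is the
  natural model for small positive autoanalyser signals. Noiseless sets
  invert exactly.
* `gen_assemblage()` draws station-by-species abundances from
  lognormal distributions (the ecological convention), over a pool
  mixing measured species, unmeasured congeners (true content set to
  the genus mean, matching the imputation model) and species with no
  measured congener. Defaults — 135 stations, sdlog 0.5, median
  abundances of order 10³–10⁴ ind m⁻² per species — are scaled to a
  dense, productive shelf survey with regional mean stocks of a few
  mg m⁻². Both the realized truth (exact) and the distributional
  expectation $\sum_s e^{\mu_s + \sigma^2/2}\,\text{content}_s \times
  95 \times 10^{-12}$ are stored.
* `gen_eds_phantom()` builds a smooth positive background field with
  fixed per-channel weights, disc enrichments of the target element
  with a specified signal contrast, and CPS bookkeeping consistent with
  the ratio transform (the background under the target's peak equals
  the outside-peak background by construction, so analytic
  $R = S/B + 1$ exactly). Counts are Poisson-sampled — the physics of
  X-ray counting.

Seeding: one master seed with per-generator derived streams, so
modules regenerate independently; generators restore the caller's RNG
state. Identical seeds give identical outputs.

What the generators do **not** emulate: spatial autocorrelation between
stations, species co-occurrence structure, autoanalyser drift or
carry-over, detector artefacts (escape peaks, pulse pile-up), and
topographic or depth-dependent EDS backgrounds that violate the
fixed-spectral-shape assumption. Passing recovery tests therefore
demonstrates correctness of the arithmetic chain under the stated
statistical models, not robustness to every feature of field data.

## Problem sizes and tolerances in the shipped tests

The suite validates shapes on 20 random axis sets per solid (0.5%
tolerance against numerical integration), extraction recovery on 1,000
seeded replicates (2 s.e. band, known s.e.), assemblage recovery on 200
seeded surveys of 135 stations (within 2 s.e. of the expected mean at
the nominal ~95% rate), and EDS contrast recovery on 50 Poisson
phantoms of 48×48 px (sign test for unbiasedness plus a 5% accuracy
band). These sizes keep the whole suite under a minute on one core
while leaving Monte-Carlo noise well below the tested tolerances.

## Known limitations

* Shape assignments beyond the two height-rule species are
  placeholders; biovolume accuracy is limited by the user's shape
  table.
* Genus-mean imputation assumes congeners share storage physiology;
  the `excluded_abundance_share` diagnostic bounds, but does not
  correct, the contribution of fully unmeasured taxa.
* Regional budgets assume the station set is representative of the
  region (no geostatistical interpolation is attempted) and the runoff
  figure matches the region's boundaries.
* The EDS transform is a background *suppression*, not quantification:
  no ZAF correction, peak fitting or spectral deconvolution is
  performed, and $R$ is comparable across maps only with a fixed LUT
  range.
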