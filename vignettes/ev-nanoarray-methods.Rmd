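---
title: "Methods: EV morphometry on AFM tethering nanoarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EV morphometry on AFM tethering nanoarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evnanoarray)
```

## The measurement model

A tethering nanoarray chip carries a square lattice of PEG-lipid brush
nanospots (~200 nm diameter, brush height 2–3 nm) on a flat substrate.
Extracellular vesicles (EVs) exposed to the chip in a flow cell anchor to
the brushes through hydrophobic interaction, ideally one vesicle per spot,
and are imaged by tapping-mode AFM as a height map $z(x, y)$ in nm.

An adsorbed vesicle flattens into (approximately) an oblate half-dome. Its
morphometry is summarised by three quantities:

* the **footprint diameter** $d$, the mean of the major and minor axis
  lengths of the footprint's equivalent ellipse;
* the **apex height** $h$ above the local supporting surface;
* the **aspect ratio** $\mathrm{AR} = h/d$, the deformability indicator —
  a stiff sphere would give $\mathrm{AR} = 1$, a strongly spread membrane a
  small AR.

Assuming the vesicle deforms without changing volume, a sphere of diameter
$D$ in suspension and the adsorbed oblate ellipsoid with axes $d, d, h$
enclose the same volume:

$$\frac{\pi}{6} D^3 = \frac{\pi}{6} d^2 h
  \quad\Longrightarrow\quad D = (d^2 h)^{1/3}.$$

Two consequences drive the analysis. First, the suspension diameter of
every measured vesicle can be estimated from its adsorbed geometry
(`estimate_suspension_diameter()`). Second, for vesicles of a common
suspension diameter $D_0$,
$\mathrm{AR} = h/d = D_0^3\, d^{-3}$, so an AR-versus-$d$ scatter should
follow a $d^{-3}$ power law whose coefficient is $D_0^3$. The package fits
$\mathrm{AR} = c\, d^{-3}$ by ordinary least squares through the origin
(closed form $c = \sum x_i \mathrm{AR}_i / \sum x_i^2$ with $x = d^{-3}$);
a free-intercept variant is available behind `intercept = TRUE` for
sensitivity analysis only, since the law itself has no intercept.

Classification uses the morphological criteria of the assay: a particle is
an **EV** when its diameter and height strictly exceed 30 nm and 7 nm (the
height floor reflects a collapsed double bilayer, 2 × 3–4 nm, so anything
flatter cannot be a closed vesicle); small peripheral bumps with
$d < 20$ nm and $\mathrm{AR} \in [0.3, 0.6]$ are **lipoprotein-like**
(LDL co-purifies with EVs and survives density-gradient centrifugation);
everything else is **unclassified**. EV classification takes precedence;
the AR band is treated as inclusive at its printed endpoints and is
configurable. Only EV-class, non-border particles enter population
summaries, AR fits and tests.

Populations from different cell lines are compared by a **pooled
two-sample Student's t-test** on AR (two-sided,
$\mathrm{df} = n_a + n_b - 2$, $\alpha = 0.05$); the pooled rather than
Welch form is deliberate, matching the assay's stated procedure. Degenerate
zero-variance inputs resolve explicitly (equal means: $t = 0, p = 1$;
unequal: $p = 0$ with a warning).

The chip's size selectivity — only small vesicles tether even though the
suspension's size distribution is centred far higher — is captured by a
dimensionless toy model: laminar drag on a sphere grows as
$c_d\, v\, D^2$ while the brush adhesion supplies a constant resistance
$F$, so vesicles with $D > D^\* = \sqrt{F/(c_d v)}$ are swept away. Only
the scaling laws ($D^\* \propto v^{-1/2}$, $\propto F^{1/2}$) and the
truncation property are meaningful; the coefficients are arbitrary, with
defaults placing $D^\*$ at 40 nm, the upper end of the tethered-size
regime.

## Image preconditioning

AFM raw maps carry a tilted background plane and per-scan-row offsets.

* `plane_level()` fits a least-squares polynomial surface (order 1 by
  default, order 2 available) with an iterative background mask: after each
  fit, pixels more than 3 robust sigmas above the surface are excluded and
  the surface refitted (two passes). If the mask would leave under 10% of
  pixels, the fit falls back to all pixels with a warning.
* `line_level()` subtracts each row's median over background pixels
  (within 3 MAD of the global median), so rows crossing particles are not
  biased.
* `estimate_noise()` is a two-pass masked MAD ($\hat\sigma = 1.4826 \cdot
  \mathrm{MAD}$), robust to feature coverage of a few tens of percent.

Heights are referenced to the leveled substrate ($z = 0$ at bare
substrate). Particle heights, however, are measured from a **local annulus
baseline** (median height on a 2-pixel-wide ring around the footprint), so
a vesicle sitting on a brush spot is measured from the brush top and $h$
excludes the 2–3 nm brush — consistent with a membrane-only height floor of
7 nm. A `baseline = "substrate"` switch measures from the substrate plane
instead, for sensitivity checks.

## Detection and measurement

The detection operator is not prescribed by the assay, so the package uses
a conservative, testable construction:

1. **Local background.** Two complementary robust estimators are combined
   by pointwise maximum: grayscale opening with a flat disc (radius 60 nm —
   wider than any particle radius, narrower than a spot radius, so brush
   plateaus are background) applied to a lightly box-smoothed surface, and
   a local median filter (window ~1.25× the opening radius). Opening is
   exact on noise-free plateaus but undershoots a noisy one by the minimum
   statistics of its structuring element; the median has no noise
   undershoot but dips at curved plateau rims where the window majority
   lies outside — exactly where opening is reliable. Their maximum tracks
   the supporting surface in both regimes. The residual is re-centred by
   its median so background sits at zero.
2. **Seeds.** Local maxima of the twice box-smoothed residual with
   prominence of at least `seed_threshold_nm` — by default
   $\max(1.0, 3\hat\sigma)$ nm — de-duplicated greedily to a minimum
   separation of 15 nm (strongest first; ties resolved by scan order).
3. **Footprints.** Each seed's footprint is the connected region of the
   residual above `footprint_fraction` ($f = 0.1$) of the seed's apex
   prominence, within a bounded crop (`max_footprint_nm`). Straggling
   single-pixel noise chains are pruned (pixels need at least two
   4-neighbours, two passes). Pixels claimed by several seeds go to the
   nearest seed; footprints under `min_area_px = 4` pixels are dropped.
4. **Measurement.** The baseline is the annulus median (above); $h$ is the
   region maximum minus baseline. Axis lengths come from the footprint
   mask's second central moments ($4\sqrt{\lambda}$ with a $px^2/12$
   within-pixel term), corrected by $1/\sqrt{1 - f^2}$ because a contour at
   fractional height $f$ of an ellipsoidal dome underestimates the true
   axes by exactly $\sqrt{1 - f^2}$ (~0.5% at $f = 0.1$). $d$ is the mean
   of the corrected axes. Footprints whose annulus would leave the image
   are flagged `border_flag` and excluded from population statistics.

No tip deconvolution is applied in measurement; tip broadening exists only
as a generator option (below), mirroring an analysis that performs none.

Spot assignment is nearest-centre within spot radius + `spot_margin_nm`
(50 nm); a spot is occupied when at least one EV-class particle is assigned
to it, and occupancy is occupied/total.

## The synthetic scene generator

Because the assay's raw scans are not available, the generator is the
package's test bed. It emulates:

* a square lattice of brush spots (default pitch 1414 nm — the value that
  reproduces the chip's printed areal density of $5.0 \times 10^5$
  spots/mm², see below — diameter 200 nm, per-spot brush height uniform in
  2–3 nm);
* one EV per occupied spot, centred on the spot (individual
  immobilization; a multi-occupancy option nudges extra vesicles to the
  spot edge for robustness tests), with $(D, \mathrm{AR})$ drawn from
  configurable distributions — defaults $D \sim N(27.7, 4.7)$ nm and
  $\mathrm{AR} \sim N(0.20, 0.04)$ truncated to $(0, 1]$, the tethered-EV
  regime — and the adsorbed dome $z(r) = h\sqrt{1 - (2r/d)^2}$ derived by
  volume conservation;
* lipoprotein-like bumps ($d$ uniform 10–18 nm, AR uniform 0.3–0.6) placed
  uniformly on an annulus at spot radius ± 20 nm, i.e. at spot peripheries
  (their exact placement in the real assay is unspecified; a Poisson count
  per spot, default rate 0.3, is an assumption);
* scan artifacts: plane tilt, per-row Gaussian offsets, per-pixel Gaussian
  noise (default $\sigma = 0.3$ nm), and optional tip broadening as
  grayscale dilation with a spherical-cap structuring element of the tip
  radius. Dilation is applied to the physical surface before the scan
  artifacts are added, since tilt and row offsets are scanner effects, not
  topography a tip dilates.

Surfaces combine by maximum; a dome on a spot rides on the brush, so its
physical apex is brush + $h$ and the annulus baseline convention recovers
$h$. Every stochastic stage draws from a sub-seed derived by hashing a
stage label into the master seed, so truth tables and pre-noise fields are
bit-reproducible and adding draws to one stage never perturbs another.

What the generator does **not** emulate — and hence what green tests do not
demonstrate about real data: non-ellipsoidal or ruptured vesicles, membrane
fluctuation noise, probe-sample adhesion artifacts and imaging-force
dependence of apparent height, piezo creep/drift nonlinearities beyond a
plane, double tips, and spatially correlated instrument noise. Recovery
tolerances established on synthetic scenes are lower bounds on real-world
error.

### The printed-geometry inconsistency

The chip's printed geometry is internally inconsistent: a 200 nm pitch
cannot coexist with $5.0 \times 10^5$ spots/mm² (that density implies a
~1414 nm centre-to-centre pitch, and a companion figure shows a 1200 nm
pitch). The package treats pitch as a free, centre-to-centre parameter with
default 1414 nm, because the areal density — not the pitch — is what the
downstream claims (a million spots per chip, $>10^5$ concurrently tethered
EVs at 20% occupancy) rely on.

## Numerical choices and degenerate inputs

* Strict threshold inequalities for EV classification ("exceeded"), an
  inclusive LDL AR band; growing $d$ and $h$ can therefore never demote an
  EV.
* The AR fit is through the origin; `rms_residual` is reported, and with a
  heterogeneous-$D$ population it reflects real spread in $D^3$, not
  misfit.
* ASCII height maps serialise at 9 significant digits ('#'-header dialect
  with mandatory `pixel_size_nm` and `units: nm`); float TIFF stores
  min–max-normalised 32-bit samples with the affine transform in a JSON
  sidecar, because common float-TIFF writers clamp samples outside
  $[0, 1]$. Both round-trip within format precision.
* Reports round floats to 4 significant digits with stable key order, so
  regenerating a report from the same inputs is byte-identical; absent
  sections are explicit JSON `null`s.
* Empty inputs: zero detections yield an empty particle table (not an
  error); an empty population or a zero-spot layout is an error; rejection
  sampling against impossible truncation bounds aborts after a bounded
  number of retries.
* A constant map has noise 0; a map smaller than the polynomial basis
  cannot be leveled and errors.

## Problem sizes

The test suite validates morphometry on rendered benchmark scenes of 100
vesicles per scene (footprints 35–85 nm, AR 0.15–0.30, 5 nm pixels,
$\sigma = 0.3$ nm — 600² to 840² pixel maps), two scenes for the
200-vesicle recovery property, and cell-line comparison scenes of ~150
vesicles per line; these sizes give stable population statistics while
keeping the default suite around a minute of CPU. Morphometric tolerances
follow the recovery contract: per-particle footprint error within 2 pixels,
noise-free apex within 0.1 nm, population means of $d$, $h$, $D$ within 5%
at $\sigma = 0.3$ nm.

## Known limitations

* The detection contour at 10% of apex prominence is appropriate for
  dome-like particles well above the noise floor; features with $h$ within
  a few $\sigma$ of the threshold have noise-limited footprints.
* Lipoprotein-sized bumps (10–18 nm) are under-resolved at the default
  5 nm pixel size (the renderer warns); resolving them requires ~2 nm
  pixels.
* The capture model is deliberately dimensionless; it supports scaling
  arguments, not force calibration.
* Per-spot brush height varies between spots but not within a spot, and
  vesicles are centred on spots by default; off-centre tethering only
  enters through the multi-occupancy option.
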