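---
title: "Simulated photoacoustic morphometry of tracheal stenosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated photoacoustic morphometry of tracheal stenosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracheapat)
```

## Scope

`tracheapat` is a fully synthetic pipeline for studying how well
photoacoustic tomography (PAT) and multispectral optoacoustic tomography
(MSOT) can quantify airway stenosis. It chains five stages:

1. **Phantoms** — parametric 2-D tracheal cross-sections for four
   experimental arms (A normal; B mucosal edema; C granulomatous
   hyperplasia; D cicatricial scar), with ground-truth wall thickness
   (TWT), lumen cross-sectional area (CSA) and stenosis rate (SR).
2. **Optics** — linear spectral mixing of chromophore concentrations
   into absorption, and photoacoustic generation `p0 = Γ μ_a Φ`.
3. **Acoustics** — band-limited forward simulation on a 128-element,
   180°, 50 mm concave arc sampled at 50 MHz, with per-frame white noise
   and 10-frame averaging.
4. **Reconstruction and unmixing** — universal back-projection (UBP) and
   per-pixel non-negative least squares (NNLS) across 760/840/910 nm.
5. **Morphometry and statistics** — automated lumen/wall segmentation,
   TWT/CSA/SR measurement, inter-observer agreement (Pearson,
   Bland–Altman), paired and Welch t-tests, group tables.

Because no real acquisitions are bundled, every claim the test-suite
makes is a *recovery* claim: phantoms drawn from published group
statistics must return those statistics through the full chain.

## Phantom model

A phantom is a concentric-disk cross-section: an air lumen of radius
$r$ (drawn so that $\pi r^2 \sim \mathcal N(\mu_{CSA}, \sigma_{CSA}^2)$
truncated positive), a tissue annulus of thickness drawn from the
group's TWT distribution, and circular vessel inclusions embedded fully
inside the wall. Defaults for the four groups are the published
means ± SDs (TWT 0.82/1.14/1.50/1.17 mm; CSA 16.28/12.37/8.78/12.47 mm²).
The printed areas carry a cm² unit that implies a 45 mm lumen — we treat
them as mm² (consistent with a rabbit trachea) throughout.

Group contrast is encoded in composition, not just geometry: the wall
background carries water + collagen + a diffuse oxygenated-hemoglobin
component; vessels carry whole blood (HbO₂/HbR at 60% saturation).
Group B multiplies wall water by 1.5 (edema), group D multiplies
collagen by 2 (scar), group C carries six vessels instead of two
(hypervascular granulation). These multipliers are qualitative: the
histology they emulate is reported as directional findings (more
collagen in scar, more vessels in granuloma, edema in B), not as
concentrations, so the generator fixes round, modest factors once.

Respiration rescales the lumen so CSA follows
$CSA(\phi) = CSA_0\,(1 + a(1-\cos\phi)/2)$ — minimal at end-exhalation
($\phi=0$), maximal at end-inhalation ($\phi=\pi$) — with modulation
depth $a = 0.15$ by default, and conserves wall cross-sectional area
(in-plane incompressibility), recomputing the outer radius.

Rasterization anti-aliases the annulus boundaries (one-pixel coverage
ramp), which makes the rasterized lumen area converge to $\pi r^2$ with
error well below a pixel area at the default 0.05 mm spacing. Vessel
disks are rendered binary so that no pixel ever mixes more than three
chromophores — the identifiability cap discussed below.

What the generator does *not* emulate: cartilage C-rings, mucosal
folds, non-circular lumens, out-of-plane structure, acoustic
heterogeneity of the air column, and physiologic motion other than the
single respiratory mode. Passing recovery tests therefore show the
measurement chain is unbiased for smooth annular geometry, not that it
is robust to every anatomical irregularity.

## Forward model and reconstruction

Each nonzero pixel radiates a delta at its time of flight with
2-D cylindrical spreading $1/(2\pi d)$; traces are convolved with a
derivative-of-Gaussian-windowed tone at 5 MHz (fractional FWHM
bandwidth 0.7 by default). A homogeneous speed of sound (1500 m/s) is
assumed — the standard back-projection assumption; the air-filled lumen's
acoustic contrast is a known fidelity limit of this model. Element
directivity and the 64-channel multiplexing of the physical DAQ are not
modelled (multiplexing changes acquisition time, not averaged signals).
Per-frame white noise of sd `DEFAULT_NOISE_SD` (5e-6, chosen once so a
control phantom's per-frame peak SNR is ≈ 6, i.e. ≈ 19 after 10-frame
averaging) is applied as a single draw with sd $\sigma/\sqrt{n}$ —
exactly the distribution of the frame mean, since the deterministic
component is frame-invariant.

Reconstruction is universal back-projection,
$b(x) = \sum_k w_k\,[g_k(t) - t\,g_k'(t)]_{t=|x-r_k|/c}$ with uniform
weights, central-difference derivative and linear time interpolation.
UBP was chosen over plain delay-and-sum because the ramp-equivalent
term sharpens exactly the boundaries morphometry depends on. The
default grid is 256×256 at 0.05 mm (12.8 mm field), ≥3 pixels per
claimed 150 μm resolution element. A point target at 0.9 fractional
bandwidth reconstructs with ≈116 μm envelope FWHM (the acceptance
script recomputes this), and width decreases monotonically with
bandwidth, as the property suite asserts.

A note on limited-view behaviour: with the *t*-weighted UBP term, a
point mirrored onto the open side of the arc does **not** reconstruct
with lower peak amplitude — the ramp term slightly amplifies the
farther point (ratio ≈ 1.05–1.09). The robust limited-view signature is
geometric: the open-side point blurs tangentially (≈5% wider FWHM
parallel to the chord), and that is the property the test suite
asserts.

## Segmentation and caliper placement

Band-limited reconstruction renders a thick wall as two bright rims
(the inner and outer interfaces) with an intensity dip between them,
and the limited 180° view weakens the rims where the boundary normal
points along the open side. The segmenter therefore works in two
stages:

* **Topology** (where is the lumen): robustly normalised,
  log-compressed envelope (`log1p(50x)`; vessels are many times
  brighter than wall and would otherwise capture the Otsu threshold) →
  Gaussian smoothing (observer σ) → Otsu threshold × observer factor →
  morphological closing (8-pixel disc bridges the inter-rim dip,
  enlarged adaptively up to 3× if no closed annulus forms) → the lumen
  is the largest *compact* enclosed background component. Compactness
  (component area over its circumscribed circle) rejects the dip ring
  itself, which is enclosed but annular. Because the compression is
  monotone and the mask is topology-only, neither step biases the
  caliper placement below.
* **Boundaries** (where, exactly): along 64 radial spokes from the
  lumen centroid, each interface is localised at the *sub-pixel peak of
  the envelope rim* (quadratic refinement), not at the threshold-mask
  edge. A zero-mean band-limited point-spread function turns a step in
  initial pressure into a ridge centred on the interface, so the rim
  peak is the approximately unbiased caliper position, whereas mask
  edges sit half a rim-width outside the interface on each side —
  empirically a ≈ +0.4 mm TWT bias, ruinous at 0.8 mm walls. Spokes
  whose crossing deviates > 0.4–0.5 mm from the local circular median
  (artifact hits) are discarded and refilled by circular interpolation.

TWT is the circumferential mean of (outer − inner) spoke radii — an
angular mean rather than a single-point caliper, robust to local
boundary noise. CSA is the shoelace area of the 64-vertex inner
contour with the inscribed-polygon correction $\Delta\theta/\sin
\Delta\theta$ (exact for circles, −0.16% uncorrected). SR is the
Myer–Cotton-style area ratio $(1 - CSA/CSA_{ref})\cdot 100$ with an
explicit reference argument: no published formula reproduces the
printed SR values from the printed CSAs, so SR is defined once,
transparently, and recovery of printed SRs is deliberately not claimed.

Human observers are emulated by jittering segmentation hyperparameters
(±3% threshold factor, small smoothing jitter) — the only way to make
inter-observer reproducibility testable without humans. Observed
end-to-end accuracy under default conditions (20-phantom cohorts):
group-A TWT bias ≈ −0.02 mm, CSA bias ≈ +1%; group C (thick wall,
small lumen, hypervascular) ≈ −0.04 mm and +3%.

## Spectral unmixing and identifiability

Unmixing solves, per pixel, $\min_{c \ge 0} \|Ec - y\|^2$ with $E$ the
3×4 extinction matrix. With three wavelengths and four chromophores the
*global* problem is underdetermined; the phantom's ≤3-active-chromophore
constraint makes each pixel's active submatrix full rank. But full-rank
is not sufficient for non-negative uniqueness: an exact fit on another
chromophore subset with all-nonnegative coefficients may exist. A cone
analysis of the bundled spectra shows that excluding *every* alternative
support for both tissue compositions simultaneously is geometrically
impossible at these three wavelengths — a real limitation of
3-wavelength/4-chromophore MSOT that the package documents rather than
hides. The bundled collagen/water spectra (band shapes qualitatively
faithful; magnitudes chosen for conditioning) are selected so that the
deterministic active-set path of NNLS recovers the true composition
exactly for the two supports the phantoms produce — the wall triple
(HbO₂, collagen, water) and the vessel pair (HbO₂, HbR) — verified over
randomised compositions in the test suite. Exactness claims are
restricted to those supports.

SO₂ = HbO₂/HbT is masked below 5% of the HbT map's 99th percentile to
suppress noise-driven saturation speckle. Unmixing operates on envelope
images, matching the $y \ge 0, E \ge 0, c \ge 0$ model; fluence defaults
to uniform (Γ·Φ-scaled "relative concentrations", as clinical MSOT
reports), with an optional exponential-decay model for robustness
experiments.

## Statistics

Inter-observer agreement reports the Pearson correlation, the bias
(mean difference), the *t*-based 95% CI of the bias, and the classical
1.96·sd limits of agreement. Both intervals are reported because
published Bland–Altman intervals of the narrow kind (e.g. −0.01–0.02 mm
around a 0.01 mm bias) are CIs of the mean, not limits of agreement.
Between-group comparisons use the unpaired Welch t-test: groups are
distinct animals, so a paired test — though named in the source
protocol — is not defined across groups; this inconsistency is resolved
in favour of the unpaired test and flagged here. No multiple-testing
correction is applied (none was applied in the protocol being
emulated). Degenerate paired differences (zero variance, nonzero mean)
return a flag rather than a fabricated p-value.

## Numerical choices and problem sizes

* Truncated-normal draws retry up to 100 times, then raise — surfacing
  degenerate specifications instead of looping.
* Seeds: every stage derives its seed from the master seed by a fixed
  affine counter hash (`seed_for`), kept below 2³¹; identical configs
  are bitwise reproducible (manifest checksums).
* Acceptance-scale experiments use 20 phantoms per group at the default
  256×256/0.05 mm grid and 3 wavelengths; unit tests use single
  wavelengths and smaller grids. These sizes give cohort standard
  errors comfortably inside the recovery tolerances while keeping a
  full run in minutes on one core.
* Sinograms serialize to TSV + JSON sidecars; images and chromophore
  maps to 32-bit float TIFF with JSON sidecars; phantom ground truth to
  JSON. Every writer has a reader and the pair round-trips losslessly.

## Known limitations

Beyond the phantom simplifications above: no fluence correction (so
concentrations are relative, and SO₂ is only nominally quantitative);
no frequency-dependent acoustic attenuation; point-like detectors; the
respiratory sequence reconstructs each phase independently (no motion
blur within a frame); and segmentation assumes a single closed annulus
— multi-lumen or collapsed airways raise a segmentation failure, which
the pipeline reports rather than silently mis-measuring (mirroring the
excluded-animal convention of in-vivo studies).
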