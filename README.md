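# tracheapat

Synthetic photoacoustic evaluation of tracheal stenosis, end to end.

Acquired airway stenosis is graded by three quantities: tracheal wall
thickness (TWT, mm), lumen cross-sectional area (CSA, mm²) and stenosis
rate (SR, % luminal narrowing against a reference cross-section).
Photoacoustic tomography (PAT) can measure all three non-invasively,
and multispectral acquisition (MSOT) adds tissue composition — oxy- and
deoxyhemoglobin (HbO₂/HbR), total hemoglobin, SO₂, collagen and water —
which distinguishes stenosis etiologies (edema vs. granulation vs.
scar). `tracheapat` is for researchers who want to study that
measurement chain quantitatively without animals: it generates digital
trachea phantoms with known ground truth, simulates the physics and the
measurement, and asks whether the numbers come back.

The pipeline:

* **Phantoms** — concentric-disk tracheal cross-sections for four
  groups (A normal, B mucosal edema, C granulomatous hyperplasia,
  D cicatricial scar), drawn from the groups' published morphometry
  distributions, with vessel inclusions, group chromophore signatures
  and a respiratory mode `CSA(φ) = CSA₀(1 + a(1−cos φ)/2)`.
* **Forward model** — initial pressure `p₀ = Γ μₐ Φ` with
  `μₐ(λ) = Σᵢ εᵢ(λ) cᵢ`; band-limited signals on a 128-element, 180°,
  50 mm concave arc (5 MHz centre frequency, 50 MHz sampling), white
  noise, 10-frame averaging.
* **Reconstruction** — universal back-projection
  `b(x) = Σₖ wₖ [g(t) − t g′(t)]` at `t = |x − rₖ|/c`; point-target
  envelope FWHM ≈ 116 μm at 0.9 fractional bandwidth.
* **Unmixing** — per-pixel non-negative least squares of the
  760/840/910 nm envelope stack; SO₂ = HbO₂/HbT with noise masking.
* **Morphometry** — Otsu + morphological topology, boundary calipers at
  the sub-pixel envelope rim peaks along 64 radial spokes; TWT, CSA and
  Myer–Cotton-style SR.
* **Statistics** — Pearson correlation and Bland–Altman agreement
  between jittered "observers", paired and Welch t-tests, group tables
  with star annotations.

## Worked example

```r
library(tracheapat)

spec <- default_group_specs()$A          # normal control group
ph <- make_phantom(spec, seed = 42)
ph
#> Trachea phantom, group A: lumen r = 2.308 mm, TWT = 0.809 mm,
#>   CSA = 16.73 mm^2, SR = -2.8%, 2 vessel(s)

# full chain: rasterize -> 3-wavelength acquisition -> UBP -> segment
res <- pipeline_morphometry(ph, seed = 42, observers = default_observers())
res$obs_a
#> Morphometry [obs_a]: TWT = 0.804 mm, CSA = 16.69 mm^2, SR = -2.5%
res$obs_b
#> Morphometry [obs_b]: TWT = 0.797 mm, CSA = 16.73 mm^2, SR = -2.8%
```

The measured wall thickness (0.804 mm) and lumen area (16.69 mm²) sit
within 5 μm and 0.3% of this phantom's ground truth (0.809 mm,
16.73 mm²); the two "observers" — the same segmenter with ±3% threshold
jitter — disagree by a few microns, which is what the agreement
statistics quantify on cohorts:

```r
bland_altman(c(0.1, -0.1, 0.2, 0), c(0, 0, 0, 0))
#> Agreement (n = 4): r = NA
#>   bias 0.05  95% CI [-0.1554, 0.2554]
#>   95% limits of agreement [-0.203, 0.303]
```

A whole experiment — cohorts for all four groups, envelopes, per-image
morphometry for every observer, group statistics, agreement, and a
checksummed manifest — is one call:

```r
cfg <- experiment_config(n = 5, master_seed = 7, out_dir = "run1")
run_experiment(cfg)
```

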