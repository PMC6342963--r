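---
title: "The leaf-contrast optical model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The leaf-contrast optical model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`leafcontrast` asks a question from visual ecology: which photoreceptor
channel best resolves the contrast between the upper and lower surfaces of
leaves in vegetated habitats, and how does that depend on habitat
structure? This vignette is the package's own account of the model it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The modelled scene

An observer with a horizontal gaze looks at two identical leaves side by
side: one tilted toward the observer (its upper surface is visible) and
one tilted away (its lower surface is visible). The tilt angle from the
zenith, `theta_l`, is the same for both and is drawn from 70–90° —
near-vertical leaves are the ones whose surfaces an animal sees side-on.
All other reflective surfaces (overlying canopy, understory, litter) are
treated as horizontal extended surfaces.

Each surface radiates two components:

* **Diffuse (Lambertian)**: downwelling irradiance times surface
  reflectance over π for the upper surface (`L_u_d = I_down R_u / π`);
  for the visible lower surface, transmitted light
  (`L_t = I_down T / π`, with the away-leaf's own direct-sun term) plus
  upwelling light reflected off the underside
  (`L_l_d = I_up R_l / π`).
* **Specular**: a mirror-like reflection of one extended scene element
  off the waxy cuticle, `L = 0.5 (R_s + R_p) L_source`, with `R_s`, `R_p`
  the polarized Fresnel components at incidence angle `theta_l`
  (a consequence of the horizontal-gaze geometry) and a roughness
  correction `K` (default 1; measured leaf values span 0.6–3.5). The
  mirrored source above is sky, cloud deck or overlying canopy; below it
  is litter or understory leaves. An extended source's radiance is its
  irradiance contribution divided by the solid-angle fraction it occupies
  times π, which reduces to `I_b/π` (sky), `I_c/π` (cloud) and
  `I_t/(p_l π)` (canopy). The below-source radiance is the downwelling
  light at ground level times the mirrored surface's reflectance over π:
  the litter reflectance `R_g` when litter is mirrored, and the
  upper-leaf reflectance `R_u` when understory leaves are, since what is
  mirrored is light diffusely reflected off leaves.

Downwelling irradiance is a bookkeeping sum over sky, cloud, direct sun
and canopy-filtered terms weighted by the occlusion fractions (`p_c`
clouds, `p_l` canopy, `p_s` solar-disc occlusion), with the direct-sun
term computed per leaf from the rotation-product geometry; a sun behind a
leaf (`theta_s ≥ 90°`) simply misses it, independently for the two
leaves. Overcast irradiance comes from a spectral cloud index
`cl(λ) = A(CL) λ + B(CL)` with `A = 0.00150 CL (1 − CL)` and
`B = 0.966 CL² + 0.0619 CL − 0.0389` at a total cloud index `CL = 0.8`
(typical overcast). Two numerical choices here: `cl` is clamped at zero
(for small `CL` the offset `B` is negative, and a negative irradiance
multiplier is unphysical — irrelevant at `CL = 0.8`), and the overcast
spectrum is recomputed inside every model iteration from that iteration's
solar zenith angle, because the clear-sky-plus-sun term it scales
(`I_cs = I_b + I_s cos θ_z`) depends on it explicitly.

## Receptors and contrast metrics

Cone spectral sensitivities are assembled from a vitamin-A1 visual
pigment template (alpha plus beta band, peak-normalized), an oil-droplet
cut-off template and a sigmoidal ocular-media cut-on. The droplet
template is a Gompertz curve parameterized by its 50%-transmittance
wavelength `lambda_mid` and the slope `B_mid` at that point (default
0.04 nm⁻¹, inside the measured 0.02–0.12 range); the published
per-droplet slope regressions are not reproduced here, so `B_mid` is
explicit configuration. The default peak positions (U 371, V 405,
S(U) 445, S(V) 470, M 505, L 565 nm; media cut-ons 320 nm for U-type and
350 nm for V-type eyes, with M/L using the mean of the two) are
representative of UVS- and VS-type terrestrially foraging birds. They are
configuration, not measurements: species means belong in an editable
parameter table (`inst/extdata/avian_cones.tsv`), and the shipped values
are defaults chosen from the typical peak positions reported for these
cone classes.

Per-channel achromatic contrast is signed Michelson contrast of the
quantum catches, `C_i = (Q_u − Q_l)/(Q_u + Q_l)`; the headline statistic
is `R = C_V − C_U`, positive when the violet-peaking UV-cone variant sees
more contrast than the ultraviolet-peaking one. Chromatic distances use
the receptor-noise-limited model with natural-log-transformed catches;
one generic expression covers any number of channels and reduces to the
standard di-/tri-/tetrachromat closed forms (cross-checked in the tests).
Channel noise (Weber fractions) follows `ω_i = ν/√η_i` with the L cone
anchored at 0.069 under abundances L:M:S:UV = 3:2.5:1.7:1, giving
0.12 / 0.092 / 0.076 / 0.069 — the M value is usually quoted as 0.075,
which the exact calibration matches to within one unit of the last
digit. Comparisons across hypothetical receptor compositions use
equal noise (all 0.069). The paired sign test uses the exact two-sided
binomial convention `p = min(1, 2 min(P(X ≤ s), P(X ≥ s)))` with ties
dropped — the common convention, verified here against exhaustive
enumeration of sign patterns.

## The Monte-Carlo driver

`run_model()` repeats the radiometry 10,000 times by default, randomizing
twelve parameters per iteration: `theta_z ~ U[0°, 90°)` (the full daytime
range), `theta_l ~ U[70°, 90°]`,
`gamma_s ~ U[0°, 360°)`, the four occlusion fractions uniform on [0, 1],
sun/shade `d` a fair coin sampled independently of `p_l` (independence is
the neutral choice; any coupling can be imposed via overrides),
the upper specular source categorical with probabilities
`(p_l, (1−p_l)p_c, (1−p_l)(1−p_c))` over canopy/cloud/sky, the lower
source `(p_g, 1−p_g)` over litter/leaves, direct sun on the below-source
surface `d_r ~ Bernoulli((1−p_l) p_s)`, and a fair coin over the two leaf
types. Scenes are drawn vectorized up front under one seed, so a run is a
pure function of (seed, config, inputs) regardless of evaluation order.

Analyses of a run:

* `canopy_crossover()` bins records by canopy cover `p_l`
  (10-percentage-point bins, medians per bin — a deliberately simple
  estimator of the threshold) and returns the lowest
  bin boundary above which every higher bin has median `R > 0`. The
  boundary is therefore quantized to the bin width; a zero-crossing
  anywhere inside a bin reports that bin's upper edge.
* `summarize_by_source()` gives median and quartiles of `R` per upper
  specular source.
* `specular_ratio_trend()` links canopy cover, the UV-band (300–400 nm)
  specular:diffuse radiance ratio of the upper surface, and `R`. Both
  trends are computed among canopy-source records: pooled across sources
  the ratio reflects the source identity (sky specular light is
  UV-bright, canopy-filtered light UV-dark) rather than the canopy-cover
  mechanism under study.
* `contrast_spectrum()` reruns the model with the canopy source fixed and
  reports the per-wavelength Michelson contrast of the median
  upper/lower radiances over 300–500 nm, split into open and closed
  canopies at `p_l = 0.8`.

## What the synthetic data emulate — and what they do not

No measured leaf, litter, illumination or camera spectra ship with the
package. The generator builds smooth parametric stand-ins that honor the
band regularities measured repeatedly for live foliage:
UV (300–400 nm) upper-surface reflectance 1–2% of incident
light with transmittance below 0.06% (ratio > 25), blue
reflectance:transmittance near 1.5, and green/red reflectance 0.7–1.3
times transmittance. The deterministic default curves satisfy all of
these with margin (UV ratio ≈ 43, UV transmittance ≈ 0.036%); random
draws jitter the amplitudes by 5% and are re-validated, and the same
validator (`validate_leaf_optics()`) accepts user-supplied measured
spectra. Lower-surface reflectance equals the upper curve brightened by
up to 25% in the visible — real undersides are typically paler — a
modelling choice constrained by data only in the UV band, where both
surfaces are equally dark.
Illumination is a direct solar curve with a steep atmospheric cut-on near
320 nm plus a Rayleigh-weighted sky; swapping in a standard terrestrial
irradiance table (`read_irradiance_table()`) changes magnitudes but no
API. Selection datasets are produced by the forward model itself plus
multiplicative log-normal pixel noise and per-image mean normalization.

Passing tests on these inputs show that the pipeline's logic is correct
and that the study's qualitative mechanism (diffuse-only: the U cone
always wins; canopy-source specular reflections under closed canopies:
the V cone wins) emerges from spectra with the stated band properties.
They do not show that the quantitative crossover of real habitats is
reproduced: that number depends on the detailed spectral shapes of real
leaves between 380 and 450 nm, which the generator only approximates. On
the default synthetic spectra the crossover estimator reports 0.9 — the
zero-crossing falls inside the 0.8–0.9 canopy-cover bin, consistent with
the reported >80% threshold at the estimator's bin resolution, but a
bin-edge above the printed 80% figure.

## Numerical conventions and problem sizes

Wavelengths run 300–700 nm at 1-nm steps (the finest resolution at which
the templates are smooth); all integrals are trapezoidal; energy-unit
irradiance tables are converted to photon-proportional units by
multiplying by wavelength, a proportionality that cancels in every
contrast. Degenerate cases are errors, not silent values: Michelson
contrast with both catches zero, sign tests with all ties, color
distances with non-positive catches, a canopy specular source drawn at
zero canopy cover. The reference problem sizes are 10,000 iterations per
run in the test suite and 20,000 in the acceptance script (for stabler
per-bin medians after conditioning on the canopy source); a 10,000-iteration
run takes roughly half a minute on one core.

## Known limitations

Single specular bounce and Lambertian diffuse terms only — no multiple
scattering between leaves, no BRDF beyond this two-term decomposition,
and no polarization tracking beyond averaging `R_s` and `R_p`. The leaf
refractive index is constant at 1.45 across 300–700 nm (no published
measurements exist below 400 nm); an optional sensitivity mode with a
linearly rising UV index is deliberately out of scope. Field photography,
exposure fusion and pixel selection are replaced by the generator; the
loader for deposited pixel-selection JSON is implemented with a field-map
adapter as its single change point but is exercised only on
generator-written files.
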