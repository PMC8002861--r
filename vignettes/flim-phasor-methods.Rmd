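---
title: "Methods: phasor analysis, decay fitting and the synthetic FLIM world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasor analysis, decay fitting and the synthetic FLIM world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimphasor)
```

## The measurement model

A spectral FLIM acquisition delivers, per pixel, a TCSPC histogram in each
of 16 detector channels spanning 400–600 nm (12.5 nm bandwidth). The laser
runs at 80 MHz, so the histogram window is one pulse period, 12.5 ns,
divided into `n_time_bins` half-open bins `[kΔt, (k+1)Δt)`. The package
treats excitation as a delta function at `t = 0`: no instrument response
function (IRF) is convolved in, and consequently no reference-dye
calibration is applied to phasors by default (`phasor_transform()` reserves
a rotation+scale `calibration` argument, identity by default). This is the
right model for the synthetic data the package validates against; real
hardware data would need an IRF-aware calibration step before the same
machinery applies quantitatively.

Photons emitted after the window are discarded and the binned profile
renormalized — no wrap-around of late photons into early bins. For the
lifetimes of interest (≤ 5 ns) under 9 % of photons fall beyond 12.5 ns, and
the choice has a convenient exact property: because the Fourier kernel
`e^{iωt}` at `ω = 2π/T` is periodic over the window `T`, the phasor of a
truncated exponential equals the untruncated closed form
`g = 1/(1+(ωτ)²)`, `s = ωτ/(1+(ωτ)²)` *exactly* in continuous time. The only
error left in the discrete transform is midpoint-rule discretization, which
is why validation scenes use ≥ 1024 bins: at 4096 bins the recovered phase
lifetime of a 4 ns decay is 4000.001 ps.

## Emission states and the three decay models

The solvatochromic aminonaphthalene probes emit from three states, which the
simulator reproduces as three decay models:

* **`decay_mono(tau_ns)`** — single-lifetime emission: gel-phase membrane
  (5.0 ns), fluid membrane (4.0 ns), and the internal-charge-transfer (ICT)
  state dominating in the apolar core of lipid droplets (3.0 ns).
* **`decay_biexp(tau_ns, fractions)`** — two emitting states at once, as in
  acidic organelles where a fast pH-activated component (0.6 ns) emits
  alongside ICT (3.0 ns). The printed "average lifetime" of 1800 ps for
  these pixels is reproduced *exactly* by the amplitude-weighted mean
  `a₁τ₁ + a₂τ₂` at equal amplitude fractions — the package therefore
  interprets that average as amplitude-weighted and defaults the synthetic
  organelles to `a = (0.5, 0.5)`; the intensity-weighted mean
  `Σaᵢτᵢ²/Σaᵢτᵢ` is always reported alongside. The source experiments print
  neither the amplitude fractions nor the weighting convention, so this is a
  declared interpretation, not a reported fact.
* **`decay_esr(rate_LE, rate_transfer, rate_R)`** — a two-state excited-state
  reaction for solvent relaxation in viscous membranes. The locally excited
  (LE) state decays with total rate `Γ_LE + k_s` feeding a relaxed state of
  rate `Γ_R`; the relaxed (green-channel) population
  `R(t) ∝ e^{−Γ_R t} − e^{−(Γ_LE+k_s)t}` rises from zero before decaying.
  Negative pre-exponential amplitude is exactly what pushes a phasor outside
  the universal semicircle, and the tests assert that sign. When
  `Γ_R = Γ_LE + k_s` the analytic limit `t·e^{−Γt}` is used. The blue-channel
  (LE) emission of the same model is mono-exponential at `1/(Γ_LE+k_s)`.

All three are binned by exact integration over each time bin (closed-form
antiderivatives), never by sampling the density at bin centers, so the
generator and the fitters share one binning convention and noiseless
round-trip tests are meaningful to 0.1 %.

## The synthetic world and what a green test establishes

`default_scene()` is a fixed, stated world, not a tuning knob: a
PC-12-like cell with a 3-px gel membrane ring (mono 5.0 ns; green channel
ESR with `Γ_R = 1/3 ns⁻¹`, `Γ_LE + k_s = 1 ns⁻¹`), fluid cytoplasm
(mono 4.0 ns), four spherical lipid droplets of radius 3–6 px (mono 3.0 ns,
co-stain contrast 10:1), and three acidic organelles (biexp 0.6/3.0 ns,
equal amplitudes, also co-stain bright). Emission spectra are Gaussian
weights over the 16-channel grid (LE band near 440–450 nm, ICT near
470–480 nm); channels with centers below 500 nm carry the blue decay,
the rest the green decay, separating the LE band from the relaxed band.
The per-pixel photon budget defaults to 5000 — a typical well-exposed
TCSPC frame; the source experiments publish no photon statistics, so this
is a package default, stated here and in the config, not a reported value.
The co-stain emits `costain_intensity × (max photon budget)/10` photons in
the two 575–600 nm channels with a fixed 3 ns mono decay (only its
*intensity* enters any statistic).

The generator emulates compartment geometry, emission spectra, decay
physics and Poisson shot noise. It does **not** emulate: optical PSF blur,
detector IRF, afterpulsing, dark counts, photobleaching, autofluorescence,
or real-cell morphology. A green test therefore establishes that the
analysis correctly inverts the stated physics at realistic counting noise —
not that the published cell-derived percentages (68.7/6.6/0.9 % ROI
fractions, 2973 ps droplet `τ_mean`) are reproduced, since those depend on
real morphology and staining. For those quantities the tests assert the
orderings the experiment relies on: the dominant compartment's ROI captures
the most probe pixels, and normalized co-stain intensity peaks in the ROI
engineered to colocalize with the co-stain.

## Numerical choices

* **Phasor transform** uses bin centers `t_k = (k+½)Δt`; harmonic fixed to 1
  by default. Pixels under `min_photons = 50` total counts are flagged
  invalid — low-count phasors are shot-noise dominated; the threshold is a
  package default (none is published).
* **Fitting objective** is Poisson-weighted least squares with weights
  `1/max(c_k, 1)`, the standard TCSPC choice; the amplitude is profiled out
  analytically (`A = Σwcf / Σwf²`), so the mono fit is a 1-D bounded search
  over `log τ` and the biexponential a 3-D bounded quasi-Newton run
  (`nlminb`) over `(log τ₁, log τ₂, logit a₁)`. Lifetimes are bounded to
  [50 ps, 12 ns]; optima within 2 % of a bound are flagged `at_bound`.
* **Biexponential initialization** is deterministic: the mono estimate
  `τ̂` seeds `(τ̂/3, 1.5τ̂)` with equal amplitudes; no random restarts, so a
  fit is a pure function of its histogram. Components are reported ordered
  `τ₁ ≤ τ₂`; `τ₁/τ₂ > 0.8` raises an ill-separated warning and flag, which
  is also how a genuinely mono-exponential input surfaces (nested-model
  degeneracy, alongside `a₁ ≈ 0`). No constant background term is fitted by
  default (synthetic data has none).
* **Percentile masks**: "top p % brightest" selects intensities at or above
  the `(100−p)`-th percentile computed by sorting; ties at the threshold are
  all included, so cardinality is `≥ ⌈p·n/100⌉` with equality when values
  are distinct. A constant image selects everything, with a warning.
* **Lifetime distributions** default to 50 ps bins: fine enough to resolve
  standard errors of a few tens of ps over ~25 cells without leaving empty
  bins at realistic photon budgets. `tau_mean` is the frequency-weighted
  bin-center mean, so it is accurate to within half a bin width and bounded
  by the distribution support.
* **Normalized co-stain intensity** implements
  `N(ROI) = [Σ_{ROI} I / Σ_image I] / [|bright ∩ ROI| / |bright|]` — the ROI's
  share of co-stain signal over its share of bright pixels. The published
  description ("normalized to the fraction of bright pixels") is verbal, so
  this formula is a declared interpretation: uniform signal with
  `ROI = image` gives 1, and signal concentrated in an ROI holding half the
  bright pixels gives 2. The published values (0.22, 0.26) are not
  reproduction targets for this reason.
* **Segmentation lifetime estimator**: distributions and maps use phase
  lifetimes by default (configurable to fitted lifetimes); the source
  figures do not state which estimator they display.

## Persistence and formats

4-D cubes persist in one HDF5 file per field of view (`counts` as 32-bit
integers plus a `meta` group), round-tripping counts bit-exactly and float
metadata to 1e-12 relative. Derived 2-D maps are written as plain TSV and
masks as 0/255 text PGM — no TIFF library is assumed by the package.
Vendor TCSPC formats (e.g. Becker & Hickl `.sdt`) are out of scope.
Spectral bands select channels by *center membership in the closed
interval*; the detector's channel-edge positions are unpublished, so the
16-channel grid `400 + 12.5(k+½)` nm is the package's declared convention.

## Known limitations

Truncation renormalization slightly biases intensity weights of long-lived
components in mixtures relative to untruncated closed forms (the phasor of
the 0.6/3.0 ns mixture at equal amplitudes is (0.409, 0.430) truncated vs
(0.407, 0.430) untruncated); all package oracles are truncation-consistent.
Phase-lifetime maps computed from noisy pixels are slightly biased as a
nonlinear function of a noisy phasor; per-compartment means converge within
~0.5 % at 2000 photons/pixel. The pipeline's full-spectrum phasor mixes
probe and co-stain photons by construction (as in the real experiment);
compartment-recovery assertions therefore use the co-stain-free blue band.
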