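# flimphasor

Phasor analysis of spectrally resolved fluorescence lifetime imaging (FLIM),
built for experiments that map the intracellular distribution of
solvatochromic membrane probes (laurdan and its long-chain fatty-acid
analogs) in living cells. Each pixel of such an acquisition carries a
TCSPC photon-arrival histogram in 16 spectral channels (400–600 nm); the
probe's lifetime reports the phase state of its lipid environment — long
lifetimes in packed gel-phase membranes, shorter in fluid membranes, shorter
still in the apolar core of lipid droplets, and a fast extra component in
acidic organelles. `flimphasor` turns those cubes into phase maps,
phasor-based segmentations and colocalization statistics, and ships a
synthetic-scene generator with ground truth so the entire pipeline is
testable without microscope data.

## The method

For a per-pixel decay `I(t)` the phasor transform at the laser repetition
angular frequency `ω = 2π × f_rep` is

    g(ω) = ∫ I(t) cos(ωt) dt / ∫ I(t) dt
    s(ω) = ∫ I(t) sin(ωt) dt / ∫ I(t) dt

Every single-exponential decay lands on the **universal semicircle**
(center (0.5, 0), radius 0.5) at `g = 1/(1+(ωτ)²)`, `s = ωτ/(1+(ωτ)²)`;
mixtures of lifetimes fall inside it (the transform is linear in intensity);
excited-state reaction products — e.g. the rising solvent-relaxation
emission seen in the green channel of very viscous membranes — fall
**outside** it. The phase lifetime is `τ_φ = s/(gω)`, the modulation
lifetime `τ_m = (1/ω)·√(1/(g²+s²) − 1)`. Circular regions of interest drawn
in phasor space are remapped to image masks, segmenting pixels by decay
signature. Complex decays are additionally fitted as
`a₁·e^(−t/τ₁) + a₂·e^(−t/τ₂)` with Poisson-weighted least squares, with both
the amplitude-weighted mean `a₁τ₁ + a₂τ₂` and the intensity-weighted mean
`Σaᵢτᵢ²/Σaᵢτᵢ` reported. Colocalization against a co-stain (e.g. Nile Red
for lipid droplets, LysoTracker for acidic organelles) uses
brightest-percentile masks, masked lifetime distributions with
`τ_mean = Σ τᵢ·fᵢ_norm`, per-ROI pixel fractions and normalized co-stain
intensities, aggregated across cells as mean ± standard error.

## Worked example

```r
library(flimphasor)

## a noiseless 4.0 ns decay, 4096 TCSPC bins over the 12.5 ns window at 80 MHz
meta  <- acquisition_metadata(n_time_bins = 4096)
hist  <- expected_decay(decay_mono(4.0), meta) * 1e6
field <- phasor_transform(hist, meta)
c(field$g[1,1], field$s[1,1])      # 0.1983 0.3987  (on the universal circle)
phase_lifetime(field)[1,1]         # 4000.0 ps
circle_residual(field)[1,1]        # 5.8e-08

## the acidic-organelle biexponential: 0.6 + 3.0 ns at equal amplitudes
fit <- biexp_fit(600, 3000, a1 = 0.5)
amplitude_weighted_mean(fit)       # 1800 ps
intensity_weighted_fractions(fit)  # 0.167 0.833

## synthetic PC-12-like scene, end to end
sc <- default_scene(shape = c(64, 64), n_time_bins = 256,
                    photons_per_pixel = 5000, seed = 1)
r   <- render_scene(sc)
tau <- phase_lifetime(phasor_transform(integrate_spectral(r$image, c(400, 475))))
sapply(r$truth$true_masks[c("membrane_ring","cytoplasm","lipid_droplet")],
       function(m) mean(tau[m$flags], na.rm = TRUE))
#  membrane_ring  cytoplasm  lipid_droplet
#           5005       4007           3020     (truth: 5000 / 4000 / 3000 ps)

## co-stain colocalization: top-2% brightest 575-600 nm pixels
co <- integrate_time(r$image, c(575, 600))
ld <- brightest_percentile_mask(co, 2, "LD")
tau_mean(lifetime_distribution(tau, ld, bin_width_ps = 50))
# 2741 ps -- the mask catches the co-stained organelles (droplets at 3000 ps
# plus biexponential acidic organelles at ~2100 ps phase lifetime)
```

The blue-band (400–475 nm) compartment means land within Poisson noise of
the generator's ground truth; the acidic organelles sit well inside the
universal circle while the membrane ring's green-channel (515–565 nm)
solvent-relaxation emission sits outside it (`circle_residual > 0`).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "flimphasor", package = "flimphasor"))')
$CLI run      --config inst/extdata/example_config.yaml --out run1
$CLI simulate --config inst/extdata/example_config.yaml --out scene.h5
```

Subcommands: `simulate`, `phasor`, `segment`, `fit`, `coloc`, `run`; configs
are YAML or JSON; outputs are an HDF5 cube, TSV/PGM maps and masks, CSV
tables and a deterministic `summary.json` (re-running a config byte-for-byte
reproduces it).

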