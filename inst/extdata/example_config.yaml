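# Example flimphasor pipeline configuration.
#
# Spectral bands (nm): blue = probe LE emission, green = relaxed/ICT emission
# (540/50 nm), costain = Nile Red / LysoTracker window.
# Rendering note (not used by the pipeline): published pseudo-color ranges
# for lifetime maps are 2500-5000 ps (figure caption) or 2392-5070 ps (text);
# both are recorded here verbatim since they disagree at the tens-of-ps level.
scene: default
scene_shape: [64, 64]
scene_time_bins: 256
scene_photons: 5000
seed: 1

blue_band_nm: [400, 475]
green_band_nm: [515, 565]
costain_band_nm: [575, 600]

harmonic: 1
min_photons: 50
probe_top_percent: 50
costain_top_percent: 2
bin_width_ps: 50
out_dir: flim_run

# Circular phasor-plot ROIs (g, s, radius). Centers are the mono-exponential
# phasor points of the gel / fluid / low-lifetime phases at 80 MHz.
rois:
  - {label: tau_mono_gel,   center_g: 0.1367, center_s: 0.3435, radius: 0.05}
  - {label: tau_mono_fluid, center_g: 0.1983, center_s: 0.3987, radius: 0.05}
  - {label: tau_mono_low,   center_g: 0.3054, center_s: 0.4606, radius: 0.05}
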