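# dopplerMC

A voxel-free Monte Carlo simulator of polarized light transport through
analytic cylindrical and planar media with flowing scatterers, built for
**through-transmission laser Doppler flowmetry**: the regime where a
collimated beam crosses a small flow tube filled with a moderately to highly
scattering liquid (bead suspensions, milk, lab-on-a-chip channels) and a
detector on the far side records the beat spectrum of the Doppler-shifted
speckle field. It is aimed at researchers designing or interpreting such
measurements who need simulated Doppler power spectra for known optical
properties, flow profiles and geometries.

## What it computes

Photons carry position, direction $\hat k$, polarization $\hat p$, weight
and a cumulative Doppler shift $f_D$. Scattering angles are drawn by
inverse-CDF sampling of the polarization-resolved phase function

$$P(\theta, \phi) = \cos^2(\phi)\, P_s(\theta) + \sin^2(\phi)\, P_p(\theta),$$

with $P_s \propto |S_1(\theta)|^2$ and $P_p \propto |S_2(\theta)|^2$ from
Mie theory (or any user-supplied table). Free paths follow
$d = -\ln(1-\chi)/\mu_s$; weights decay by Lambert-Beer absorption with
Russian roulette below a threshold; interfaces use polarization-resolved
Fresnel reflectivities and vector Snell refraction; cylinder and plane
intersections are solved analytically, so curved tube walls are exact
rather than voxelized. At each scattering event in a flowing medium,

$$f_{D,i} = -\vec v \cdot \vec q + f_{D,i-1}, \qquad
  \vec q = \frac{n}{\lambda}\left(\hat k_{\rm in} - \hat k_{\rm out}\right),$$

with $\vec v$ the local flow (Poiseuille profile plus an isotropic Brownian
component). Detected photons are split into detector strips perpendicular
to the flow, histogrammed in $f_D$, and turned into a power spectrum from
the interference of all photon pairs per difference frequency, with
polarization overlap taken into account — an $O(\mathrm{bins}^2)$
factorization of the $O(N^2)$ pair sum. Utilities cover spectrum
normalization against measurements, noise floors, segmented-FFT processing
of detector time traces, and synthesis of such traces from simulated
records.

## Worked example

```r
library(dopplerMC)

# 1. What scattering coefficient does a 0.028 % v/v suspension of 1.0 um
#    polystyrene beads in water have at 633 nm?
mus_from_concentration(1e-6, 1.586, 1.33, 633e-9, 0.00028)
#> [1] 1.066948        # mm^-1

# 2. Simulate the packaged through-transmission scene (0.95 mm glass tube,
#    170 um spot, 1 mm detector) at mus = 1 mm^-1 and 5 mL/min:
sc  <- reference_scene(mus = 1, flow_rate = 5)
run <- run_simulation(sc, stop = list(n_detected = 2000), seed = 42)
run
#> <doppler_run> launched 20000, detected 7790 (w = 7790), escaped 12210,
#>               roulette-absorbed 0

# 3. Doppler power spectrum with the detector split into 3 strips:
ps <- power_spectrum(bin_doppler(run$records, sc$detector,
                                 n_strips = 3, n_bins = 128))
spectral_width(ps)
#> [1] 28011           # Hz below which 90 % of the beat power lies
```

The first number is the suspension's scattering coefficient in mm^-1
(1.07 mm^-1: this concentration was designed to hit ~1 mm^-1). The run
summary counts photon fates; at this low scattering about 39% of launched
photons reach the 1 mm detector and 84% of those are ballistic. The
spectral width says that 90% of the beat power of the detected speckle
field lies below 28 kHz at this flow rate; it grows monotonically with the
flow.

A thin command-line front end wraps the same functions:

```sh
dopplermc simulate --config run.json --records rec.csv --manifest man.json
dopplermc spectra  --records rec.csv --out spectrum.txt --strips 3
dopplermc mie      --diameter-um 1.0 --concentration 0.028
dopplermc fixtures --kind trace --seed 1
```

(`dopplermc` is `inst/cli/dopplermc`, runnable via
`Rscript $(Rscript -e 'cat(system.file("cli","dopplermc",package="dopplerMC"))') ...`.)

## Package layout

| Area | Functions |
| --- | --- |
| Mie / phase functions | `mie_phase_functions`, `mus_from_concentration`, `concentration_for_mus`, `combined_phase`, `phase_table`, `read/write_phase_table` |
| Angle sampling | `build_scatter_sampler`, `sample_angles` |
| Scene | `reference_scene`, `scene`, `medium_spec`, `cylinder`, `slab`, `boundary_*`, `source_spec`, `detector_spec`, `poiseuille_flow`, `flow_field`, `brownian_velocity`, `locate_medium`, `ray_cylinder_intersect`, `ray_plane_intersect`, `read/write_scene` |
| Transport | `run_simulation`, `emit_photons`, `propagate_step`, `sample_path_length`, `apply_absorption`, `russian_roulette`, `fresnel_reflectivity`, `reflect_or_refract`, `scatter_photons`, `detect_photons` |
| Spectra | `bin_doppler`, `power_spectrum`, `spectral_width`, `normalize_to_measurement`, `add_noise_floor`, `estimate_noise_floor`, `read/write_spectrum` |
| Traces | `measured_trace`, `process_measured_trace`, `synth_detector_trace`, `read/write_trace` |
| Entry points | `cli_simulate`, `cli_spectra`, `cli_mie`, `make_fixtures`, `read_run_config` |

The methods vignette (`vignettes/doppler-monte-carlo.Rmd`) documents the
transport model, the sampling construction, the reference geometry, all
numerical choices and the known limitations.
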