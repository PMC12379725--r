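Package: dopplerMC
Title: Voxel-Free Monte Carlo Simulation of Polarized Light Transport with
    Doppler Shifts in Flowing Scattering Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxel-free Monte Carlo simulator of polarized light transport
    through analytic cylindrical and planar media containing flowing
    scatterers, aimed at through-transmission laser Doppler flowmetry.
    Scattering phase functions are computed from Mie theory for spherical
    particles (or supplied as tables), scattering angles are drawn by
    inverse-CDF sampling of the polarization-resolved phase function, and
    each photon accumulates a Doppler shift from the local flow field at
    every scattering event. Detected photons are converted into Doppler
    power spectra via a strip-wise pairwise-interference procedure, and
    utilities are provided to synthesize and process detector time traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
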