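Package: resonet
Title: Resonance and Gating in Spiking Networks with Strong Feedback Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of inhibition-based oscillator networks of
    excitatory principal cells and fast-spiking interneurons, as found in deep
    layers of prefrontal cortex.  Provides rate-modulated inhomogeneous Poisson
    input generators (asynchronous, sinusoidal, and square-wave pulse-packet
    drives), conductance-based Hodgkin-Huxley and leaky integrate-and-fire
    network models integrated with a fixed-step fourth-order Runge-Kutta engine,
    and the output statistics used to characterize spiking resonance:
    instantaneous firing rates by Gaussian kernel regression, Welch spectra of
    population rates, natural frequency, firing-rate resonance, and
    population-frequency resonance.  Includes scripted experiments for
    frequency, synchrony, and strength sweeps, ion-channel knockouts, and
    winner-take-all competition between pathways sharing interneurons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
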