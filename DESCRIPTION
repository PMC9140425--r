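Package: noneqcode
Title: Nonequilibrium Kinetic Ising Networks for Optimal Population Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction, inference and analysis of nonequilibrium (kinetic
    Ising) neural networks that encode dynamic stimuli. Generates dynamic
    inputs from linear stochastic and bistable telegraph dynamics, builds
    optimal target population spike codes from a linear-decoding Gaussian
    posterior, fits asymmetric coupling matrices by maximum-likelihood
    gradient ascent or naive mean-field inversion, decodes the stimulus back
    from simulated spin activity, and quantifies decoding performance,
    connectivity asymmetry and entropy production. Includes a continuous
    rate recurrent network trained by recursive least squares for comparison,
    and an orchestration layer that runs the full protocol and parameter
    sweeps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
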