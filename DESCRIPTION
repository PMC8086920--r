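Package: peristalsim
Title: Discrete Multiphysics Simulation of Neurally Controlled Intestinal Peristalsis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Couples a weakly compressible smoothed-particle-hydrodynamics (SPH)
    fluid with a lattice-spring-model (LSM) membrane to simulate peristaltic
    transport of luminal content through a flexible tube. A travelling radial
    contraction propels the fluid; its speed can be fixed (static waves) or
    chosen every 0.1 s by a small stretch-sensing policy network that mimics
    the input-output structure of the enteric nervous system and is trained
    with cross-entropy reinforcement learning. A digital-inflammation model
    distorts the controller's strain perception without altering the physics,
    emulating the perceptual effect of inflammatory bowel disease. Includes
    tube geometry builders, the coupled particle engine, the policy network
    and trainer, experiment drivers (constant-wave sweeps, adaptive and
    inflamed runs), and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
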