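Package: crowdsim
Title: Spatial Stochastic Simulation of Gene Expression Under Macromolecular
    Crowding
Version: 0.1.0
Authors@R:
    person("crowdsim", "maintainers", email = "crowdsim@example.org",
           role = c("aut", "cre"))
Description: Lattice reaction-diffusion simulation of a single-gene
    transcription/translation network in a crowded nuclear volume.  A
    modified next subvolume method attenuates transcription-factor
    diffusion into each voxel by the local chromatin density and by
    randomly placed artificial crowding agents of two size classes.
    Includes a synthetic chromatin-intensity field generator emulating
    voxelised DAPI image stacks, promoter switch statistics and effective
    rate-constant estimation, population kurtosis and kernel density
    summaries, effective-diffusion mapping, power-spectrum comparison
    against a well-mixed two-state reduction, and a command-line
    experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
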