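Package: lipidgate
Title: Lipid Contact Analysis and Photoactivation Kinetics for DAG-Gated TRPC3 Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how diacylglycerol (DAG) engages the L1/L2 lipid
    coordination sites of the tetrameric TRPC3 cation channel. Provides a
    synthetic coarse-grained membrane trajectory generator (asymmetric
    PC/PE/PS/cholesterol bilayers with inner-leaflet DAG, a Z-restraint phase
    followed by free flip-flop, and site-specific capture/dwell binding),
    contact analytics (lipid counts near the protein, per-residue species
    fingerprints, DAG occupancy of the L2 sites, equilibration detection),
    species-resolved 3D voxel density maps with OpenDX export, and
    photopharmacology kinetics: robust bounded fits of power-exponential
    activation models to photocurrent traces, Tau-ON sensitization metrics,
    ramp I-V utilities, fluorescence normalization, and the normality-gated
    group comparisons used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
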