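Package: chromK27
Title: Stochastic Kinetic Modeling of H3K27 Acetylation and Methylation
    Dynamics Around Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the chromatin-state dynamics of histone H3 lysine 27
    (H3K27) on a one-dimensional histone lattice around a transcription start
    site. Each histone tail carries one of five states (unmodified, acetylated,
    mono-, di- or tri-methylated) and evolves by enzyme-occupancy-driven
    nucleation, long-range allosteric spreading of trimethylation through 3D
    chromatin contacts, active demethylation, (de)acetylation, histone turnover
    and replication dilution. Provides an exact continuous-time stochastic
    simulation engine (Gillespie algorithm with scheduled replication events and
    old/new histone pool tracking), synthetic enzyme-occupancy profile presets,
    steady-state observables (mark profiles, methylation valency, correlation
    maps, recruitment phase diagrams), time-resolved protocols (inhibitor
    washout, profile switch, synchronized cell-cycle averages, effective histone
    decay time), and a multi-step parameter-inference scheme with a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
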