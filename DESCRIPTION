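Package: synhomeo
Title: Mass-Action Modelling of Mirtron-Mediated Synaptic Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action kinetic model of a synaptic
    homeostasis network in which a nicotinic acetylcholine receptor
    (nAcRb2) drives membrane depolarization, an incoherent feedforward
    loop (activity-dependent Adf-1 phosphorylation inducing SKIP and the
    Shal potassium channel) tempers the potential, and a negative
    feedback loop (the mirtron miR-1010, spliced from SKIP transcripts,
    degrading nAcRb2 mRNA) restores it to rest. Genotypes and
    pharmacological treatments are encoded as parameter-level
    perturbations; trajectories are reduced to peak, return-delay and
    switch-classification metrics and to steady-state fold changes.
    Includes least-squares calibration of rate parameters against
    printed RT-qPCR fold-change observations, a delta-delta-Ct relative
    quantification pipeline with a Bartlett variance-decision test
    (Student versus Welch), and a seeded synthetic Ct-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
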