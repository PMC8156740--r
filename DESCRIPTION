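Package: cvmniche
Title: Cancer-Niche Lattice Simulation with Kikuchi Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the construction, metastasis and apoptosis of cancer
    niches on a two-dimensional binary lattice of healthy and cancerous cells.
    The lattice evolves by single-site flip proposals that are retained only
    when they lower the Kikuchi (cluster-variation) free energy of the system,
    subject to a tolerance cap on the admissible cancer fraction. Provides
    region-graph construction with Moebius overcounting numbers for cluster
    sizes d = 1 (mean field), d = 2 (Bethe) and d = 3 (B3 triangles), empirical
    cluster marginals under translation homogeneity, interaction-energy and
    cluster-variation entropy evaluators, an exact brute-force free-energy
    oracle for tiny systems, scenario presets for local growth, metastasis and
    apoptosis trajectories, trajectory plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
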