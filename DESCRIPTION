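Package: jetcool
Title: Conformer Populations and Kinetic Trapping in Supersonic Jet Cooling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interprets supersonic-jet-cooling single-molecule spectroscopy of
    small flexible molecules such as aromatic dipeptides. From a conformer
    ensemble with relative energies and free-energy corrections it computes
    equilibrium Boltzmann populations at an effective pre-expansion
    temperature, classifies conformer-interconversion barriers, pools
    populations across low-barrier pathways into kinetic basins, predicts
    which conformers remain observable after the rapid cooling, and scores
    scaled harmonic IR frequencies against experimental band positions.
    Includes geometric hydrogen-bond detection, Ramachandran-style backbone
    typing of capped dipeptides, a toy internal-coordinate dipeptide builder
    and a synthetic-ensemble generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
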