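Package: atomscreen
Title: Atom-Level Contrastive Embeddings for Ultra-Fast Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns per-atom embeddings of protein binding pockets and small
    molecules with twin graph-attention encoders trained under a contrastive
    "positive margin" objective, so that atoms observed interacting in 3D
    complexes become near neighbours in embedding space. Compound libraries
    are then screened by accumulating nearest-neighbour similarity scores per
    compound, and screens are evaluated with enrichment factors. Includes a
    synthetic complex generator with planted atomic complementarity so the
    full pipeline (graph construction, training, calibration, scoring,
    enrichment) can be exercised end-to-end at desk scale, plus inverted
    (ligand-to-pocket and pocket-to-pocket) search.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
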