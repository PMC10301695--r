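Package: pathvae
Title: Ontology-Guided Variational Autoencoders for Pathway Activity
    Inference and In Silico Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variational autoencoder whose latent space and sparse linear
    decoder mirror a biological ontology (for example the Gene Ontology or
    the Human Phenotype Ontology), so that every hidden neuron group
    corresponds to an ontology term and its activation can be read as a
    pathway or phenotype activity.  Provides ontology parsing, trimming and
    mask compilation, model fitting with a masked non-negative linear
    decoder, activity extraction, in silico gene knockout and stimulation
    screens with paired rank tests, hypergeometric over-representation
    analysis, and a seeded synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
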