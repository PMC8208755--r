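Package: LatentMicrobiome
Title: Deep Latent-Space Autoencoders for Predicting Microbiome
    Composition from Environmental Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compresses microbial community composition (OTU tables with
    hundreds of taxa) into a small deep latent space using heterogeneous
    autoencoders, and predicts the full composition from a handful of
    environmental features (temperature, precipitation, plant age,
    host genotype). Provides compositional normalizations (TSS, CLR),
    Bray-Curtis and crossentropy training losses, per-OTU error ranking,
    taxonomic-rank aggregation, frozen-decoder transfer learning to small
    datasets, hypothetical-scenario (climate-change style) prediction,
    baseline predictors, grid search with cross-validation, a seeded
    synthetic-data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, MASS, optparse
Suggests: testthat (>= 3.0.0), biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
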