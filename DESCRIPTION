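Package: stormtracer
Title: Microbial Communities as Hydrologic Tracers of Storm Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Treats daily streamwater 16S rRNA amplicon sequence variant (ASV)
    counts as a hydrologic tracer of a storm event. Provides rarefaction, alpha
    diversity (richness, base-2 Shannon entropy), Bray-Curtis beta diversity and
    principal coordinates analysis of daily communities against a storm
    hydrograph; ordinary least-squares regression of discharge on ordination
    coordinates and diversity; per-taxon abundance-discharge (cQ) classification
    into mobilized, diluted, static and uncharacterized responses with a
    shuffled-surrogates null for taxonomic-group class fractions; habitat-based
    source-environment attribution of the community; stable-isotope
    two-component hydrograph separation and deuterium excess; and a synthetic
    generator that produces coupled hydrograph, count, isotope and habitat
    inputs with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
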