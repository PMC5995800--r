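Package: iopqsar
Title: Pharmacophore Enrichment and Neural-Network QSAR for
    Intraocular-Pressure-Lowering Benzimidazoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A structure-activity pipeline for small heterocyclic series
    tested for intraocular-pressure (IOP) lowering activity. Molecules read
    from SMILES or SDF are translated into fragment-pair structural
    descriptors (atom-environment and ring tokens joined by topological
    length and bond-path codes); descriptor frequencies in the active and
    inactive classes are compared with a one-sided hypergeometric test to
    flag pharmacophores of presence or absence of activity. Compounds are
    separated into activity classes by k-means over IOP response indicators;
    hypotensive potency is scored on an ED20-based ordinal scale; an
    ensemble of single-hidden-layer perceptrons links four hypotensive
    predictors to the binary IOP class, and agreement between experimental
    and predicted activity is assessed with the Spearman rank correlation.
    A seeded synthetic-data generator emulates compound libraries with
    planted fragments, class-shifted IOP indicator matrices, and linked
    hypotensive activity tables so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
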