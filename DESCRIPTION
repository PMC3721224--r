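Package: chemotypemap
Title: Metabogenomic Chemotyping of Halogenated Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint analysis of GC/MS secondary-metabolite profiles and DNA
    barcode sequences for red algae rich in polyhalogenated monoterpenes.
    Predicts and scores chlorine/bromine isotopologue envelopes to annotate
    features as polyhalogenated, builds base-peak-relative feature tables
    from per-sample peak lists, delineates chemogroups by Bray-Curtis
    group-average clustering cut at a similarity threshold, assigns
    phylogroups from pairwise divergences via neighbor joining, and
    cross-tabulates chemogroups, phylogroups and collection sites to
    quantify site specificity and partition concordance. Includes a
    synthetic-study generator with known ground truth for end-to-end
    validation.
License: MIT
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr,
    vegan
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
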