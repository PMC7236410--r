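Package: f8missense
Title: In Silico Analysis of FVIII Missense Variants and Inhibitor Risk in
    Severe Hemophilia A
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation and association analysis of missense variants of the
    F8 gene (coagulation factor VIII) in severe hemophilia A. Maps
    mature-protein residue positions onto the A1-A2-B-A3-C1-C2 domain
    architecture, classifies substitutions with a four-class physicochemical
    scheme and Grantham distance (including GV/GD-style alignment scoring and
    C0-C65 binning), harmonizes SIFT, PolyPhen-2, Align-GVGD, KD4v and
    MutationTaster outputs into a binary deleterious/neutral consensus, scores
    positional conservation from protein multiple alignments, and tests
    contingency-table associations with inhibitor development. Includes a
    seeded synthetic cohort generator and a deterministic fixture reproducing
    the marginal counts of a CHAMP-style severe-missense cohort, plus an
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
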