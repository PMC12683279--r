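Package: viromark
Title: Skin Virome Marker Selection and Individual-Specificity Statistics
Version: 0.1.0
Authors@R:
    person("Viromark", "Developers", email = "viromark@example.org",
           role = c("aut", "cre"))
Description: Tools for forensic analysis of skin virome profiles. Starting
    from taxon-by-sample abundance tables, a taxonomy and sample metadata,
    the package selects viral families that are temporally stable on skin
    (detected at two or more of three time points at each anatomical site)
    and transmissible to handled objects (detected on two or more of four
    contacted objects), intersects the two sets into candidate marker
    families, and extracts the species-level markers they contain. It
    quantifies individual specificity of the resulting presence/absence
    profiles via Jaccard dissimilarity, within- versus between-subject
    distance comparisons with Wilcoxon rank-sum tests, principal
    coordinates analysis, PERMANOVA, Shannon diversity and one-way ANOVA,
    all implemented from first principles. A synthetic study generator
    emulates the full sampling design (subjects x sites x time points x
    contacted objects plus negative controls) with planted subject
    signatures, cosmopolitan taxa, transients, detection dropout and
    per-object transfer probabilities, so that every pipeline stage is
    testable against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
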