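Package: stoichcomp
Title: Protein Complex Stoichiometry Compensation Analysis in Aneuploid Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how aneuploid tumors compensate for
    protein-complex stoichiometry imbalance. Turns arm-level aneuploidy calls
    into whole-chromosome states, detects recurrent cancer-type-specific
    aneuploidies and co-amplifications, calls differential transcripts and
    proteins between aneuploid and diploid sample groups, tests co-complex
    partner enrichment with chi-square standard residuals, assesses
    protein-protein interaction enrichment with a degree-preserving
    randomization null, attributes other-chromosome dysregulation to promoter
    methylation, transcription-factor and ubiquitination layers, scores
    functional-term enrichment among complexes of top-correlated partners, and
    computes a per-sample stoichiometry deviation score linked to survival.
    Includes a fully parameterized synthetic multi-omics cohort generator with
    recorded ground truth so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
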