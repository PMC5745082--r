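Package: growthpred
Title: Predicting Conditional Growth Defects of Bacterial Strains from
    Variant Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers condition-specific growth defects of bacterial strain
    panels from annotated coding variants. Per-variant effect predictions
    (SIFT probabilities, FoldX stability changes) and variant-class
    heuristics are converted into the probability that each gene's function
    is affected in each strain (a disruption score), after phylogeny-aware
    allele-frequency and founder filtering. Disruption scores are combined
    with conditionally essential gene sets from a reference-strain
    chemical-genomics screen into a per-strain, per-condition sensitivity
    score, which is assessed against binary growth-defect phenotypes with
    precision-recall curves and three randomization nulls, and used to rank
    in-silico complementations that would restore growth. Includes a
    synthetic strain-panel generator with planted ground truth for
    end-to-end validation, and the colony-array quality control and S-score
    normalization used to derive binary phenotype calls from high-density
    agar-plate screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    limma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
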