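Package: mgfscreen
Title: Compartment Classification of Myeloma Growth Factor Expression in Bone Marrow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening myeloma growth factor (MGF) and MGF-receptor genes
    by expression compartment in the multiple-myeloma bone marrow. Implements
    MAS5-style per-array scaling and signal flooring, detection-call (present/
    marginal/absent) filtering of non-informative probe sets, probe-set-to-gene
    selection, two-group Student t contrasts with Benjamini-Hochberg adjustment
    and fold-change screening, a rule cascade assigning each gene to the tumor
    cell, niche (stromal cell / osteoclast), environment (T cell / monocyte /
    neutrophil), shared or not-expressed compartment, per-receptor expression
    summaries in tumor cells, stage-wise contrasts across normal plasma-cell
    differentiation, and a synthetic expression-matrix generator with planted
    compartment structure for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
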