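Package: juncfilter
Title: Splice Junction Filtering for RNA-Seq Alignments via Overhang Anomaly Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of spliced RNA-Seq alignments (e.g. TopHat2
    output) to remove false-positive exon-exon junctions. Split-read
    overhangs across each junction are modelled as discrete uniform; a
    subset of patently anomalous junctions (systematically short overhangs
    with a recurrent mismatch near the splice site) is labelled as
    potential false positives and an L1-regularized logistic regression is
    fitted over per-junction overhang-deviation feature vectors in a
    semi-supervised fashion. Junctions with a high posterior probability of
    belonging to the false-positive class are discarded and multimapped
    reads left with a single surviving location are rescued. Includes a
    synthetic spliced-alignment simulator and detection/quantification
    evaluation metrics so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    glmnet,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
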