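Package: uniedit
Title: Quantification of Genome-Editing Outcomes from Anchored
    Uni-Directional Tagmentation Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying CRISPR genome-editing outcomes -- small
    indels, large deletions, inversions, homolog/sister-chromatid fusions and
    inter-chromosomal translocations -- from anchored uni-directional
    tagmentation sequencing libraries in which each template molecule carries
    a unique molecular identifier (UMI). The package enumerates the
    end-joining outcome classes reachable from one or two programmable cuts,
    constructs reference junction amplicons, demultiplexes dual-barcoded
    paired reads, aligns them with a semi-global affine-gap aligner, classifies
    molecules by junction-window coverage and cut-site indel inspection,
    collapses UMIs to molecule counts, and reports per-category frequencies.
    It also provides the assay-validation statistics (haplome-equivalent input
    accounting, exact binomial power and limit-of-detection curves, titration
    linearity regression with slope comparison) and a fully seeded synthetic
    library simulator that emits ground-truth-labelled paired FASTQ for
    offline testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
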