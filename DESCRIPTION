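Package: podlnc
Title: Integrative lncRNA-mRNA Microarray Analysis for Two-Group Designs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible re-implementation of the integrative
    lncRNA/mRNA peripheral-blood microarray workflow used in small two-group
    case/control studies (case = postoperative delirium): detection-flag
    filtering and quantile normalization, two-group differential expression
    with fold-change and p-value gates, coding-non-coding (CNC) co-expression
    networks from thresholded Pearson correlation, cis nearby-gene pairing
    within a genomic window, ceRNA (lncRNA-miRNA-mRNA) triad inference via
    canonical miRNA seed matching, Fisher-exact gene-set enrichment,
    score-thresholded PPI networks with degree hubs and MCODE-style dense
    module detection, and demographic group statistics. A seeded synthetic
    data generator plants ground-truth effects at every stage so the whole
    pipeline is testable without any external download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
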