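Package: m6acerna
Title: m6A-Related lncRNA Module Discovery via ceRNA Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for discovering N6-methyladenosine
    (m6A)-related long non-coding RNA modules in two-group expression studies
    such as gestational diabetes mellitus versus normal glucose tolerance.
    Screens differentially expressed lncRNAs and mRNAs from a small two-group
    profile, pools literature miRNA evidence into a consensus list, assembles a
    tripartite lncRNA-miRNA-mRNA competing-endogenous-RNA network, filters
    confidence-weighted protein-protein interaction edges and detects dense
    complexes with an MCODE-style algorithm, screens lncRNAs for Pearson
    correlation with the 21 m6A regulators, extracts a four-node
    lncRNA/regulator/miRNA/mRNA module, and evaluates it with a linear
    support-vector-machine classifier. A synthetic-data generator with known
    ground truth emulates the statistical structure of placental expression
    cohorts for testing and calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    fgsea,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
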