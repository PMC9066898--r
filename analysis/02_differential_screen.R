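#!/usr/bin/env Rscript
# Screen differentially expressed lncRNAs (DELs) and mRNAs (DEMs) from the
# discovery profile (|log2FC| > 1 and BH-adjusted P < 0.05, Welch t on
# log2(x + 1)), and pool the literature miRNA evidence into the consensus
# DEMi list (>= 2 concordant records, contradictions excluded).

library(m6acerna)

bundle <- "results/synthetic_bundle"
profile <- read_expression_profile(file.path(bundle, "discovery_expression.tsv"),
                                   file.path(bundle, "discovery_samples.tsv"),
                                   file.path(bundle, "discovery_features.tsv"))
cfg <- threshold_config(seed = 1L)

de <- screen_differential(profile, cfg)
demis <- pool_mirna_evidence(
  read.delim(file.path(bundle, "mirna_evidence.tsv"), colClasses = "character"),
  cfg)

dir.create("results", showWarnings = FALSE)
write.table(de, "results/differential_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(demis, "results/consensus_demis.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path(bundle, "ground_truth.json"),
                             simplifyVector = TRUE)
dels <- de[de$feature_class == "lncRNA", ]
dems <- de[de$feature_class == "mRNA", ]
cat(sprintf("%d DELs, %d DEMis, and %d DEMs retained\n",
            nrow(dels), nrow(demis), nrow(dems)))
cat(sprintf("recall vs planted truth: %d/%d lncRNAs, %d/%d mRNAs; %d false positives\n",
            length(intersect(dels$feature_id, truth$de_lncrna$id)),
            nrow(truth$de_lncrna),
            length(intersect(dems$feature_id, truth$de_mrna$id)),
            nrow(truth$de_mrna),
            length(setdiff(de$feature_id,
                           c(truth$de_lncrna$id, truth$de_mrna$id)))))
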