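#!/usr/bin/env Rscript
# Over-representation analysis of the ceRNA-network mRNAs against the
# gene-set collection (hypergeometric upper tail, raw P < 0.05 cutoff,
# BH-adjusted P reported alongside).

library(m6acerna)

bundle <- "results/synthetic_bundle"
cfg <- threshold_config(seed = 1L)
net <- import_network("results/cerna_network.graphml", "GraphML")
sets <- read_gmt(file.path(bundle, "gene_sets.gmt"))

query <- net$nodes$id[net$nodes$type == "mRNA"]
res <- overrepresentation(query, sets, cfg)
write.table(res, "results/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("query of %d network mRNAs against %d sets: %d enriched at raw P < %.2f\n",
            length(query), length(sets$sets), nrow(res), cfg$enrich_alpha))
if (nrow(res) > 0) {
  cat(sprintf("top set: %s (k/K = %d/%d, P = %.3g, BH = %.3g)\n",
              res$set[1], res$k[1], res$K[1], res$p_raw[1], res$p_adj[1]))
}
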