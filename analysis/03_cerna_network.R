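#!/usr/bin/env Rscript
# Assemble the lncRNA-miRNA-mRNA ceRNA network from the screened DELs/DEMs,
# the consensus DEMis, and the interaction table; export it (SIF + GraphML)
# and tabulate node degrees.

library(m6acerna)

bundle <- "results/synthetic_bundle"
de <- read.delim("results/differential_records.tsv", colClasses = "character")
demis <- read.delim("results/consensus_demis.tsv", colClasses = "character")
inter <- read_interaction_table(file.path(bundle, "interactions.tsv"))

net <- assemble_cerna(de[de$feature_class == "lncRNA", ], demis,
                      de[de$feature_class == "mRNA", ], inter)
export_network(net, "results/cerna_network.sif", "SIF")
export_network(net, "results/cerna_network.graphml", "GraphML")
deg <- node_degree_table(net)
write.table(deg, "results/cerna_degrees.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tt <- table(factor(net$nodes$type, levels = c("lncRNA", "miRNA", "mRNA")))
cat(sprintf("ceRNA network: %d lncRNA, %d miRNA, %d mRNA nodes and %d edges\n",
            tt[["lncRNA"]], tt[["miRNA"]], tt[["mRNA"]], nrow(net$edges)))
if (nrow(net$nodes) > 0) {
  top <- top_degree_node(net, "lncRNA")
  cat(sprintf("hub lncRNA: %s (degree %d)\n", top, deg$degree[deg$id == top]))
}
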