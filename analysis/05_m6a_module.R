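#!/usr/bin/env Rscript
# Screen the retained DELs for Pearson correlation with the 21 m6A
# regulators (|PCC| > 0.9, P < 0.01, both groups pooled), build the
# m6A-related subnetwork, and extract the four-node module: the
# highest-degree m6A-related lncRNA, its strongest-correlated regulator,
# the top-PPI-degree gene, and their shared miRNA.

library(m6acerna)

bundle <- "results/synthetic_bundle"
cfg <- threshold_config(seed = 1L)
profile <- read_expression_profile(file.path(bundle, "discovery_expression.tsv"),
                                   file.path(bundle, "discovery_samples.tsv"),
                                   file.path(bundle, "discovery_features.tsv"))
de <- read.delim("results/differential_records.tsv", colClasses = "character")
net <- import_network("results/cerna_network.graphml", "GraphML")
ppi_deg <- read.delim("results/ppi_degrees.tsv")

cors <- screen_m6a_lncrnas(profile, de[de$feature_class == "lncRNA", ],
                           m6a_regulators(), cfg)
write.table(cors, "results/m6a_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("m6A screen: %d retained pairs over %d m6A-related lncRNAs\n",
            nrow(cors), length(unique(cors$lncrna))))

core <- intersect(unique(cors$lncrna),
                  net$nodes$id[net$nodes$type == "lncRNA"])
cat(sprintf("core m6A-related DELs in the ceRNA network: %s\n",
            paste(core, collapse = ", ")))
sub <- attach_regulators(extract_subnetwork(net, core), cors)
export_network(sub, "results/m6a_subnetwork.graphml", "GraphML")

module <- extract_m6a_module(net, ppi_deg, cors)
print(module)
jsonlite::write_json(unclass(module), "results/m6a_module.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
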