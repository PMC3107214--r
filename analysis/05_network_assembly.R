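#!/usr/bin/env Rscript
# Assemble the motif-category -> gene regulatory network: keep motifs that
# are enriched in a group (p < 0.05) and have at least one well-matched site
# there, consolidate related motifs into categorical regulator nodes, and
# connect each category to the group genes whose promoters score >= 0.95.
# Exports DOT (double circles for motif categories, ovals for genes, edges
# colored by temporal group), GraphML and an edge-list TSV.

library(grnflow)

out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scores_df <- read.delim("results/motifs/score_table.tsv")
scores <- as.matrix(scores_df[, -1])
rownames(scores) <- scores_df$gene

assign <- read.delim("results/profiles/assignments.tsv")
assign <- assign[nzchar(assign$group), ]
groups <- setNames(assign$group, assign$gene)

enr <- read.delim("results/motifs/enrichment.tsv")

retained <- prune_unmatched_motifs(enr, scores, groups,
                                   threshold = 0.95, alpha = 0.05)
message("retained (group, motif) pairs after pruning: ", nrow(retained))

# consolidate the NF-kB-like matrices into one categorical regulator node
cmap <- c(SYN_NFKB = "NF-kB", SYN_RELA = "NF-kB")
net <- build_network(retained, scores, groups, category_map = cmap,
                     threshold = 0.95)
print(net)

export_network(net, file.path(out, "network.dot"), "dot")
export_network(net, file.path(out, "network.graphml"), "graphml")
export_network(net, file.path(out, "network_edges.tsv"), "tsv")

# the edge-list TSV is a faithful serialization
stopifnot(identical(read_network_tsv(file.path(out, "network_edges.tsv"))$edges,
                    net$edges))
message("done: ", out)
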