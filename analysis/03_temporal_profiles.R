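#!/usr/bin/env Rscript
# Short time-series profiling of the discriminant genes: enumerate the 25
# bounded-step model profiles for 3 time points, assign each gene to its
# best-correlated profile on the reference (log2-fold-vs-0h) scale, test
# profile gene counts against the time-permutation null, and label the
# significant profiles A, B, C, ... by descending gene count.

library(grnflow)

out <- "results/profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

m <- read_expression_tsv("results/sim/expression.tsv",
                         "results/sim/samples.tsv")
filtered <- filter_noise(m)
discriminant <- readLines("results/de/discriminant_genes.txt")

series <- mean_time_series(filtered, "IL1B")[discriminant, , drop = FALSE]
series <- to_reference_scale(series)

profiles <- enumerate_profiles(T = ncol(series), c = 2)
message("model profiles: ", nrow(profiles$levels))
assignment <- assign_genes(series, profiles)
significance <- profile_significance(series, profiles, alpha = 0.05)
grouping <- group_profiles(assignment, significance)
message(nrow(grouping$groups), " significant profiles (",
        length(grouping$gene_groups), " genes grouped, ",
        length(grouping$unassigned), " unassigned)")
for (i in seq_len(nrow(grouping$groups))) {
  lv <- profiles$levels[as.character(grouping$groups$profile_id[i]), ]
  message("  group ", grouping$groups$label[i], ": profile (",
          paste(lv, collapse = ","), "), ", grouping$groups$count[i],
          " genes")
}

write.table(significance, file.path(out, "profile_significance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
a <- assignment$assignments
a$group <- grouping$gene_groups[a$gene]
a$group[is.na(a$group)] <- ""
adj <- series[a$gene, , drop = FALSE]
colnames(adj) <- paste0("adj_", colnames(adj), "h")
write.table(cbind(a, adj), file.path(out, "assignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("done: ", out)
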