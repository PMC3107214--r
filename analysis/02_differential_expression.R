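#!/usr/bin/env Rscript
# Differential expression on the simulated time course: noise filtering,
# gene-level consolidation, moderated t over the three pairwise time-point
# contrasts, selection at |fold change| >= 2 and p <= 0.05, and the
# hierarchical ordering of the discriminant genes for heatmap layout.

library(grnflow)

sim_dir <- "results/sim"
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

m <- read_expression_tsv(file.path(sim_dir, "expression.tsv"),
                         file.path(sim_dir, "samples.tsv"))
filtered <- filter_noise(m, cutoff = 6.0)
message("noise filter removed ", length(attr(filtered, "removed")),
        " of ", nrow(m$values), " probes (log2 < 6 on >= 7 of 9 chips)")
writeLines(attr(filtered, "removed"), file.path(out, "removed_probes.txt"))

ann <- read_annotation_tsv(file.path(sim_dir, "annotation.tsv"))
genes <- consolidate_probesets(filtered, ann)

fit <- fit_moderated_model(genes, default_contrasts("IL1B"))
message(sprintf("variance shrinkage: d0 = %.2f, s0^2 = %.4f",
                fit$model$d0, fit$model$s0_sq))
crit <- selection_criteria(fc_threshold = 2.0, p_threshold = 0.05)
tab <- fit$table
tab$selected <- FALSE
for (cn in unique(tab$contrast)) {
  sel <- select_differential(fit, crit, cn)
  tab$selected[tab$contrast == cn & tab$feature %in% sel] <- TRUE
  message(cn, ": ", length(sel), " genes at |FC| >= 2, p <= 0.05")
}
write.table(tab, file.path(out, "de_table.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

volcano <- data.frame(feature = tab$feature, contrast = tab$contrast,
                      log2_fc = tab$log2_fc,
                      neg_log10_p = -log10(pmax(tab$p_value, 1e-300)),
                      selected = tab$selected)
write.table(volcano, file.path(out, "volcano.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

discriminant <- discriminant_features(fit, crit)
message("discriminant list (selected in >= 1 contrast): ",
        length(discriminant), " genes")
writeLines(discriminant, file.path(out, "discriminant_genes.txt"))

ord <- hierarchical_order(genes$values[discriminant, , drop = FALSE])
write.table(data.frame(order = seq_along(ord$order), gene = ord$order),
            file.path(out, "cluster_order.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("done: ", out)
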