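#!/usr/bin/env Rscript
# Simulate the study dataset: a 3-time-point (0, 1, 8 h) x 3-replicate log2
# expression matrix with five temporal response groups plus unresponsive
# genes, and a matching promoter universe with binding sites planted in two
# of the groups (an NF-kB-like motif in the sustained group A, an IRF-like
# motif in the gradual group C). Everything downstream reads the TSV/FASTA
# written here.

library(grnflow)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

motifs <- read_jaspar_pfm(system.file("extdata", "synthetic_motifs.pfm",
                                      package = "grnflow"))

design <- simulation_design(
  groups = default_groups(n_genes = 30, effect = 1.0),
  n_null = 850,
  plant_specs = list(
    list(motif_id = "SYN_NFKB", group = "A", probability = 0.9,
         site = "pwm-sampled"),
    list(motif_id = "SYN_IRF", group = "C", probability = 0.8,
         site = "pwm-sampled")),
  seed = 20260928L)

sim <- simulate_expression(design)
message("simulated ", nrow(sim$matrix$values), " genes x ",
        ncol(sim$matrix$values), " samples (",
        sum(sim$truth$group != "null"), " responsive)")
write_expression_tsv(sim$matrix, file.path(out, "expression.tsv"),
                     file.path(out, "samples.tsv"))
write.table(sim$truth, file.path(out, "expression_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# identity probeset->gene annotation (the simulator works at gene level)
ann <- data.frame(probeset_id = rownames(sim$matrix$values),
                  gene_symbol = rownames(sim$matrix$values),
                  gene_id = "", refseq = "")
write.table(ann, file.path(out, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

prom <- simulate_promoters(design, motifs)
message("planted ", nrow(prom$truth), " sites over ",
        length(prom$promoters$sequences), " promoters")
write_promoters(prom$promoters, file.path(out, "promoters.fa"))
write.table(prom$truth, file.path(out, "site_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("done: ", out)
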