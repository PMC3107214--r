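#!/usr/bin/env Rscript
# Promoter motif analysis: scan every promoter (region -950..+50 relative to
# the TSS) with the motif library, then z-test each temporal group's mean
# best-site score against the whole promoter universe, and summarize the
# fraction of each group's genes carrying a well-matched site (score >=
# 0.95) per motif.

library(grnflow)

out <- "results/motifs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

motifs <- read_jaspar_pfm(system.file("extdata", "synthetic_motifs.pfm",
                                      package = "grnflow"))
promoters <- read_promoters("results/sim/promoters.fa")
scores <- scan_universe(motifs, promoters)
write.table(data.frame(gene = rownames(scores), scores),
            file.path(out, "score_table.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

assign <- read.delim("results/profiles/assignments.tsv")
assign <- assign[nzchar(assign$group), ]
groups <- setNames(assign$group, assign$gene)

enr <- do.call(rbind, lapply(sort(unique(groups)), function(lab) {
  fg <- names(groups)[groups == lab]
  res <- enrichment_ztest(scores, fg)
  res$name <- vapply(res$motif_id, function(id) motifs[[id]]$name,
                     character(1))
  cbind(group = lab, res[, c("name", "motif_id", "z", "p", "fg_mean",
                             "bg_mean", "bg_sd", "n_fg")])
}))
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- enr[!duplicated(enr$group), ]
for (i in seq_len(nrow(top))) {
  message(sprintf("group %s: top motif %s (z = %.2f, p = %.2g)",
                  top$group[i], top$motif_id[i], top$z[i], top$p[i]))
}

fm <- fraction_matrix(scores, groups, threshold = 0.95)
write.table(data.frame(motif_id = rownames(fm), fm),
            file.path(out, "fraction_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("done: ", out)
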