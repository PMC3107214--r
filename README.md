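# grnflow

Inference of inflammatory gene regulatory networks from short time-course
transcription profiling.

## The problem

Acute inflammatory stimuli (cytokines such as IL-1β acting on primary
cells) reprogram transcription within hours. A typical experiment profiles
expression at a handful of time points (here 0, 1 and 8 h) with three
biological replicates — too few samples for per-gene statistics to be
stable, and too few time points for generic clustering to be meaningful.
`grnflow` implements the analysis chain used to turn such data into a
candidate regulatory network:

1. **Noise filtering and gene consolidation** of a normalized log2
   expression matrix (a probe is dropped when it falls below the noise
   floor, log2 = 6, on at least 7 of 9 chips; probesets of one gene are
   averaged).
2. **Moderated t-statistics** with empirical-Bayes variance shrinkage:
   per-gene variances s² are shrunk toward a prior s₀² with prior degrees
   of freedom d₀ estimated by method of moments on the log variances,
   t = log₂FC / (s̃·√(1/nₐ+1/n_b)), referred to t(d₀+d). Genes are selected
   at |FC| ≥ 2 and p ≤ 0.05 per pairwise time contrast; an
   expected-number-of-false-positives cutoff (m·t ≤ EFP) is available.
3. **Short time-series profiling**: genes (as log₂ fold change vs 0 h) are
   assigned to enumerated bounded-step model profiles ((2c+1)^(T−1) = 25
   for T = 3, c = 2) by maximal correlation; profile gene counts are tested
   against the time-permutation null (with a permutation-calibrated
   binomial fallback, since T = 3 admits only 6 orderings), and significant
   profiles become groups A, B, C, …
4. **Promoter motif enrichment**: JASPAR-format position frequency
   matrices are scanned over fixed-length promoters (−950..+50 relative to
   the TSS) on both strands; window scores are min-max normalized so the
   consensus scores exactly 1, and each group's mean best-site score is
   compared to the promoter universe by z-test,
   z = (s̄_fg − μ_bg)/(σ_bg/√n_fg).
5. **Network assembly**: motifs enriched in a group (p < 0.05) with at
   least one well-matched site (score ≥ 0.95) are consolidated into
   categorical regulator nodes (e.g. an NF-κB category) and connected to
   the group genes carrying well-matched sites; exports to DOT, GraphML and
   edge-list TSV.

A fully seeded synthetic-data module (`simulation_design()`,
`simulate_expression()`, `simulate_promoters()`,
`end_to_end_benchmark()`) generates matrices and promoter universes with
known ground truth, so the whole chain is testable offline. The bundled
motif library (`inst/extdata/synthetic_motifs.pfm`) is synthetic:
hand-built matrices named after the factor families they imitate, not real
JASPAR entries.

## Worked example

```r
library(grnflow)
motifs <- read_jaspar_pfm(system.file("extdata", "synthetic_motifs.pfm",
                                      package = "grnflow"))

design <- simulation_design(
  groups = default_groups(n_genes = 30), n_null = 850,
  plant_specs = list(list(motif_id = "SYN_NFKB", group = "A",
                          probability = 0.9, site = "pwm-sampled")),
  seed = 101L)

sim  <- simulate_expression(design)
expr <- filter_noise(sim$matrix)
fit  <- fit_moderated_model(expr, default_contrasts("IL1B"))
sel  <- discriminant_features(fit, selection_criteria(2.0, 0.05))

series     <- to_reference_scale(mean_time_series(expr, "IL1B")[sel, ])
profiles   <- enumerate_profiles(3, c = 2)
assignment <- assign_genes(series, profiles)
grouping   <- group_profiles(assignment,
                             profile_significance(series, profiles))

prom   <- simulate_promoters(design, motifs)
scores <- scan_universe(motifs, prom$promoters)
fg     <- names(grouping$gene_groups)[grouping$gene_groups == "A"]
enr    <- enrichment_ztest(scores, fg)
head(enr, 3)
```

Output:

```
selected 150 discriminant genes
  profile_id label count
1         18     A    30
2         22     B    30
3         19     C    20
         motif_id    z        p fg_mean bg_mean  bg_sd n_fg
SYN_NFKB SYN_NFKB 6.42 6.61e-11   0.869   0.799 0.0590   30
SYN_AP1   SYN_AP1 1.89 2.96e-02   0.881   0.860 0.0621   30
SYN_RELA SYN_RELA 1.42 7.81e-02   0.795   0.781 0.0545   30
```

All 150 planted responders pass the ±2-fold / p ≤ 0.05 rule; three of the
five planted temporal shapes reach significance (with three time points,
shapes that map into each other under time permutation — delayed vs
transient induction — are only weakly identifiable; see the methods
vignette). The motif planted in group A ranks first by a wide margin
(z = 6.4 against a universe mean score of 0.80). Building the network then
connects the NF-κB category to the group-A genes whose promoters carry a
well-matched (≥ 0.95) site:

```r
retained <- prune_unmatched_motifs(
  cbind(group = "A", enr[, c("motif_id", "p")]), scores,
  grouping$gene_groups)
net <- build_network(retained, scores, grouping$gene_groups,
                     category_map = c(SYN_NFKB = "NF-kB"))
net
#> regulatory_network: 2 motif categories, 11 genes, 12 edges
export_network(net, "network.dot", "dot")
```

## The analysis workflow

`analysis/` contains the numbered drivers that run the full study on the
simulated dataset, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R                 # expression + promoters + truth
Rscript analysis/02_differential_expression.R  # filter, moderated t, selection
Rscript analysis/03_temporal_profiles.R        # profile assignment + groups
Rscript analysis/04_motif_enrichment.R         # scanning, z-tests, fractions
Rscript analysis/05_network_assembly.R         # pruning, categories, exports
Rscript analysis/06_benchmark_and_comparison.R # truth metrics, set comparison
```

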