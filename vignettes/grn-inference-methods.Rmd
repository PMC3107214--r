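---
title: "Inferring inflammatory regulatory networks from short time-course expression data"
author: "grnflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring inflammatory regulatory networks from short time-course expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnflow)
```

# Overview

`grnflow` implements a systems workflow for reconstructing candidate gene
regulatory networks from short stimulation time courses, the setting typical
of acute inflammatory challenges (e.g. cytokine stimulation of primary cells
sampled at 0, 1 and 8 h with three biological replicates). The chain is:

1. **Expression preprocessing** — noise filtering of a normalized log2
   matrix and probeset-to-gene consolidation.
2. **Differential expression** — empirical-Bayes moderated t-statistics over
   pairwise time-point contrasts, selection at a fold-change/p-value rule,
   and control of the expected number of false positives.
3. **Temporal profiling** — assignment of genes to enumerated bounded-step
   model profiles with permutation significance, yielding co-expressed
   groups (A, B, C, ...).
4. **Promoter motif analysis** — position-weight-matrix scanning of
   fixed-length promoters with min-max-normalized scores and z-test
   enrichment of each group against the promoter universe.
5. **Network assembly** — a bipartite graph connecting motif *categories*
   (consolidating matrices bound by homologous factor families) to the
   group genes carrying well-matched sites.

A seeded synthetic-data module generates expression matrices and promoter
universes with known ground truth, so every stage — and the pipeline end to
end — is testable without any external download.

# Differential expression

## Variance shrinkage

With three replicates per time point, per-gene variance estimates are
unstable. The moderated t-statistic pools information across genes: the
per-gene residual variance $s_g^2$ (pooled within the (condition, time)
groups, $d$ residual degrees of freedom) is shrunk toward a prior variance
$s_0^2$ with prior degrees of freedom $d_0$,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},
\qquad
t_g = \frac{\bar x_{gA} - \bar x_{gB}}
           {\tilde s_g \sqrt{1/n_A + 1/n_B}},$$

with two-sided p-values from a t distribution on $d_0 + d$ degrees of
freedom. $(d_0, s_0^2)$ are estimated by method of moments on the log
sample variances under the scaled-F model: the excess spread of
$\log s_g^2$ beyond $\psi'(d/2)$ identifies $d_0$ through the trigamma
function, and the location identifies $s_0^2$. $d_0$ is capped at $10^6$,
which represents the infinite-shrinkage limit ($\tilde s_g^2 \equiv s_0^2$)
finitely; fixing $d_0 = 0$ recovers the ordinary pooled-variance t-test
exactly. Both limits are asserted in the test suite, and the estimates are
cross-checked against an independent empirical-Bayes implementation.

## Selection and multiplicity

Genes are selected per contrast when $|\log_2 \mathrm{FC}| \ge \log_2 2$
**and** $p \le 0.05$, both boundaries inclusive; the *discriminant list* is
the union over the three pairwise contrasts (1 h vs 0 h, 8 h vs 0 h, 8 h vs
1 h). The expected-false-positive rule is the bound $m \cdot t \le
\mathrm{EFP}$: over $m$ tests, the largest cutoff $t$ keeping the expected
null count at the target. It is deliberately simple (no p-value ordering),
and is provided alongside, not composed with, the fold-change rule.

An open question in designs like this is whether an omnibus ANOVA should
gate genes before the pairwise tests; `grnflow` applies the per-contrast
moderated t directly, since the published selection rule is expressed per
comparison.

# Temporal profiles

A model profile over $T$ time points is an integer level vector starting at
0 whose step change is bounded by $c$ units; all $(2c+1)^{T-1}$ profiles
are enumerated (for $T = 3$, $c = 2$: 25 profiles). Gene series are first
re-expressed relative to the first time point (log2 fold change vs
baseline), then assigned to the profile with maximal Pearson correlation;
ties go to the lowest profile id and constant series to the flat profile.
Because correlation is scale-free, profiles that are positive scalar
multiples of each other form one equivalence class and all mass lands on
the class's lowest-id (canonical) member — "100% assignment accuracy" for
noiseless data therefore means recovery of the canonical class
representative. For $T > 5$ a greedy max-min representative selection
(seeded by the profile of largest total change, distance $1 - r$) is
available; at $T = 3$ the full enumeration is used.

## Significance

Profile gene counts are tested against the time-permutation null: every
ordering of the $T$ time points is applied identically to all genes
(re-referencing to the permuted first point), assignments are recomputed,
and the permutation p-value is the fraction of orderings reaching the
observed count, Bonferroni-corrected over profiles. At $T = 3$ only $3! =
6$ orderings exist, so the smallest attainable p is $1/6$ and the
permutation test alone can never reach a corrected 0.05. The package
therefore also reports a parametric fallback: a binomial tail
$P(X \ge k_j)$ with per-profile success probability estimated as profile
$j$'s **average count over the permutation ensemble** divided by the number
of genes. We deliberately do not use a uniform $1/\#\text{profiles}$ rate:
the correlation assignment concentrates genes on canonical profiles even
under the null, and a uniform rate would flag those systematically. Using
the permutation-averaged expectation keeps the fallback calibrated (the
null false-flag rate stays at or below $\alpha$ in the test suite) while
still detecting genuinely over-populated profiles. The output labels which
criterion (permutation, binomial, or both) flagged each profile.

A consequence worth knowing: shapes that map into each other under a time
permutation — e.g. delayed induction $(0,0,2)$ and transient induction
$(0,2,0)$, which swap when the 1 h and 8 h columns are exchanged — inflate
each other's null expectation, and with only three time points such
profile pairs may fail to reach significance even for clean data. This is
a genuine identifiability limit of three-point designs, not an
implementation artifact; adding time points dissolves it.

Significant profiles are labeled A, B, C, ... in descending gene count;
genes in non-significant profiles are reported unassigned.

# Promoter motif analysis

## Scoring

Promoters are fixed-length sequences (default region $-950..+50$ relative
to the TSS, 1001 nt). A motif is a position frequency matrix; after adding
a pseudocount (default 0.01 per cell, guarding sparse matrices) and
normalizing per position, the raw score of an $L$-mer is the sum of the
observed-base frequencies. Scores are min-max normalized,

$$S' = \frac{S - S_{\min}}{S_{\max} - S_{\min}},$$

so the best attainable match (consensus) scores exactly 1 and the worst
(anti-consensus) exactly 0. The additive min-max form is one of several
variants in use by promoter-scanning tools; it is chosen here because it
pins both endpoints of the published 0-1 relative scale and makes the
"well-matched site" rule (score $\ge 0.95$, inclusive) exactly testable.
Windows containing N are skipped rather than averaged (conservative).
Scanning covers both strands (minus strand via the reverse-complemented
matrix); ties prefer the smaller start position, then the plus strand. A
gene's score for a motif is its best window anywhere in the promoter.

## Enrichment

For a foreground gene set (a temporal group), the mean best-site score is
compared to the whole promoter universe by z-test:

$$z = \frac{\bar s_{\mathrm{fg}} - \mu_{\mathrm{bg}}}
          {\sigma_{\mathrm{bg}} / \sqrt{n_{\mathrm{fg}}}},$$

with the population standard deviation over all universe genes and a
one-tailed (enrichment-only) normal p-value. The background is the supplied
promoter universe itself — a genome-wide background cannot be bundled, so
calibration statements are relative to the universe the user scans. The
null calibration of this test (random foregrounds of 25 genes from a
simulated 1000-promoter universe give $P(p \le 0.05) \approx 0.05$) is
checked in the acceptance suite; mild anti-conservativity can appear for
very small foregrounds because best-score distributions are left-skewed.

# Network assembly

A motif survives for a group only when it is enriched there ($p$ strictly
below $\alpha = 0.05$, matching the convention "p-values of less than
0.05") *and* at least one group gene carries a well-matched site; enriched
motifs with no well-matched site anywhere are omitted. Retained motifs are
mapped to categorical regulator nodes — matrices recognized by homologous
factor families are merged (the shipped default consolidates
myeloid-zinc-finger-domain and NF-kB-family matrices under one NF-kB
category; the map is user-overridable and motifs absent from it keep their
own name). Edges connect a category to every group gene scoring at least
the match threshold under any of the category's motifs; parallel support
is recorded on the edge (`motif_ids`, `best_score`) rather than
duplicated. Edges carry the temporal group, and exports color them
conventionally (A red, B green, C blue, D black, E purple). DOT, GraphML
and edge-list TSV exports carry identical information; the TSV round-trips
to an identical edge set and is written at full precision for that reason.

Whether an edge should require enrichment in the gene's *own* group or in
any group is ambiguous in principle; `grnflow` requires the gene's own
group (the stricter reading), which makes every edge reproducible from
(enrichment table, score table, threshold) alone.

# Synthetic data and what the benchmarks mean

The generator emulates the statistical skeleton of a short cytokine
stimulation experiment, with defaults chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| time points | 0, 1, 8 h | vehicle baseline plus acute/late sampling |
| replicates | 3 | biological replicates per time point |
| baseline | $N(8, 1)$ | log2 intensity of an expressed gene |
| replicate noise | sd 0.25 | log2-scale measurement + biological noise |
| group effect | 1.0 per level | a level-2 profile step is a 4-fold change |
| groups | 5 × 30 genes | sustained, transient-slow, gradual, delayed, transient-fast |
| null genes | 850 | unresponsive background (universe ≈ 1000) |
| promoters | 1001 nt, uniform ACGT | region −950..+50 |

Planted binding sites (consensus or PWM-sampled) overwrite the background
at a uniform position on a random strand with a per-gene probability. All
stages draw from per-stage substreams derived from one global seed (the
stage name is hashed into the seed), so each stage is independently
reproducible and bit-identical across runs.

What the generator does **not** model: probe-level microarray noise
(hybridization, cross-hybridization, probe affinity), correlated noise
across genes, non-uniform genomic base composition, CpG islands, repeats,
and clustered or cooperative binding sites. Passing benchmarks therefore
demonstrate algorithmic correctness and calibration under the model, not
performance on real promoters, where background composition alone can
shift score distributions substantially.

Benchmark problem sizes (used by the tests and the acceptance script):
100 scanner oracle pairs on 60-nt sequences; 2000 foreground draws from a
1000-promoter universe; 20 seeded planted-motif runs (100-gene foreground,
planting probability 0.8, 900 background genes); 10,000-feature null for
the moderated-t calibration; 20 seeded recovery runs at the default design;
one noiseless end-to-end run for network recall. Network edge recall is
computed over *recoverable* planted edges — the host gene survived
selection and grouping and the realized (possibly PWM-sampled) site
re-scores at least the match threshold — since a sampled site below the
well-matched cutoff is invisible to any threshold-based method by
construction.

# Numerical conventions and degenerate inputs

- "Below the noise cutoff" is strict (`value < cutoff`); a value exactly at
  the cutoff counts as detectable. The 7-of-9-chips removal rule rescales
  as `ceiling(7/9 * n_samples)` for other designs.
- Probeset averaging is the arithmetic mean of log2 values (not anti-logged
  means), matching how consolidated log2 tables are reported.
- Selection boundaries are inclusive ($\ge$ 2-fold, $p \le 0.05$);
  enrichment alpha for network pruning is strict ($p < 0.05$).
- A degenerate motif whose best and worst additive scores coincide scores
  1.0 everywhere; constant gene series go to the flat profile with
  similarity 1 by convention.
- Hierarchical clustering (Euclidean, complete linkage) delegates to
  `stats::hclust`; a brute-force merge oracle in the tests pins the
  agglomeration sequence on a hand-checkable instance.
- Minus-strand window scores sum the same frequencies in reversed order, so
  plus/minus scores of a palindromic site can differ by ~1e-16; comparisons
  in the package use exact maxima, and tests allow double-precision slack.

# Limitations

- With three time points the permutation test is bounded at $p = 1/6$ and
  time-symmetric shape pairs are only weakly identifiable (see above).
- The z-test treats best-site scores as exchangeable across the universe;
  foregrounds that differ systematically in promoter composition (GC
  content, CpG islands) will confound enrichment.
- Motif categories must be curated; the default map covers only the NF-kB
  consolidation and leaves every other matrix as its own category.
- The expected-false-positive rule assumes independent tests; under strong
  correlation it controls the expectation but not the variance of the
  false-positive count.
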