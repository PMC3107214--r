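#' Simulation design emulating a short stimulation time course
#'
#' Defines the ground-truth structure of a simulated experiment: temporal
#' response groups (each a model-profile shape with a per-step log2 effect
#' size and a gene count), replicate noise, the sampling design (three time
#' points, three biological replicates by default) and, for promoter
#' simulation, the background base composition and planted binding sites.
#'
#' The defaults mirror a cytokine-stimulation study design: log2 intensities
#' around a baseline of 8 (sd 1 across genes), replicate noise sd 0.25 in
#' log2 units, time points 0, 1 and 8 h with 3 replicates each, and five
#' response groups whose shapes (sustained, transient-slow, gradual,
#' delayed, transient-fast induction) carry a per-step log2 effect of 1.0
#' (a 4-fold change at the +2 level). Promoters are 1001 nt (region -950 to
#' +50 relative to the TSS) with uniform base composition.
#'
#' @param groups List of group specs, each a list with `label`, `levels`
#'   (integer profile shape starting at 0, one entry per time point),
#'   `effect` (log2 units per unit level) and `n_genes`.
#' @param n_null Number of unresponsive (flat, no planted site) genes.
#' @param baseline_mean,baseline_sd Log2 baseline intensity distribution.
#' @param noise_sd Replicate noise sd (log2 units).
#' @param n_replicates Replicates per time point.
#' @param time_points Time points in hours.
#' @param condition Condition label of the stimulated samples.
#' @param promoter_length Promoter length in nt.
#' @param base_composition Background probabilities over A, C, G, T
#'   (must sum to 1).
#' @param plant_specs List of planting specs, each a list with `motif_id`,
#'   `group` (label), `probability` and `site` (`"consensus"` or
#'   `"pwm-sampled"`).
#' @param seed Integer seed; all generators derive per-stage substreams
#'   from it.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(
    groups = default_groups(),
    n_null = 850,
    baseline_mean = 8.0, baseline_sd = 1.0, noise_sd = 0.25,
    n_replicates = 3, time_points = c(0, 1, 8), condition = "IL1B",
    promoter_length = 1001,
    base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    plant_specs = list(), seed = 1L) {
  stopifnot(abs(sum(base_composition) - 1) < 1e-9,
            all(base_composition >= 0), noise_sd >= 0, baseline_sd >= 0,
            n_replicates >= 1, n_null >= 0)
  for (g in groups) {
    stopifnot(length(g$levels) == length(time_points), g$levels[1] == 0,
              g$n_genes >= 1)
  }
  for (ps in plant_specs) {
    stopifnot(ps$probability >= 0, ps$probability <= 1,
              ps$site %in% c("consensus", "pwm-sampled"))
  }
  structure(list(groups = groups, n_null = n_null,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 time_points = time_points, condition = condition,
                 promoter_length = promoter_length,
                 base_composition = base_composition,
                 plant_specs = plant_specs, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Default response-group shapes for a three-point time course
#'
#' Five groups of 30 genes each with a per-step log2 effect of 1.0:
#' sustained induction (0,2,2), induction then partial decay (0,2,1),
#' gradual induction (0,1,2), delayed induction (0,0,2), and transient
#' induction (0,2,0).
#'
#' @param n_genes Genes per group.
#' @param effect Log2 effect per unit profile level.
#' @return List of group specs for [simulation_design()].
#' @export
default_groups <- function(n_genes = 30, effect = 1.0) {
  shapes <- list(A = c(0, 2, 2), B = c(0, 2, 1), C = c(0, 1, 2),
                 D = c(0, 0, 2), E = c(0, 2, 0))
  lapply(names(shapes), function(lab)
    list(label = lab, levels = shapes[[lab]], effect = effect,
         n_genes = n_genes))
}

# Per-stage substream: mixes the stage name into the global seed so stages
# are reproducible independently; kept within 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483647L
}

sim_gene_table <- function(design) {
  labs <- vapply(design$groups, `[[`, character(1), "label")
  counts <- vapply(design$groups, `[[`, numeric(1), "n_genes")
  data.frame(
    gene = sprintf("G%04d", seq_len(sum(counts) + design$n_null)),
    group = c(rep(labs, counts), rep("null", design$n_null)),
    row.names = NULL)
}

#' Simulate an expression matrix with known temporal ground truth
#'
#' Each gene draws a baseline `N(baseline_mean, baseline_sd)`; its expected
#' value at time t adds `effect * level[t]` for its group's profile shape;
#' each replicate measurement adds `N(0, noise_sd)`. Fully deterministic
#' given the design seed.
#'
#' @param design A [simulation_design()].
#' @return List with `matrix` (an `expression_matrix`) and `truth` (data
#'   frame `gene`, `group`, plus the true log2 fold change at each time
#'   point, columns `lfc_<t>`).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(stage_seed(design$seed, "expression"))
  genes <- sim_gene_table(design)
  n_gene <- nrow(genes)
  tps <- design$time_points
  effects <- matrix(0, n_gene, length(tps))
  for (g in design$groups) {
    rows <- which(genes$group == g$label)
    effects[rows, ] <- matrix(g$effect * g$levels, length(rows),
                              length(tps), byrow = TRUE)
  }
  baseline <- stats::rnorm(n_gene, design$baseline_mean, design$baseline_sd)
  samples <- expand.grid(replicate = seq_len(design$n_replicates),
                         time_h = tps)
  samples <- data.frame(
    sample_id = sprintf("%s_t%g_r%d", design$condition, samples$time_h,
                        samples$replicate),
    condition = design$condition, time_h = samples$time_h,
    replicate = samples$replicate)
  vals <- matrix(NA_real_, n_gene, nrow(samples),
                 dimnames = list(genes$gene, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    t_idx <- match(samples$time_h[j], tps)
    noise <- if (design$noise_sd > 0) {
      stats::rnorm(n_gene, 0, design$noise_sd)
    } else 0
    vals[, j] <- baseline + effects[, t_idx] + noise
  }
  truth <- cbind(genes, as.data.frame(effects))
  names(truth)[-(1:2)] <- paste0("lfc_", tps)
  list(matrix = expression_matrix(vals, samples), truth = truth)
}

sample_site <- function(motif, kind) {
  if (kind == "consensus") return(consensus_sequence(motif))
  f <- motif_freq(motif)
  paste(apply(f, 1, function(p) sample(BASES, 1, prob = p)), collapse = "")
}

#' Simulate a promoter universe with planted binding sites
#'
#' Background bases are drawn i.i.d. from the design's base composition.
#' For each planting spec, every gene of the target group receives --- with
#' the stated probability --- one site (motif consensus or a PWM-sampled
#' realization) written over the background at a uniform random valid
#' position on a random strand. Deterministic given the design seed.
#'
#' @param design A [simulation_design()].
#' @param motifs Named list of `motif_matrix` objects covering every
#'   `plant_specs` motif id.
#' @return List with `promoters` (a `promoter_set` whose region ends at +50
#'   relative to the TSS) and `truth` (data frame `gene`, `motif_id`,
#'   `position`, `strand` of the planted sites).
#' @export
simulate_promoters <- function(design, motifs) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(stage_seed(design$seed, "promoters"))
  genes <- sim_gene_table(design)
  len <- design$promoter_length
  mat <- matrix(sample(BASES, nrow(genes) * len, replace = TRUE,
                       prob = design$base_composition),
                nrow(genes), len)
  truth <- list()
  for (ps in design$plant_specs) {
    motif <- motifs[[ps$motif_id]]
    if (is.null(motif)) stop("no motif matrix for ", ps$motif_id)
    L <- motif_length(motif)
    if (L > len) stop("motif ", ps$motif_id, " longer than the promoter")
    rows <- which(genes$group == ps$group)
    for (r in rows) {
      if (stats::runif(1) > ps$probability) next
      pos <- sample.int(len - L + 1, 1)
      strand <- sample(c("+", "-"), 1)
      site <- sample_site(motif, ps$site)
      if (strand == "-") site <- reverse_complement(site)
      mat[r, pos:(pos + L - 1)] <- strsplit(site, "")[[1]]
      truth[[length(truth) + 1]] <- data.frame(
        gene = genes$gene[r], motif_id = ps$motif_id, position = pos,
        strand = strand, row.names = NULL)
    }
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- genes$gene
  truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(gene = character(), motif_id = character(),
               position = integer(), strand = character())
  }
  list(promoters = promoter_set(seqs, region = c(50 - len + 1, 50)),
       truth = truth)
}

#' Run the full inference pipeline on a simulated dataset and score it
#'
#' Simulates expression and promoters from the design, runs noise filtering,
#' moderated-t differential expression, temporal-profile assignment and
#' significance, promoter scanning, per-group enrichment, pruning and
#' network assembly, then scores every stage against the ground truth.
#'
#' @param design A [simulation_design()].
#' @param motifs Named list of `motif_matrix` objects scanned against the
#'   promoters (must include all planted motifs).
#' @param criteria A [selection_criteria()] for the differential-expression
#'   stage.
#' @param match_threshold Well-matched-site score threshold (default 0.95).
#' @param alpha Significance level for profiles and enrichment (default
#'   0.05).
#' @return List with the intermediate objects (`fit`, `selected`,
#'   `assignment`, `significance`, `grouping`, `scores`, `enrichment`,
#'   `network`) and `metrics`: DE sensitivity/specificity, profile
#'   assignment accuracy, per-group rank of the planted motif, and network
#'   edge precision/recall against the planted truth.
#' @export
end_to_end_benchmark <- function(design, motifs,
                                 criteria = selection_criteria(),
                                 match_threshold = 0.95, alpha = 0.05) {
  sim <- simulate_expression(design)
  filtered <- filter_noise(sim$matrix)
  contrasts <- default_contrasts(design$condition, design$time_points)
  fit <- fit_moderated_model(filtered, contrasts)
  selected <- discriminant_features(fit, criteria)

  truth <- sim$truth
  responsive <- truth$gene[truth$group != "null"]
  nulls <- truth$gene[truth$group == "null"]
  de_sens <- if (length(responsive)) {
    mean(responsive %in% selected)
  } else NA_real_
  de_fpr <- if (length(nulls)) mean(nulls %in% selected) else NA_real_

  # temporal profiling of the selected genes
  series_all <- mean_time_series(filtered, design$condition)
  sel_series <- to_reference_scale(series_all[intersect(selected,
                                                        rownames(series_all)),
                                              , drop = FALSE])
  profiles <- enumerate_profiles(length(design$time_points), c = 2)
  assignment <- assign_genes(sel_series, profiles)
  significance <- profile_significance(sel_series, profiles, alpha = alpha,
                                       seed = stage_seed(design$seed,
                                                         "permutation"))
  grouping <- group_profiles(assignment, significance)

  # accuracy: a responsive gene is correct when assigned to a profile whose
  # level vector matches its group's true shape (up to the positive scaling
  # correlation cannot distinguish)
  shape_of <- function(lab) {
    for (g in design$groups) if (g$label == lab) return(g$levels)
    NULL
  }
  correct <- 0; scored <- 0
  lv <- profiles$levels
  for (i in seq_len(nrow(assignment$assignments))) {
    gene <- assignment$assignments$gene[i]
    lab <- truth$group[match(gene, truth$gene)]
    shape <- shape_of(lab)
    if (is.null(shape)) next
    scored <- scored + 1
    assigned_lv <- lv[as.character(assignment$assignments$profile_id[i]), ]
    correct <- correct + (profile_cor(assigned_lv, shape) > 1 - 1e-9)
  }
  profile_acc <- if (scored) correct / scored else NA_real_

  # promoter scanning and per-group enrichment
  prom <- simulate_promoters(design, motifs)
  scores <- scan_universe(motifs, prom$promoters)
  gene_groups <- grouping$gene_groups
  enr <- list()
  for (lab in unique(gene_groups)) {
    fg <- names(gene_groups)[gene_groups == lab]
    res <- enrichment_ztest(scores, fg)
    res$group <- lab
    enr[[lab]] <- res
  }
  enrichment <- if (length(enr)) do.call(rbind, enr) else NULL

  planted_rank <- NULL
  if (!is.null(enrichment) && length(design$plant_specs)) {
    planted_rank <- vapply(design$plant_specs, function(ps) {
      # rank of the planted motif among the enrichment p-values of the
      # temporal group its host genes were assigned to
      host <- truth$gene[truth$group == ps$group]
      host_labels <- gene_groups[names(gene_groups) %in% host]
      if (!length(host_labels)) return(NA_real_)
      lab <- names(sort(table(host_labels), decreasing = TRUE))[1]
      sub <- enrichment[enrichment$group == lab, , drop = FALSE]
      match(ps$motif_id, sub$motif_id)
    }, numeric(1))
  }

  network <- NULL; edge_precision <- NA_real_; edge_recall <- NA_real_
  if (!is.null(enrichment) && nrow(enrichment)) {
    retained <- prune_unmatched_motifs(
      enrichment[, c("group", "motif_id", "p")], scores, gene_groups,
      threshold = match_threshold, alpha = alpha)
    network <- build_network(retained, scores, gene_groups,
                             category_map = default_category_map(),
                             threshold = match_threshold)
    if (nrow(prom$truth)) {
      cat_of <- function(m) apply_category_map(m, default_category_map())
      # recoverable planted edges: the host gene survived grouping and the
      # realized site re-scores at least the match threshold
      seen <- prom$truth[prom$truth$gene %in% names(gene_groups), ,
                         drop = FALSE]
      realized <- scores[cbind(seen$gene, seen$motif_id)]
      seen <- seen[realized >= match_threshold, , drop = FALSE]
      truth_edges <- unique(paste(cat_of(seen$motif_id), seen$gene))
      got_edges <- paste(network$edges$category, network$edges$gene)
      if (length(got_edges)) {
        edge_precision <- mean(got_edges %in% truth_edges)
      }
      if (length(truth_edges)) {
        edge_recall <- mean(truth_edges %in% got_edges)
      }
    }
  }

  list(fit = fit, selected = selected, assignment = assignment,
       significance = significance, grouping = grouping, scores = scores,
       enrichment = enrichment, network = network,
       truth = list(expression = truth, sites = prom$truth),
       metrics = list(de_sensitivity = de_sens, de_fpr = de_fpr,
                      profile_accuracy = profile_acc,
                      planted_motif_rank = planted_rank,
                      edge_precision = edge_precision,
                      edge_recall = edge_recall))
}
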