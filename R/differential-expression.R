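#' Define a two-group contrast between (condition, time) cells
#'
#' @param name Contrast label, e.g. `"1v0"`.
#' @param group_a,group_b Lists with elements `condition` and `time_h`
#'   identifying the two sample groups; the log2 fold change is
#'   mean(group_a) - mean(group_b).
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(name, group_a, group_b) {
  stopifnot(is.character(name), length(name) == 1)
  if (identical(group_a, group_b)) stop("group_a and group_b must differ")
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "contrast_spec")
}

#' Default pairwise time-point contrasts
#'
#' The three pairwise comparisons among the vehicle (0 h), 1 h and 8 h time
#' points of a single stimulated condition.
#'
#' @param condition Condition label shared by all time points.
#' @param times Numeric vector of the three time points (hours).
#' @return List of [contrast_spec()] objects named `1v0`, `8v0`, `8v1` (using
#'   the supplied times).
#' @export
default_contrasts <- function(condition, times = c(0, 1, 8)) {
  stopifnot(length(times) == 3)
  t0 <- times[1]; t1 <- times[2]; t2 <- times[3]
  mk <- function(a, b) contrast_spec(
    paste0(a, "v", b),
    group_a = list(condition = condition, time_h = a),
    group_b = list(condition = condition, time_h = b))
  list(mk(t1, t0), mk(t2, t0), mk(t2, t1))
}

group_columns <- function(m, grp) {
  which(m$samples$condition == grp$condition & m$samples$time_h == grp$time_h)
}

# Newton inversion of trigamma, used by the method-of-moments fit of the
# prior degrees of freedom from the spread of log sample variances.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Fit an empirical-Bayes moderated t model over a set of contrasts
#'
#' Per-feature residual variances are pooled within the (condition, time)
#' groups of the design and shrunk toward a prior variance `s0_sq` with prior
#' degrees of freedom `d0`, both estimated from the spread of the log sample
#' variances by method of moments (the scaled-F model of variance
#' shrinkage). The moderated statistic for a contrast is
#' `t = log2_fc / (s_tilde * sqrt(1/n_a + 1/n_b))` with
#' `s_tilde_sq = (d0*s0_sq + d*s_sq) / (d0 + d)`, referred to a t
#' distribution on `d0 + d` degrees of freedom (two-sided p-values).
#'
#' @param m An `expression_matrix`; every group named by the contrasts must
#'   have at least 2 replicates.
#' @param contrasts List of [contrast_spec()] objects.
#' @param d0 Optional fixed prior degrees of freedom, overriding estimation
#'   (`0` recovers the ordinary pooled-variance t; `Inf` uses `s0_sq` for
#'   every feature). Values above `1e6` are treated as infinite.
#' @return A list of class `moderated_fit` with elements `model` (a list with
#'   `d0`, `s0_sq`, and per-feature `s_sq`, `df_residual`, `s_tilde_sq`) and
#'   `table`, a data frame with columns `feature`, `contrast`, `log2_fc`,
#'   `t_mod`, `p_value`.
#' @export
fit_moderated_model <- function(m, contrasts, d0 = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  s <- m$samples
  grp <- interaction(s$condition, s$time_h, drop = TRUE)
  sizes <- table(grp)
  if (any(sizes < 2)) {
    stop("every (condition, time) group needs >= 2 replicates")
  }
  n <- ncol(m$values)
  k <- nlevels(grp)
  d <- n - k
  if (d < 1) stop("zero residual degrees of freedom")

  # pooled within-group residual variance per feature
  centred <- m$values
  for (lev in levels(grp)) {
    cols <- which(grp == lev)
    centred[, cols] <- m$values[, cols, drop = FALSE] -
      rowMeans(m$values[, cols, drop = FALSE])
  }
  s_sq <- rowSums(centred^2) / d

  if (is.null(d0)) {
    z <- log(pmax(s_sq, 1e-300))
    evar <- stats::var(z) - trigamma(d / 2)
    if (!is.finite(evar) || evar <= 0) {
      d0 <- 1e6
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                     digamma(d0 / 2) - log(d0 / 2))
    }
    d0 <- min(d0, 1e6)
  } else {
    stopifnot(d0 >= 0)
    if (is.infinite(d0) || d0 > 1e6) d0 <- 1e6
    s0_sq <- exp(mean(log(pmax(s_sq, 1e-300))))
  }

  s_tilde_sq <- if (d0 >= 1e6) rep(s0_sq, length(s_sq)) else {
    (d0 * s0_sq + d * s_sq) / (d0 + d)
  }
  df_total <- min(d0 + d, 1e6)

  rows <- lapply(contrasts, function(cs) {
    ca <- group_columns(m, cs$group_a)
    cb <- group_columns(m, cs$group_b)
    if (length(ca) < 2 || length(cb) < 2) {
      stop("contrast '", cs$name, "': each group needs >= 2 replicates")
    }
    fc <- rowMeans(m$values[, ca, drop = FALSE]) -
      rowMeans(m$values[, cb, drop = FALSE])
    se <- sqrt(s_tilde_sq) * sqrt(1 / length(ca) + 1 / length(cb))
    t_mod <- fc / se
    p <- 2 * stats::pt(-abs(t_mod), df = df_total)
    data.frame(feature = probes(m), contrast = cs$name, log2_fc = fc,
               t_mod = t_mod, p_value = p, row.names = NULL)
  })
  structure(list(
    model = list(d0 = d0, s0_sq = s0_sq, s_sq = s_sq, df_residual = d,
                 s_tilde_sq = s_tilde_sq, df_total = df_total),
    table = do.call(rbind, rows)),
    class = "moderated_fit")
}

#' Selection thresholds for differential expression
#'
#' @param fc_threshold Linear-scale fold-change threshold (default 2.0, i.e.
#'   at least a doubling or halving).
#' @param p_threshold P-value threshold (default 0.05). Both boundaries are
#'   inclusive.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return A `selection_criteria` object.
#' @export
selection_criteria <- function(fc_threshold = 2.0, p_threshold = 0.05,
                               direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold <= 1)
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 direction = direction), class = "selection_criteria")
}

#' Select differentially expressed features for one contrast
#'
#' A feature is selected when `|log2_fc| >= log2(fc_threshold)` and
#' `p <= p_threshold` (both inclusive), restricted to the requested
#' direction.
#'
#' @param fit A `moderated_fit` (or its `table` data frame).
#' @param criteria A [selection_criteria()].
#' @param contrast Contrast name present in the table.
#' @return Character vector of selected feature ids.
#' @export
select_differential <- function(fit, criteria = selection_criteria(),
                                contrast) {
  tab <- if (inherits(fit, "moderated_fit")) fit$table else fit
  if (!contrast %in% tab$contrast) stop("unknown contrast: ", contrast)
  tab <- tab[tab$contrast == contrast, , drop = FALSE]
  lfc <- log2(criteria$fc_threshold)
  ok <- tab$p_value <= criteria$p_threshold
  ok <- ok & switch(criteria$direction,
                    both = abs(tab$log2_fc) >= lfc,
                    up   = tab$log2_fc >= lfc,
                    down = tab$log2_fc <= -lfc)
  tab$feature[ok]
}

#' Union of features selected in any contrast
#'
#' The discriminant list: features passing the selection rule in at least one
#' of the pairwise time-point comparisons.
#'
#' @inheritParams select_differential
#' @param contrasts Contrast names; default all contrasts in the table.
#' @return Character vector of feature ids, in table order.
#' @export
discriminant_features <- function(fit, criteria = selection_criteria(),
                                  contrasts = NULL) {
  tab <- if (inherits(fit, "moderated_fit")) fit$table else fit
  if (is.null(contrasts)) contrasts <- unique(tab$contrast)
  sel <- unlist(lapply(contrasts, function(cn)
    select_differential(tab, criteria, cn)))
  unique(tab$feature[tab$feature %in% sel])
}

#' P-value cutoff controlling the expected number of false positives
#'
#' Under the null, selecting tests with p <= t yields on average `m * t`
#' false positives over `m` tests; the returned cutoff is the largest t with
#' `m * t <= target_efp`.
#'
#' @param p_values Numeric vector of p-values (only its length is used).
#' @param target_efp Expected number of false positives to tolerate (> 0).
#' @return The p-value cutoff.
#' @export
enfp_threshold <- function(p_values, target_efp) {
  if (length(p_values) == 0) stop("empty p-value list")
  stopifnot(target_efp > 0)
  min(target_efp / length(p_values), 1)
}

#' Hierarchical clustering order for heatmap export
#'
#' Agglomerates rows with Euclidean distance and complete linkage and
#' returns the leaf ordering together with the merge tree, the ordering used
#' to lay out heatmaps of the discriminant genes.
#'
#' @param mat Numeric matrix with at least 2 rows (rownames are feature ids).
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `order` (feature ids in leaf order), `merge`, `height`,
#'   and the underlying `hclust` object.
#' @export
hierarchical_order <- function(mat, distance = "euclidean",
                               linkage = "complete") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 rows to cluster")
  hc <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  list(order = ids[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}

#' Relative quantification of qPCR data by the comparative CT method
#'
#' Per sample, `dCT = CT(target) - CT(reference)`; per target gene and
#' condition, `ddCT = mean dCT(condition) - mean dCT(calibrator)` and the
#' fold change is `2^-ddCT`.
#'
#' @param records Data frame with columns `sample_id`, `gene`, `ct`,
#'   `condition` (cycle-threshold values, `ct > 0`).
#' @param reference_gene Endogenous control gene, which must be measured in
#'   every sample.
#' @param calibrator Condition label of the calibrator (untreated) samples.
#' @return Data frame with columns `gene`, `condition`, `ddct`, `fold` for
#'   every non-calibrator condition and non-reference gene.
#' @export
comparative_ct <- function(records, reference_gene, calibrator) {
  records <- as.data.frame(records)
  stopifnot(all(c("sample_id", "gene", "ct", "condition") %in% names(records)))
  if (any(records$ct <= 0)) stop("CT values must be positive")
  ref <- records[records$gene == reference_gene, , drop = FALSE]
  if (!calibrator %in% records$condition) {
    stop("calibrator condition '", calibrator, "' not present")
  }
  tgt <- records[records$gene != reference_gene, , drop = FALSE]
  ref_ct <- ref$ct[match(tgt$sample_id, ref$sample_id)]
  if (anyNA(ref_ct)) {
    bad <- unique(tgt$sample_id[is.na(ref_ct)])
    stop("reference gene not measured in sample(s): ",
         paste(bad, collapse = ", "))
  }
  tgt$dct <- tgt$ct - ref_ct
  out <- list()
  for (g in unique(tgt$gene)) {
    gi <- tgt[tgt$gene == g, , drop = FALSE]
    cal <- gi$dct[gi$condition == calibrator]
    if (length(cal) == 0) {
      stop("gene '", g, "' has no calibrator measurements")
    }
    for (cond in setdiff(unique(gi$condition), calibrator)) {
      ddct <- mean(gi$dct[gi$condition == cond]) - mean(cal)
      out[[length(out) + 1]] <- data.frame(
        gene = g, condition = cond, ddct = ddct, fold = 2^(-ddct))
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), condition = character(),
                      ddct = numeric(), fold = numeric()))
  }
  do.call(rbind, out)
}
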