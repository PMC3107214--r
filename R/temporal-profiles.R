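#' Enumerate candidate temporal model profiles
#'
#' A model profile is an integer level vector over the T time points,
#' starting at 0, whose change between consecutive time points is bounded by
#' `c` units. All `(2c+1)^(T-1)` profiles are generated in a deterministic
#' order (lexicographic by the step deltas, from -c to +c, first step most
#' significant) and numbered 1..N in that order.
#'
#' @param T Number of time points (>= 2).
#' @param c Maximum unit change per step (>= 1, default 2).
#' @return Object of class `model_profiles`: list with `levels` (N x T
#'   integer matrix, rownames = profile ids), `c` and `T`.
#' @export
enumerate_profiles <- function(T, c = 2) {
  stopifnot(c >= 1)
  if (T < 2) stop("need at least 2 time points")
  steps <- -c:c
  grids <- rep(list(steps), T - 1)
  # expand.grid varies the first factor fastest; reverse so the first step
  # is most significant, then order rows lexicographically
  deltas <- as.matrix(rev(expand.grid(rev(grids))))
  colnames(deltas) <- NULL
  ord <- do.call(order, as.data.frame(deltas))
  deltas <- deltas[ord, , drop = FALSE]
  levels <- cbind(0L, t(apply(deltas, 1, cumsum)))
  if (T == 2) levels <- cbind(0L, deltas)
  storage.mode(levels) <- "integer"
  rownames(levels) <- seq_len(nrow(levels))
  colnames(levels) <- NULL
  structure(list(levels = levels, c = c, T = T), class = "model_profiles")
}

#' @export
print.model_profiles <- function(x, ...) {
  cat("model_profiles: ", nrow(x$levels), " profiles over ", x$T,
      " time points (max step ", x$c, ")\n", sep = "")
  invisible(x)
}

flat_profile_id <- function(profiles) {
  which(rowSums(abs(profiles$levels)) == 0)[1]
}

# Correlation with a convention for constant vectors: a constant vector has
# correlation 0 with anything non-constant and 1 with another constant.
profile_cor <- function(x, y) {
  cx <- stats::sd(x) == 0
  cy <- stats::sd(y) == 0
  if (cx && cy) return(1)
  if (cx || cy) return(0)
  stats::cor(x, y)
}

#' Greedy max-min selection of representative profiles
#'
#' When the full enumeration is too large, picks `m` mutually dissimilar
#' profiles: seed with the profile of largest total absolute change (ties to
#' the lowest id), then repeatedly add the profile maximizing its minimum
#' 1 - correlation distance to the chosen set (ties to the lowest id).
#'
#' @param profiles A `model_profiles` object.
#' @param m Number of representatives (>= 1).
#' @return A `model_profiles` object containing the selected profiles (ids
#'   preserved).
#' @export
select_representatives <- function(profiles, m) {
  stopifnot(inherits(profiles, "model_profiles"), m >= 1)
  n <- nrow(profiles$levels)
  if (n == 0) stop("empty profile list")
  if (m >= n) return(profiles)
  lv <- profiles$levels
  total_change <- rowSums(abs(lv[, -1, drop = FALSE] -
                              lv[, -ncol(lv), drop = FALSE]))
  chosen <- which.max(total_change)  # which.max takes the first (lowest id) tie
  dist_to_chosen <- vapply(seq_len(n), function(i)
    1 - profile_cor(lv[i, ], lv[chosen, ]), numeric(1))
  while (length(chosen) < m) {
    cand <- setdiff(seq_len(n), chosen)
    best <- cand[which.max(dist_to_chosen[cand])]
    chosen <- c(chosen, best)
    d_new <- vapply(seq_len(n), function(i)
      1 - profile_cor(lv[i, ], lv[best, ]), numeric(1))
    dist_to_chosen <- pmin(dist_to_chosen, d_new)
  }
  structure(list(levels = lv[sort(chosen), , drop = FALSE],
                 c = profiles$c, T = profiles$T), class = "model_profiles")
}

#' Re-express a time series relative to its first time point
#'
#' @param x Numeric vector (length >= 2) or genes-by-time matrix of log2
#'   values.
#' @return Same shape with the first time point subtracted, so the series
#'   starts at 0 (log2 fold change relative to baseline).
#' @export
to_reference_scale <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("need >= 2 time points")
    return(x - x[, 1])
  }
  if (length(x) < 2) stop("need >= 2 time points")
  x - x[1]
}

#' Assign genes to their best-matching model profile
#'
#' Each gene series (already on the reference scale, i.e. starting at 0) is
#' assigned to the profile whose level vector it correlates with most
#' strongly; ties go to the lowest profile id, and constant series go to the
#' flat profile by convention (similarity 1). Profiles are ranked by the
#' number of genes assigned.
#'
#' @param series Genes-by-time numeric matrix on the reference scale
#'   (rownames are gene ids).
#' @param profiles A `model_profiles` object with matching `T`.
#' @return Object of class `profile_assignment`: list with `assignments`
#'   (data frame gene, profile_id, similarity), `counts` (named integer
#'   vector over all profile ids, descending), and `profiles`.
#' @export
assign_genes <- function(series, profiles) {
  series <- as.matrix(series)
  if (ncol(series) != profiles$T) {
    stop("series length (", ncol(series), ") != profile length (",
         profiles$T, ")")
  }
  lv <- profiles$levels
  ids <- as.integer(rownames(lv))
  flat <- flat_profile_id(profiles)
  gene_sd <- apply(series, 1, stats::sd)
  prof_sd <- apply(lv, 1, stats::sd)
  # correlation matrix genes x profiles; constant rows handled by convention
  cors <- matrix(-Inf, nrow(series), nrow(lv))
  ok_g <- gene_sd > 0
  ok_p <- prof_sd > 0
  if (any(ok_g) && any(ok_p)) {
    cors[ok_g, ok_p] <- stats::cor(t(series[ok_g, , drop = FALSE]),
                                   t(lv[ok_p, , drop = FALSE]))
  }
  best <- integer(nrow(series))
  sim <- numeric(nrow(series))
  for (i in seq_len(nrow(series))) {
    if (!ok_g[i]) {
      best[i] <- if (length(flat)) flat else 1L
      sim[i] <- 1
    } else {
      j <- which.max(cors[i, ])  # first maximum = lowest profile id
      best[i] <- j
      sim[i] <- cors[i, j]
    }
  }
  genes <- rownames(series)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(series)))
  assignments <- data.frame(gene = genes, profile_id = ids[best],
                            similarity = sim, row.names = NULL)
  counts <- integer(nrow(lv))
  names(counts) <- ids
  tab <- table(factor(assignments$profile_id, levels = ids))
  counts[] <- as.integer(tab)
  counts <- sort(counts, decreasing = TRUE)
  structure(list(assignments = assignments, counts = counts,
                 profiles = profiles), class = "profile_assignment")
}

#' Permutation significance of profile gene counts
#'
#' Applies every permutation of the time-point order identically to all gene
#' series (re-referencing to the permuted first time point), recomputes the
#' profile assignment, and reports for each profile the fraction of
#' permutations whose gene count reaches the observed count:
#' `p = #\{perm : count >= observed\} / #perms`. P-values are
#' Bonferroni-corrected over profiles. With T = 3 only 6 orderings exist, so
#' the smallest attainable permutation p is 1/6 and no profile can pass a
#' Bonferroni-corrected 0.05; a parametric binomial fallback is therefore
#' also reported: `P(Binom(n_genes, pi_j) >= observed)` where `pi_j` is
#' profile j's expected assignment probability estimated as its average
#' count over the permutation ensemble divided by the number of genes
#' (correlation assignment does not spread genes uniformly over profiles,
#' so a uniform `1/n_profiles` rate would be miscalibrated). The
#' `criterion` column records which rule flagged each profile.
#'
#' @param series Genes-by-time matrix on the reference scale.
#' @param profiles A `model_profiles` object.
#' @param alpha Significance level for the corrected p-values (default 0.05).
#' @param B Number of random permutations when `T! > 120`; ignored for
#'   exhaustive enumeration.
#' @param seed Seed for the random permutations (exhaustive mode is
#'   deterministic).
#' @return Data frame with one row per profile: `profile_id`, `count`,
#'   `p_perm`, `p_perm_adj`, `p_binom`, `p_binom_adj`, `significant`,
#'   `criterion` (`"permutation"`, `"binomial"`, `"both"` or `""`).
#' @export
profile_significance <- function(series, profiles, alpha = 0.05, B = 1000,
                                 seed = 1L) {
  series <- as.matrix(series)
  Tn <- profiles$T
  obs <- assign_genes(series, profiles)
  ids <- as.integer(rownames(profiles$levels))
  observed <- obs$counts[as.character(ids)]
  n_genes <- nrow(series)
  n_prof <- nrow(profiles$levels)

  perms <- if (factorial(Tn) <= 120) {
    all_permutations(Tn)
  } else {
    set.seed(seed)
    unique(c(list(seq_len(Tn)),
             replicate(B, sample(Tn), simplify = FALSE)))
  }
  ge <- integer(n_prof)
  names(ge) <- ids
  count_sum <- numeric(n_prof)
  for (perm in perms) {
    permuted <- series[, perm, drop = FALSE]
    permuted <- permuted - permuted[, 1]
    counts <- assign_genes(permuted, profiles)$counts[as.character(ids)]
    ge <- ge + as.integer(counts >= observed)
    count_sum <- count_sum + counts
  }
  p_perm <- ge / length(perms)
  p_perm[observed == 0] <- 1
  expected_prob <- count_sum / (length(perms) * n_genes)
  p_binom <- stats::pbinom(observed - 1, n_genes, expected_prob,
                           lower.tail = FALSE)
  p_binom[observed == 0] <- 1
  p_perm_adj <- pmin(1, p_perm * n_prof)
  p_binom_adj <- pmin(1, p_binom * n_prof)
  sig_perm <- p_perm_adj <= alpha
  sig_binom <- p_binom_adj <= alpha
  criterion <- ifelse(sig_perm & sig_binom, "both",
               ifelse(sig_perm, "permutation",
               ifelse(sig_binom, "binomial", "")))
  data.frame(profile_id = ids, count = as.integer(observed),
             p_perm = as.numeric(p_perm), p_perm_adj = p_perm_adj,
             p_binom = p_binom, p_binom_adj = p_binom_adj,
             significant = sig_perm | sig_binom, criterion = criterion,
             row.names = NULL)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_permutations(n - 1)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1]] <- c(i, tail)
    }
  }
  out
}

#' Label significant profiles as ordered groups
#'
#' Significant profiles are labeled A, B, C, ... in descending order of gene
#' count; genes assigned to non-significant profiles are reported as
#' unassigned.
#'
#' @param assignment A `profile_assignment` from [assign_genes()].
#' @param significance Data frame from [profile_significance()].
#' @return List with `groups` (data frame profile_id, label, count),
#'   `gene_groups` (named character vector gene -> label for genes in
#'   significant profiles) and `unassigned` (character vector of the
#'   remaining genes).
#' @export
group_profiles <- function(assignment, significance) {
  sig <- significance[significance$significant, , drop = FALSE]
  sig <- sig[order(-sig$count, sig$profile_id), , drop = FALSE]
  if (nrow(sig) == 0) {
    return(list(groups = data.frame(profile_id = integer(),
                                    label = character(), count = integer()),
                gene_groups = stats::setNames(character(0), character(0)),
                unassigned = assignment$assignments$gene))
  }
  labels <- make.unique(c(LETTERS, paste0("Z", seq_len(max(0, nrow(sig) - 26)))))
  groups <- data.frame(profile_id = sig$profile_id,
                       label = labels[seq_len(nrow(sig))],
                       count = sig$count, row.names = NULL)
  a <- assignment$assignments
  idx <- match(a$profile_id, groups$profile_id)
  assigned <- !is.na(idx)
  gene_groups <- stats::setNames(groups$label[idx[assigned]], a$gene[assigned])
  list(groups = groups, gene_groups = gene_groups,
       unassigned = a$gene[!assigned])
}
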