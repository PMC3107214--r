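#' Default motif-to-category consolidation map
#'
#' Binding motifs recognized by homologous factor families are collapsed to
#' categorical regulator nodes. The default map merges the two myeloid zinc
#' finger 1 domain matrices (highly similar to NF-kB response elements) and
#' the NF-kB family matrices (NF-kappaB, RELA, NFKB1) under a single
#' `NF-kB` category; all other motifs map to themselves.
#'
#' @return Named character vector, motif id -> category name.
#' @export
default_category_map <- function() {
  c("MZF1_1-4" = "NF-kB", "MZF1_5-13" = "NF-kB",
    "NF-kappaB" = "NF-kB", "RELA" = "NF-kB", "NFKB1" = "NF-kB")
}

#' Read a motif-to-category map from TSV
#'
#' @param path TSV with columns `motif_id`, `category`.
#' @return Named character vector, motif id -> category.
#' @export
read_category_map <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("motif_id", "category") %in% names(tab)))
  stats::setNames(tab$category, tab$motif_id)
}

apply_category_map <- function(motif_ids, category_map) {
  out <- category_map[motif_ids]
  missing <- is.na(out)
  if (any(missing)) {
    out[missing] <- motif_ids[missing]  # identity fallback
  }
  unname(out)
}

#' Fraction of group genes with a well-matched site per motif
#'
#' For every (motif, temporal group) cell, the fraction of the group's genes
#' whose best promoter score for the motif reaches the threshold.
#'
#' @param score_table Genes-by-motifs score matrix from [scan_universe()].
#' @param groups Named character vector, gene -> group label.
#' @param threshold Minimum score counting as well-matched (inclusive,
#'   default 0.95).
#' @return Motifs-by-groups numeric matrix of fractions with attribute
#'   `counts` (matching integer matrix of per-cell gene counts reaching the
#'   threshold) and `group_sizes`.
#' @export
fraction_matrix <- function(score_table, groups, threshold = 0.95) {
  if (!length(groups)) stop("empty group assignment")
  absent <- setdiff(names(groups), rownames(score_table))
  if (length(absent)) {
    stop("group gene(s) absent from score table: ",
         paste(absent, collapse = ", "))
  }
  labs <- sort(unique(groups))
  sizes <- table(factor(groups, levels = labs))
  if (any(sizes == 0)) stop("group with zero genes")
  frac <- matrix(0, ncol(score_table), length(labs),
                 dimnames = list(colnames(score_table), labs))
  counts <- frac
  for (g in labs) {
    genes <- names(groups)[groups == g]
    hits <- colSums(score_table[genes, , drop = FALSE] >= threshold)
    counts[, g] <- hits
    frac[, g] <- hits / length(genes)
  }
  storage.mode(counts) <- "integer"
  attr(frac, "counts") <- counts
  attr(frac, "group_sizes") <- as.integer(sizes)
  frac
}

#' Motifs retained per group after the well-matched-site prune
#'
#' A motif survives for a group only if it is enriched there (p strictly
#' below `alpha`) and at least one of the group's genes carries a
#' well-matched site (score >= threshold); over-represented motifs without a
#' single well-matched site are omitted from further consideration.
#'
#' @param enrichment Data frame with columns `group`, `motif_id`, `p`
#'   (stacked per-group results of [enrichment_ztest()]).
#' @param score_table Genes-by-motifs score matrix.
#' @param groups Named character vector, gene -> group label.
#' @param threshold Well-matched-site score threshold (default 0.95).
#' @param alpha Enrichment significance level (default 0.05, strict `<`).
#' @return Data frame with columns `group`, `motif_id` of retained pairs.
#' @export
prune_unmatched_motifs <- function(enrichment, score_table, groups,
                                   threshold = 0.95, alpha = 0.05) {
  stopifnot(all(c("group", "motif_id", "p") %in% names(enrichment)))
  enr <- enrichment[enrichment$p < alpha, , drop = FALSE]
  keep <- logical(nrow(enr))
  for (i in seq_len(nrow(enr))) {
    genes <- names(groups)[groups == enr$group[i]]
    keep[i] <- any(score_table[genes, enr$motif_id[i]] >= threshold)
  }
  out <- enr[keep, c("group", "motif_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the motif-category to gene regulatory network
#'
#' For each temporal group and each motif retained by
#' [prune_unmatched_motifs()], the motif is mapped to its categorical node
#' and an edge category -> gene is added for every gene of the group whose
#' promoter scores at least `threshold` for that motif. Motifs sharing a
#' category contribute to the same edge (the edge records the union of
#' supporting motif ids and the best supporting score); duplicate edges are
#' merged.
#'
#' @param retained Data frame `group`, `motif_id` from
#'   [prune_unmatched_motifs()].
#' @param score_table Genes-by-motifs score matrix.
#' @param groups Named character vector, gene -> group label.
#' @param category_map Named character vector motif id -> category; motifs
#'   missing from the map fall back to themselves with a warning. Default
#'   [default_category_map()].
#' @param threshold Well-matched-site score threshold (default 0.95).
#' @return Object of class `regulatory_network`: list with `edges` (data
#'   frame `category`, `gene`, `group`, `motif_ids`, `best_score`),
#'   `categories` (character) and `genes` (data frame `gene`, `group`).
#' @export
build_network <- function(retained, score_table, groups,
                          category_map = default_category_map(),
                          threshold = 0.95) {
  absent <- setdiff(retained$motif_id, colnames(score_table))
  if (length(absent)) {
    stop("retained motif(s) missing from score table: ",
         paste(absent, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(retained))) {
    grp <- retained$group[i]
    mid <- retained$motif_id[i]
    cat_name <- apply_category_map(mid, category_map)
    genes <- names(groups)[groups == grp]
    sc <- score_table[genes, mid]
    hit <- genes[sc >= threshold]
    if (!length(hit)) next
    rows[[length(rows) + 1]] <- data.frame(
      category = cat_name, gene = hit, group = grp, motif_id = mid,
      score = score_table[hit, mid], row.names = NULL)
  }
  if (!length(rows)) {
    edges <- data.frame(category = character(), gene = character(),
                        group = character(), motif_ids = character(),
                        best_score = numeric())
  } else {
    raw <- do.call(rbind, rows)
    key <- paste(raw$category, raw$gene, raw$group, sep = "\r")
    edges <- do.call(rbind, lapply(split(raw, key), function(d) {
      data.frame(category = d$category[1], gene = d$gene[1],
                 group = d$group[1],
                 motif_ids = paste(sort(unique(d$motif_id)), collapse = ","),
                 best_score = max(d$score), row.names = NULL)
    }))
    edges <- edges[order(edges$category, edges$group, edges$gene), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  gene_nodes <- unique(edges[, c("gene", "group")])
  rownames(gene_nodes) <- NULL
  structure(list(edges = edges, categories = unique(edges$category),
                 genes = gene_nodes), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network: ", length(x$categories), " motif categories, ",
      nrow(x$genes), " genes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Colors of the temporal groups used in network figures
#'
#' @return Named character vector of the conventional group colors
#'   (A = red, B = green, C = blue, D = black, E = purple).
#' @export
default_group_colors <- function() {
  c(A = "red", B = "green", C = "blue", D = "black", E = "purple")
}

#' Export a regulatory network to DOT, GraphML or edge-list TSV
#'
#' DOT draws motif categories as double circles and genes as ovals, edges
#' colored by temporal group; GraphML (via igraph) and TSV carry the same
#' node and edge attributes. A TSV export can be read back with
#' [read_network_tsv()] and rebuilt into an identical edge set.
#'
#' @param net A `regulatory_network`.
#' @param path Output file path.
#' @param format `"dot"`, `"graphml"` or `"tsv"`.
#' @param group_colors Named character vector, group label -> color; must
#'   cover every group present in the network. Default
#'   [default_group_colors()].
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("dot", "graphml", "tsv"),
                           group_colors = default_group_colors()) {
  format <- match.arg(format)
  if (nrow(net$edges) == 0) stop("cannot export an empty network")
  missing <- setdiff(unique(net$edges$group), names(group_colors))
  if (length(missing)) {
    stop("no color for group(s): ", paste(missing, collapse = ", "))
  }
  if (format == "tsv") {
    edges <- net$edges
    # full-precision scores so a read-back reproduces the edge set exactly
    edges$best_score <- sprintf("%.17g", edges$best_score)
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (format == "dot") {
    q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
    lines <- c("digraph regulatory_network {")
    for (cat_name in net$categories) {
      lines <- c(lines, paste0("  ", q(cat_name),
                               " [shape=doublecircle, style=filled, fillcolor=tan];"))
    }
    for (i in seq_len(nrow(net$genes))) {
      col <- group_colors[[net$genes$group[i]]]
      lines <- c(lines, paste0("  ", q(net$genes$gene[i]),
                               " [shape=oval, color=", col, "];"))
    }
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      lines <- c(lines, paste0("  ", q(e$category), " -> ", q(e$gene),
                               " [color=", group_colors[[e$group]],
                               ", label=", q(e$group), "];"))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
    return(invisible(path))
  }
  # graphml via igraph
  verts <- data.frame(
    name = c(net$categories, net$genes$gene),
    type = c(rep("category", length(net$categories)),
             rep("gene", nrow(net$genes))),
    group = c(rep(NA_character_, length(net$categories)), net$genes$group),
    color = c(rep("tan", length(net$categories)),
              unname(group_colors[net$genes$group])),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("category", "gene", "group", "motif_ids", "best_score")],
    directed = TRUE, vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network edge list written by [export_network()] (TSV)
#'
#' @param path Path to the edge-list TSV.
#' @return A `regulatory_network` with the same edge set.
#' @export
read_network_tsv <- function(path) {
  edges <- utils::read.delim(path, colClasses = c(
    category = "character", gene = "character", group = "character",
    motif_ids = "character", best_score = "numeric"))
  edges <- edges[order(edges$category, edges$group, edges$gene), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  gene_nodes <- unique(edges[, c("gene", "group")])
  rownames(gene_nodes) <- NULL
  structure(list(edges = edges, categories = unique(edges$category),
                 genes = gene_nodes), class = "regulatory_network")
}

#' Compare up/down gene sets between two datasets
#'
#' Gene symbols are upper-cased before comparison. Per direction, genes are
#' split into common, unique-to-A and unique-to-B; genes moving in opposite
#' directions between the datasets are reported as divergent (and excluded
#' from the common sets).
#'
#' @param a_up,a_down Up- and downregulated genes of dataset A.
#' @param b_up,b_down Up- and downregulated genes of dataset B.
#' @return Object of class `set_comparison`: list with `common_up`,
#'   `common_down`, `unique_a_up`, `unique_a_down`, `unique_b_up`,
#'   `unique_b_down`, `divergent`, and a `counts` integer vector.
#' @export
compare_gene_sets <- function(a_up, a_down, b_up, b_down) {
  up_a <- unique(toupper(a_up));   dn_a <- unique(toupper(a_down))
  up_b <- unique(toupper(b_up));   dn_b <- unique(toupper(b_down))
  bad_a <- intersect(up_a, dn_a)
  if (length(bad_a)) {
    stop("gene(s) in both up and down of dataset A: ",
         paste(bad_a, collapse = ", "))
  }
  bad_b <- intersect(up_b, dn_b)
  if (length(bad_b)) {
    stop("gene(s) in both up and down of dataset B: ",
         paste(bad_b, collapse = ", "))
  }
  divergent <- sort(union(intersect(up_a, dn_b), intersect(dn_a, up_b)))
  common_up <- sort(intersect(up_a, up_b))
  common_down <- sort(intersect(dn_a, dn_b))
  res <- list(
    common_up = common_up, common_down = common_down,
    unique_a_up = sort(setdiff(up_a, union(up_b, dn_b))),
    unique_a_down = sort(setdiff(dn_a, union(up_b, dn_b))),
    unique_b_up = sort(setdiff(up_b, union(up_a, dn_a))),
    unique_b_down = sort(setdiff(dn_b, union(up_a, dn_a))),
    divergent = divergent)
  res$counts <- vapply(res, length, integer(1))
  class(res) <- "set_comparison"
  res
}

#' @export
print.set_comparison <- function(x, ...) {
  cat("set_comparison:\n")
  for (nm in setdiff(names(x), "counts")) {
    cat("  ", nm, ": ", length(x[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the gene set and the term's genes within
#' the universe, with Benjamini-Hochberg adjustment across terms. Term gene
#' lists are intersected with the universe first.
#'
#' @param gene_set Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Character vector of all considered genes.
#' @param term_map Named list, term -> character vector of member genes.
#' @return Data frame with columns `term`, `overlap`, `term_size`,
#'   `set_size`, `p`, `q`, ordered by increasing p.
#' @export
term_enrichment <- function(gene_set, universe, term_map) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    stop("gene(s) outside the universe: ", paste(outside, collapse = ", "))
  }
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(term_map), function(tm) {
    tg <- intersect(unique(term_map[[tm]]), universe)
    K <- length(tg)
    k <- length(intersect(tg, gene_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, set_size = n, p = p,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}
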