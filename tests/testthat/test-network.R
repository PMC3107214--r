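toy_scores <- function() {
  tab <- rbind(
    g1 = c(1.00, 0.30), g2 = c(0.96, 0.40), g3 = c(0.50, 0.97),
    g4 = c(0.20, 0.99), g5 = c(0.97, 0.10), g6 = c(0.10, 0.20))
  colnames(tab) <- c("M1", "M2")
  tab
}

toy_groups <- function() {
  c(g1 = "A", g2 = "A", g3 = "A", g4 = "B", g5 = "B", g6 = "B")
}

test_that("fraction matrix counts well-matched genes per group", {
  tab <- matrix(c(1.0, 0.96, 0.5, 0.2), ncol = 1,
                dimnames = list(paste0("g", 1:4), "M"))
  fm <- fraction_matrix(tab, c(g1 = "A", g2 = "A", g3 = "A", g4 = "A"), 0.95)
  expect_equal(unname(fm["M", "A"]), 0.5)

  # threshold 0 makes every fraction 1
  fm0 <- fraction_matrix(toy_scores(), toy_groups(), threshold = 0)
  expect_true(all(fm0 == 1))

  # random tables vs brute-force recount
  set.seed(55)
  tab <- matrix(runif(300), 100, 3,
                dimnames = list(sprintf("g%03d", 1:100), c("M1", "M2", "M3")))
  groups <- setNames(sample(c("A", "B", "C"), 100, replace = TRUE),
                     rownames(tab))
  fm <- fraction_matrix(tab, groups, 0.7)
  for (m in colnames(tab)) for (g in c("A", "B", "C")) {
    genes <- names(groups)[groups == g]
    expect_equal(unname(fm[m, g]),
                 sum(tab[genes, m] >= 0.7) / length(genes))
  }
})

test_that("pruning drops enriched motifs without a well-matched site", {
  scores <- toy_scores()
  groups <- toy_groups()
  enr <- data.frame(group = c("A", "A", "B", "B"),
                    motif_id = c("M1", "M2", "M1", "M2"),
                    p = c(0.001, 0.002, 0.2, 0.01))
  kept <- prune_unmatched_motifs(enr, scores, groups, threshold = 0.95)
  # A/M1 kept (g1 = 1.0); A/M2 kept (g3 = 0.97); B/M1 dropped only if not
  # enriched (p = 0.2); B/M2 kept (g4 = 0.99)
  expect_setequal(paste(kept$group, kept$motif_id),
                  c("A M1", "A M2", "B M2"))

  # enriched but best foreground score below threshold -> pruned
  scores2 <- scores; scores2[c("g4", "g5", "g6"), "M2"] <- 0.90
  kept2 <- prune_unmatched_motifs(enr, scores2, groups, threshold = 0.95)
  expect_false("B M2" %in% paste(kept2$group, kept2$motif_id))
  # boundary: a single exact 0.95 hit retains the motif
  scores2["g4", "M2"] <- 0.95
  kept3 <- prune_unmatched_motifs(enr, scores2, groups, threshold = 0.95)
  expect_true("B M2" %in% paste(kept3$group, kept3$motif_id))

  # alpha is strict: p exactly 0.05 is not enriched
  enr2 <- data.frame(group = "A", motif_id = "M1", p = 0.05)
  expect_equal(nrow(prune_unmatched_motifs(enr2, scores, groups)), 0)
})

test_that("network assembly adds edges for passing genes and dedups categories", {
  scores <- toy_scores()
  groups <- toy_groups()
  retained <- data.frame(group = "A", motif_id = "M1")
  net <- build_network(retained, scores, groups, category_map = character(0))
  expect_equal(net$categories, "M1")
  expect_equal(nrow(net$genes), 2)       # g1, g2 pass 0.95
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$gene, c("g1", "g2"))
  expect_equal(unique(net$edges$group), "A")

  # two motifs in one category with the same passing gene -> one edge
  scores3 <- cbind(toy_scores(), M3 = c(0.99, 0.1, 0.1, 0.1, 0.1, 0.1))
  retained <- data.frame(group = c("A", "A"), motif_id = c("M1", "M3"))
  cmap <- c(M1 = "NFKB", M3 = "NFKB")
  net2 <- build_network(retained, scores3, groups, category_map = cmap)
  e_g1 <- net2$edges[net2$edges$gene == "g1", ]
  expect_equal(nrow(e_g1), 1)
  expect_equal(e_g1$category, "NFKB")
  expect_equal(e_g1$motif_ids, "M1,M3")
  expect_equal(e_g1$best_score, 1.0)

  expect_error(build_network(data.frame(group = "A", motif_id = "ZZ"),
                             scores, groups), "missing from score table")
})

test_that("edge counts shrink monotonically as the match threshold rises", {
  set.seed(56)
  tab <- matrix(runif(400, 0.5, 1), 100, 4,
                dimnames = list(sprintf("g%03d", 1:100), paste0("M", 1:4)))
  groups <- setNames(sample(c("A", "B"), 100, replace = TRUE), rownames(tab))
  retained <- expand.grid(group = c("A", "B"), motif_id = paste0("M", 1:4),
                          stringsAsFactors = FALSE)
  sizes <- vapply(c(0.6, 0.7, 0.8, 0.9, 0.99), function(th) {
    nrow(build_network(retained, tab, groups, character(0), th)$edges)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("DOT export declares shapes and colors; TSV round-trips the edge set", {
  scores <- toy_scores()
  groups <- toy_groups()
  retained <- data.frame(group = c("A", "B"), motif_id = c("M1", "M2"))
  net <- build_network(retained, scores, groups, category_map = character(0))

  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  txt <- readLines(dot)
  expect_true(any(grepl("doublecircle", txt)))
  expect_true(any(grepl("shape=oval", txt)))
  expect_true(any(grepl('"M1" -> "g1"', txt)))
  expect_true(any(grepl("color=red", txt)))    # group A
  expect_true(any(grepl("color=green", txt)))  # group B

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- read_network_tsv(tsv)
  expect_equal(back$edges, net$edges)
  expect_equal(back$categories, net$categories)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))

  # missing group color is an error listing the group
  expect_error(export_network(net, dot, "dot", group_colors = c(A = "red")),
               "B")
})

test_that("gene-set comparison partitions shared and divergent genes", {
  cmp <- compare_gene_sets(a_up = c("X", "Y"), a_down = c("D"),
                           b_up = c("Y", "Z"), b_down = c("D", "X"))
  expect_equal(cmp$divergent, "X")
  expect_equal(cmp$common_up, "Y")
  expect_equal(cmp$common_down, "D")
  expect_equal(cmp$unique_b_up, "Z")

  # disjoint sets share nothing
  cmp0 <- compare_gene_sets(c("A1"), c("A2"), c("B1"), c("B2"))
  expect_equal(unname(cmp0$counts[c("common_up", "common_down", "divergent")]),
               c(0L, 0L, 0L))

  # case-insensitive symbol matching
  cmp_case <- compare_gene_sets("Il6", character(0), "IL6", character(0))
  expect_equal(cmp_case$common_up, "IL6")

  # a gene up and down in the same dataset is an error
  expect_error(compare_gene_sets(c("X"), c("X"), "Y", "Z"), "dataset A")
})

test_that("gene-set comparison counts match a brute-force set oracle", {
  set.seed(57)
  pool <- sprintf("G%02d", 1:40)
  for (k in 1:10) {
    au <- sample(pool, 12); ad <- sample(setdiff(pool, au), 8)
    bu <- sample(pool, 10); bd <- sample(setdiff(pool, bu), 10)
    cmp <- compare_gene_sets(au, ad, bu, bd)
    expect_setequal(cmp$common_up, intersect(au, bu))
    expect_setequal(cmp$common_down, intersect(ad, bd))
    expect_setequal(cmp$divergent,
                    union(intersect(au, bd), intersect(ad, bu)))
    # common + unique-A + divergent members cover a_up entirely
    expect_setequal(au, c(cmp$common_up, cmp$unique_a_up,
                          intersect(au, cmp$divergent)))
  }
})

test_that("term over-representation matches the hypergeometric tail", {
  uni <- sprintf("g%02d", 1:10)
  tm <- list(hit = uni[1:3], miss = uni[8:10])
  res <- term_enrichment(uni[1:3], uni, tm)
  expect_equal(res$p[res$term == "hit"], 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(res$p[res$term == "miss"], 1.0)

  # random instances vs explicit enumeration of the tail
  set.seed(58)
  uni <- sprintf("g%03d", 1:60)
  for (k in 1:10) {
    gs <- sample(uni, 15)
    tg <- sample(uni, 20)
    res <- term_enrichment(gs, uni, list(t = tg))
    kk <- length(intersect(gs, tg))
    tail_p <- sum(vapply(kk:min(15, 20), function(x) {
      choose(20, x) * choose(40, 15 - x) / choose(60, 15)
    }, numeric(1)))
    expect_equal(res$p, tail_p, tolerance = 1e-10)
  }
  expect_error(term_enrichment("g001", character(0), list()), "empty universe")
  expect_error(term_enrichment("zzz", uni, list()), "outside")
})
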