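two_group_expr <- function(n_feat, seed = 1, sd_per_feature = NULL) {
  set.seed(seed)
  sds <- if (is.null(sd_per_feature)) rep(1, n_feat) else sd_per_feature
  vals <- matrix(rnorm(n_feat * 6, 8, rep(sds, 6)), n_feat, 6)
  make_expr(vals, times = c(0, 1), reps = 3)
}

contrast_1v0 <- function() {
  contrast_spec("1v0", list(condition = "stim", time_h = 1),
                list(condition = "stim", time_h = 0))
}

test_that("d0 = 0 recovers the ordinary pooled-variance two-sample t", {
  m <- two_group_expr(40, seed = 3)
  fit <- fit_moderated_model(m, contrast_1v0(), d0 = 0)
  a <- which(m$samples$time_h == 1); b <- which(m$samples$time_h == 0)
  for (i in seq_len(10)) {
    tt <- t.test(m$values[i, a], m$values[i, b], var.equal = TRUE)
    expect_equal(fit$table$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit$table$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("d0 = Inf uses the prior variance for every feature", {
  m <- two_group_expr(40, seed = 4)
  fit <- fit_moderated_model(m, contrast_1v0(), d0 = Inf)
  expect_true(all(fit$model$s_tilde_sq == fit$model$s0_sq))
})

test_that("moderated t matches a formula-by-formula recomputation", {
  # heterogeneous true variances so the shrinkage is non-trivial
  set.seed(9)
  sds <- sqrt(0.05 * 4 / rchisq(50, df = 4))
  m <- two_group_expr(50, seed = 9, sd_per_feature = sds)
  fit <- fit_moderated_model(m, contrast_1v0())

  # independent recomputation: pooled variances, method-of-moments via
  # uniroot on the trigamma equation, then the moderated statistic
  a <- which(m$samples$time_h == 1); b <- which(m$samples$time_h == 0)
  s_sq <- vapply(seq_len(50), function(i) {
    (sum((m$values[i, a] - mean(m$values[i, a]))^2) +
       sum((m$values[i, b] - mean(m$values[i, b]))^2)) / 4
  }, numeric(1))
  d <- 4
  z <- log(s_sq)
  rhs <- var(z) - trigamma(d / 2)
  half_d0 <- uniroot(function(y) trigamma(y) - rhs, c(1e-6, 1e8),
                     tol = 1e-14)$root
  d0 <- 2 * half_d0
  s0 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
              digamma(half_d0) - log(half_d0))
  expect_equal(fit$model$d0, d0, tolerance = 1e-6)
  expect_equal(fit$model$s0_sq, s0, tolerance = 1e-6)

  s_tilde <- (d0 * s0 + d * s_sq) / (d0 + d)
  fc <- rowMeans(m$values[, a]) - rowMeans(m$values[, b])
  t_ref <- fc / sqrt(s_tilde * (1 / 3 + 1 / 3))
  p_ref <- 2 * pt(-abs(t_ref), df = d0 + d)
  # identical shrinkage formulas given the hyperparameters; compare at the
  # fitted hyperparameters to isolate the statistic computation
  s_tilde_fit <- (fit$model$d0 * fit$model$s0_sq + d * s_sq) /
    (fit$model$d0 + d)
  t_fit_ref <- fc / sqrt(s_tilde_fit * (2 / 3))
  expect_equal(fit$table$t_mod, unname(t_fit_ref), tolerance = 1e-10)
  expect_equal(fit$table$t_mod, unname(t_ref), tolerance = 1e-5)
  expect_equal(fit$table$p_value,
               unname(2 * pt(-abs(t_fit_ref), df = fit$model$df_total)),
               tolerance = 1e-10)
  expect_equal(fit$table$log2_fc, unname(fc), tolerance = 1e-12)
})

test_that("shrinkage agrees with limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(10)
  sds <- sqrt(0.05 * 4 / rchisq(200, df = 4))
  m <- two_group_expr(200, seed = 10, sd_per_feature = sds)
  fit <- fit_moderated_model(m, contrast_1v0())
  design <- model.matrix(~ factor(m$samples$time_h))
  lf <- limma::eBayes(limma::lmFit(m$values, design))
  expect_equal(fit$model$d0, lf$df.prior, tolerance = 1e-3)
  expect_equal(fit$model$s0_sq, lf$s2.prior, tolerance = 1e-3)
  expect_equal(fit$table$t_mod, unname(lf$t[, 2]), tolerance = 1e-4)
})

test_that("selection respects inclusive fold-change and p boundaries", {
  tab <- data.frame(
    feature = c("f1", "f2", "f3", "f4"),
    contrast = "1v0",
    log2_fc = c(1.0, 0.9, -1.2, 2.0),
    t_mod = 0,
    p_value = c(0.05, 0.001, 0.04, 0.5))
  sel <- select_differential(tab, selection_criteria(), "1v0")
  expect_setequal(sel, c("f1", "f3"))  # boundary included, f2 under fc, f4 over p
  expect_error(select_differential(tab, selection_criteria(), "8v0"),
               "unknown contrast")
})

test_that("up and down selections partition the two-sided selection", {
  set.seed(5)
  tab <- data.frame(feature = paste0("f", 1:500), contrast = "c",
                    log2_fc = rnorm(500, 0, 1.5), t_mod = 0,
                    p_value = runif(500))
  up <- select_differential(tab, selection_criteria(direction = "up"), "c")
  dn <- select_differential(tab, selection_criteria(direction = "down"), "c")
  both <- select_differential(tab, selection_criteria(direction = "both"), "c")
  expect_setequal(union(up, dn), both)
  expect_length(intersect(up, dn), 0)
})

test_that("expected-false-positive cutoff has its closed form and is monotone", {
  expect_equal(enfp_threshold(runif(100), 5), 0.05)
  expect_equal(enfp_threshold(runif(1000), 1), 0.001)
  expect_error(enfp_threshold(numeric(0), 1), "empty")
  ps <- runif(500)
  cuts <- vapply(c(0.5, 1, 5, 20), function(t) enfp_threshold(ps, t),
                 numeric(1))
  expect_true(all(diff(cuts) > 0))
})

test_that("ENFP cutoff controls the expected false positives under the null", {
  set.seed(123)
  m <- 2000; target <- 10
  cutoff <- enfp_threshold(numeric(m), target)
  fp <- replicate(500, sum(runif(m) <= cutoff))
  se <- sd(fp) / sqrt(500)
  expect_lt(abs(mean(fp) - target), 2 * se + 1e-9)
})

test_that("hierarchical ordering reproduces a brute-force complete-linkage merge", {
  # two identical rows merge first at height 0
  mat <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9), d = c(4, 0))
  h <- hierarchical_order(mat)
  expect_equal(sort(h$merge[1, ]), c(-2, -1))
  expect_equal(h$height[1], 0)

  # brute-force agglomeration oracle on a 4-row instance
  set.seed(21)
  mat <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], NULL))
  d <- as.matrix(dist(mat))
  clusters <- as.list(1:4)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      link <- max(d[clusters[[j]], clusters[[i]]])
      if (link < best[1]) best <- c(link, j, i)
    }
    merges[[length(merges) + 1]] <-
      list(height = best[1],
           members = sort(c(clusters[[best[2]]], clusters[[best[3]]])))
    clusters[[best[2]]] <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    clusters[[best[3]]] <- NULL
  }
  h <- hierarchical_order(mat)
  for (k in seq_along(merges)) {
    expect_equal(h$height[k], merges[[k]]$height)
    # members of the cluster formed at step k
    members <- function(node) {
      if (node < 0) return(-node)
      sort(unlist(lapply(h$merge[node, ], members)))
    }
    expect_equal(members(k), merges[[k]]$members)
  }
})

test_that("hierarchical ordering is invariant to row permutation", {
  set.seed(22)
  mat <- matrix(rnorm(24), 8, 3, dimnames = list(letters[1:8], NULL))
  h1 <- hierarchical_order(mat)
  perm <- sample(8)
  h2 <- hierarchical_order(mat[perm, ])
  co1 <- as.matrix(cophenetic(h1$hclust))
  co2 <- as.matrix(cophenetic(h2$hclust))
  expect_equal(co1, co2[rownames(co1), colnames(co1)])
  expect_error(hierarchical_order(mat[1, , drop = FALSE]), "at least 2")
})

test_that("comparative CT reproduces the 2^-ddCT closed form", {
  recs <- data.frame(
    sample_id = c("t1", "t1", "c1", "c1"),
    gene = c("IL6", "ACTB", "IL6", "ACTB"),
    ct = c(20, 18, 24, 18),
    condition = c("treated", "treated", "calibrator", "calibrator"))
  out <- comparative_ct(recs, "ACTB", "calibrator")
  expect_equal(out$ddct, -4)
  expect_equal(out$fold, 16)

  # ddCT of zero gives fold 1
  recs$ct <- c(20, 18, 20, 18)
  expect_equal(comparative_ct(recs, "ACTB", "calibrator")$fold, 1)

  # missing reference measurement is an error
  expect_error(comparative_ct(recs[-2, ], "ACTB", "calibrator"),
               "reference gene")
})

test_that("comparative CT matches a spreadsheet-style recomputation", {
  set.seed(31)
  conds <- c("calibrator", "1h", "8h")
  genes <- c("IL6", "CXCL2", "PTGS2")
  recs <- expand.grid(rep = 1:3, condition = conds, gene = c(genes, "ACTB"),
                      stringsAsFactors = FALSE)
  recs$sample_id <- paste0(recs$condition, "_", recs$rep)
  recs$ct <- runif(nrow(recs), 15, 30)
  # reference CT must be shared per sample, not per gene: rebuild ACTB rows
  ref <- recs[recs$gene == "ACTB", ]
  out <- comparative_ct(recs[, c("sample_id", "gene", "ct", "condition")],
                        "ACTB", "calibrator")
  for (g in genes) for (cond in c("1h", "8h")) {
    dct <- function(cc) {
      sub <- recs[recs$gene == g & recs$condition == cc, ]
      refct <- ref$ct[match(sub$sample_id, ref$sample_id)]
      mean(sub$ct - refct)
    }
    dd <- dct(cond) - dct("calibrator")
    row <- out[out$gene == g & out$condition == cond, ]
    expect_equal(row$ddct, dd, tolerance = 1e-12)
    expect_equal(row$fold, 2^(-dd), tolerance = 1e-12)
  }
})
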