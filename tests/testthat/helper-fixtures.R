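# Fixture builders and independent oracles shared across the suite. Oracles
# deliberately avoid the package's vectorized code paths: they recompute from
# first principles with plain loops.

make_samples <- function(times = c(0, 1, 8), reps = 3, condition = "stim") {
  grid <- expand.grid(replicate = seq_len(reps), time_h = times)
  data.frame(sample_id = sprintf("s_t%g_r%d", grid$time_h, grid$replicate),
             condition = condition, time_h = grid$time_h,
             replicate = grid$replicate)
}

make_expr <- function(values, times = c(0, 1, 8), reps = 3,
                      condition = "stim") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  }
  meta <- make_samples(times, reps, condition)
  stopifnot(ncol(values) == nrow(meta))
  colnames(values) <- meta$sample_id
  expression_matrix(values, meta)
}

random_pfm <- function(L, id = "RND") {
  counts <- matrix(stats::rexp(L * 4) * 20, L, 4)
  motif_matrix(id, id, counts)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# position-by-position recomputation of the normalized site score
oracle_site_score <- function(motif, oligo) {
  f <- motif$counts + motif$pseudocount
  f <- f / rowSums(f)
  chars <- strsplit(oligo, "")[[1]]
  base_idx <- c(A = 1, C = 2, G = 3, T = 4)
  raw <- 0; smin <- 0; smax <- 0
  for (i in seq_len(nrow(f))) {
    raw <- raw + f[i, base_idx[[chars[i]]]]
    smin <- smin + min(f[i, ])
    smax <- smax + max(f[i, ])
  }
  if (smax == smin) return(1)
  unname((raw - smin) / (smax - smin))
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# exhaustive window enumeration on both strands with the tie rules:
# smaller position first, '+' before '-'
oracle_best_hit <- function(motif, sequence) {
  L <- nrow(motif$counts)
  n <- nchar(sequence)
  best <- list(score = -Inf, position = NA_integer_, strand = NA_character_)
  any_window <- FALSE
  for (pos in seq_len(n - L + 1)) {
    win <- substr(sequence, pos, pos + L - 1)
    if (grepl("N", win)) next
    any_window <- TRUE
    for (strand in c("+", "-")) {
      oligo <- if (strand == "+") win else oracle_revcomp(win)
      sc <- oracle_site_score(motif, oligo)
      if (sc > best$score) {
        best <- list(score = sc, position = pos, strand = strand)
      }
    }
  }
  if (!any_window) return(list(score = 0, position = NA_integer_,
                               strand = NA_character_))
  best
}

syn_motifs <- function() {
  read_jaspar_pfm(system.file("extdata", "synthetic_motifs.pfm",
                              package = "grnflow"))
}
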