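BASES <- c("A", "C", "G", "T")

#' Construct a motif position frequency matrix
#'
#' @param id Motif identifier (e.g. a JASPAR-style accession).
#' @param name Factor name.
#' @param counts L x 4 non-negative numeric matrix of base counts, columns
#'   in A, C, G, T order (rows are motif positions).
#' @param pseudocount Added to every cell before per-position normalization
#'   (default 0.01); guards against zero frequencies in sparse matrices.
#' @return Object of class `motif_matrix`.
#' @export
motif_matrix <- function(id, name = id, counts, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) stop("counts must have 4 columns (A, C, G, T)")
  if (nrow(counts) < 1) stop("motif must have at least one position")
  if (any(counts < 0)) stop("counts must be non-negative")
  stopifnot(pseudocount >= 0)
  if (any(rowSums(counts) + 4 * pseudocount <= 0)) {
    stop("every position needs a positive total count after pseudocount")
  }
  colnames(counts) <- BASES
  rownames(counts) <- NULL
  structure(list(id = id, name = name, counts = counts,
                 pseudocount = pseudocount), class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("motif_matrix ", x$id, " (", x$name, "), length ", nrow(x$counts),
      "\n", sep = "")
  invisible(x)
}

#' Motif length
#' @param motif A `motif_matrix`.
#' @return Integer number of positions.
#' @export
motif_length <- function(motif) nrow(motif$counts)

motif_freq <- function(motif) {
  f <- motif$counts + motif$pseudocount
  f / rowSums(f)
}

#' Consensus and anti-consensus sequences of a motif
#'
#' The consensus takes the most frequent base at every position (ties to the
#' earlier base in A, C, G, T order) and by construction scores 1.0; the
#' anti-consensus takes the least frequent base and scores 0.0.
#'
#' @param motif A `motif_matrix`.
#' @return Character string.
#' @export
consensus_sequence <- function(motif) {
  f <- motif_freq(motif)
  paste(BASES[apply(f, 1, which.max)], collapse = "")
}

#' @rdname consensus_sequence
#' @export
anticonsensus_sequence <- function(motif) {
  f <- motif_freq(motif)
  paste(BASES[apply(f, 1, which.min)], collapse = "")
}

#' Read motifs from a JASPAR-style PFM text file
#'
#' Accepts the standard four-row format with base-labeled rows and optional
#' brackets (`A [ 3 0 19 ... ]`) as well as the unlabeled four-row variant
#' (rows in A, C, G, T order). Headers are `>ID NAME` lines.
#'
#' @param path Path to the PFM file.
#' @param pseudocount Pseudocount stored on every motif (default 0.01).
#' @return Named list of `motif_matrix` objects (names are motif ids).
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' header lines found in ", path)
  bounds <- c(heads, length(lines) + 1)
  out <- list()
  for (k in seq_along(heads)) {
    header <- sub("^>\\s*", "", lines[heads[k]])
    fields <- strsplit(trimws(header), "\\s+")[[1]]
    id <- fields[1]
    name <- if (length(fields) > 1) paste(fields[-1], collapse = " ") else id
    body <- lines[seq(heads[k] + 1, bounds[k + 1] - 1)]
    body <- body[!grepl("^>", body)]
    if (length(body) < 4) stop("motif '", id, "': expected 4 count rows")
    body <- body[1:4]
    labels <- toupper(sub("^\\s*([A-Za-z]).*$", "\\1", body))
    labeled <- all(grepl("^\\s*[A-Za-z]", body))
    rows <- vector("list", 4)
    order_idx <- 1:4
    if (labeled) {
      if (!setequal(labels, BASES)) {
        bad <- setdiff(labels, BASES)
        stop("motif '", id, "': unknown base label(s): ",
             paste(bad, collapse = ", "))
      }
      order_idx <- match(BASES, labels)
    }
    for (j in 1:4) {
      line <- body[if (labeled) order_idx[j] else j]
      line <- gsub("^\\s*[A-Za-z:]+\\s*", "", line)
      line <- gsub("[][|]", " ", line)
      nums <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
      if (!length(nums) || anyNA(nums)) {
        stop("motif '", id, "': unparsable count row")
      }
      rows[[j]] <- nums
    }
    lens <- lengths(rows)
    if (length(unique(lens)) != 1) {
      stop("motif '", id, "': count rows have unequal lengths (",
           paste(lens, collapse = ", "), ")")
    }
    counts <- t(do.call(rbind, rows))  # L x 4
    out[[id]] <- motif_matrix(id, name, counts, pseudocount)
  }
  out
}

#' Write motifs in JASPAR PFM format
#'
#' @param motifs List of `motif_matrix` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  if (inherits(motifs, "motif_matrix")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$id, " ", m$name), con)
    for (j in 1:4) {
      writeLines(paste0(BASES[j], " [ ",
                        paste(format(m$counts[, j], trim = TRUE),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Construct a fixed-length promoter set
#'
#' @param sequences Named character vector of equal-length promoter
#'   sequences over A, C, G, T, N; names are gene symbols.
#' @param region Length-2 integer vector `(start_offset, end_offset)`
#'   relative to the transcription start site; default `c(-950, 50)`, so the
#'   default promoter length is 1001 nt.
#' @return Object of class `promoter_set`.
#' @export
promoter_set <- function(sequences, region = c(-950, 50)) {
  sequences <- toupper(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("promoter sequences must be named by gene symbol")
  }
  if (anyDuplicated(names(sequences))) stop("duplicate gene symbols")
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1) {
    stop("all promoter sequences must have equal length")
  }
  span <- region[2] - region[1] + 1
  if (length(sequences) && lens[1] != span) {
    stop("sequence length (", lens[1], ") != region span (", span, ")")
  }
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("sequences may only contain A, C, G, T, N")
  }
  structure(list(sequences = sequences, region = region),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("promoter_set: ", length(x$sequences), " promoters, region ",
      x$region[1], "..", x$region[2], " relative to TSS\n", sep = "")
  invisible(x)
}

#' Read promoters from FASTA (record ids are gene symbols)
#'
#' @param path FASTA file of equal-length promoter sequences.
#' @param region Region offsets relative to the TSS; defaults to the span of
#'   the sequences ending at +50.
#' @return A `promoter_set`.
#' @export
read_promoters <- function(path, region = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  x <- as.character(seqs)
  names(x) <- sub("\\s.*$", "", names(seqs))
  if (is.null(region)) {
    len <- if (length(x)) nchar(x[1]) else 1001
    region <- c(50 - len + 1, 50)
  }
  promoter_set(x, region)
}

#' Write promoters to FASTA
#'
#' @param promoters A `promoter_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_promoters <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequences)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

encode_seq <- function(s) {
  x <- match(strsplit(s, "")[[1]], c(BASES, "N"))
  if (anyNA(x)) stop("sequence contains a base outside A, C, G, T, N")
  x
}

# min-max bounds of the additive frequency score
score_bounds <- function(freq) {
  list(smin = sum(apply(freq, 1, min)), smax = sum(apply(freq, 1, max)))
}

#' Normalized match score of a motif against a single oligo
#'
#' The raw score of an L-mer is the sum over positions of the (pseudocounted,
#' per-position normalized) frequency of the observed base. It is min-max
#' normalized to the 0-1 relative scale on which 1 is the best achievable
#' match (the consensus) and 0 the worst (the anti-consensus). A degenerate
#' motif whose best and worst scores coincide scores 1.0.
#'
#' @param motif A `motif_matrix`.
#' @param oligo Character string over A, C, G, T with length equal to the
#'   motif length.
#' @return Score in `[0, 1]`.
#' @export
site_score <- function(motif, oligo) {
  L <- motif_length(motif)
  if (nchar(oligo) != L) {
    stop("oligo length (", nchar(oligo), ") != motif length (", L, ")")
  }
  code <- encode_seq(toupper(oligo))
  if (any(code == 5)) stop("oligo may not contain N")
  f <- motif_freq(motif)
  raw <- sum(f[cbind(seq_len(L), code)])
  b <- score_bounds(f)
  if (b$smax == b$smin) return(1)
  (raw - b$smin) / (b$smax - b$smin)
}

# Window scores for all promoters at once. codes: genes x len integer matrix
# (1..4 bases, 5 = N). Returns genes x n_windows matrix of normalized
# scores; windows containing N are NA.
window_scores <- function(freq, codes) {
  L <- nrow(freq)
  len <- ncol(codes)
  if (len < L) stop("sequence shorter than motif")
  P <- len - L + 1
  G <- nrow(codes)
  fmat <- cbind(freq, NA_real_)  # column 5 poisons N-containing windows
  S <- matrix(0, G, P)
  for (i in seq_len(L)) {
    block <- codes[, i:(i + P - 1), drop = FALSE]
    S <- S + matrix(fmat[cbind(rep(i, length(block)), as.vector(block))],
                    G, P)
  }
  b <- score_bounds(freq)
  if (b$smax == b$smin) {
    S[!is.na(S)] <- 1
    return(S)
  }
  (S - b$smin) / (b$smax - b$smin)
}

# frequency matrix of the reverse complement of a motif
revcomp_freq <- function(freq) {
  freq[rev(seq_len(nrow(freq))), c(4, 3, 2, 1), drop = FALSE]
}

#' Reverse complement of a DNA string (N preserved)
#' @param s Character string over A, C, G, T, N.
#' @return Character string.
#' @export
reverse_complement <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

#' Best-scoring binding site of a motif in a sequence
#'
#' Scores every window on both strands (the minus strand via the
#' reverse-complemented matrix), skipping windows that contain N, and
#' returns the maximum. Ties go to the smaller start position, then to the
#' plus strand. If every window is skipped the score is 0 with a missing
#' position.
#'
#' @param motif A `motif_matrix`.
#' @param sequence Character string over A, C, G, T, N, at least as long as
#'   the motif.
#' @return List with `gene` (NA here; filled by [scan_universe()]), `score`,
#'   `position` (1-based window start within the region) and `strand`
#'   (`"+"`/`"-"`).
#' @export
best_hit <- function(motif, sequence) {
  codes <- matrix(encode_seq(toupper(sequence)), nrow = 1)
  f <- motif_freq(motif)
  sp <- window_scores(f, codes)[1, ]
  sm <- window_scores(revcomp_freq(f), codes)[1, ]
  pick_best(sp, sm)
}

pick_best <- function(sp, sm) {
  if (all(is.na(sp)) && all(is.na(sm))) {
    return(list(score = 0, position = NA_integer_, strand = NA_character_))
  }
  best <- max(c(sp, sm), na.rm = TRUE)
  hit_p <- which(!is.na(sp) & sp == best)
  hit_m <- which(!is.na(sm) & sm == best)
  pos <- min(c(hit_p, hit_m))
  strand <- if (pos %in% hit_p) "+" else "-"
  list(score = best, position = as.integer(pos), strand = strand)
}

#' Best per-gene motif scores over a promoter universe
#'
#' @param motifs List of `motif_matrix` objects (or a single one).
#' @param promoters A `promoter_set`.
#' @param details Logical; when TRUE also return the best hit position and
#'   strand per (gene, motif).
#' @return Genes-by-motifs numeric matrix of best normalized scores
#'   (rownames = gene symbols, colnames = motif ids). With
#'   `details = TRUE`, a list with elements `scores`, `positions`,
#'   `strands`.
#' @export
scan_universe <- function(motifs, promoters, details = FALSE) {
  if (inherits(motifs, "motif_matrix")) motifs <- list(motifs)
  stopifnot(inherits(promoters, "promoter_set"))
  seqs <- promoters$sequences
  if (!length(seqs) || !length(motifs)) stop("empty motifs or promoters")
  codes <- t(vapply(seqs, encode_seq, integer(nchar(seqs[1]))))
  ids <- vapply(motifs, function(m) m$id, character(1))
  G <- length(seqs)
  scores <- matrix(NA_real_, G, length(motifs),
                   dimnames = list(names(seqs), ids))
  positions <- matrix(NA_integer_, G, length(motifs),
                      dimnames = dimnames(scores))
  strands <- matrix(NA_character_, G, length(motifs),
                    dimnames = dimnames(scores))
  for (j in seq_along(motifs)) {
    f <- motif_freq(motifs[[j]])
    sp <- window_scores(f, codes)
    sm <- window_scores(revcomp_freq(f), codes)
    for (g in seq_len(G)) {
      h <- pick_best(sp[g, ], sm[g, ])
      scores[g, j] <- h$score
      positions[g, j] <- h$position
      strands[g, j] <- h$strand
    }
  }
  if (details) list(scores = scores, positions = positions, strands = strands)
  else scores
}

#' Z-test enrichment of motif scores in a foreground gene set
#'
#' Compares the mean best-site score of the foreground genes against the
#' whole promoter universe: `z = (fg_mean - bg_mean) / (bg_sd / sqrt(n_fg))`
#' with the population standard deviation of all universe scores, and a
#' one-tailed (enrichment-only) standard normal p-value.
#'
#' @param score_table Genes-by-motifs score matrix from [scan_universe()].
#' @param fg_genes Character vector of foreground gene symbols, a subset of
#'   the universe.
#' @param motifs Motif ids to test (default: all columns).
#' @return Data frame with columns `motif_id`, `z`, `p`, `fg_mean`,
#'   `bg_mean`, `bg_sd`, `n_fg`, ordered by increasing p.
#' @export
enrichment_ztest <- function(score_table, fg_genes, motifs = NULL) {
  if (!length(fg_genes)) stop("empty foreground gene set")
  if (nrow(score_table) < 2) stop("universe needs >= 2 genes")
  absent <- setdiff(fg_genes, rownames(score_table))
  if (length(absent)) {
    stop("foreground gene(s) absent from the score table: ",
         paste(absent, collapse = ", "))
  }
  if (is.null(motifs)) motifs <- colnames(score_table)
  res <- lapply(motifs, function(mid) {
    x <- score_table[, mid]
    bg_mean <- mean(x)
    bg_sd <- sqrt(mean((x - bg_mean)^2))
    if (bg_sd == 0) stop("zero background variance for motif ", mid)
    fg <- x[fg_genes]
    n_fg <- length(fg)
    z <- (mean(fg) - bg_mean) / (bg_sd / sqrt(n_fg))
    data.frame(motif_id = mid, z = z,
               p = stats::pnorm(z, lower.tail = FALSE),
               fg_mean = mean(fg), bg_mean = bg_mean, bg_sd = bg_sd,
               n_fg = n_fg, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out[order(out$p, out$motif_id), , drop = FALSE]
}

#' Foreground genes carrying a well-matched site for a motif
#'
#' @inheritParams enrichment_ztest
#' @param motif_id Motif column to inspect.
#' @param threshold Minimum normalized score (inclusive, default 0.95 --- the
#'   "well-matched site" rule).
#' @return Character vector of gene symbols.
#' @export
well_matched_genes <- function(score_table, fg_genes, motif_id,
                               threshold = 0.95) {
  absent <- setdiff(fg_genes, rownames(score_table))
  if (length(absent)) {
    stop("gene(s) absent from the score table: ",
         paste(absent, collapse = ", "))
  }
  fg <- score_table[fg_genes, motif_id]
  fg_genes[fg >= threshold]
}
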