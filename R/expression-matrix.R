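#' Construct an expression matrix with sample metadata
#'
#' Bundles a probes-by-samples matrix of log2 intensities with per-sample
#' metadata (condition label, time point in hours, replicate number). This is
#' the entry point of the workflow: all downstream filtering, differential
#' testing and temporal profiling operate on this container.
#'
#' @param values Numeric matrix, probes in rows (rownames are probeset ids),
#'   samples in columns (colnames are sample ids). All values must be finite
#'   log2 intensities.
#' @param samples Data frame with columns `sample_id`, `condition`, `time_h`
#'   (non-negative, hours) and `replicate` (positive integer), one row per
#'   column of `values`, in matching order.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `samples`.
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stop("`values` must have probeset rownames")
  }
  if (nrow(values) == 0) rownames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate probeset id(s): ", paste(dup, collapse = ", "))
  }
  if (!all(is.finite(values))) stop("all expression values must be finite")
  samples <- as.data.frame(samples)
  required <- c("sample_id", "condition", "time_h", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("sample metadata rows (", nrow(samples), ") != matrix columns (",
         ncol(values), ")")
  }
  if (!is.null(colnames(values)) &&
      !identical(as.character(samples$sample_id), colnames(values))) {
    stop("sample metadata order does not match matrix column order")
  }
  if (any(samples$time_h < 0)) stop("time_h must be non-negative")
  if (any(samples$replicate < 1)) stop("replicate must be a positive integer")
  key <- paste(samples$condition, samples$time_h, samples$replicate)
  if (anyDuplicated(key)) {
    stop("(condition, time_h, replicate) must be unique across samples")
  }
  colnames(values) <- as.character(samples$sample_id)
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("conditions: ", paste(unique(x$samples$condition), collapse = ", "),
      "; time points (h): ",
      paste(sort(unique(x$samples$time_h)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Probeset ids of an expression matrix
#' @param m An `expression_matrix`.
#' @return Character vector of probeset ids.
#' @export
probes <- function(m) rownames(m$values)

#' Read an expression matrix and its sample metadata from TSV
#'
#' The expression file has a header of sample ids and a first column of
#' probeset ids; the metadata file has columns `sample_id`, `condition`,
#' `time_h`, `replicate`. Row and column order is preserved from the files.
#'
#' @param path Path to the expression TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression TSV needs an id column plus >=1 sample")
  ids <- tab[[1]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate probeset id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric value at probeset '", ids[bad[1]], "', sample '",
         colnames(vals)[bad[2]], "'")
  }
  rownames(vals) <- ids
  meta <- utils::read.delim(meta_path, check.names = FALSE)
  missing <- setdiff(colnames(vals), as.character(meta$sample_id))
  if (length(missing)) {
    stop("sample(s) without metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(vals), as.character(meta$sample_id)), , drop = FALSE]
  rownames(meta) <- NULL
  expression_matrix(vals, meta)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' @param m An `expression_matrix`.
#' @param path Output path for the expression table.
#' @param meta_path Optional output path for the sample metadata table.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(m, path, meta_path = NULL) {
  # full-precision doubles so write-then-read round-trips exactly
  chr <- apply(m$values, 2, function(x) sprintf("%.17g", x))
  chr <- matrix(chr, nrow = nrow(m$values),
                dimnames = dimnames(m$values))
  df <- data.frame(probeset_id = probes(m), chr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(m$samples, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Remove probesets not reliably above the array noise floor
#'
#' A probeset is discarded when its log2 intensity falls below `cutoff` in at
#' least `min_below` samples. Values exactly equal to the cutoff count as
#' detectable. With the defaults this keeps a probe only if it exceeds the
#' noise floor on at least 3 of 9 chips, the detectability rule used for
#' 3 time points x 3 replicates designs.
#'
#' @param m An `expression_matrix`.
#' @param cutoff Log2 intensity noise floor (default 6.0).
#' @param min_below Number of below-cutoff samples required for removal.
#'   Defaults to `ceiling(7/9 * n_samples)`, the 7-of-9 rule rescaled to the
#'   actual sample count.
#' @return Filtered `expression_matrix` with attribute `removed`, the ids of
#'   the discarded probesets.
#' @export
filter_noise <- function(m, cutoff = 6.0, min_below = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  n <- ncol(m$values)
  if (nrow(m$values) == 0) stop("empty expression matrix")
  if (is.null(min_below)) min_below <- ceiling(7 / 9 * n)
  if (min_below > n) stop("min_below exceeds the number of samples")
  below <- rowSums(m$values < cutoff)
  drop <- below >= min_below
  out <- expression_matrix(m$values[!drop, , drop = FALSE], m$samples)
  attr(out, "removed") <- rownames(m$values)[drop]
  out
}

#' Read a probeset annotation table
#'
#' @param path TSV with columns `probeset_id`, `gene_symbol`, `gene_id`,
#'   `refseq`. An empty `gene_symbol` marks an unmapped probeset.
#' @return Data frame of the annotation.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  required <- c("probeset_id", "gene_symbol")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols)) {
    stop("annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ann$probeset_id)) {
    stop("duplicate probeset_id in annotation")
  }
  ann
}

#' Collapse probesets to one row per gene symbol
#'
#' Probesets mapping to the same gene symbol are averaged (arithmetic mean of
#' the log2 values, per sample). Probesets absent from the annotation or with
#' an empty gene symbol are excluded from the gene-level output and reported.
#'
#' @param m An `expression_matrix`, or a numeric matrix/data frame keyed by
#'   probeset rownames (e.g. a per-probe statistics table).
#' @param ann Annotation data frame with columns `probeset_id` and
#'   `gene_symbol` (see [read_annotation_tsv()]).
#' @return For an `expression_matrix` input, a gene-level
#'   `expression_matrix`; otherwise a gene-level matrix. Either way the
#'   result carries attribute `unmapped`, the probeset ids that were dropped.
#' @export
consolidate_probesets <- function(m, ann) {
  vals <- if (inherits(m, "expression_matrix")) m$values else as.matrix(m)
  ids <- rownames(vals)
  sym <- ann$gene_symbol[match(ids, ann$probeset_id)]
  mapped <- !is.na(sym) & nzchar(sym)
  unmapped <- ids[!mapped]
  if (!any(mapped)) {
    empty <- vals[0, , drop = FALSE]
    out <- if (inherits(m, "expression_matrix")) {
      expression_matrix(empty, m$samples)
    } else empty
    attr(out, "unmapped") <- unmapped
    return(out)
  }
  sub <- vals[mapped, , drop = FALSE]
  g <- factor(sym[mapped], levels = unique(sym[mapped]))
  agg <- rowsum(sub, g) / as.vector(table(g))
  out <- if (inherits(m, "expression_matrix")) {
    expression_matrix(agg, m$samples)
  } else agg
  attr(out, "unmapped") <- unmapped
  out
}

#' Per-gene mean series over time points
#'
#' Averages replicates within each (condition, time) cell and returns a
#' genes-by-time-points matrix ordered by increasing time, the shape consumed
#' by the temporal-profile operations.
#'
#' @param m An `expression_matrix` (typically gene-level).
#' @param condition Optional condition label to restrict to; default uses all
#'   samples.
#' @return Numeric matrix, rows = genes, columns = time points (named by
#'   `time_h`).
#' @export
mean_time_series <- function(m, condition = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  s <- m$samples
  keep <- if (is.null(condition)) rep(TRUE, nrow(s)) else s$condition == condition
  times <- sort(unique(s$time_h[keep]))
  out <- sapply(times, function(t) {
    cols <- which(keep & s$time_h == t)
    rowMeans(m$values[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(probes(m), as.character(times)))
  out
}
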