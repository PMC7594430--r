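# The shared count container: transcript-level (isoform-resolved) read counts
# with per-transcript annotation. Counts are deliberately kept at transcript
# resolution; aggregating to gene level can mask changes restricted to single
# splice variants, so gene symbols exist only for cross-cohort matching.

#' Construct a transcript-level count matrix
#'
#' The central data container of the package: an integer matrix of read
#' counts (transcripts in rows, samples in columns) together with a gene
#' symbol and a transcript length for every row. Symbols may repeat across
#' isoforms of the same gene; transcript and sample identifiers must be
#' unique.
#'
#' @param counts Non-negative integer matrix with rownames (transcript ids)
#'   and colnames (sample ids).
#' @param gene_symbols Character vector, one symbol per transcript.
#' @param lengths_bp Positive integer vector of transcript lengths in bases.
#' @return An object of class `count_matrix` with fields `counts`,
#'   `gene_symbols`, `lengths_bp`, `transcript_ids`, `sample_ids`.
#' @examples
#' cm <- count_matrix(
#'   matrix(0:3, 2, 2, dimnames = list(c("t1", "t2"), c("s1", "s2"))),
#'   gene_symbols = c("GENE1", "GENE2"), lengths_bp = c(1000L, 2500L)
#' )
#' @export
count_matrix <- function(counts, gene_symbols, lengths_bp) {
  if (!is.matrix(counts)) {
    cdeg_stop("`counts` must be a matrix", "cdeg_format_error")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    cdeg_stop("`counts` must carry transcript rownames and sample colnames",
              "cdeg_format_error")
  }
  obj <- structure(
    list(
      counts = counts,
      gene_symbols = as.character(gene_symbols),
      lengths_bp = as.integer(round(lengths_bp)),
      transcript_ids = rownames(counts),
      sample_ids = colnames(counts)
    ),
    class = "count_matrix"
  )
  validate_count_matrix(obj)
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  gene symbols: %d unique\n", length(unique(x$gene_symbols))))
  cat(sprintf("  length range: %d-%d bp\n",
              min(x$lengths_bp), max(x$lengths_bp)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

validate_count_matrix <- function(cm) {
  counts <- cm$counts
  if (anyDuplicated(rownames(counts))) {
    cdeg_stop("duplicated transcript ids", "cdeg_format_error")
  }
  if (anyDuplicated(colnames(counts))) {
    cdeg_stop("duplicated sample ids", "cdeg_format_error")
  }
  if (length(cm$gene_symbols) != nrow(counts)) {
    cdeg_stop("gene_symbols length does not match transcript count",
              "cdeg_format_error")
  }
  if (length(cm$lengths_bp) != nrow(counts)) {
    cdeg_stop("lengths_bp length does not match transcript count",
              "cdeg_format_error")
  }
  if (!all(is_wholenumber(counts))) {
    cdeg_stop("counts must be whole numbers", "cdeg_format_error")
  }
  if (any(counts < 0)) {
    cdeg_stop("counts must be non-negative", "cdeg_format_error")
  }
  if (any(!is.finite(cm$lengths_bp)) || any(cm$lengths_bp < 1)) {
    cdeg_stop("transcript lengths must be >= 1 bp", "cdeg_format_error")
  }
  invisible(cm)
}

# Subset a count_matrix by transcript ids and/or sample ids.
subset_count_matrix <- function(cm, transcripts = NULL, samples = NULL) {
  ti <- transcripts %||% cm$transcript_ids
  si <- samples %||% cm$sample_ids
  ridx <- match(ti, cm$transcript_ids)
  cidx <- match(si, cm$sample_ids)
  if (anyNA(ridx)) cdeg_stop("unknown transcript id in subset",
                             "cdeg_design_error")
  if (anyNA(cidx)) cdeg_stop("unknown sample id in subset",
                             "cdeg_design_error")
  count_matrix(cm$counts[ridx, cidx, drop = FALSE],
               cm$gene_symbols[ridx], cm$lengths_bp[ridx])
}

#' Read a count matrix from a tab-separated file
#'
#' The expected layout is a header row followed by one row per transcript:
#' columns `transcript_id`, `gene_symbol`, `length_bp`, then one integer
#' column per sample. Column order is preserved.
#'
#' @param path Path to a TSV file.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  need <- c("transcript_id", "gene_symbol", "length_bp")
  if (ncol(df) < 4L || !identical(names(df)[1:3], need)) {
    cdeg_stop("count matrix must start with transcript_id, gene_symbol, length_bp",
              "cdeg_format_error")
  }
  sample_cols <- names(df)[-(1:3)]
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(counts)) {
    cdeg_stop("count columns must be numeric", "cdeg_format_error")
  }
  storage.mode(counts) <- "double"
  rownames(counts) <- df$transcript_id
  colnames(counts) <- sample_cols
  count_matrix(counts, df$gene_symbol, df$length_bp)
}

#' Write a count matrix to a tab-separated file
#'
#' Inverse of [read_count_matrix()]; `read(write(x))` reproduces `x` exactly.
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(
    transcript_id = cm$transcript_ids,
    gene_symbol = cm$gene_symbols,
    length_bp = cm$lengths_bp,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(cm$counts, check.names = FALSE))
  write_tsv_file(df, path)
}
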