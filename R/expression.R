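# Normalized expression metrics: RPKM, prevalence filtering and fold
# changes. RPKM divides each count by the transcript length in kilobases and
# by the sample's informative reads in millions; "informative reads" are the
# column sums of the supplied count matrix.

#' Compute reads per kilobase per million informative reads
#'
#' `rpkm[g, s] = count[g, s] / (length_bp[g] / 1000) / (total[s] / 1e6)`.
#' A value is zero exactly when the count is zero.
#'
#' @param cm A [count_matrix()].
#' @return An object of class `rpkm_matrix` with the same axes as `cm`.
#' @export
compute_rpkm <- function(cm) {
  totals <- colSums(cm$counts)
  if (any(totals <= 0)) {
    cdeg_stop(sprintf("sample(s) with zero total count: %s",
                      paste(cm$sample_ids[totals <= 0], collapse = ", ")),
              "cdeg_design_error")
  }
  vals <- cm$counts / (cm$lengths_bp / 1000)
  vals <- sweep(vals, 2, totals / 1e6, "/")
  structure(
    list(values = vals, gene_symbols = cm$gene_symbols,
         lengths_bp = cm$lengths_bp, transcript_ids = cm$transcript_ids,
         sample_ids = cm$sample_ids),
    class = "rpkm_matrix"
  )
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat(sprintf("rpkm_matrix: %d transcripts x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Pull the numeric matrix out of a count_matrix / rpkm_matrix / plain matrix.
expr_values <- function(x) {
  if (inherits(x, "count_matrix")) return(x$counts)
  if (inherits(x, "rpkm_matrix")) return(x$values)
  if (is.matrix(x)) return(x)
  cdeg_stop("expected a count_matrix, rpkm_matrix or matrix",
            "cdeg_format_error")
}

check_two_groups <- function(groups, n_cols) {
  groups <- as.factor(groups)
  if (length(groups) != n_cols) {
    cdeg_stop("group labels must match the sample columns",
              "cdeg_design_error")
  }
  if (nlevels(droplevels(groups)) != 2L) {
    cdeg_stop("exactly two non-empty groups are required",
              "cdeg_design_error")
  }
  droplevels(groups)
}

#' Prevalence filter on RPKM
#'
#' A transcript is kept when, in at least one diagnostic group, the fraction
#' of samples in which it is present (RPKM strictly above `tau`) reaches
#' `phi`. The fraction comparison is done on integer sample counts
#' (`n_present >= ceiling(phi * n)` up to exact rational rounding) so that
#' e.g. 70% of 10 samples means 7, never 7.000000001.
#'
#' @param rpkm An [compute_rpkm()] result (or a plain matrix).
#' @param groups Per-sample group labels (two non-empty groups).
#' @param tau Detection threshold, default 0.01 RPKM.
#' @param phi Required fraction, default 0.70.
#' @return Character vector of kept transcript ids, with a per-transcript
#'   report data frame in `attr(, "report")`.
#' @export
prevalence_filter <- function(rpkm, groups, tau = 0.01, phi = 0.70) {
  vals <- expr_values(rpkm)
  groups <- check_two_groups(groups, ncol(vals))
  present <- vals > tau
  lv <- levels(groups)
  frac <- sapply(lv, function(g) {
    cols <- which(groups == g)
    rowSums(present[, cols, drop = FALSE]) / length(cols)
  })
  # minimal integer count of present samples satisfying n_present/n >= phi
  need <- vapply(lv, function(g) {
    n <- sum(groups == g)
    ceiling(phi * n - 1e-9)
  }, numeric(1))
  npresent <- sapply(lv, function(g) {
    cols <- which(groups == g)
    rowSums(present[, cols, drop = FALSE])
  })
  kept_mat <- sweep(npresent, 2, need, ">=")
  kept <- rowSums(kept_mat) > 0
  ids <- if (inherits(rpkm, "rpkm_matrix")) rpkm$transcript_ids else
    rownames(vals) %||% as.character(seq_len(nrow(vals)))
  report <- data.frame(transcript_id = ids, check.names = FALSE,
                       stringsAsFactors = FALSE)
  for (g in lv) report[[paste0("frac_", g)]] <- frac[, g]
  report$kept <- kept
  structure(ids[kept], report = report)
}

#' Group-mean fold change
#'
#' Ratio of pseudocount-stabilised group means, affected over unaffected,
#' with its log2 and direction.
#'
#' @param x Expression values (count or RPKM matrix).
#' @param groups Per-sample labels; must contain `affected` and
#'   `unaffected`.
#' @param pseudocount Added to both group means; default 0.25.
#' @return Data frame with `transcript_id`, `mean_affected`,
#'   `mean_unaffected`, `ratio`, `log2fc`, `direction`.
#' @export
fold_change <- function(x, groups, pseudocount = 0.25) {
  vals <- expr_values(x)
  groups <- check_two_groups(groups, ncol(vals))
  if (!setequal(levels(groups), c("affected", "unaffected"))) {
    cdeg_stop("groups must be labelled affected/unaffected",
              "cdeg_design_error")
  }
  if (pseudocount <= 0) {
    cdeg_stop("pseudocount must be positive", "cdeg_config_error")
  }
  m_aff <- rowMeans(vals[, groups == "affected", drop = FALSE])
  m_una <- rowMeans(vals[, groups == "unaffected", drop = FALSE])
  ratio <- (m_aff + pseudocount) / (m_una + pseudocount)
  ids <- if (is.list(x)) x$transcript_ids else
    rownames(vals) %||% as.character(seq_len(nrow(vals)))
  data.frame(
    transcript_id = ids,
    mean_affected = m_aff, mean_unaffected = m_una,
    ratio = ratio, log2fc = log2(ratio),
    direction = ifelse(ratio > 1, "up", ifelse(ratio < 1, "down", "flat")),
    stringsAsFactors = FALSE
  )
}

#' Within-pair fold changes for the twin design
#'
#' One log2 fold change (affected over unaffected, pseudocount-stabilised)
#' per transcript per twin pair.
#'
#' @param x Expression values (count or RPKM matrix).
#' @param pairs Pair table with columns `pair_id`, `affected`, `unaffected`
#'   (sample ids), as produced by the sample sheet for the twin cohort.
#' @param pseudocount Added to both members' values; default 0.25.
#' @return Numeric matrix, transcripts x pairs, of log2 fold changes.
#' @export
pairwise_fold_change <- function(x, pairs, pseudocount = 0.25) {
  vals <- expr_values(x)
  sample_ids <- if (is.list(x)) x$sample_ids else colnames(vals)
  ai <- match(pairs$affected, sample_ids)
  ui <- match(pairs$unaffected, sample_ids)
  if (anyNA(ai) || anyNA(ui)) {
    cdeg_stop("pair table references samples absent from the matrix",
              "cdeg_design_error")
  }
  out <- log2((vals[, ai, drop = FALSE] + pseudocount) /
                (vals[, ui, drop = FALSE] + pseudocount))
  colnames(out) <- pairs$pair_id
  ids <- if (is.list(x)) x$transcript_ids else rownames(vals)
  rownames(out) <- ids
  out
}
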