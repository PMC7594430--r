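# Appearance-count consensus across methods: each method contributes its
# top-K transcripts, and transcripts are ranked by how many method lists
# they appear on.

#' Top-K transcript list for one method
#'
#' Results are ranked by adjusted p (or raw p), with ties broken by raw p
#' and then lexicographic transcript id, so the cut at K is deterministic.
#'
#' @param res A `DEResult` data frame.
#' @param k List length.
#' @param rank_by `"p_adj"` (default) or `"p_raw"`.
#' @return Ordered character vector of at most `k` transcript ids.
#' @export
top_k_list <- function(res, k, rank_by = c("p_adj", "p_raw")) {
  rank_by <- match.arg(rank_by)
  if (!nrow(res)) cdeg_stop("empty result set", "cdeg_design_error")
  if (k < 1) cdeg_stop("k must be >= 1", "cdeg_config_error")
  ord <- order(res[[rank_by]], res$p_raw, res$transcript_id)
  res$transcript_id[ord][seq_len(min(k, nrow(res)))]
}

#' Appearance-count consensus table
#'
#' @param lists Named list of per-method top-K id vectors.
#' @param all_results Combined `DEResult` rows for every method (used for
#'   the per-method best adjusted p and the mean log2 fold change).
#' @return Data frame with one row per transcript appearing on at least one
#'   list: per-method membership flags, `appearance_count`, best adjusted
#'   p, mean log2 fold change across methods, and `consensus_rank`
#'   (appearance count descending, then best adjusted p, then id).
#' @export
consensus_rank <- function(lists, all_results) {
  if (!length(lists)) cdeg_stop("no method lists supplied",
                                "cdeg_design_error")
  universe <- unique(all_results$transcript_id)
  unknown <- setdiff(unique(unlist(lists)), universe)
  if (length(unknown)) {
    cdeg_stop(sprintf("list transcript(s) absent from results: %s",
                      paste(utils::head(unknown, 5), collapse = ", ")),
              "cdeg_design_error")
  }
  ids <- sort(unique(unlist(lists)))
  flags <- vapply(lists, function(l) ids %in% l, logical(length(ids)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = length(ids))
  colnames(flags) <- names(lists)
  count <- rowSums(flags)
  sub <- all_results[all_results$transcript_id %in% ids, , drop = FALSE]
  best_padj <- tapply(sub$p_adj, sub$transcript_id, min)[ids]
  mean_l2fc <- tapply(sub$log2fc, sub$transcript_id, mean)[ids]
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  for (m in colnames(flags)) out[[paste0("in_", m)]] <- flags[, m]
  out$appearance_count <- as.integer(count)
  out$best_p_adj <- as.numeric(best_padj)
  out$mean_log2fc <- as.numeric(mean_l2fc)
  ord <- order(-out$appearance_count, out$best_p_adj, out$transcript_id)
  out <- out[ord, , drop = FALSE]
  out$consensus_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Jaccard similarity matrix between method lists
#'
#' `J(A, B) = |A intersect B| / |A union B|`.
#'
#' @param lists Named list of nonempty id sets.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
jaccard_matrix <- function(lists) {
  if (any(!lengths(lists))) cdeg_stop("empty set in Jaccard input",
                                      "cdeg_design_error")
  M <- length(lists)
  out <- matrix(1, M, M, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (j <= i) next
      a <- unique(lists[[i]])
      b <- unique(lists[[j]])
      out[i, j] <- out[j, i] <-
        length(intersect(a, b)) / length(union(a, b))
    }
  }
  out
}
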