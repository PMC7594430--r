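# Discordance eligibility, the ADHD-RS discrepancy score, rank construction
# and the fold-change/discordance correlation. Discrepancy variables are
# absolute within-pair differences of parent-rated ADHD-RS raw scores; ranks
# put the most discrepant pair at 1. A clinician consensus ranking cannot be
# derived from data and is only ever accepted as an input column.

#' Is a twin pair discordant?
#'
#' A pair qualifies when any enabled criterion holds: a raw-score symptom
#' separation of at least `sep_min` with the lower twin below
#' `diagnostic_threshold`; a T-score difference of at least
#' `tscore_diff_min`; or a diagnosis/treatment asymmetry (exactly one twin
#' previously diagnosed).
#'
#' @param pair_rows Two sample-sheet rows forming one pair.
#' @param sep_min Minimum raw-score separation (default 3).
#' @param tscore_diff_min Minimum T-score difference (default 10).
#' @param diagnostic_threshold Raw total at or above which the lower twin
#'   would itself be considered affected (default 12; instrument- and
#'   site-dependent, exposed as configuration).
#' @return Logical with attribute `reasons`: the criteria that fired.
#' @export
is_discordant <- function(pair_rows, sep_min = 3, tscore_diff_min = 10,
                          diagnostic_threshold = 12) {
  if (nrow(pair_rows) != 2L) {
    cdeg_stop("a pair consists of exactly two rows", "cdeg_design_error")
  }
  reasons <- character(0)
  evaluable <- FALSE
  tot <- pair_rows$adhd_rs_total
  if (all(is.finite(tot))) {
    evaluable <- TRUE
    if (abs(tot[1] - tot[2]) >= sep_min &&
        min(tot) < diagnostic_threshold) {
      reasons <- c(reasons, "symptom_separation")
    }
  }
  ts <- pair_rows$adhd_rs_tscore
  if (all(is.finite(ts))) {
    evaluable <- TRUE
    if (abs(ts[1] - ts[2]) >= tscore_diff_min) {
      reasons <- c(reasons, "tscore_difference")
    }
  }
  dx <- pair_rows$prior_diagnosis
  if (!anyNA(dx)) {
    evaluable <- TRUE
    if (sum(dx) == 1L) reasons <- c(reasons, "diagnosis_asymmetry")
  }
  if (!evaluable) {
    cdeg_stop("no evaluable discordance criterion: need adhd_rs_total, adhd_rs_tscore or prior_diagnosis for both twins",
              "cdeg_design_error")
  }
  structure(length(reasons) > 0, reasons = reasons)
}

#' Per-pair ADHD-RS discrepancy scores
#'
#' Absolute within-pair differences of the inattention, hyperactivity and
#' total raw scores. Pairs with missing scores are flagged and excluded
#' from later ranking. An externally supplied clinician consensus rank is
#' passed through untouched.
#'
#' @param sheet Twin-cohort [sample_sheet()].
#' @param consensus_rank Optional named vector (by pair id) of clinician
#'   consensus ranks.
#' @return Data frame, one row per pair: `d_inattention`,
#'   `d_hyperactivity`, `d_total`, `complete`, `consensus_rank_input`.
#' @export
discrepancy_scores <- function(sheet, consensus_rank = NULL) {
  pairs <- twin_pairs(sheet)
  take <- function(ids, col) sheet[[col]][match(ids, sheet$sample_id)]
  d <- data.frame(
    pair_id = pairs$pair_id,
    d_inattention = abs(take(pairs$affected, "adhd_rs_inattention") -
                          take(pairs$unaffected, "adhd_rs_inattention")),
    d_hyperactivity = abs(take(pairs$affected, "adhd_rs_hyperactivity") -
                            take(pairs$unaffected, "adhd_rs_hyperactivity")),
    d_total = abs(take(pairs$affected, "adhd_rs_total") -
                    take(pairs$unaffected, "adhd_rs_total")),
    stringsAsFactors = FALSE
  )
  d$complete <- is.finite(d$d_total)
  d$consensus_rank_input <- if (!is.null(consensus_rank)) {
    as.integer(consensus_rank[d$pair_id])
  } else {
    NA_integer_
  }
  d
}

#' Rank pairs by degree of discordance
#'
#' Rank 1 is the most discrepant pair; ties share the average rank.
#'
#' @param scores Output of [discrepancy_scores()].
#' @param variable Which variable to rank on: `"d_total"` (default),
#'   `"d_inattention"`, `"d_hyperactivity"` or `"consensus_rank_input"`.
#' @return `scores` restricted to complete pairs, with a
#'   `discordance_rank` column.
#' @export
rank_discordance <- function(scores, variable = "d_total") {
  if (!variable %in% names(scores)) {
    cdeg_stop(sprintf("unknown ranking variable '%s'", variable),
              "cdeg_config_error")
  }
  use <- scores[scores$complete & is.finite(scores[[variable]]), ,
                drop = FALSE]
  if (!nrow(use)) cdeg_stop("no complete pairs to rank", "cdeg_design_error")
  if (variable == "consensus_rank_input") {
    # already a rank: 1 = most discordant
    use$discordance_rank <- rank(use[[variable]], ties.method = "average")
  } else {
    use$discordance_rank <- rank(-use[[variable]], ties.method = "average")
  }
  use
}

#' Correlate per-pair expression fold change with discordance rank
#'
#' For every transcript, the correlation between its within-pair log2 fold
#' changes and the pairs' discordance ranks. Under the expected pattern the
#' most discrepant pairs (rank 1) show the largest fold changes, giving a
#' negative r; transcripts are flagged when `r <= -r_thresh`. Positive
#' correlations are reported too. Constant fold-change vectors give a
#' missing r, never zero.
#'
#' @param per_pair_log2fc Matrix from [pairwise_fold_change()]
#'   (transcripts x pairs).
#' @param ranked Output of [rank_discordance()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param r_thresh Flag threshold on -r (default 0.4).
#' @return Data frame sorted by r ascending: `transcript_id`, `r`,
#'   `n_pairs`, `flagged`.
#' @export
correlate_discordance <- function(per_pair_log2fc, ranked,
                                  method = c("pearson", "spearman"),
                                  r_thresh = 0.4) {
  method <- match.arg(method)
  idx <- match(ranked$pair_id, colnames(per_pair_log2fc))
  if (anyNA(idx)) {
    cdeg_stop("ranked pairs absent from the fold-change matrix",
              "cdeg_design_error")
  }
  x <- per_pair_log2fc[, idx, drop = FALSE]
  if (ncol(x) < 3L) {
    cdeg_stop("need >= 3 pairs with finite fold changes",
              "cdeg_design_error")
  }
  rk <- ranked$discordance_rank
  if (method == "spearman") {
    xr <- t(apply(x, 1, rank))
    rr <- rank(rk)
  } else {
    xr <- x
    rr <- rk
  }
  rr_c <- rr - mean(rr)
  xm <- xr - rowMeans(xr)
  denom <- sqrt(rowSums(xm^2) * sum(rr_c^2))
  r <- as.numeric(xm %*% rr_c) / denom
  r[rowSums(xm^2) < 1e-300 | sum(rr_c^2) < 1e-300] <- NA_real_
  out <- data.frame(
    transcript_id = rownames(per_pair_log2fc),
    r = r,
    n_pairs = ncol(x),
    flagged = !is.na(r) & r <= -r_thresh,
    stringsAsFactors = FALSE
  )
  out[order(out$r), , drop = FALSE]
}
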