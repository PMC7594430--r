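# The triple filter (prevalence + fold change + raw p), cross-cohort
# intersection at the gene-symbol level with direction concordance, and the
# hypergeometric overlap significance test.

# Vectorized two-group Welch t on rows of a matrix.
welch_rows <- function(x, groups) {
  aff <- which(groups == "affected")
  una <- which(groups == "unaffected")
  nA <- length(aff)
  nU <- length(una)
  mA <- rowMeans(x[, aff, drop = FALSE])
  mU <- rowMeans(x[, una, drop = FALSE])
  vA <- rowSums((x[, aff, drop = FALSE] - mA)^2) / (nA - 1)
  vU <- rowSums((x[, una, drop = FALSE] - mU)^2) / (nU - 1)
  se2 <- vA / nA + vU / nU
  tstat <- (mA - mU) / sqrt(pmax(se2, 1e-300))
  df <- se2^2 / pmax(vA^2 / (nA^2 * (nA - 1)) +
                       vU^2 / (nU^2 * (nU - 1)), 1e-300)
  degenerate <- se2 < 1e-300 | !is.finite(df) | df < 1e-3
  df[degenerate] <- 1
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[degenerate] <- 1
  p
}

#' Joint prevalence / fold-change / p-value filter
#'
#' A transcript passes when (i) its group-mean expression ratio exceeds
#' `fc_min` or falls below `1/fc_min`, (ii) the raw p of a t-test on log2
#' expression (Welch for the unpaired cohort, paired one-sample on
#' within-pair log2 fold changes for the twin cohort) is below `p_max`, and
#' (iii) it survives the RPKM prevalence filter at `tau`.
#'
#' @param rpkm An [compute_rpkm()] result.
#' @param sheet Sample sheet covering the matrix columns.
#' @param fc_min Fold-change bound (default 1.5).
#' @param p_max Raw-p bound (default 0.01, uncorrected).
#' @param tau RPKM detection threshold (default 0.01).
#' @param phi Prevalence fraction (default 0.70).
#' @param paired Use the paired test; defaults to whether the sheet is the
#'   twin cohort.
#' @param pseudocount Stabilizer for ratios and logs.
#' @return Data frame with per-criterion flags, `passed`, the ratio, log2
#'   fold change, raw p and direction per transcript.
#' @export
triple_filter <- function(rpkm, sheet, fc_min = 1.5, p_max = 0.01,
                          tau = 0.01, phi = 0.70, paired = NULL,
                          pseudocount = 0.25) {
  vals <- expr_values(rpkm)
  idx <- match(rpkm$sample_ids, sheet$sample_id)
  if (anyNA(idx)) cdeg_stop("samples absent from sheet", "cdeg_design_error")
  sheet <- sheet[idx, , drop = FALSE]
  groups <- factor(sheet$group, levels = c("unaffected", "affected"))
  is_twins <- all(sheet$cohort == "twins")
  paired <- paired %||% is_twins
  if (paired && !is_twins) {
    cdeg_stop("paired filter requested on a non-twin sheet",
              "cdeg_design_error")
  }

  fc <- fold_change(rpkm, groups, pseudocount = pseudocount)
  if (paired) {
    pairs <- twin_pairs(sheet)
    pfc <- pairwise_fold_change(rpkm, pairs, pseudocount = pseudocount)
    P <- ncol(pfc)
    m <- rowMeans(pfc)
    s2 <- rowSums((pfc - m)^2) / (P - 1)
    tstat <- m / sqrt(pmax(s2, 1e-300) / P)
    p_raw <- 2 * stats::pt(-abs(tstat), df = P - 1)
    p_raw[s2 < 1e-300 & abs(m) < 1e-300] <- 1
  } else {
    p_raw <- welch_rows(log2(vals + pseudocount), groups)
  }

  kept <- prevalence_filter(rpkm, groups, tau = tau, phi = phi)
  pass_prev <- rpkm$transcript_ids %in% kept
  pass_fc <- fc$ratio > fc_min | fc$ratio < 1 / fc_min
  pass_p <- p_raw < p_max
  data.frame(
    transcript_id = rpkm$transcript_ids,
    gene_symbol = rpkm$gene_symbols,
    ratio = fc$ratio,
    log2fc = fc$log2fc,
    p_raw = p_raw,
    direction = fc$direction,
    pass_fold_change = pass_fc,
    pass_p = pass_p,
    pass_prevalence = pass_prev,
    passed = pass_fc & pass_p & pass_prev,
    stringsAsFactors = FALSE
  )
}

# Collapse a passed triple-filter table to one direction per gene symbol
# (the direction of the largest-|log2fc| passing transcript).
symbol_directions <- function(tf) {
  hits <- tf[tf$passed, , drop = FALSE]
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  hits <- hits[order(-abs(hits$log2fc)), , drop = FALSE]
  hits <- hits[!duplicated(hits$gene_symbol), , drop = FALSE]
  stats::setNames(hits$direction, hits$gene_symbol)
}

#' Intersect two cohorts' hit sets at the gene-symbol level
#'
#' @param dir_a,dir_b Named character vectors mapping gene symbol to
#'   direction (`"up"` / `"down"`).
#' @return List with `common` (symbol intersection), `excluded` (opposite
#'   directions), `concordant` (common minus excluded) and a per-symbol
#'   table.
#' @export
intersect_cohorts <- function(dir_a, dir_b) {
  check_dir <- function(d, lab) {
    if (length(d) && (is.null(names(d)) ||
                      !all(d %in% c("up", "down")))) {
      cdeg_stop(sprintf("cohort %s: directions must be named up/down", lab),
                "cdeg_design_error")
    }
  }
  check_dir(dir_a, "A")
  check_dir(dir_b, "B")
  common <- intersect(names(dir_a), names(dir_b))
  tab <- data.frame(
    gene_symbol = common,
    direction_a = unname(dir_a[common]),
    direction_b = unname(dir_b[common]),
    stringsAsFactors = FALSE
  )
  tab$concordant <- tab$direction_a == tab$direction_b
  list(
    common = common,
    excluded = tab$gene_symbol[!tab$concordant],
    concordant = tab$gene_symbol[tab$concordant],
    table = tab
  )
}

#' Hypergeometric test of cross-cohort overlap
#'
#' One-sided enrichment: the probability of observing `k` or more shared
#' members between lists of sizes `n1` and `n2` drawn from a universe of
#' `N`. The universe must be supplied explicitly.
#'
#' @param n1,n2 List sizes.
#' @param k Observed overlap.
#' @param N Universe size.
#' @return List with the inputs and `p = P(X >= k)`.
#' @export
overlap_test <- function(n1, n2, k, N) {
  if (k > min(n1, n2) || max(n1, n2) > N || k < 0 || N < 1) {
    cdeg_stop("overlap test requires k <= min(n1, n2) <= N",
              "cdeg_design_error")
  }
  p <- stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  list(n1 = n1, n2 = n2, k_overlap = k, universe = N, p = p)
}
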