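# Between-sample normalization. Factors here are *effective size factors*:
# they absorb sequencing depth as well as composition bias, so a column with
# exactly twice the reads of another gets (about) twice its factor. Used
# downstream as offsets in the NB models and to form pseudo-counts for the
# exact test.

new_norm_factors <- function(factors, method) {
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    cdeg_stop("normalization factors must be positive and finite",
              "cdeg_runtime_error")
  }
  structure(list(factors = factors, method = method), class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("norm_factors (%s): ", x$method))
  cat(signif(x$factors, 4), "\n")
  invisible(x)
}

#' Trimmed mean of M-values (TMM) effective size factors
#'
#' For each sample a weighted mean of log2 count ratios against a reference
#' sample is taken after double trimming: the most extreme 30% of M-values
#' (each tail) and 5% of A-values are discarded, and the surviving ratios are
#' weighted by their delta-method (binomial) variances. Factors are rescaled
#' to geometric mean one.
#'
#' @param cm A [count_matrix()] with at least two samples.
#' @param ref_sample Optional reference sample id; defaults to the sample
#'   whose upper-quartile count fraction is closest to the mean.
#' @param trim_m,trim_a Trim fractions for M and A values (per tail for M).
#' @return A `norm_factors` object.
#' @export
tmm_factors <- function(cm, ref_sample = NULL, trim_m = 0.3, trim_a = 0.05) {
  y <- cm$counts
  if (ncol(y) < 2L) cdeg_stop("TMM requires >= 2 samples", "cdeg_design_error")
  N <- colSums(y)
  if (is.null(ref_sample)) {
    uq <- apply(y, 2, function(v) stats::quantile(v / sum(v), 0.75))
    ref_sample <- colnames(y)[which.min(abs(uq - mean(uq)))]
  }
  r <- match(ref_sample, colnames(y))
  if (is.na(r)) cdeg_stop("unknown reference sample", "cdeg_design_error")
  yr <- y[, r]
  f <- numeric(ncol(y))
  for (s in seq_len(ncol(y))) {
    if (s == r) {
      f[s] <- 1
      next
    }
    ys <- y[, s]
    ok <- ys > 0 & yr > 0
    if (!any(ok)) {
      cdeg_stop(sprintf("sample %s shares no nonzero transcript with the reference",
                        colnames(y)[s]), "cdeg_runtime_error")
    }
    M <- log2(ys[ok] / yr[ok])
    A <- 0.5 * log2(as.numeric(ys[ok]) * as.numeric(yr[ok]))
    w <- 1 / ((N[s] - ys[ok]) / (N[s] * ys[ok]) +
                (N[r] - yr[ok]) / (N[r] * yr[ok]))
    n <- length(M)
    keep <- rank(M, ties.method = "first") >= floor(n * trim_m) + 1 &
      rank(M, ties.method = "first") <= n - floor(n * trim_m) &
      rank(A, ties.method = "first") >= floor(n * trim_a) + 1 &
      rank(A, ties.method = "first") <= n - floor(n * trim_a)
    if (!any(keep)) keep <- rep(TRUE, n)  # degenerate tiny input
    f[s] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- f / geometric_mean(f)
  new_norm_factors(stats::setNames(f, colnames(y)), "tmm")
}

#' Median-of-ratios size factors
#'
#' Per-transcript geometric means over samples are computed for transcripts
#' with nonzero counts in every sample; each sample's factor is the median
#' (taken on the log scale) of its count ratios to those geometric means.
#'
#' @param cm A [count_matrix()].
#' @return A `norm_factors` object.
#' @export
median_of_ratios_factors <- function(cm) {
  y <- cm$counts
  ok <- rowSums(y == 0) == 0L
  if (!any(ok)) {
    cdeg_stop("no transcript with nonzero counts in every sample",
              "cdeg_runtime_error")
  }
  logy <- log(y[ok, , drop = FALSE])
  loggeo <- rowMeans(logy)
  # median taken on the log scale (geometric interpolation at even counts)
  f <- exp(apply(sweep(logy, 1, loggeo, "-"), 2, stats::median))
  new_norm_factors(stats::setNames(f, colnames(y)), "median_of_ratios")
}

#' DEGES iterative normalization
#'
#' Multi-step normalization by elimination of putative differentially
#' expressed transcripts: compute factors, run an inner DE test, drop the
#' top `removal_fraction` of transcripts by raw p, recompute factors on the
#' remainder, and repeat. This removes the bias that one-sided differential
#' expression exerts on single-pass factors.
#'
#' @param cm A [count_matrix()].
#' @param groups Per-sample group labels.
#' @param inner_method A [method_spec()] naming the inner test and base
#'   normalization; defaults to the NB exact test over TMM.
#' @param iterations Number of normalize-test-remove rounds, default 3.
#' @param removal_fraction Fraction of transcripts removed per round.
#' @return A `norm_factors` object (method tag `"deges"`), rescaled to
#'   geometric mean one.
#' @export
deges_normalize <- function(cm, groups,
                            inner_method = method_spec("inner", "nb_exact", "tmm"),
                            iterations = 3L, removal_fraction = 0.3) {
  if (iterations < 1L) cdeg_stop("iterations must be >= 1", "cdeg_config_error")
  groups <- check_two_groups(groups, ncol(cm$counts))
  base_norm <- function(sub) {
    switch(inner_method$normalization,
           median_of_ratios = median_of_ratios_factors(sub),
           tmm_factors(sub))
  }
  keep_ids <- cm$transcript_ids
  nf <- base_norm(cm)
  if (removal_fraction <= 0) {
    return(new_norm_factors(nf$factors, "deges"))
  }
  # one common-dispersion estimate serves every inner pass; the factors
  # move little between iterations and the inner test only needs a ranking
  disp <- estimate_dispersion(cm, groups, nf, tagwise = FALSE)
  n_total <- nrow(cm$counts)
  if (n_total - floor(removal_fraction * n_total) < 50L) {
    cdeg_stop("DEGES removal would leave fewer than 50 transcripts",
              "cdeg_config_error")
  }
  for (it in seq_len(iterations)) {
    # inner DE pass on the full matrix under the current factors
    res <- run_de_test(cm, groups, inner_method, nf, disp)
    ord <- order(res$p_raw, res$transcript_id)
    n_drop <- floor(removal_fraction * nrow(res))
    keep_ids <- res$transcript_id[ord][-seq_len(n_drop)]
    sub <- subset_count_matrix(cm, transcripts = keep_ids)
    nf <- base_norm(sub)
  }
  f <- nf$factors / geometric_mean(nf$factors)
  new_norm_factors(f, "deges")
}
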