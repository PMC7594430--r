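# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: negative-binomial counts whose transcript-specific
# baseline means span 15 log2 orders of magnitude, per-sample library-size
# variation, a configurable spiked-DE fraction, and -- for the twin design --
# a shared within-pair biological effect plus ADHD-RS discrepancy scores
# optionally coupled to the per-pair fold change of designated transcripts.

# Draw NB counts; dispersion 0 degenerates to Poisson.
rnb_counts <- function(n, mu, dispersion) {
  if (dispersion < 1e-12) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
}

simulate_annotation <- function(cfg) {
  n <- cfg$n_transcripts
  # isoform-resolved ids; symbols repeat across isoforms (1-3 per gene)
  iso <- sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  gene_idx <- rep(seq_along(iso), iso)[seq_len(n)]
  list(
    transcript_ids = sprintf("tx%05d", seq_len(n)),
    gene_symbols = sprintf("GENE%05d", gene_idx),
    lengths_bp = round(exp(stats::runif(n, log(cfg$length_bp_range[1]),
                                        log(cfg$length_bp_range[2]))))
  )
}

simulate_baselines <- function(cfg) {
  2^stats::runif(cfg$n_transcripts, cfg$baseline_log2_range[1],
                 cfg$baseline_log2_range[2])
}

simulate_de_effects <- function(cfg, baseline) {
  n <- cfg$n_transcripts
  lfc <- numeric(n)
  n_de <- round(cfg$de_fraction * n)
  if (n_de > 0) {
    eligible <- which(baseline >= cfg$de_baseline_min)
    if (length(eligible) < n_de) {
      cdeg_stop("not enough transcripts above de_baseline_min to spike",
                "cdeg_config_error")
    }
    de_idx <- sample(eligible, n_de)
    mag <- stats::runif(n_de, cfg$de_log2fc[1], cfg$de_log2fc[2])
    lfc[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
  }
  lfc
}

sim_truth_frame <- function(ann, baseline, lfc, cfg) {
  data.frame(
    transcript_id = ann$transcript_ids,
    gene_symbol = ann$gene_symbols,
    length_bp = ann$lengths_bp,
    baseline_mean = baseline,
    mean_unaffected = baseline,
    mean_affected = baseline * 2^lfc,
    true_log2fc = lfc,
    is_de = lfc != 0,
    dispersion = cfg$dispersion,
    stringsAsFactors = FALSE
  )
}

#' Simulate an unpaired case-control cohort
#'
#' Counts are drawn as `NB(mean = baseline * libsize * 2^(log2fc * group),
#' dispersion)` with baselines log-uniform across the configured dynamic
#' range and per-sample library-size factors log-uniform over
#' `cfg$libsize_range`. Identical seeds give identical output.
#'
#' @param cfg A [cohort_config()]; group sizes default to 23 affected vs 21
#'   unaffected.
#' @param seed Integer seed.
#' @return A list with elements `counts` ([count_matrix()]), `sheet`
#'   ([sample_sheet()]) and `truth` (per-transcript ground-truth data frame;
#'   per-sample library sizes in `attr(truth, "libsize")`).
#' @export
simulate_case_control <- function(cfg, seed = cfg$seed) {
  validate_config(cfg)
  with_seed(seed, {
    ann <- simulate_annotation(cfg)
    baseline <- simulate_baselines(cfg)
    lfc <- simulate_de_effects(cfg, baseline)
    n_aff <- cfg$n_affected
    n_una <- cfg$n_unaffected
    sample_ids <- c(sprintf("case%02d", seq_len(n_aff)),
                    sprintf("ctrl%02d", seq_len(n_una)))
    group <- c(rep("affected", n_aff), rep("unaffected", n_una))
    libsize <- 2^stats::runif(n_aff + n_una, log2(cfg$libsize_range[1]),
                              log2(cfg$libsize_range[2]))
    names(libsize) <- sample_ids
    mu_group <- cbind(unaffected = baseline, affected = baseline * 2^lfc)
    counts <- matrix(0, cfg$n_transcripts, n_aff + n_una,
                     dimnames = list(ann$transcript_ids, sample_ids))
    for (s in seq_along(sample_ids)) {
      mu <- mu_group[, group[s]] * libsize[s]
      counts[, s] <- rnb_counts(cfg$n_transcripts, mu, cfg$dispersion)
    }
    cm <- count_matrix(counts, ann$gene_symbols, ann$lengths_bp)
    sheet <- sample_sheet(data.frame(
      sample_id = sample_ids, cohort = "case_control", group = group,
      stringsAsFactors = FALSE
    ))
    truth <- sim_truth_frame(ann, baseline, lfc, cfg)
    attr(truth, "libsize") <- libsize
    list(counts = cm, sheet = sheet, truth = truth)
  })
}

# Integer ADHD-RS scores for one cohort of pairs: the affected twin scores
# above the unaffected one on both 0-27 subscales, with T-score means/SDs
# taken from the study population (62 +/- 9 vs 47 +/- 6.8).
simulate_adhd_scores <- function(n_pairs) {
  una_inatt <- sample(0:8, n_pairs, replace = TRUE)
  una_hyper <- sample(0:8, n_pairs, replace = TRUE)
  aff_inatt <- pmin(27L, una_inatt + sample(2:14, n_pairs, replace = TRUE))
  aff_hyper <- pmin(27L, una_hyper + sample(0:12, n_pairs, replace = TRUE))
  data.frame(
    aff_inatt = aff_inatt, aff_hyper = aff_hyper,
    aff_total = aff_inatt + aff_hyper,
    una_inatt = una_inatt, una_hyper = una_hyper,
    una_total = una_inatt + una_hyper,
    aff_t = round(stats::rnorm(n_pairs, 62, 9), 1),
    una_t = round(stats::rnorm(n_pairs, 47, 6.8), 1)
  )
}

#' Simulate a discordant monozygotic twin cohort
#'
#' Both members of a pair share a multiplicative log-normal biological
#' effect per transcript (sd `cfg$pair_effect_sd` on the natural-log scale),
#' which induces the within-pair correlation a paired test exploits. The
#' affected member additionally carries the spiked DE effect. ADHD-RS raw
#' scores are drawn per twin; for `cfg$n_coupled` designated transcripts the
#' per-pair log2 fold change is generated with latent correlation
#' `cfg$coupling_rho` to the pair's total-score discrepancy.
#'
#' @inheritParams simulate_case_control
#' @return As [simulate_case_control()]; additionally `attr(truth,
#'   "coupling")` holds the coupled transcript ids, the per-pair latent
#'   log2 fold changes, and the per-pair discrepancy scores.
#' @export
simulate_twins <- function(cfg, seed = cfg$seed) {
  validate_config(cfg)
  with_seed(seed, {
    ann <- simulate_annotation(cfg)
    baseline <- simulate_baselines(cfg)
    lfc <- simulate_de_effects(cfg, baseline)
    P <- cfg$n_pairs
    n <- cfg$n_transcripts
    pair_ids <- sprintf("pair%02d", seq_len(P))
    aff_ids <- sprintf("twinA%02d", seq_len(P))
    una_ids <- sprintf("twinU%02d", seq_len(P))
    sample_ids <- c(rbind(aff_ids, una_ids))
    libsize <- 2^stats::runif(2 * P, log2(cfg$libsize_range[1]),
                              log2(cfg$libsize_range[2]))
    names(libsize) <- sample_ids

    # per-(pair, transcript) biological effect shared by both twins
    pair_eff <- matrix(exp(stats::rnorm(n * P, 0, cfg$pair_effect_sd)), n, P)

    scores <- simulate_adhd_scores(P)
    d_total <- abs(scores$aff_total - scores$una_total)

    # coupling of designated per-pair fold changes to the discrepancy score
    delta <- matrix(0, n, P)
    coupled_idx <- integer(0)
    if (cfg$n_coupled > 0) {
      eligible <- which(baseline >= cfg$coupling_min_mean & lfc == 0)
      if (length(eligible) < cfg$n_coupled) {
        cdeg_stop("not enough expressed transcripts for the coupling set",
                  "cdeg_config_error")
      }
      coupled_idx <- sort(sample(eligible, cfg$n_coupled))
      z <- as.numeric(scale(d_total))
      if (any(!is.finite(z))) z <- rep(0, P)  # all-equal scores
      rho <- cfg$coupling_rho
      for (g in coupled_idx) {
        eps <- stats::rnorm(P)
        delta[g, ] <- cfg$coupling_log2fc_sd *
          (rho * z + sqrt(1 - rho^2) * eps)
      }
    }

    counts <- matrix(0, n, 2 * P,
                     dimnames = list(ann$transcript_ids, sample_ids))
    for (p in seq_len(P)) {
      mu_una <- baseline * pair_eff[, p] * libsize[una_ids[p]]
      mu_aff <- baseline * pair_eff[, p] * 2^(lfc + delta[, p]) *
        libsize[aff_ids[p]]
      counts[, aff_ids[p]] <- rnb_counts(n, mu_aff, cfg$dispersion)
      counts[, una_ids[p]] <- rnb_counts(n, mu_una, cfg$dispersion)
    }
    cm <- count_matrix(counts, ann$gene_symbols, ann$lengths_bp)
    sheet <- sample_sheet(data.frame(
      sample_id = sample_ids,
      cohort = "twins",
      group = rep(c("affected", "unaffected"), P),
      pair_id = rep(pair_ids, each = 2),
      adhd_rs_inattention = c(rbind(scores$aff_inatt, scores$una_inatt)),
      adhd_rs_hyperactivity = c(rbind(scores$aff_hyper, scores$una_hyper)),
      adhd_rs_total = c(rbind(scores$aff_total, scores$una_total)),
      adhd_rs_tscore = c(rbind(scores$aff_t, scores$una_t)),
      prior_diagnosis = FALSE,
      stringsAsFactors = FALSE
    ))
    truth <- sim_truth_frame(ann, baseline, lfc, cfg)
    truth$is_coupled <- seq_len(n) %in% coupled_idx
    attr(truth, "libsize") <- libsize
    attr(truth, "coupling") <- list(
      transcript_ids = ann$transcript_ids[coupled_idx],
      delta = delta[coupled_idx, , drop = FALSE],
      d_total = stats::setNames(d_total, pair_ids)
    )
    list(counts = cm, sheet = sheet, truth = truth)
  })
}

#' Write the simulation ground truth as TSV
#'
#' @param truth Truth data frame from a simulation.
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  write_tsv_file(truth, path)
}
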