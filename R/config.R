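# Run configuration. Every analysis threshold is a named key whose default
# is the value used throughout the study design this package implements:
# RPKM detection threshold 0.01, prevalence 70%, fold-change 1.5, raw p 0.01,
# top-100 per method.

#' Describe one differential-expression method
#'
#' A method is a (test family, normalization, pairing) triple. The battery of
#' methods is data, not a constant: any number of `method_spec`s can be run
#' and fed to the consensus layer.
#'
#' @param method_id Unique label for the run.
#' @param test One of `"nb_exact"`, `"nb_glm_lrt"`, `"nb_wald"`,
#'   `"moderated_t"`, `"clr_mc"`.
#' @param normalization One of `"tmm"`, `"median_of_ratios"`, `"deges"`,
#'   `"log_cpm"`, `"clr"`. `"log_cpm"` and `"clr"` mark methods that carry
#'   their own internal scaling.
#' @param paired Use the within-pair design (twin cohort)? Only the GLM
#'   likelihood-ratio test and the moderated t have paired formulations.
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(method_id, test, normalization = "tmm",
                        paired = FALSE) {
  test <- match.arg(test, c("nb_exact", "nb_glm_lrt", "nb_wald",
                            "moderated_t", "clr_mc"))
  normalization <- match.arg(normalization,
                             c("tmm", "median_of_ratios", "deges",
                               "log_cpm", "clr"))
  if (paired && !test %in% c("nb_glm_lrt", "moderated_t")) {
    cdeg_stop(sprintf("test '%s' has no paired formulation", test),
              "cdeg_config_error")
  }
  structure(list(method_id = as.character(method_id), test = test,
                 normalization = normalization, paired = paired),
            class = "method_spec")
}

#' The default six-method battery
#'
#' Six statistics spanning five families of analysis: the NB exact test under
#' TMM and under DEGES normalization, the NB GLM likelihood-ratio test (TMM),
#' a simplified NB Wald test under median-of-ratios factors, the moderated t
#' on log2-CPM, and the Dirichlet Monte-Carlo CLR test.
#'
#' @param paired Use paired formulations where available (twin cohort).
#' @return A list of [method_spec()] objects.
#' @export
default_battery <- function(paired = FALSE) {
  list(
    method_spec("exact_tmm", "nb_exact", "tmm"),
    method_spec("exact_deges", "nb_exact", "deges"),
    method_spec("glm_lrt", "nb_glm_lrt", "tmm", paired = paired),
    method_spec("wald_mor", "nb_wald", "median_of_ratios"),
    method_spec("mod_t", "moderated_t", "log_cpm", paired = paired),
    method_spec("clr_mc", "clr_mc", "clr")
  )
}

#' Cohort configuration: thresholds, battery and simulation parameters
#'
#' @param rpkm_tau RPKM detection threshold; a transcript counts as present
#'   in a sample when its RPKM exceeds `rpkm_tau` (strict inequality).
#' @param prevalence_phi Required fraction of present samples in at least one
#'   diagnostic group.
#' @param fc_min Fold-change threshold of the triple filter (ratio must
#'   exceed `fc_min` or fall below `1/fc_min`).
#' @param p_max Raw-p threshold of the triple filter.
#' @param top_k Number of transcripts taken from each method's ranked list.
#' @param methods List of [method_spec()]s; defaults to [default_battery()].
#' @param rank_by Rank per-method lists by `"p_adj"` (default) or `"p_raw"`.
#' @param seed Run seed; all stage seeds derive from it.
#' @param paired Paired design (twin cohort)?
#' @param n_transcripts,n_affected,n_unaffected,n_pairs Simulation sizes.
#'   Group sizes default to the study's cohorts: 23 affected vs 21
#'   unaffected, and 16 discordant monozygotic pairs.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param de_fraction Fraction of transcripts spiked as truly differential.
#' @param de_log2fc Range of |log2 fold change| for spiked transcripts.
#' @param de_baseline_min Restrict spiked transcripts to baselines at or
#'   above this mean count (0 = unrestricted).
#' @param baseline_log2_range Range of log2 baseline means; the default spans
#'   15 log2 units, emulating the wide dynamic range of single-molecule
#'   whole-blood sequencing.
#' @param libsize_range Multiplicative library-size range (log-uniform).
#' @param length_bp_range Transcript length range in bases (log-uniform).
#' @param pair_effect_sd Standard deviation (natural-log scale) of the
#'   per-(pair, transcript) shared biological effect in the twin design.
#' @param n_coupled Number of transcripts whose per-pair fold change is
#'   coupled to the pair's ADHD-RS discrepancy score.
#' @param coupling_rho Latent correlation between coupled per-pair log2 fold
#'   changes and the discrepancy score.
#' @param coupling_log2fc_sd Across-pair SD of the coupled log2 fold change.
#' @param coupling_min_mean Coupled transcripts are drawn among baselines at
#'   or above this mean count so the per-pair fold change is measurable.
#' @param pseudocount Added to group means before forming expression ratios.
#' @param n_mc Monte-Carlo instances for the CLR test.
#' @param prior_df Prior degrees of freedom shrinking tagwise dispersions
#'   toward the common value.
#' @param r_thresh Discordance-correlation flag threshold (|r|).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(rpkm_tau = 0.01,
                          prevalence_phi = 0.70,
                          fc_min = 1.5,
                          p_max = 0.01,
                          top_k = 100L,
                          methods = NULL,
                          rank_by = c("p_adj", "p_raw"),
                          seed = 1L,
                          paired = FALSE,
                          n_transcripts = 2000L,
                          n_affected = 23L,
                          n_unaffected = 21L,
                          n_pairs = 16L,
                          dispersion = 0.2,
                          de_fraction = 0.1,
                          de_log2fc = c(1, 2.5),
                          de_baseline_min = 0,
                          baseline_log2_range = c(-4, 11),
                          libsize_range = c(0.5, 2),
                          length_bp_range = c(200, 20000),
                          pair_effect_sd = 0.15,
                          n_coupled = 0L,
                          coupling_rho = 0.8,
                          coupling_log2fc_sd = 1.5,
                          coupling_min_mean = 50,
                          pseudocount = 0.25,
                          n_mc = 128L,
                          prior_df = 10,
                          r_thresh = 0.4) {
  rank_by <- match.arg(rank_by)
  cfg <- structure(
    list(rpkm_tau = rpkm_tau, prevalence_phi = prevalence_phi,
         fc_min = fc_min, p_max = p_max, top_k = as.integer(top_k),
         methods = methods %||% default_battery(paired = paired),
         rank_by = rank_by, seed = as.integer(seed), paired = paired,
         n_transcripts = as.integer(n_transcripts),
         n_affected = as.integer(n_affected),
         n_unaffected = as.integer(n_unaffected),
         n_pairs = as.integer(n_pairs),
         dispersion = dispersion, de_fraction = de_fraction,
         de_log2fc = de_log2fc, de_baseline_min = de_baseline_min,
         baseline_log2_range = baseline_log2_range,
         libsize_range = libsize_range,
         length_bp_range = length_bp_range,
         pair_effect_sd = pair_effect_sd,
         n_coupled = as.integer(n_coupled), coupling_rho = coupling_rho,
         coupling_log2fc_sd = coupling_log2fc_sd,
         coupling_min_mean = coupling_min_mean,
         pseudocount = pseudocount, n_mc = as.integer(n_mc),
         prior_df = prior_df, r_thresh = r_thresh),
    class = "cohort_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) cdeg_stop(msg, "cdeg_config_error")
  chk(cfg$prevalence_phi > 0 && cfg$prevalence_phi <= 1,
      "prevalence_phi must lie in (0, 1]")
  chk(cfg$top_k >= 1L, "top_k must be >= 1")
  chk(cfg$fc_min > 1, "fc_min must exceed 1")
  chk(cfg$p_max > 0 && cfg$p_max < 1, "p_max must lie in (0, 1)")
  chk(cfg$rpkm_tau >= 0, "rpkm_tau must be non-negative")
  chk(cfg$n_transcripts >= 1L, "n_transcripts must be >= 1")
  chk(cfg$de_fraction >= 0 && cfg$de_fraction <= 1,
      "de_fraction must lie in [0, 1]")
  chk(cfg$dispersion >= 0, "dispersion must be >= 0")
  chk(cfg$pair_effect_sd >= 0, "pair_effect_sd must be >= 0")
  chk(cfg$pseudocount > 0, "pseudocount must be positive")
  chk(cfg$n_mc >= 16L, "n_mc must be >= 16")
  chk(diff(cfg$baseline_log2_range) >= 15,
      "baseline_log2_range must span at least 15 log2 units")
  chk(abs(cfg$coupling_rho) <= 1, "coupling_rho must lie in [-1, 1]")
  ids <- vapply(cfg$methods, function(m) m$method_id, character(1))
  chk(!anyDuplicated(ids), "method ids must be unique")
  invisible(cfg)
}
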