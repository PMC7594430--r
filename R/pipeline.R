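# End-to-end orchestration: simulate (or load) the two cohorts, filter,
# run the DE battery, build the consensus, apply the triple filter, cross
# the cohorts, and correlate twin discordance -- one configured, logged,
# reproducible run. Identical config + seed gives byte-identical outputs.

pipeline_files <- function(outdir) {
  rel <- c(cc_counts = "cc_counts.tsv", cc_sheet = "cc_samples.csv",
           cc_truth = "cc_truth.tsv",
           tw_counts = "tw_counts.tsv", tw_sheet = "tw_samples.csv",
           tw_truth = "tw_truth.tsv")
  stats::setNames(file.path(outdir, rel), names(rel))
}

# Analyse one cohort: prevalence filter, DE battery, consensus, triple
# filter. Returns tables plus record counts for the run report.
analyse_cohort <- function(cm, sheet, cfg, label, outdir, seed) {
  rpkm <- compute_rpkm(cm)
  groups <- group_labels(cm, sheet)
  kept <- prevalence_filter(rpkm, groups, tau = cfg$rpkm_tau,
                            phi = cfg$prevalence_phi)
  write_tsv_file(attr(kept, "report"),
                 file.path(outdir, paste0(label, "_filter_report.tsv")))
  cm_f <- subset_count_matrix(cm, transcripts = kept)

  battery <- run_de_battery(cm_f, sheet, methods = cfg$methods,
                            n_mc = cfg$n_mc, seed = seed,
                            prior_df = cfg$prior_df)
  for (m in names(battery)) {
    write_tsv_file(battery[[m]],
                   file.path(outdir, sprintf("%s_de_%s.tsv", label, m)))
  }
  lists <- lapply(battery, top_k_list, k = cfg$top_k, rank_by = cfg$rank_by)
  all_res <- do.call(rbind, battery)
  cons <- consensus_rank(lists, all_res)
  write_tsv_file(cons, file.path(outdir, paste0(label, "_consensus.tsv")))
  jac <- jaccard_matrix(lists)
  jac_df <- data.frame(method_id = rownames(jac), jac, check.names = FALSE)
  write_tsv_file(jac_df, file.path(outdir, paste0(label, "_jaccard.tsv")))

  tf <- triple_filter(rpkm, sheet, fc_min = cfg$fc_min, p_max = cfg$p_max,
                      tau = cfg$rpkm_tau, phi = cfg$prevalence_phi,
                      pseudocount = cfg$pseudocount)
  write_tsv_file(tf, file.path(outdir, paste0(label, "_triple_filter.tsv")))

  M <- length(battery)
  list(rpkm = rpkm, kept = kept, battery = battery, consensus = cons,
       jaccard = jac, triple = tf,
       counts = list(universe = nrow(cm$counts),
                     filtered = length(kept),
                     consensus = nrow(cons),
                     tier_all_methods = sum(cons$appearance_count == M),
                     tier_all_but_one = sum(cons$appearance_count >= M - 1),
                     triple_pass = sum(tf$passed)))
}

#' Run the full two-cohort pipeline
#'
#' Simulates (or reloads) a case-control and a twin cohort, analyses each
#' (prevalence filter, DE battery, consensus ranking, triple filter),
#' intersects the cohorts at the gene-symbol level with direction
#' concordance, tests the overlap against the shared symbol universe, and
#' correlates twin per-pair fold changes with discrepancy ranks. All stage
#' outputs are written under `outdir` together with a JSON run report.
#'
#' @param cfg A [cohort_config()].
#' @param outdir Output directory (created if missing).
#' @param inputs Optional list of file paths
#'   (`cc_counts`, `cc_sheet`, `tw_counts`, `tw_sheet`) to analyse real
#'   tables instead of simulating.
#' @param resume Reuse simulated cohort files already present in `outdir`.
#' @return The run report, invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(cfg, outdir, inputs = NULL, resume = FALSE) {
  validate_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_files(outdir)

  if (!is.null(inputs)) {
    cc <- list(counts = read_count_matrix(inputs$cc_counts),
               sheet = read_sample_sheet(inputs$cc_sheet))
    tw <- list(counts = read_count_matrix(inputs$tw_counts),
               sheet = read_sample_sheet(inputs$tw_sheet))
  } else if (resume && all(file.exists(paths[c("cc_counts", "cc_sheet",
                                               "tw_counts", "tw_sheet")]))) {
    cc <- list(counts = read_count_matrix(paths["cc_counts"]),
               sheet = read_sample_sheet(paths["cc_sheet"]))
    tw <- list(counts = read_count_matrix(paths["tw_counts"]),
               sheet = read_sample_sheet(paths["tw_sheet"]))
  } else {
    cc <- simulate_case_control(cfg, seed = derive_seed(cfg$seed, 11))
    tw <- simulate_twins(cfg, seed = derive_seed(cfg$seed, 23))
    write_count_matrix(cc$counts, paths["cc_counts"])
    write_sample_sheet(cc$sheet, paths["cc_sheet"])
    write_sim_truth(cc$truth, paths["cc_truth"])
    write_count_matrix(tw$counts, paths["tw_counts"])
    write_sample_sheet(tw$sheet, paths["tw_sheet"])
    write_sim_truth(tw$truth, paths["tw_truth"])
  }

  res_cc <- analyse_cohort(cc$counts, cc$sheet, cfg, "cc", outdir,
                           seed = derive_seed(cfg$seed, 31))
  res_tw <- analyse_cohort(tw$counts, tw$sheet, cfg, "tw", outdir,
                           seed = derive_seed(cfg$seed, 47))

  # cross-cohort: symbol-level intersection of triple-filter hits,
  # direction concordance, and the overlap test against the shared
  # filtered symbol universe (supplied explicitly, never defaulted)
  dir_cc <- symbol_directions(res_cc$triple)
  dir_tw <- symbol_directions(res_tw$triple)
  inter <- intersect_cohorts(dir_cc, dir_tw)
  sym_cc <- unique(res_cc$triple$gene_symbol[res_cc$triple$pass_prevalence])
  sym_tw <- unique(res_tw$triple$gene_symbol[res_tw$triple$pass_prevalence])
  universe <- length(intersect(sym_cc, sym_tw))
  ov <- overlap_test(length(dir_cc), length(dir_tw),
                     length(inter$common), max(universe, 1L))
  write_tsv_file(inter$table, file.path(outdir, "concordant_symbols.tsv"))
  jsonlite::write_json(c(ov, list(n_concordant = length(inter$concordant),
                                  n_excluded = length(inter$excluded))),
                       file.path(outdir, "cross_cohort_overlap.json"),
                       auto_unbox = TRUE, digits = NA)

  # twin discordance: eligibility report, discrepancy scores, ranks and
  # the fold-change correlation over the twin triple-filter universe
  pairs <- twin_pairs(tw$sheet)
  elig <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    rows <- tw$sheet[tw$sheet$sample_id %in%
                       c(pairs$affected[i], pairs$unaffected[i]), ,
                     drop = FALSE]
    res <- tryCatch(is_discordant(rows), cdeg_error = function(e) NA)
    data.frame(pair_id = pairs$pair_id[i],
               discordant = as.logical(res),
               criteria = paste(attr(res, "reasons"), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  write_tsv_file(elig, file.path(outdir, "tw_discordance_eligibility.tsv"))
  scores <- discrepancy_scores(tw$sheet)
  ranked <- rank_discordance(scores, "d_total")
  write_tsv_file(ranked, file.path(outdir, "tw_discrepancy.tsv"))
  pfc <- pairwise_fold_change(res_tw$rpkm, pairs,
                              pseudocount = cfg$pseudocount)
  tw_univ <- res_tw$triple$transcript_id[res_tw$triple$pass_prevalence]
  corr <- correlate_discordance(pfc[tw_univ, , drop = FALSE], ranked,
                                r_thresh = cfg$r_thresh)
  write_tsv_file(corr, file.path(outdir, "tw_discordance_correlation.tsv"))

  report <- list(
    config = config_echo(cfg),
    seed = cfg$seed,
    stages = list(
      case_control = res_cc$counts,
      twins = res_tw$counts,
      cross_cohort = list(n_common = length(inter$common),
                          n_excluded_direction = length(inter$excluded),
                          n_concordant = length(inter$concordant),
                          universe = universe,
                          overlap_p = ov$p),
      discordance = list(n_pairs_ranked = nrow(ranked),
                         n_flagged = sum(corr$flagged))
    ),
    files = sort(unique(c(list.files(outdir), "run_report.json")))
  )
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# Serializable echo of the configuration for the run report.
config_echo <- function(cfg) {
  out <- unclass(cfg)
  out$methods <- lapply(cfg$methods, function(m) unclass(m))
  out
}
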