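# The DE statistics: exact-test enumeration, GLM limits, moderated-t
# limits, CLR Monte-Carlo behaviour and BH adjustment.

unit_norm <- function(cm) {
  consensusDEG:::new_norm_factors(
    stats::setNames(rep(1, length(cm$sample_ids)), cm$sample_ids), "tmm")
}

fixed_disp <- function(cm, phi) {
  structure(list(common = phi,
                 tagwise = stats::setNames(rep(phi, length(cm$transcript_ids)),
                                           cm$transcript_ids),
                 prior_df = Inf, design = "unpaired"),
            class = "dispersion_model")
}

test_that("exact NB test: all-zero transcripts, symmetry, enumeration", {
  withr::with_seed(3, {
    n <- 40
    counts <- matrix(rpois(n * 8, lambda = 2), n, 8,
                     dimnames = list(sprintf("t%02d", 1:n),
                                     sprintf("s%d", 1:8)))
    counts[1, ] <- 0L
    cm <- count_matrix(counts, sprintf("G%02d", 1:n), rep(1000L, n))
  })
  groups <- small_groups(4, 4)
  nf <- unit_norm(cm)
  disp <- fixed_disp(cm, 0.3)
  res <- de_nb_exact(cm, groups, nf, disp)
  expect_equal(res$p_raw[1], 1)  # both groups all zero

  swapped <- factor(ifelse(groups == "affected", "unaffected", "affected"),
                    levels = c("unaffected", "affected"))
  res_sw <- de_nb_exact(cm, swapped, nf, disp)
  expect_equal(res_sw$p_raw, res$p_raw, tolerance = 1e-12)
  expect_equal(res_sw$log2fc, -res$log2fc, tolerance = 1e-12)

  # tiny totals: the windowed computation must equal full enumeration
  for (g in seq_len(n)) {
    s1 <- sum(counts[g, 1:4])
    s2 <- sum(counts[g, 5:8])
    if (s1 + s2 > 30 || s1 + s2 == 0) next
    expect_equal(res$p_raw[g], oracle_exact_nb(s1, s2, 4, 4, 0.3),
                 tolerance = 1e-8, label = sprintf("transcript %d", g))
  }
  # and in the Poisson limit too
  res0 <- de_nb_exact(cm, groups, nf, fixed_disp(cm, 0))
  for (g in 2:10) {
    s1 <- sum(counts[g, 1:4]); s2 <- sum(counts[g, 5:8])
    if (s1 + s2 == 0) next
    expect_equal(res0$p_raw[g], oracle_exact_nb(s1, s2, 4, 4, 0),
                 tolerance = 1e-8)
  }
})

test_that("windowed exact test matches full summation at large totals", {
  # direct check of the stride-grid accumulation against an (expensive)
  # full-support evaluation for a handful of large-count cases
  for (case in list(c(5000, 4200), c(12000, 15000), c(800, 2000))) {
    got <- consensusDEG:::exact_nb_p(case[1], case[2], 10, 12, 0.15)
    want <- oracle_exact_nb(case[1], case[2], 10, 12, 0.15)
    expect_equal(got, want, tolerance = 1e-2)
  }
})

test_that("NB GLM LRT reduces to Poisson regression as phi -> 0", {
  cm <- random_count_matrix(n_tx = 15, n_s = 10, seed = 6)
  groups <- small_groups(5, 5)
  nf <- tmm_factors(cm)
  res <- de_nb_glm_lrt(cm, groups, nf, fixed_disp(cm, 0))
  off <- log(nf$factors)
  for (g in seq_len(15)) {
    df <- data.frame(y = cm$counts[g, ], grp = groups, off = off)
    full <- glm(y ~ grp + offset(off), family = poisson(), data = df)
    red <- glm(y ~ offset(off), family = poisson(), data = df)
    lrt <- as.numeric(2 * (logLik(full) - logLik(red)))
    p_ref <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
    expect_equal(res$p_raw[g], p_ref, tolerance = 1e-6)
  }
})

test_that("a separated large effect is detected at 16 per group", {
  cfg <- cohort_config(n_transcripts = 200, de_fraction = 0,
                       n_affected = 16, n_unaffected = 16,
                       dispersion = 0.2, seed = 12)
  sim <- simulate_case_control(cfg, seed = 12)
  counts <- sim$counts$counts
  # spike one well-expressed transcript 8-fold
  target <- which.min(abs(sim$truth$baseline_mean - 100))[1]
  g <- consensusDEG:::group_labels(sim$counts, sim$sheet)
  counts[target, g == "affected"] <- counts[target, g == "affected"] * 8L
  cm <- count_matrix(counts, sim$counts$gene_symbols, sim$counts$lengths_bp)
  nf <- tmm_factors(cm)
  disp <- estimate_dispersion(cm, g, nf)
  res <- de_nb_glm_lrt(cm, g, nf, disp)
  expect_lt(res$p_raw[target], 1e-4)
  expect_gt(res$log2fc[target], 2)
})

test_that("Wald and LRT agree in ranking; empty designs are rejected", {
  cfg <- cohort_config(n_transcripts = 400, de_fraction = 0.2,
                       dispersion = 0.2, seed = 9)
  sim <- simulate_case_control(cfg, seed = 9)
  g <- consensusDEG:::group_labels(sim$counts, sim$sheet)
  # compare on the filtered working universe under one normalization so
  # that only the test statistic differs between the two routes
  kept <- prevalence_filter(compute_rpkm(sim$counts), g)
  cm <- consensusDEG:::subset_count_matrix(sim$counts, transcripts = kept)
  nf <- tmm_factors(cm)
  disp <- estimate_dispersion(cm, g, nf)
  lrt <- de_nb_glm_lrt(cm, g, nf, disp)
  wald <- de_nb_wald(cm, g, nf, disp)
  expect_gte(cor(lrt$p_raw, wald$p_raw, method = "spearman"), 0.95)

  one_group <- factor(rep("affected", 44), levels = c("unaffected", "affected"))
  expect_error(de_nb_wald(cm, one_group, nf, disp),
               class = "cdeg_design_error")
})

test_that("moderated t with d0 = 0 equals the ordinary pooled t-test", {
  cm <- random_count_matrix(n_tx = 25, n_s = 12, seed = 15)
  groups <- small_groups(6, 6)
  res <- de_moderated_t(cm, groups, trend = FALSE,
                        prior = list(d0 = 0, s02 = 1))
  lib <- colSums(cm$counts)
  logcpm <- log2(sweep(cm$counts + 0.5, 2, lib + 1, "/") * 1e6)
  for (g in seq_len(25)) {
    ref <- t.test(logcpm[g, groups == "affected"],
                  logcpm[g, groups == "unaffected"], var.equal = TRUE)
    expect_equal(res$p_raw[g], ref$p.value, tolerance = 1e-9)
  }
})

test_that("paired moderated t with d0 = 0 equals the one-sample t-test", {
  cm <- random_count_matrix(n_tx = 20, n_s = 8, seed = 16)
  pairs <- data.frame(pair_id = sprintf("p%d", 1:4),
                      affected = cm$sample_ids[c(1, 3, 5, 7)],
                      unaffected = cm$sample_ids[c(2, 4, 6, 8)])
  groups <- factor(rep(c("affected", "unaffected"), 4),
                   levels = c("unaffected", "affected"))
  res <- de_moderated_t(cm, groups, pairs = pairs,
                        prior = list(d0 = 0, s02 = 1))
  lib <- colSums(cm$counts)
  logcpm <- log2(sweep(cm$counts + 0.5, 2, lib + 1, "/") * 1e6)
  for (g in seq_len(20)) {
    dd <- logcpm[g, c(1, 3, 5, 7)] - logcpm[g, c(2, 4, 6, 8)]
    expect_equal(res$p_raw[g], t.test(dd)$p.value, tolerance = 1e-9)
  }
})

test_that("the moderated t tracks the reference voom pipeline", {
  skip_if_not_installed("limma")
  cfg <- cohort_config(n_transcripts = 500, de_fraction = 0.15,
                       dispersion = 0.2, seed = 24)
  sim <- simulate_case_control(cfg, seed = 24)
  g <- consensusDEG:::group_labels(sim$counts, sim$sheet)
  kept <- prevalence_filter(compute_rpkm(sim$counts), g)
  cm <- consensusDEG:::subset_count_matrix(sim$counts, transcripts = kept)
  ours <- de_moderated_t(cm, g)
  design <- model.matrix(~ g)
  v <- limma::voom(cm$counts, design)
  fit <- limma::eBayes(limma::lmFit(v, design))
  ref_p <- fit$p.value[, 2]
  expect_gte(cor(-log10(ours$p_raw + 1e-300), -log10(ref_p + 1e-300),
                 method = "spearman"), 0.9)
})

test_that("an all-equal transcript gets p = 1 from the moderated t", {
  # equal library sizes so a constant count row is constant in log-CPM
  row2 <- c(9L, 2L, 7L, 1L, 8L, 3L)
  counts <- rbind(t1 = rep(5L, 6), t2 = row2, t3 = 10L - row2,
                  t4 = rep(20L, 6))
  colnames(counts) <- sprintf("s%d", 1:6)
  cm <- count_matrix(counts, sprintf("G%d", 1:4), rep(1000L, 4))
  res <- de_moderated_t(cm, small_groups(3, 3), trend = FALSE)
  expect_equal(res$p_raw[1], 1)
  expect_equal(res$p_raw[4], 1)
})

test_that("CLR Monte-Carlo is seed-deterministic and finds strong shifts", {
  cfg <- cohort_config(n_transcripts = 150, de_fraction = 0,
                       n_affected = 10, n_unaffected = 10, seed = 18)
  sim <- simulate_case_control(cfg, seed = 18)
  g <- consensusDEG:::group_labels(sim$counts, sim$sheet)
  r1 <- de_clr_mc(sim$counts, g, n_mc = 32, seed = 5)
  r2 <- de_clr_mc(sim$counts, g, n_mc = 32, seed = 5)
  expect_identical(r1$p_raw, r2$p_raw)
  r3 <- de_clr_mc(sim$counts, g, n_mc = 32, seed = 6)
  expect_false(identical(r3$p_raw, r2$p_raw))

  # one transcript at ~50% of every affected library vs ~5% unaffected
  counts <- sim$counts$counts
  tot <- colSums(counts)
  counts[1, g == "affected"] <- round(tot[g == "affected"])
  counts[1, g == "unaffected"] <- round(0.05 / 0.95 * tot[g == "unaffected"])
  cm <- count_matrix(counts, sim$counts$gene_symbols, sim$counts$lengths_bp)
  res <- de_clr_mc(cm, g, n_mc = 64, seed = 7)
  expect_lt(res$p_raw[1], 0.01)
  expect_gt(res$log2fc[1], 1)
})

test_that("BH adjustment: worked example, permutation invariance, oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "cdeg_format_error")
  expect_error(bh_adjust(c(0.5, NA)), class = "cdeg_format_error")
  withr::with_seed(44, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
      perm <- sample(seq_along(p))
      expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
    }
  })
})

test_that("paired variants beat unpaired power under strong pair effects", {
  cfg <- cohort_config(n_transcripts = 400, de_fraction = 0.1,
                       de_log2fc = c(1.5, 2), de_baseline_min = 20,
                       dispersion = 0.1, pair_effect_sd = 0.8, seed = 21)
  tw <- simulate_twins(cfg, seed = 21)
  g <- consensusDEG:::group_labels(tw$counts, tw$sheet)
  pairs <- consensusDEG:::twin_pairs(tw$sheet)
  nf <- tmm_factors(tw$counts)
  de_idx <- which(tw$truth$is_de)

  disp_u <- estimate_dispersion(tw$counts, g, nf)
  disp_p <- estimate_dispersion(tw$counts, g, nf, pairs = pairs)
  lrt_u <- de_nb_glm_lrt(tw$counts, g, nf, disp_u)
  lrt_p <- de_nb_glm_lrt(tw$counts, g, nf, disp_p, pairs = pairs)
  expect_gt(mean(-log10(lrt_p$p_raw[de_idx] + 1e-300)),
            mean(-log10(lrt_u$p_raw[de_idx] + 1e-300)))

  mt_u <- de_moderated_t(tw$counts, g)
  mt_p <- de_moderated_t(tw$counts, g, pairs = pairs)
  expect_gt(mean(-log10(mt_p$p_raw[de_idx] + 1e-300)),
            mean(-log10(mt_u$p_raw[de_idx] + 1e-300)))
})
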