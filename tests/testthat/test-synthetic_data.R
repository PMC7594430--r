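# The synthetic cohort generator: determinism, ground-truth bookkeeping,
# within-pair structure and discrepancy-score coupling.

test_that("identical seeds give identical cohorts; distinct seeds differ", {
  cfg <- cohort_config(n_transcripts = 120, seed = 4)
  a <- simulate_case_control(cfg, seed = 9)
  b <- simulate_case_control(cfg, seed = 9)
  c <- simulate_case_control(cfg, seed = 10)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$counts$counts, c$counts$counts))

  ta <- simulate_twins(cfg, seed = 9)
  tb <- simulate_twins(cfg, seed = 9)
  expect_identical(ta$counts$counts, tb$counts$counts)
})

test_that("de_fraction zero yields no truly differential transcripts", {
  cfg <- cohort_config(n_transcripts = 100, de_fraction = 0, seed = 2)
  sim <- simulate_case_control(cfg)
  expect_equal(sum(sim$truth$is_de), 0L)
  expect_true(all(sim$truth$mean_affected == sim$truth$mean_unaffected))
})

test_that("group sizes follow the two cohort designs", {
  cfg <- cohort_config(n_transcripts = 50, seed = 1)
  cc <- simulate_case_control(cfg)
  expect_equal(sum(cc$sheet$group == "affected"), 23L)
  expect_equal(sum(cc$sheet$group == "unaffected"), 21L)
  tw <- simulate_twins(cfg)
  expect_equal(nrow(tw$sheet), 32L)
  expect_equal(length(unique(tw$sheet$pair_id)), 16L)
})

test_that("per-transcript sample means track true means (slope near 1)", {
  cfg <- cohort_config(n_transcripts = 2000, de_fraction = 0,
                       dispersion = 0.2, seed = 1)
  sim <- simulate_case_control(cfg, seed = 1)
  libsize <- attr(sim$truth, "libsize")
  expected <- sim$truth$baseline_mean * mean(libsize)
  observed <- rowMeans(sim$counts$counts)
  slope <- coef(lm(observed ~ expected))[["expected"]]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("counts are overdispersed when dispersion is positive", {
  cfg <- cohort_config(n_transcripts = 600, de_fraction = 0,
                       dispersion = 0.4, libsize_range = c(1, 1), seed = 3)
  sim <- simulate_case_control(cfg, seed = 3)
  m <- rowMeans(sim$counts$counts)
  v <- apply(sim$counts$counts, 1, var)
  hi <- m > 20  # overdispersion is unmistakable at decent depth
  expect_gt(mean(v[hi] > m[hi]), 0.95)
})

test_that("zero pair effect removes the within-pair correlation excess", {
  cfg0 <- cohort_config(n_transcripts = 800, de_fraction = 0,
                        pair_effect_sd = 0, libsize_range = c(1, 1),
                        seed = 5)
  cfg1 <- cohort_config(n_transcripts = 800, de_fraction = 0,
                        pair_effect_sd = 0.8, libsize_range = c(1, 1),
                        seed = 5)
  within_minus_between <- function(sim) {
    lg <- log2(sim$counts$counts + 0.5)
    pairs <- consensusDEG:::twin_pairs(sim$sheet)
    ai <- match(pairs$affected, sim$counts$sample_ids)
    ui <- match(pairs$unaffected, sim$counts$sample_ids)
    lg <- lg - rowMeans(lg)
    within <- mean(sapply(seq_along(ai), function(p) {
      cor(lg[, ai[p]], lg[, ui[p]])
    }))
    between <- mean(sapply(seq_along(ai), function(p) {
      q <- if (p == length(ai)) 1L else p + 1L
      cor(lg[, ai[p]], lg[, ui[q]])
    }))
    within - between
  }
  expect_lt(abs(within_minus_between(simulate_twins(cfg0, seed = 11))), 0.05)
  expect_gt(within_minus_between(simulate_twins(cfg1, seed = 11)), 0.1)
})

test_that("discrepancy coupling reproduces the generative-model correlation", {
  # package route: mean Spearman r between per-pair count fold change and
  # the discrepancy rank over simulated cohorts
  cfg <- cohort_config(n_transcripts = 60, de_fraction = 0, n_coupled = 5,
                       coupling_rho = 0.8, seed = 1)
  rs <- c()
  for (seed in 1:100) {
    tw <- simulate_twins(cfg, seed = seed)
    coup <- attr(tw$truth, "coupling")
    pairs <- consensusDEG:::twin_pairs(tw$sheet)
    pfc <- pairwise_fold_change(tw$counts, pairs)
    scores <- discrepancy_scores(tw$sheet)
    ranked <- rank_discordance(scores, "d_total")
    corr <- correlate_discordance(pfc, ranked, method = "spearman",
                                  r_thresh = 0.4)
    rs <- c(rs, corr$r[match(coup$transcript_ids, corr$transcript_id)])
  }
  pkg_mean_r <- mean(rs, na.rm = TRUE)

  # independent brute-force Monte-Carlo of the generative model: blocks of
  # 16 pairs, baseline log-uniform above the coupling floor, NB counts,
  # depth-corrected fold change, Spearman against the discrepancy rank
  oracle_mean_r <- withr::with_seed(99, {
    n_blocks <- 4000
    out <- numeric(n_blocks)
    for (bl in seq_len(n_blocks)) {
      P <- 16
      b <- 2^runif(1, log2(50), 11)
      # regenerate the score model exactly as the generator defines it
      una_i <- sample(0:8, P, TRUE); una_h <- sample(0:8, P, TRUE)
      aff_i <- pmin(27, una_i + sample(2:14, P, TRUE))
      aff_h <- pmin(27, una_h + sample(0:12, P, TRUE))
      d <- abs((aff_i + aff_h) - (una_i + una_h))
      z <- as.numeric(scale(d))
      delta <- 1.5 * (0.8 * z + sqrt(1 - 0.8^2) * rnorm(P))
      e <- exp(rnorm(P, 0, 0.15))
      la <- 2^runif(P, -1, 1); lu <- 2^runif(P, -1, 1)
      ya <- rnbinom(P, mu = b * e * 2^delta * la, size = 1 / 0.2)
      yu <- rnbinom(P, mu = b * e * lu, size = 1 / 0.2)
      fc <- log2((ya / la + 0.25) / (yu / lu + 0.25))
      rk <- rank(-d, ties.method = "average")
      out[bl] <- suppressWarnings(cor(fc, rk, method = "spearman"))
    }
    mean(out, na.rm = TRUE)
  })
  expect_lt(abs(pkg_mean_r - oracle_mean_r), 0.2)
  expect_lt(pkg_mean_r, -0.3)  # coupling must produce a clear inverse trend
})

test_that("zero coupling leaves fold change and rank uncorrelated", {
  cfg <- cohort_config(n_transcripts = 40, de_fraction = 0, n_coupled = 3,
                       coupling_rho = 0, seed = 1)
  rs <- c()
  for (seed in 1:60) {
    tw <- simulate_twins(cfg, seed = seed)
    coup <- attr(tw$truth, "coupling")
    pfc <- pairwise_fold_change(tw$counts,
                                consensusDEG:::twin_pairs(tw$sheet))
    ranked <- rank_discordance(discrepancy_scores(tw$sheet), "d_total")
    corr <- correlate_discordance(pfc, ranked)
    rs <- c(rs, corr$r[match(coup$transcript_ids, corr$transcript_id)])
  }
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
})
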