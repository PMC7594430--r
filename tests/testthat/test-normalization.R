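# TMM, median-of-ratios and DEGES normalization factors.

test_that("identical columns give unit factors for both methods", {
  counts <- matrix(rep(c(5L, 80L, 300L, 2L, 40L), 4), 5, 4,
                   dimnames = list(sprintf("t%d", 1:5), sprintf("s%d", 1:4)))
  cm <- count_matrix(counts, sprintf("G%d", 1:5), rep(1000L, 5))
  expect_equal(unname(tmm_factors(cm)$factors), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(median_of_ratios_factors(cm)$factors), rep(1, 4),
               tolerance = 1e-9)
})

test_that("TMM recovers a pure depth change within 5%", {
  withr::with_seed(21, {
    n <- 5000
    base <- rnbinom(n, mu = 2^runif(n, 1, 10), size = 5)
    y2 <- rnbinom(n, mu = 2 * (base + 1), size = 20)
    counts <- cbind(s1 = base + 1L, s2 = y2)
    rownames(counts) <- sprintf("t%04d", 1:n)
    cm <- count_matrix(counts, sprintf("G%04d", 1:n), rep(1000L, n))
    f <- tmm_factors(cm)$factors
    expect_equal(unname(f["s2"] / f["s1"]), 2, tolerance = 0.05)
  })
})

test_that("the trimmed extreme M-value transcript cannot move the factor", {
  withr::with_seed(8, {
    n <- 400
    base <- rpois(n, 200) + 1L
    y2 <- rpois(n, 200) + 1L
    counts <- cbind(s1 = base, s2 = y2)
    rownames(counts) <- sprintf("t%03d", 1:n)
    cm <- count_matrix(counts, sprintf("G%03d", 1:n), rep(1000L, n))
    f0 <- tmm_factors(cm, ref_sample = "s1")$factors
    # push one transcript to an absurd ratio: it lands in the trimmed tail
    counts2 <- counts
    counts2[1, "s2"] <- 100000L
    cm2 <- count_matrix(counts2, cm$gene_symbols, cm$lengths_bp)
    f1 <- tmm_factors(cm2, ref_sample = "s1")$factors
    expect_equal(unname(f1["s2"] / f1["s1"]), unname(f0["s2"] / f0["s1"]),
                 tolerance = 0.02)
  })
})

test_that("TMM agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  cm <- random_count_matrix(n_tx = 500, n_s = 6, seed = 14)
  ours <- tmm_factors(cm)$factors
  nf <- edgeR::calcNormFactors(cm$counts, method = "TMM",
                               logratioTrim = 0.3, sumTrim = 0.05)
  # edgeR's factors are depth-free; ours absorb depth -> compare effective
  eff <- nf * colSums(cm$counts)
  eff <- eff / exp(mean(log(eff)))
  expect_equal(unname(ours), unname(eff), tolerance = 0.05)
})

test_that("median-of-ratios scales exactly with an injected factor", {
  cm <- random_count_matrix(n_tx = 200, n_s = 5, seed = 5)
  cm$counts[cm$counts == 0] <- 1L
  cm <- count_matrix(cm$counts, cm$gene_symbols, cm$lengths_bp)
  f0 <- median_of_ratios_factors(cm)$factors
  scaled <- cm$counts
  scaled[, 3] <- scaled[, 3] * 3L
  f1 <- median_of_ratios_factors(
    count_matrix(scaled, cm$gene_symbols, cm$lengths_bp))$factors
  # every ratio in column 3 scales by 3 (the per-transcript geometric means
  # shift all columns equally), so relative to any other column the factor
  # moves by exactly 3
  expect_equal(unname(f1[3] / f1[1]), unname(3 * f0[3] / f0[1]),
               tolerance = 1e-9)
  expect_equal(unname(f1[2] / f1[1]), unname(f0[2] / f0[1]),
               tolerance = 1e-9)
})

test_that("median-of-ratios equals its brute-force definition", {
  cm <- random_count_matrix(n_tx = 60, n_s = 4, seed = 9)
  got <- median_of_ratios_factors(cm)$factors
  ok <- apply(cm$counts, 1, function(r) all(r > 0))
  expected <- sapply(seq_len(4), function(s) {
    lratios <- c()
    for (g in which(ok)) {
      geo <- exp(mean(log(cm$counts[g, ])))
      lratios <- c(lratios, log(cm$counts[g, s] / geo))
    }
    exp(median(lratios))
  })
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)

  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  expect_equal(unname(got / got[1]), unname(ref / ref[1]), tolerance = 1e-6)
})

test_that("no all-nonzero transcript is an error for median-of-ratios", {
  counts <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
                   dimnames = list(c("t1", "t2"), c("s1", "s2")))
  cm <- count_matrix(counts, c("A", "B"), c(100L, 100L))
  expect_error(median_of_ratios_factors(cm), class = "cdeg_runtime_error")
})

test_that("DEGES with zero removal equals the inner normalization", {
  cm <- random_count_matrix(n_tx = 150, n_s = 8, seed = 4)
  groups <- small_groups(4, 4)
  inner <- tmm_factors(cm)$factors
  dg <- deges_normalize(cm, groups, iterations = 1L, removal_fraction = 0)
  expect_equal(unname(dg$factors), unname(inner), tolerance = 1e-12)
  expect_identical(dg$method, "deges")
})

test_that("DEGES corrects one-sided composition bias better than TMM", {
  # 30% of transcripts spiked up in the affected group only: the symmetric
  # rank trim of single-pass TMM then sits asymmetrically inside the null
  # M-value cluster and biases the factors group-wise; DEGES removes the
  # putative DEGs and renormalizes on the clean remainder
  groups <- small_groups(10, 10)
  one_sided_sim <- function(seed, n = 2500) {
    withr::with_seed(seed, {
      baseline <- 2^runif(n, 0, 12)
      lfc <- numeric(n)
      lfc[sample(n, round(0.3 * n))] <- runif(round(0.3 * n), 1.5, 2.5)
      libsize <- 2^runif(20, -1, 1)
      counts <- sapply(1:20, function(s) {
        mu <- baseline * libsize[s] *
          (if (groups[s] == "affected") 2^lfc else rep(1, n))
        rnbinom(n, mu = mu, size = 1 / 0.2)
      })
      dimnames(counts) <- list(sprintf("t%05d", 1:n), sprintf("s%02d", 1:20))
      list(cm = count_matrix(counts, sprintf("G%05d", 1:n), rep(1000L, n)),
           libsize = libsize)
    })
  }
  err <- function(f, libsize) {
    rel <- (f / libsize) / exp(mean(log(f / libsize)))
    max(abs(log(rel)))
  }
  wins <- 0
  for (seed in 1:4) {
    sim <- one_sided_sim(seed)
    e_tmm <- err(tmm_factors(sim$cm)$factors, sim$libsize)
    e_deges <- err(deges_normalize(sim$cm, groups)$factors, sim$libsize)
    if (e_deges < e_tmm) wins <- wins + 1
  }
  expect_gte(wins, 3)
})
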