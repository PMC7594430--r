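# Shared fixtures and independently coded brute-force oracles. The oracles
# deliberately use naive element-wise logic (loops, full enumeration) and
# never touch the package's vectorized implementations.

tiny_count_matrix <- function() {
  count_matrix(
    matrix(c(100L, 0L, 7L, 3L), 2, 2,
           dimnames = list(c("t1", "t2"), c("s1", "s2"))),
    gene_symbols = c("GENE1", "GENE2"),
    lengths_bp = c(2000L, 500L)
  )
}

random_count_matrix <- function(n_tx = 50, n_s = 6, seed = 1) {
  withr::with_seed(seed, {
    counts <- matrix(rnbinom(n_tx * n_s, mu = 2^runif(n_tx * n_s, -2, 8),
                             size = 5), n_tx, n_s,
                     dimnames = list(sprintf("t%03d", 1:n_tx),
                                     sprintf("s%02d", 1:n_s)))
    count_matrix(counts,
                 gene_symbols = sprintf("G%03d", ceiling((1:n_tx) / 2)),
                 lengths_bp = sample(200:5000, n_tx))
  })
}

small_groups <- function(n_aff, n_una) {
  factor(c(rep("affected", n_aff), rep("unaffected", n_una)),
         levels = c("unaffected", "affected"))
}

twin_sheet_fixture <- function(n_pairs = 4, seed = 1) {
  withr::with_seed(seed, {
    una_t <- sample(0:10, n_pairs, replace = TRUE)
    aff_t <- una_t + sample(3:12, n_pairs, replace = TRUE)
    sample_sheet(data.frame(
      sample_id = c(rbind(sprintf("a%02d", 1:n_pairs),
                          sprintf("u%02d", 1:n_pairs))),
      cohort = "twins",
      group = rep(c("affected", "unaffected"), n_pairs),
      pair_id = rep(sprintf("p%02d", 1:n_pairs), each = 2),
      adhd_rs_inattention = c(rbind(pmin(aff_t, 27), pmin(una_t, 27))),
      adhd_rs_hyperactivity = 0,
      adhd_rs_total = c(rbind(pmin(aff_t, 27), pmin(una_t, 27))),
      adhd_rs_tscore = c(rbind(60 + aff_t, 45 + una_t)),
      prior_diagnosis = FALSE
    ))
  })
}

# ---- oracles -------------------------------------------------------------

# textbook BH step-up, coded directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    val <- p[ord[i]] * m / i
    running_min <- min(running_min, val)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# per-cell RPKM formula
oracle_rpkm <- function(counts, lengths_bp) {
  out <- counts * NA_real_
  totals <- colSums(counts)
  for (g in seq_len(nrow(counts))) {
    for (s in seq_len(ncol(counts))) {
      out[g, s] <- counts[g, s] / (lengths_bp[g] / 1000) / (totals[s] / 1e6)
    }
  }
  out
}

# per-transcript prevalence predicate, evaluated sample by sample
oracle_prevalence <- function(vals, groups, tau, phi) {
  kept <- logical(nrow(vals))
  for (g in seq_len(nrow(vals))) {
    ok <- FALSE
    for (lv in unique(as.character(groups))) {
      cols <- which(groups == lv)
      n_present <- 0
      for (s in cols) if (vals[g, s] > tau) n_present <- n_present + 1
      if (n_present / length(cols) >= phi - 1e-12) ok <- TRUE
    }
    kept[g] <- ok
  }
  kept
}

# exhaustive hypergeometric tail by enumerating draws
oracle_overlap_p <- function(n1, n2, k, N) {
  total <- choose(N, n2)
  hits <- 0
  for (x in k:min(n1, n2)) {
    hits <- hits + choose(n1, x) * choose(N - n1, n2 - x)
  }
  hits / total
}

# full-support conditional NB exact test (small totals only)
oracle_exact_nb <- function(s1, s2, n1, n2, phi) {
  t_tot <- s1 + s2
  if (t_tot == 0) return(1)
  lambda <- t_tot / (n1 + n2)
  pk <- numeric(t_tot + 1)
  for (k in 0:t_tot) {
    pk[k + 1] <- if (phi < 1e-10) {
      dbinom(k, t_tot, n1 / (n1 + n2))
    } else {
      dnbinom(k, size = n1 / phi, mu = n1 * lambda) *
        dnbinom(t_tot - k, size = n2 / phi, mu = n2 * lambda)
    }
  }
  pk <- pk / sum(pk)
  obs <- pk[s1 + 1]
  sum(pk[pk <= obs * (1 + 1e-10)])
}

# naive top-k by explicit pairwise ordering
oracle_top_k <- function(res, k) {
  key <- order(res$p_adj, res$p_raw, res$transcript_id)
  res$transcript_id[key][seq_len(min(k, nrow(res)))]
}

# set-arithmetic Jaccard
oracle_jaccard <- function(a, b) {
  length(intersect(unique(a), unique(b))) /
    length(union(unique(a), unique(b)))
}
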