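# The differential-expression battery. Five test families over pluggable
# normalizations, each emitting one row per transcript: a signed log2 fold
# change (affected vs unaffected), a raw p and a BH-adjusted p. The
# consensus layer is method-agnostic: the number of methods in a run is
# data, not a constant.

de_result <- function(method_id, transcript_ids, log2fc, p_raw) {
  p_raw <- pmin(pmax(p_raw, 0), 1)
  data.frame(
    method_id = method_id,
    transcript_id = transcript_ids,
    log2fc = log2fc,
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validating wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    cdeg_stop("p-values must be finite and lie in [0, 1]",
              "cdeg_format_error")
  }
  stats::p.adjust(p, method = "BH")
}

# Depth-equalized pseudo-counts: counts divided by effective size factors
# (factors have geometric mean ~1, so pseudo-counts live on the scale of a
# typical library), rounded to integers for the exact test.
pseudo_counts <- function(cm, norm) {
  f <- norm$factors[cm$sample_ids]
  sweep(cm$counts, 2, f, "/")
}

# Two-sided exact NB test for one transcript: group sums s1 (n1 samples) vs
# s2 (n2 samples) at a common per-sample mean, conditional on the total.
# The conditional pmf is log-concave, so mass outside the quantile window
# bounded at 1e-14 per component is negligible.
exact_nb_p <- function(s1, s2, n1, n2, phi) {
  t_tot <- s1 + s2
  if (t_tot == 0) return(1)
  lambda <- t_tot / (n1 + n2)
  if (phi < 1e-10) {
    # Poisson limit: conditional distribution is binomial
    lp_fun <- function(k) stats::dbinom(k, t_tot, n1 / (n1 + n2), log = TRUE)
    lo <- stats::qbinom(1e-15, t_tot, n1 / (n1 + n2))
    hi <- stats::qbinom(1e-15, t_tot, n1 / (n1 + n2), lower.tail = FALSE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    mu1 <- n1 * lambda
    mu2 <- n2 * lambda
    lp_fun <- function(k) {
      stats::dnbinom(k, size = r1, mu = mu1, log = TRUE) +
        stats::dnbinom(t_tot - k, size = r2, mu = mu2, log = TRUE)
    }
    lo <- min(stats::qnbinom(1e-15, size = r1, mu = mu1),
              t_tot - stats::qnbinom(1e-15, size = r2, mu = mu2,
                                     lower.tail = FALSE))
    hi <- max(stats::qnbinom(1e-15, size = r1, mu = mu1, lower.tail = FALSE),
              t_tot - stats::qnbinom(1e-15, size = r2, mu = mu2))
  }
  lo <- max(0, min(lo, s1))
  hi <- min(t_tot, max(hi, s1))
  # the pmf is smooth on the scale of the window; beyond ~4000 support
  # points accumulate mass on a stride-aligned grid through the observed
  # value (midpoint rule; relative error is negligible at these widths)
  stride <- max(1, ceiling((hi - lo + 1) / 4000))
  ks <- seq(s1, lo, by = -stride)
  ks <- c(rev(ks[-1]), seq(s1, hi, by = stride))
  lp <- lp_fun(ks)
  lp_obs <- lp[ks == s1]
  m <- max(lp)
  keep <- lp <= lp_obs + 1e-10
  p <- sum(exp(lp[keep] - m)) / sum(exp(lp - m))
  min(max(p, 0), 1)
}

#' Exact negative-binomial test
#'
#' Counts are rescaled to a common effective depth, summed within each
#' diagnostic group, and compared by a two-sided conditional exact test:
#' the p-value is the conditional probability mass of all outcomes no more
#' probable than the observed split of the total.
#'
#' @param cm A [count_matrix()].
#' @param groups Per-sample labels (`affected` / `unaffected`).
#' @param norm A `norm_factors` object.
#' @param disp A `dispersion_model`.
#' @param method_id Label for the output rows.
#' @return A `DEResult` data frame.
#' @export
de_nb_exact <- function(cm, groups, norm, disp, method_id = "nb_exact") {
  groups <- check_two_groups(groups, ncol(cm$counts))
  pc <- round(pseudo_counts(cm, norm))
  aff <- which(groups == "affected")
  una <- which(groups == "unaffected")
  s1 <- rowSums(pc[, aff, drop = FALSE])
  s2 <- rowSums(pc[, una, drop = FALSE])
  phi <- disp_per_transcript(disp, cm$transcript_ids)
  p <- vapply(seq_len(nrow(pc)), function(g) {
    exact_nb_p(s1[g], s2[g], length(aff), length(una), phi[g])
  }, numeric(1))
  fc <- fold_change(pseudo_counts(cm, norm), groups)
  de_result(method_id, cm$transcript_ids, fc$log2fc, p)
}

# Vectorized two-group NB fits for the unpaired GLM likelihood-ratio and
# Wald tests; phi may be a per-transcript vector. Newton on the per-group
# log-mean with per-sample factors as offsets.
fit_two_groups_vec <- function(y, f, groups, phi) {
  fit_set <- function(cols) {
    ys <- y[, cols, drop = FALSE]
    fs <- f[cols]
    lq <- log((rowSums(ys) + 0.1) / sum(fs))
    for (it in 1:12) {
      mu <- exp(lq) %o% fs
      denom <- 1 + phi * mu
      score <- rowSums((ys - mu) / denom)
      info <- rowSums(mu / denom)
      step <- pmin(pmax(score / pmax(info, 1e-10), -5), 5)
      lq <- pmin(pmax(lq + step, -30), 30)
      if (max(abs(step)) < 1e-10) break
    }
    mu <- exp(lq) %o% fs
    info <- rowSums(mu / (1 + phi * mu))
    ll <- rowSums(nb_logpmf_vecphi(ys, mu, phi))
    list(lq = lq, ll = ll, info = info)
  }
  aff <- fit_set(which(groups == "affected"))
  una <- fit_set(which(groups == "unaffected"))
  all <- fit_set(seq_len(ncol(y)))
  list(aff = aff, una = una, all = all)
}

# nb_logpmf with phi possibly a per-transcript vector (rows of y).
nb_logpmf_vecphi <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (length(phi) == 1L) return(nb_logpmf(y, mu, phi))
  phim <- matrix(phi, nrow(y), ncol(y))
  out <- matrix(0, nrow(y), ncol(y))
  pois <- phi < 1e-10
  if (any(pois)) {
    out[pois, ] <- stats::dpois(y[pois, , drop = FALSE],
                                lambda = mu[pois, , drop = FALSE], log = TRUE)
  }
  if (any(!pois)) {
    out[!pois, ] <- stats::dnbinom(y[!pois, , drop = FALSE],
                                   size = 1 / phim[!pois, , drop = FALSE],
                                   mu = mu[!pois, , drop = FALSE], log = TRUE)
  }
  out
}

#' NB generalized linear model likelihood-ratio test
#'
#' Log-link NB regression with fixed tagwise dispersion, fitted by
#' iteratively reweighted least squares; the p-value comes from the
#' chi-squared (1 df) likelihood ratio of dropping the group term. In the
#' paired design the model additionally carries pair indicator columns.
#' Transcripts whose IRLS does not converge are reported conservatively
#' with p = 1.
#'
#' @inheritParams de_nb_exact
#' @param pairs Optional pair table; when given the paired design is used.
#' @return A `DEResult` data frame.
#' @export
de_nb_glm_lrt <- function(cm, groups, norm, disp, pairs = NULL,
                          method_id = "nb_glm_lrt") {
  groups <- check_two_groups(groups, ncol(cm$counts))
  y <- cm$counts
  f <- norm$factors[cm$sample_ids]
  phi <- disp_per_transcript(disp, cm$transcript_ids)
  if (is.null(pairs)) {
    fits <- fit_two_groups_vec(y, f, groups, phi)
    lrt <- pmax(2 * (fits$aff$ll + fits$una$ll - fits$all$ll), 0)
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    l2fc <- (fits$aff$lq - fits$una$lq) / log(2)
  } else {
    idx <- paired_columns(cm, pairs)
    ya <- y[, idx$aff, drop = FALSE]
    yu <- y[, idx$una, drop = FALSE]
    full <- fit_paired_vec(ya, yu, f[idx$aff], f[idx$una], phi,
                           with_group = TRUE)
    red <- fit_paired_vec(ya, yu, f[idx$aff], f[idx$una], phi,
                          with_group = FALSE)
    lrt <- pmax(2 * (full$ll - red$ll), 0)
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    # non-converged fits are reported conservatively
    p[!(full$converged & red$converged)] <- 1
    l2fc <- full$b / log(2)
  }
  de_result(method_id, cm$transcript_ids, l2fc, p)
}

#' Simplified NB Wald test
#'
#' The group coefficient of the unpaired NB GLM divided by its Fisher
#' standard error, referred to the standard normal. No independent
#' filtering and no fold-change shrinkage are applied.
#'
#' @inheritParams de_nb_exact
#' @return A `DEResult` data frame.
#' @export
de_nb_wald <- function(cm, groups, norm, disp, method_id = "nb_wald") {
  groups <- check_two_groups(groups, ncol(cm$counts))
  y <- cm$counts
  f <- norm$factors[cm$sample_ids]
  phi <- disp_per_transcript(disp, cm$transcript_ids)
  fits <- fit_two_groups_vec(y, f, groups, phi)
  beta <- fits$aff$lq - fits$una$lq
  se <- sqrt(1 / pmax(fits$aff$info, 1e-8) + 1 / pmax(fits$una$info, 1e-8))
  z <- beta / se
  # transcripts with no information (all-zero): report p = 1
  none <- fits$aff$info < 1e-6 & fits$una$info < 1e-6
  p <- 2 * stats::pnorm(-abs(z))
  p[none] <- 1
  de_result(method_id, cm$transcript_ids, beta / log(2), p)
}

# Newton inversion of the trigamma function (for the prior df of the
# moderated t); x must be positive.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:30) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

# Moment-match s^2 ~ s0^2 * F(d, d0) on the log scale (empirical Bayes
# hyperparameters for variance moderation).
fit_f_moments <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 1e-300
  e <- log(s2[ok])
  if (length(e) < 2L) return(list(d0 = Inf, s02 = mean(s2[ok])))
  ev <- stats::var(e) - trigamma(d / 2)
  if (ev > 1e-8) {
    d0 <- 2 * trigamma_inverse(ev)
    s02 <- exp(mean(e) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e) - digamma(d / 2) + log(d / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t-test on log2-CPM
#'
#' Counts are transformed to log2 counts-per-million (pseudocount 0.5), a
#' lowess mean-variance trend provides per-observation precision weights,
#' each transcript is fitted by weighted least squares, and residual
#' variances are squeezed by empirical Bayes:
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)` with `(d0, s02)` fitted by
#' moment-matching an F distribution to the observed variances. The
#' moderated t is referred to a t distribution on `d0 + d` degrees of
#' freedom. In the paired design the test is a one-sample moderated t on
#' within-pair differences.
#'
#' @inheritParams de_nb_glm_lrt
#' @param trend Use the mean-variance trend weights (unpaired only).
#' @param prior Optional list `list(d0 =, s02 =)` overriding the fitted
#'   hyperparameters; `d0 = 0` reduces the test to the ordinary
#'   (pooled-variance or one-sample) t-test.
#' @return A `DEResult` data frame.
#' @export
de_moderated_t <- function(cm, groups, pairs = NULL, trend = TRUE,
                           prior = NULL, method_id = "moderated_t") {
  groups <- check_two_groups(groups, ncol(cm$counts))
  y <- cm$counts
  lib <- colSums(y)
  logcpm <- log2(sweep(y + 0.5, 2, lib + 1, "/") * 1e6)

  if (is.null(pairs)) {
    aff <- which(groups == "affected")
    una <- which(groups == "unaffected")
    n <- ncol(y)
    d <- n - 2L
    if (length(aff) < 2L || length(una) < 2L) {
      cdeg_stop("need >= 2 samples per group", "cdeg_design_error")
    }
    w <- matrix(1, nrow(y), n)
    if (trend) {
      # voom-style: sqrt residual sd against average log2 count
      mA <- rowMeans(logcpm[, aff, drop = FALSE])
      mU <- rowMeans(logcpm[, una, drop = FALSE])
      res <- logcpm
      res[, aff] <- logcpm[, aff, drop = FALSE] - mA
      res[, una] <- logcpm[, una, drop = FALSE] - mU
      s <- sqrt(rowSums(res^2) / d)
      sx <- rowMeans(logcpm) + mean(log2(lib + 1)) - log2(1e6)
      sy <- sqrt(s)
      lo <- stats::lowess(sx, sy, f = 0.5)
      trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
      fitted_lcpm <- logcpm
      fitted_lcpm[, aff] <- mA
      fitted_lcpm[, una] <- mU
      fitted_cnt <- sweep(fitted_lcpm, 2, log2(lib + 1) - log2(1e6), "+")
      w <- 1 / pmax(trend_fun(fitted_cnt), 0.05)^4
      dim(w) <- dim(y)
    }
    WA <- rowSums(w[, aff, drop = FALSE])
    WU <- rowSums(w[, una, drop = FALSE])
    mA <- rowSums(w[, aff, drop = FALSE] * logcpm[, aff, drop = FALSE]) / WA
    mU <- rowSums(w[, una, drop = FALSE] * logcpm[, una, drop = FALSE]) / WU
    beta <- mA - mU
    resA <- logcpm[, aff, drop = FALSE] - mA
    resU <- logcpm[, una, drop = FALSE] - mU
    s2 <- (rowSums(w[, aff, drop = FALSE] * resA^2) +
             rowSums(w[, una, drop = FALSE] * resU^2)) / d
    varb_unit <- 1 / WA + 1 / WU
  } else {
    P <- nrow(pairs)
    if (P < 3L) cdeg_stop("paired moderated t needs >= 3 pairs",
                          "cdeg_design_error")
    ai <- match(pairs$affected, cm$sample_ids)
    ui <- match(pairs$unaffected, cm$sample_ids)
    dmat <- logcpm[, ai, drop = FALSE] - logcpm[, ui, drop = FALSE]
    d <- P - 1L
    beta <- rowMeans(dmat)
    s2 <- rowSums((dmat - beta)^2) / d
    varb_unit <- 1 / P
  }

  hyper <- prior %||% fit_f_moments(s2, d)
  d0 <- hyper$d0
  s02 <- hyper$s02
  if (d0 <= 0) {
    s2_post <- s2
    df_total <- d
  } else if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  tstat <- beta / sqrt(s2_post * varb_unit)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  degenerate <- s2 < 1e-12 & abs(beta) < 1e-12
  p[degenerate] <- 1
  p[!is.finite(p)] <- 1
  de_result(method_id, cm$transcript_ids, beta, p)
}

#' Dirichlet Monte-Carlo CLR test
#'
#' Counts plus a 0.5 prior parameterize per-sample Dirichlet distributions;
#' each Monte-Carlo instance draws a composition, applies the centered
#' log-ratio transform, and runs a Welch t-test per transcript. The
#' reported p is the expectation over instances, which makes the test
#' deliberately conservative; the effect size is the expected CLR
#' difference in log2 units.
#'
#' @inheritParams de_nb_exact
#' @param n_mc Number of Monte-Carlo instances (>= 16).
#' @param seed Seed making the instance draws reproducible.
#' @return A `DEResult` data frame.
#' @export
de_clr_mc <- function(cm, groups, n_mc = 128L, seed = 1L,
                      method_id = "clr_mc") {
  groups <- check_two_groups(groups, ncol(cm$counts))
  if (n_mc < 16L) cdeg_stop("n_mc must be >= 16", "cdeg_config_error")
  y <- cm$counts + 0.5
  G <- nrow(y)
  n <- ncol(y)
  aff <- which(groups == "affected")
  una <- which(groups == "unaffected")
  nA <- length(aff)
  nU <- length(una)
  with_seed(seed, {
    p_acc <- numeric(G)
    eff_acc <- numeric(G)
    for (i in seq_len(n_mc)) {
      gam <- matrix(stats::rgamma(G * n, shape = y), G, n)
      lcomp <- log(gam) - rep(log(colSums(gam)), each = G)
      clr <- lcomp - rep(colMeans(lcomp), each = G)
      xA <- clr[, aff, drop = FALSE]
      xU <- clr[, una, drop = FALSE]
      mA <- rowMeans(xA)
      mU <- rowMeans(xU)
      vA <- rowSums((xA - mA)^2) / (nA - 1)
      vU <- rowSums((xU - mU)^2) / (nU - 1)
      se2 <- vA / nA + vU / nU
      tstat <- (mA - mU) / sqrt(pmax(se2, 1e-300))
      df <- se2^2 / pmax(vA^2 / (nA^2 * (nA - 1)) +
                           vU^2 / (nU^2 * (nU - 1)), 1e-300)
      p_acc <- p_acc + 2 * stats::pt(-abs(tstat), df = df)
      eff_acc <- eff_acc + (mA - mU)
    }
    de_result(method_id, cm$transcript_ids,
              (eff_acc / n_mc) / log(2), p_acc / n_mc)
  })
}

# Dispatch one method_spec. `context` carries cached factors and dispersion
# models so a battery run computes each (normalization, design) combination
# once.
run_de_test <- function(cm, groups, spec, norm, disp, pairs = NULL,
                        n_mc = 128L, seed = 1L) {
  pr <- if (spec$paired) pairs else NULL
  switch(spec$test,
         nb_exact = de_nb_exact(cm, groups, norm, disp, spec$method_id),
         nb_glm_lrt = de_nb_glm_lrt(cm, groups, norm, disp, pairs = pr,
                                    method_id = spec$method_id),
         nb_wald = de_nb_wald(cm, groups, norm, disp, spec$method_id),
         moderated_t = de_moderated_t(cm, groups, pairs = pr,
                                      method_id = spec$method_id),
         clr_mc = de_clr_mc(cm, groups, n_mc = n_mc, seed = seed,
                            method_id = spec$method_id),
         cdeg_stop("unknown test", "cdeg_config_error"))
}

#' Run a battery of DE methods
#'
#' Computes each required normalization and dispersion model once, runs
#' every [method_spec()], and returns the per-method result tables.
#'
#' @param cm A [count_matrix()].
#' @param sheet A [sample_sheet()] covering the matrix columns.
#' @param methods List of [method_spec()]s, default [default_battery()].
#' @param n_mc,seed Monte-Carlo settings for the CLR test.
#' @param prior_df Tagwise-dispersion shrinkage weight.
#' @return Named list of `DEResult` data frames, one per method.
#' @export
run_de_battery <- function(cm, sheet, methods = NULL, n_mc = 128L,
                           seed = 1L, prior_df = 10) {
  groups <- group_labels(cm, sheet)
  is_twins <- any(sheet$cohort == "twins")
  pairs <- if (is_twins) twin_pairs(sheet) else NULL
  methods <- methods %||% default_battery(paired = is_twins)

  norm_cache <- list()
  get_norm <- function(kind) {
    if (kind %in% c("log_cpm", "clr")) return(NULL)
    if (is.null(norm_cache[[kind]])) {
      norm_cache[[kind]] <<- switch(kind,
        tmm = tmm_factors(cm),
        median_of_ratios = median_of_ratios_factors(cm),
        deges = deges_normalize(cm, groups))
    }
    norm_cache[[kind]]
  }
  disp_cache <- list()
  get_disp <- function(norm, paired) {
    key <- paste(norm$method, if (paired) "paired" else "unpaired")
    if (is.null(disp_cache[[key]])) {
      disp_cache[[key]] <<- estimate_dispersion(
        cm, groups, norm, pairs = if (paired) pairs else NULL,
        prior_df = prior_df)
    }
    disp_cache[[key]]
  }

  out <- list()
  for (spec in methods) {
    norm <- get_norm(spec$normalization)
    disp <- if (spec$test %in% c("nb_exact", "nb_glm_lrt", "nb_wald")) {
      get_disp(norm, spec$paired)
    } else NULL
    out[[spec$method_id]] <- run_de_test(
      cm, groups, spec, norm, disp, pairs = pairs, n_mc = n_mc,
      seed = derive_seed(seed, match(spec$method_id,
                                     vapply(methods, `[[`, "", "method_id")))
    )
  }
  out
}
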