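# NB dispersion estimation. Variance model: var = mu + phi * mu^2.
# The common dispersion maximizes the Cox-Reid adjusted profile likelihood
# (APL) summed over transcripts; per-transcript maxima are shrunk toward the
# common value with a prior-degrees-of-freedom weight. The APL is computed
# under the same design matrix the downstream test uses (group only, or
# group plus pair indicators), so paired tests are not biased by the
# nuisance pair parameters.

nb_logpmf <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi < 1e-10) {
    stats::dpois(y, lambda = mu, log = TRUE)
  } else {
    stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
  }
}

# Vectorized (across transcripts) Newton fit of a single NB mean parameter
# per transcript for one set of columns, with per-sample effective size
# factors f as offsets. Returns per-transcript log-likelihood contributions
# and Fisher information for the fitted log-mean.
fit_one_group <- function(y, f, cols, phi) {
  ys <- y[, cols, drop = FALSE]
  fs <- f[cols]
  lq <- log((rowSums(ys) + 0.1) / sum(fs))
  for (it in 1:10) {
    mu <- exp(lq) %o% fs
    denom <- 1 + phi * mu
    score <- rowSums((ys - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -5), 5)
    lq <- pmin(pmax(lq + step, -30), 30)
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(lq) %o% fs
  info <- rowSums(mu / (1 + phi * mu))
  ll <- rowSums(nb_logpmf(ys, mu, phi))
  list(lq = lq, ll = ll, info = info, mu = mu)
}

# Per-transcript APL under the two-group (unpaired) design.
apl_unpaired <- function(y, f, groups, phi) {
  lv <- levels(groups)
  fa <- fit_one_group(y, f, which(groups == lv[1]), phi)
  fb <- fit_one_group(y, f, which(groups == lv[2]), phi)
  fa$ll + fb$ll - 0.5 * log(pmax(fa$info, 1e-8)) -
    0.5 * log(pmax(fb$info, 1e-8))
}

# Vectorized NB fit for the paired design (per-pair intercepts plus an
# optional shared group effect), by alternating Newton steps on the pair
# log-means and the group coefficient. The design matrix is never formed:
# the Fisher information is an arrow matrix whose log-determinant has a
# closed Schur-complement form, which makes the Cox-Reid adjustment cheap.
# phi may be scalar or per-transcript. All quantities are (transcripts x
# pairs) matrices; recycling of per-transcript vectors down columns is
# exact because matrices are column-major with transcripts in rows.
fit_paired_vec <- function(y_aff, y_una, f_aff, f_una, phi,
                           with_group = TRUE, max_sweeps = 40L,
                           tol = 1e-8) {
  G <- nrow(y_aff)
  P <- ncol(y_aff)
  fa <- matrix(f_aff, G, P, byrow = TRUE)
  fu <- matrix(f_una, G, P, byrow = TRUE)
  lq <- log((y_aff + y_una + 0.1) / (fa + fu))
  b <- numeric(G)
  last_step <- rep(Inf, G)
  for (sw in seq_len(max_sweeps)) {
    E <- exp(pmin(pmax(lq, -30), 30))
    mu_a <- E * exp(b) * fa
    mu_u <- E * fu
    da <- 1 + phi * mu_a
    du <- 1 + phi * mu_u
    score_q <- (y_aff - mu_a) / da + (y_una - mu_u) / du
    info_q <- mu_a / da + mu_u / du
    step_q <- pmin(pmax(score_q / pmax(info_q, 1e-10), -5), 5)
    lq <- pmin(pmax(lq + step_q, -30), 30)
    max_step <- apply(abs(step_q), 1, max)
    if (with_group) {
      E <- exp(lq)
      mu_a <- E * exp(b) * fa
      da <- 1 + phi * mu_a
      score_b <- rowSums((y_aff - mu_a) / da)
      info_b <- rowSums(mu_a / da)
      step_b <- pmin(pmax(score_b / pmax(info_b, 1e-10), -5), 5)
      b <- pmin(pmax(b + step_b, -20), 20)
      max_step <- pmax(max_step, abs(step_b))
    }
    last_step <- max_step
    if (max(max_step) < tol) break
  }
  E <- exp(lq)
  mu_a <- E * exp(b) * fa
  mu_u <- E * fu
  w_a <- mu_a / (1 + phi * mu_a)
  w_u <- mu_u / (1 + phi * mu_u)
  info_q <- w_a + w_u
  ll <- rowSums(nb_logpmf_vecphi(y_aff, mu_a, phi)) +
    rowSums(nb_logpmf_vecphi(y_una, mu_u, phi))
  # Cox-Reid: 0.5 log det of the information in (b, lq_1..lq_P)
  cr <- 0.5 * rowSums(log(pmax(info_q, 1e-8)))
  if (with_group) {
    info_b_adj <- rowSums(w_a) - rowSums(w_a^2 / pmax(info_q, 1e-10))
    cr <- cr + 0.5 * log(pmax(info_b_adj, 1e-8))
  }
  list(b = b, lq = lq, ll = ll, cr = cr,
       converged = last_step < 1e-4)
}

# Align the columns of a count matrix to a pair table.
paired_columns <- function(cm, pairs) {
  ai <- match(pairs$affected, cm$sample_ids)
  ui <- match(pairs$unaffected, cm$sample_ids)
  if (anyNA(ai) || anyNA(ui)) {
    cdeg_stop("unpaired sample in paired design", "cdeg_design_error")
  }
  extra <- setdiff(cm$sample_ids, c(pairs$affected, pairs$unaffected))
  if (length(extra)) {
    cdeg_stop(sprintf("sample(s) without a pair: %s",
                      paste(extra, collapse = ", ")), "cdeg_design_error")
  }
  list(aff = ai, una = ui)
}

# Per-transcript APL under the paired design.
apl_paired <- function(y, f, idx, phi) {
  fit <- fit_paired_vec(y[, idx$aff, drop = FALSE],
                        y[, idx$una, drop = FALSE],
                        f[idx$aff], f[idx$una], phi)
  fit$ll - fit$cr
}

# Quadratic interpolation of the maximum on a log-phi grid.
interp_max <- function(lphi, v) {
  j <- which.max(v)
  if (j == 1L || j == length(v)) return(lphi[j])
  x1 <- lphi[j - 1]; x2 <- lphi[j]; x3 <- lphi[j + 1]
  v1 <- v[j - 1]; v2 <- v[j]; v3 <- v[j + 1]
  denom <- (x2 - x1) * (v2 - v3) - (x2 - x3) * (v2 - v1)
  if (abs(denom) < 1e-12) return(x2)
  xhat <- x2 - 0.5 * ((x2 - x1)^2 * (v2 - v3) - (x2 - x3)^2 * (v2 - v1)) / denom
  min(max(xhat, x1), x3)
}

default_phi_grid <- function() {
  c(1e-4, exp(seq(log(0.003), log(3), length.out = 14)))
}

#' Estimate NB dispersion
#'
#' Fits a common dispersion by maximizing the Cox-Reid adjusted profile
#' likelihood pooled over transcripts on a log-spaced grid (with quadratic
#' interpolation of the maximum), and tagwise dispersions as a
#' residual-df-weighted combination of per-transcript maxima with the common
#' value: `phi_g = (d * phi_g_raw + prior_df * phi_0) / (d + prior_df)`.
#' With `prior_df = Inf` the tagwise values equal the common one.
#'
#' @param cm A [count_matrix()].
#' @param groups Per-sample group labels (two groups, each with at least two
#'   samples).
#' @param norm A `norm_factors` object (effective size factors).
#' @param pairs Optional pair table (see [pairwise_fold_change()]); when
#'   given, the APL is computed under the paired design.
#' @param prior_df Prior degrees of freedom for tagwise shrinkage.
#' @param tagwise Compute tagwise dispersions (set `FALSE` for a cheap
#'   common-only estimate).
#' @param grid Optional dispersion grid.
#' @return A `dispersion_model` list with `common`, `tagwise` (named vector)
#'   and `prior_df`.
#' @export
estimate_dispersion <- function(cm, groups, norm, pairs = NULL,
                                prior_df = 10, tagwise = TRUE, grid = NULL) {
  y <- cm$counts
  groups <- check_two_groups(groups, ncol(y))
  if (any(table(groups) < 2L)) {
    cdeg_stop("dispersion is unidentifiable with a single sample per group",
              "cdeg_design_error")
  }
  f <- norm$factors[cm$sample_ids]
  phis <- grid %||% default_phi_grid()
  lphi <- log(phis)
  G <- nrow(y)

  if (is.null(pairs)) {
    n_par <- 2L
    apl_mat <- vapply(phis, function(phi) apl_unpaired(y, f, groups, phi),
                      numeric(G))
  } else {
    idx <- paired_columns(cm, pairs)
    n_par <- length(idx$aff) + 1L
    apl_mat <- vapply(phis, function(phi) apl_paired(y, f, idx, phi),
                      numeric(G))
  }

  common <- exp(interp_max(lphi, colSums(apl_mat)))
  if (common < 2e-4) common <- 0

  tw <- NULL
  if (tagwise) {
    raw <- numeric(G)
    for (g in seq_len(G)) raw[g] <- exp(interp_max(lphi, apl_mat[g, ]))
    raw[raw < 2e-4] <- 0
    d <- ncol(y) - n_par
    if (is.infinite(prior_df)) {
      tw <- rep(common, G)
    } else {
      tw <- (d * raw + prior_df * common) / (d + prior_df)
    }
    names(tw) <- cm$transcript_ids
  }
  structure(list(common = common, tagwise = tw, prior_df = prior_df,
                 design = if (is.null(pairs)) "unpaired" else "paired"),
            class = "dispersion_model")
}

# Tagwise dispersions if present, else the common value recycled.
disp_per_transcript <- function(disp, ids) {
  if (!is.null(disp$tagwise)) {
    out <- disp$tagwise[ids]
    out[is.na(out)] <- disp$common
    unname(out)
  } else {
    rep(disp$common, length(ids))
  }
}
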