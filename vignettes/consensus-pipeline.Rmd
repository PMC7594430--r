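---
title: "Consensus differential expression and twin discordance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression and twin discordance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(consensusDEG)
```

This vignette is the package's own account of its statistical machinery:
the count model, the six-method battery and its calibration, the consensus
and cross-cohort layers, the twin discordance analysis, what the synthetic
cohorts do and do not emulate, and the numerical choices that matter.

## The count model

All tests work on a transcript-by-sample matrix of read counts. Counts for
transcript $g$ in sample $s$ are modelled as negative binomial,

$$ y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi), \qquad
   \mathrm{Var}(y_{gs}) = \mu_{gs} + \phi\,\mu_{gs}^2, $$

with $\mu_{gs} = q_{g(\text{group})} \, f_s$, where $f_s$ is a per-sample
*effective size factor*. Unlike the depth-free convention used by some
count packages, factors here absorb sequencing depth as well as
composition bias: a library with exactly twice the reads of another gets
about twice its factor. This makes the factors directly usable as GLM
offsets and as divisors when forming depth-equalized pseudo-counts, and
`run_pipeline()` treats them uniformly across methods. Factors are
rescaled to geometric mean one, so only their ratios matter.

Analysis is deliberately at transcript (isoform) resolution. Aggregating
to gene level can cancel or dilute changes restricted to one splice
variant; gene symbols are carried only for the cross-cohort match.

## Expression metrics and the prevalence filter

RPKM divides each count by transcript length in kilobases and by the
sample's total informative reads in millions; "informative reads" are the
column sums of the supplied matrix, since everything upstream of the count
matrix (alignment, read filtering) is outside this package's scope. A
transcript is *detected* in a sample when its RPKM strictly exceeds
`rpkm_tau` (default 0.01), and it is kept when the detected fraction
reaches `prevalence_phi` (default 0.70) in at least one diagnostic group.
The fraction comparison is made on integer sample counts
(`n_present >= ceiling(phi * n)` with a guard against floating-point
`0.7 * n` artifacts), and "at least phi" is used because the inclusive
reading is the natural one for a fraction-of-samples rule; the comparison
is exposed through `phi` so a strict variant costs one argument.

The DE battery always runs on this filtered working universe, exactly as
the pipeline's analytical funnel prescribes (filter, then the battery,
then consensus). This matters for calibration: on all-zero or trace-level
transcripts, a log-CPM t statistic responds to library-size structure
rather than biology — the artifact expression filters exist to remove.

## The six-method battery

The battery spans five families of analysis; a run's method count *M* is
configuration, not a constant, and the consensus layer is method-agnostic.

**Conditional NB exact test** (`exact_tmm`, `exact_deges`). Counts are
divided by the effective size factors, rounded, and summed within groups.
Conditional on the total $t = s_1 + s_2$, the probability of each split
$k$ is proportional to the product of two NB masses with sizes
$n_i/\phi$; the two-sided p is the conditional mass of all outcomes no
more probable than the observed split. For supports wider than ~4000
outcomes the (log-concave) conditional pmf is accumulated on a
stride-aligned grid passing through the observed value; against full
enumeration the relative error measured at supports of ~30,000 outcomes
is about 0.3%, and the test suite asserts 1%.

**NB GLM likelihood-ratio test** (`glm_lrt`). A log-link NB regression
with fixed tagwise dispersion, design intercept + group, plus pair
indicator columns in the twin cohort. The unpaired fit reduces to
per-group Newton updates on the log-mean and is fully vectorized. The
paired fit exploits the arrow structure of the design: alternating Newton
steps on the per-pair log-means and the shared group coefficient, with a
closed Schur-complement form for the information determinant. The p-value
is $\chi^2_1$ on twice the log-likelihood difference from dropping the
group term; transcripts whose fit does not converge are reported
conservatively with p = 1.

**NB Wald test** (`wald_mor`). The same unpaired GLM, with the group
coefficient divided by its Fisher standard error and referred to the
standard normal, under median-of-ratios factors. No independent filtering
and no fold-change shrinkage are applied.

**Moderated t on log2-CPM** (`mod_t`). Counts become
$\log_2((y + 0.5)/(\mathrm{lib} + 1) \times 10^6)$; a lowess trend of
$\sqrt{s_g}$ against average log count supplies per-observation precision
weights (weights $1/\text{trend}^4$); each transcript is fitted by
weighted least squares; and residual variances are squeezed,
$s^2_{\text{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with $(d_0, s_0^2)$
fitted by moment-matching a scaled F distribution to the observed
variances on the log scale (trigamma inversion). The paired variant is a
one-sample moderated t on within-pair differences; per-transcript scalar
weights cannot change a one-sample t, so the trend is not applied there.
Setting the prior to $d_0 = 0$ recovers the ordinary t-test exactly,
which the test suite uses as a limit oracle.

**Dirichlet Monte-Carlo CLR test** (`clr_mc`). Counts plus a 0.5 prior
parameterize per-sample Dirichlet distributions; each of `n_mc` (default
128) instances draws a composition, applies the centered log-ratio
transform, and runs a Welch t per transcript; the reported p is the mean
over instances. Averaging p-values makes the test conservative by
construction — it never reaches the nominal type-I rate, and the
acceptance suite holds it only to the upper bound.

**Dispersion.** The common $\phi_0$ maximizes the Cox–Reid adjusted
profile likelihood summed over transcripts, evaluated on a 15-point
log-spaced grid in $[10^{-4}, 3]$ with quadratic interpolation of the
maximum; per-transcript maxima from the same grid are shrunk toward
$\phi_0$ with a prior weight of 10 residual-df equivalents (tagwise
$\phi_g = (d\,\hat\phi_g + d_0\,\phi_0)/(d + d_0)$, so `prior_df = Inf`
collapses tagwise onto common). Crucially, the APL uses the *same design*
as the downstream test, including pair indicators: estimating dispersion
under a group-only model on twin data absorbs the shared pair effect into
$\phi$ and would make the paired likelihood-ratio test conservative while
leaving its nuisance-parameter bias uncorrected. The paired APL on 2000
transcripts recovers a true $\phi = 0.2$ within a few percent where the
unpaired estimate is visibly inflated (a unit test pins this contrast).

**DEGES** (`exact_deges` normalization). Single-pass TMM fails under
heavily one-sided differential expression: with ~30% of transcripts
shifted in one group, the symmetric rank trim lands asymmetrically inside
the null M-value cluster and biases factors group-wise. DEGES iterates
(default 3 rounds): normalize, run the inner exact test with a common
dispersion, drop the top 30% of transcripts by raw p, renormalize on the
remainder. Under 30% one-sided spikes it beats single-pass TMM on maximum
relative factor error in 10 of 10 acceptance seeds.

## Consensus, cross-cohort and discordance layers

Each method's table is ranked by BH-adjusted p (raw p by configuration),
ties broken by raw p then lexicographic id so the cut at `top_k`
(default 100) is deterministic. The consensus table counts appearances
across the *M* lists, sorts by count, then best adjusted p, then id, and
reports per-method membership flags; Jaccard similarity between lists
summarizes method concordance.

The triple filter requires, jointly: group-mean RPKM ratio above `fc_min`
(1.5) or below its reciprocal; raw p below `p_max` (0.01, uncorrected)
from a Welch t on log2 RPKM (unpaired) or a one-sample t on per-pair log2
fold changes (twins) — the filter's test statistic is a deliberate,
assumption-light choice logged in the run report; and prevalence at
`rpkm_tau`. Passing symbols from the two cohorts are intersected,
opposite-direction symbols excluded, and the overlap size referred to a
hypergeometric tail $P(X \ge k)$ — the one-sided enrichment form of
Fisher's exact test. The universe $N$ must be supplied explicitly;
`run_pipeline()` uses the count of gene symbols present in both cohorts'
filtered universes and records it in the report, because an unstated
universe makes an overlap p-value uninterpretable.

For the twin cohort, each pair's discrepancy score is the absolute
within-pair difference of parent-rated ADHD-RS raw scores (inattention,
hyperactivity-impulsivity, total; subscales live on 0–27). Ranks put the
most discrepant pair at 1, ties sharing the average rank. A fourth,
clinician-consensus ranking cannot be computed from data and is only ever
accepted as an input column. Per-transcript correlations between per-pair
log2 fold changes (affected over unaffected) and the rank are reported for
both signs; the flag fires at $r \le -0.4$, the inverse pattern in which
the most discordant pairs show the largest expression change. Pearson on
(fold change, rank) is the default and Spearman is offered because ranks
are ordinal; with 16 pairs the two differ little.

Discordance *eligibility* is a separate rule set: a raw-score separation
of at least 3 with the lower twin below a diagnostic threshold, a T-score
difference of at least 10, or a treated/untreated asymmetry. The
raw-score threshold for "below diagnostic threshold" is instrument- and
site-dependent; the default of 12 is exposed as configuration rather than
hard-coded.

## The synthetic cohorts

The generator emulates the statistical structure the analysis assumes —
nothing more:

* baseline means log-uniform over $2^{-4}$–$2^{11}$ expected counts
  (15 log2 orders, the dynamic range contract; most transcripts at trace
  abundance, as in ribo-depleted whole blood);
* NB noise at a single configurable dispersion (default 0.2, a typical
  bulk-RNA biological CV; the source data publish no dispersion
  estimates, so the default is chosen for testability, not fidelity);
* library sizes log-uniform over 0.5–2 to exercise normalization;
* a spiked-DE fraction with configurable |log2FC| range, sign-balanced,
  optionally restricted to baselines above a floor;
* for twins, a per-(pair, transcript) log-normal effect shared by both
  members (sd 0.15 on the natural-log scale by default — a modest shared
  component that leaves the unpaired battery members testable on twin
  data; raise it to make pairing decisive, as the paired-power test
  does). A single scalar per pair would be indistinguishable from a
  library-size shift and would induce no transcript-level pair
  correlation, so it is not what the generator produces;
* integer ADHD-RS raw scores with the affected twin scoring higher and
  T scores drawn at the study population's means (62 ± 9 vs 47 ± 6.8);
* optional coupling: for designated transcripts the per-pair log2 fold
  change is $1.5\,(\rho z_p + \sqrt{1-\rho^2}\,\varepsilon_{gp})$, with
  $z_p$ the standardized total-score discrepancy. The amplitude 1.5
  mirrors the multi-fold per-pair swings reported for severity-coupled
  transcripts; coupled transcripts are drawn among baselines ≥ 50 so the
  fold change is measurable at realistic depths. A brute-force
  Monte-Carlo of this generative model, coded independently in the test
  suite, pins the realized Spearman correlation the package recovers.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: cell-type composition shifts
in whole blood, batch and RNA-quality effects, gene–gene correlation,
length-dependent coverage bias, isoform-level mapping ambiguity, and any
fidelity to a particular published cohort's dispersions.

## Numerical choices and problem sizes

* Pseudocount 0.25 on the mean scale for all expression ratios (zero
  handling is otherwise undefined); 0.5 on counts for log-CPM and the
  Dirichlet prior.
* IRLS/Newton: relative log-likelihood tolerance $10^{-8}$, at most
  50 iterations (40 sweeps for the alternating paired fit); steps clamped
  to ±5 on the log scale, linear predictors to ±30; non-converged fits
  flagged and reported at p = 1.
* TMM trims 30% of M-values per tail and 5% of A-values, with
  delta-method weights — the canonical fractions. Median-of-ratios takes
  the median on the log scale (geometric interpolation at even counts).
* Ties everywhere break by raw p then lexicographic transcript id;
  top-100 cuts will hit ties and must be reproducible.
* All randomness flows from a single run seed through fixed offsets;
  `run_pipeline()` is byte-identical across invocations, which the
  acceptance suite checks by hashing every output file.
* Calibration checks run at the study's group sizes (23 + 21; 16 pairs)
  on 2000-transcript cohorts over 10 seeds; consensus recovery at 5000
  transcripts with 50 strong spikes over 3 seeds; coupling recovery at
  200 seeds of 200-transcript twin cohorts. These sizes give Monte-Carlo
  standard errors comfortably inside the asserted bands while keeping a
  full run in minutes on one CPU.

## Known limitations

The battery's six statistics are simplified re-derivations of the ideas
behind the field's standard packages, not numerical replicas; tests pin
them to limits and reference implementations where exact agreement is
well-defined (Poisson-limit GLM, ordinary-t limit, TMM/median-of-ratios
cross-checks, voom rank agreement) and to calibration bands elsewhere. An
empirical-Bayes posterior ranking method (the battery's most discordant
relative in the source analysis) is not implemented; the consensus layer
accepts any method that emits per-transcript p-values. The moderated t, like any
normal-theory statistic applied to count data, carries a slightly heavy
far tail, so its empirical false-discovery rate on spiked simulations runs
somewhat above the nominal BH level (the acceptance report computes the
number). The overlap test
treats gene symbols as exchangeable, ignoring expression-dependent
selection; and the discordance correlation with 16 pairs has wide
sampling bands — at $|r| \ge 0.4$ roughly 6% of null transcripts flag,
which is why the pipeline reports correlations for the filtered universe
rather than claiming per-transcript significance.
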