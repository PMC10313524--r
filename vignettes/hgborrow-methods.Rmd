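---
title: "Methods: dynamic borrowing and pharmacodynamic analysis for perioperative 2-HG trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic borrowing and pharmacodynamic analysis for perioperative 2-HG trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgborrow)
```

## The scientific setting

Perioperative ("window-of-opportunity") trials of mutant-IDH1 inhibitors in
low-grade glioma give a drug for about four weeks before a planned resection
and assay the resected tumor tissue.  The primary pharmacodynamic endpoint is
the tumor concentration of d-2-hydroxyglutarate (2-HG), the oncometabolite
produced by the mutant enzyme: effective target inhibition suppresses tumor
2-HG by roughly an order of magnitude.  Because only a handful of enrolled
patients can ethically be randomized to no pre-surgical treatment, the
untreated comparison pools two control sources: the few concurrent untreated
patients and a larger bank of archival untreated mIDH1 tumor samples.  The
statistical question is how much to *borrow* from the external bank, given
that archival samples may differ systematically from concurrent controls.

`hgborrow` implements the full analysis chain for such a trial — the Bayesian
hierarchical borrowing model for 2-HG suppression, the design's
operating-characteristics simulation, RANO-LGG response classification with
exact binomial ORR intervals, and the pharmacodynamic association /
enrichment machinery — driven by a synthetic-cohort generator so every stage
runs without patient-level data.

## The borrowing model

All modelling is on $y = \log_{10}$(tumor 2-HG, µg/g).  For groups $g$
(treated dose arms, concurrent controls, external controls):

$$y_{gj} \mid \theta_g, \sigma^2_g \sim N(\theta_g, \sigma^2_g)$$

Treated arm means get a flat prior $\theta_t \sim N(m_0, v_0)$.  The two
control-source means are exchangeable around a control hypermean,

$$\theta_c \mid \mu_c, \tau^2 \sim N(\mu_c, \tau^2), \qquad
  \mu_c \sim N(m_0, v_0), \qquad \tau^2 \sim \mathrm{InvGamma}(a_\tau, b_\tau),$$

and each observation variance has $\sigma^2_g \sim \mathrm{InvGamma}(a_\sigma,
b_\sigma)$.  The *commensurability variance* $\tau^2$ governs borrowing:
when the two control sources agree, its posterior concentrates near zero and
the external bank informs $\mu_c$ almost as strongly as concurrent controls;
when they disagree, $\tau^2$ inflates and the external data are discounted.
Per-group observation variances are kept separate because the observed
per-arm dispersions differ by an order of magnitude.

Every full conditional is conjugate (normal for the means, inverse-gamma for
the variances), so the model is fitted with a plain Gibbs sampler
(`fit_borrowing_model()`), 4 chains × 10,000 iterations with 2,000 burn-in by
default, overdispersed data-based initialization with seeded jitter, and
deterministic output given the seed.  Convergence is monitored with
split-chain $\widehat R$ and autocovariance-based effective sample size
(`diagnostics()`).

The treatment effect for arm $t$ is computed per retained draw as the percent
reduction relative to the combined untreated control level,

$$R_t = 100\,(1 - 10^{\,\theta_t - \mu_c}),$$

and summarized by its posterior mean and equal-tail 95% credible interval
(`summarize_reduction()`).  Summarizing the per-draw transform, rather than
transforming a posterior summary of $\theta_t - \mu_c$, matters: $R_t$ is
skewed, so its posterior mean sits below the point transform of the mean
contrast.

### Prior choices, and why the commensurability prior is informative

Location priors default to $N(0, 10^6)$ and observation-variance priors to
$\mathrm{InvGamma}(0.001, 0.001)$; with $n_g \ge 5$ per group these are
effectively noninformative.

The $\tau^2$ prior is deliberately *not* vague.  With only $K = 2$ control
sources $\tau^2$ is weakly identified, and the classical
$\mathrm{InvGamma}(\varepsilon, \varepsilon)$ choice leaves a
near-scale-invariant tail: the chain then makes excursions in which $\tau^2$
explodes, $\mu_c$ decouples from the controls (its conditional precision
$2/\tau^2 + 1/v_0$ collapses to the flat prior), the control-source
discrepancy $d^2 = \sum_c (\theta_c - \mu_c)^2$ inflates, and the next
$\tau^2$ draw — $\mathrm{InvGamma}(a_\tau + 1, b_\tau + d^2/2)$, with mean
$\approx d^2/(2 a_\tau)$ — amplifies the excursion whenever $a_\tau < 1$.
Because $R_t$ is a $10^{x}$ transform, even a handful of wandering $\mu_c$
draws produce reduction draws around $-10^6$ and destroy the posterior mean.

The default is $\mathrm{InvGamma}(2, 0.1)$: prior mean $0.1$ on the squared
log10 scale, i.e. $\tau \approx 0.3$, about a two-fold concentration discord
between control sources, with $P(\tau^2 > 1) \approx 5\times10^{-5}$.  A
ten-fold *systematic* difference between two sets of untreated mIDH1 tumors
is scientifically implausible, and that is exactly the information this prior
encodes.  Borrowing remains dynamic — the posterior rate $b_\tau + d^2/2$
tracks the observed discord.  Because any single choice is debatable with
$K = 2$, `sweep_tau_prior()` refits over a hyperparameter grid so the
sensitivity is visible rather than hidden.

### Numerical choices

- The exponent in $10^{\theta_t - \mu_c}$ is clamped at $\pm 300$ (with a
  warning) so pathological draws cannot overflow to infinity.
- Known-variance analyses are supported by fixing selected $\sigma^2_g$
  (`model_config(fix_sigma2 = ...)`); this is also how the sampler is checked
  against conjugate closed forms in the tests.
- Sample variances used for initialization are floored at $10^{-4}$ so
  degenerate groups cannot produce zero-variance starting points.
- The external IDH wild-type bank is excluded from the model (descriptive
  only): the endpoint contrasts treated versus untreated mIDH1 tumors, and
  wild-type tumors carry no mutant-enzyme 2-HG signal.

## The synthetic-cohort generator

The generator (`simulate_cohort()` and friends) emulates the study
conditions: evaluable arm sizes 11/7/10/7 for the four dose arms, 5
concurrent untreated controls, 61 banked external mIDH1 samples (plus a
wild-type bank used descriptively), with per-arm 2-HG drawn from base-10
lognormals *moment-matched* to the published arithmetic means and standard
deviations (8.9/4.1, 67.5/65.4, 20.9/30.7, 16.8/18.1 µg/g for the treated
arms; 154.9/146.9 internal; 276.8/231.4 external).  Moment matching
(`moment_match_lognormal()`) solves

$$\mathrm{scale}^2 = \frac{\ln(1 + sd^2/mean^2)}{\ln^2 10}, \qquad
  \mathrm{location} = \log_{10}(mean) - \frac{\ln 10}{2}\,\mathrm{scale}^2,$$

so the printed arithmetic summaries are reproduced in expectation on the
concentration scale while the model sees its assumed log10-normal data.  The
data-generating link between the published summaries and the log-scale model
is a package choice: the trial never states one.

Biomarkers (Ki-67, CD3⁺/CD8⁺ densities, 5hmC percent) are linear in log10
2-HG with Gaussian noise truncated at zero — truncation, rather than
redrawing, is documented and configurable.  The 5hmC coupling is negative
(DNA hydroxymethylation rises when 2-HG falls, as TET enzymes are
de-repressed), and 5hmC is stored as nucleoside counts so
`compute_5hmc_percent()` recovers it.  The expression generator plants a
signature of genes linear in the z-scored covariate (half up-, half
down-coupled) on a log2 scale and exponentiates, and SPD lesion series follow
per-visit multiplicative drift with lognormal noise and a configurable
complete-resection fraction.  Exclusion flags are independent Bernoulli
draws; the trial reports only realized counts, so flag probabilities default
to zero and flagged rosters are constructed explicitly where needed.

What the generator does *not* emulate: negative-binomial sequencing counts
(the expression model is lognormal), informative missingness, correlated
biomarker noise, measurement error in cellularity, or non-lognormal 2-HG
shapes.  Passing tests therefore demonstrate that the analysis machinery is
correct under its own assumptions, not that those assumptions hold in real
tumors.

## Evaluability and derived quantities

`eligibility_filter()` excludes treated subjects for insufficient tissue,
unconfirmed mIDH1, incorrect pre-surgery dosing, or two or more missed doses
in the final two weeks; untreated subjects only for the first two reasons.
Reasons are recorded with a fixed precedence (tissue → confirmation → dosing
→ missed doses) so a doubly-flagged subject is counted once,
deterministically.  Missing numeric cells are a distinct absent state (`NA`),
never zero and never imputed.  Normalized 2-HG divides the bulk concentration
by the tumor-cell fraction — the simplest cellularity correction consistent
with its purpose; 5hmC percent uses the unmodified-cytosine denominator, with
the denominator explicit in the call so a total-cytosine convention is one
argument away.

## Operating characteristics

`operating_characteristics()` reruns the whole design — generate a cohort
under a stated truth, fit the borrowing model, declare detection when
$\Pr(\theta_t < \mu_c \mid \text{data}) > p^\*$ — across replicates and
aggregates detection rate, bias, credible-interval coverage and width.  The
detection rule with $p^\* = 0.975$ is this package's definition; the original
design states the detection event but not its rule.  Replicate seeds are
`base_seed + replicate`, recorded in the output.  The implied true reduction
of a truth table takes the unweighted mean of the two control-source log10
locations as the true combined control level, matching the model's
exchangeability assumption; design sweeps in the tests use concordant
sources, where no ambiguity arises.  The published "approximately 94%
probability of detection" arises from unreported generative assumptions, so
it is checked qualitatively (high power at the published summaries) rather
than numerically.

## Response evaluation

`classify_best_response()` implements RANO-LGG categories from SPD (sum of
products of perpendicular lesion diameters) series: CR = confirmed
disappearance, PR ≤ −50%, minor response in (−50%, −25%], each requiring the
same threshold to be met again at the immediately next scan (56-day cadence
by default); PD = ≥ +25% over the nadir (smallest SPD so far, baseline
included; once the nadir is zero any regrowth is progression); SD otherwise.
An unconfirmed qualifying decrease is SD.  Subjects resected to no measurable
disease are SD unless measurable disease appears, which this package treats
as progression.  Responses qualify only before the first progression event.
Note one geometric consequence of the thresholds: after a one-scan decrease
deeper than −50%, any next scan either confirms at least a minor response
(≤ −25%) or lies ≥ +25% above the nadir, so "deep but unconfirmed decrease
ending in SD" occurs when the qualifying scan is the last one available.

`orr()` counts CR/PR/mR responders and attaches the exact Clopper–Pearson
interval (Beta-quantile inversion of the binomial tails); this interval type
reproduces all four published ORR intervals exactly, which is why it is the
default.  Printed-value comparisons round half away from zero to one decimal
(`round_half_up()`), matching publication convention.

## Pharmacodynamic associations and enrichment

Biomarker–2-HG associations use simple linear regression
(`simple_linear_regression()`, two-sided slope t-test) and pooled-variance
two-sample t-tests (`two_group_ttest()`).  `per_gene_association()` regresses
log2 expression on the z-scored (population-n) covariate gene by gene — a
deliberately simple association engine for exercising the downstream ranking
and enrichment machinery, not a count-model differential-expression method —
then applies Benjamini–Hochberg adjustment and attaches the signed ranking
statistic

$$\mathrm{rank} = -\log_{10}(p_{\text{unadjusted}}) \times
  \mathrm{sign}(\log_2 \mathrm{FC}),$$

with $p = 0$ clamped to the smallest representable double (configurable) and
a warning.  `preranked_gsea()` computes the weighted Kolmogorov–Smirnov
running-sum enrichment score with weight $|\mathrm{rank}|^1$, a seeded
gene-sampling permutation null, NES as ES over the mean magnitude of
same-sign null scores, permutation p-values with +1 continuity, BH adjustment
across retained sets, and set-size bounds of 15–500 after intersection with
the ranked list.  `top_split_clusters()` z-scores gene rows, clusters samples
by complete-linkage on Euclidean distance, cuts the dendrogram at the root
into two groups, and compares a per-sample variable between them with the
pooled t-test.

One invariant worth stating because it is commonly assumed and false: BH
adjustment is *not* idempotent on arbitrary monotone vectors (re-adjusting
(0.5, 0.9, 0.9) gives (0.9, 0.9, 0.9)); the tests assert the true properties
(pointwise no smaller than the input, capped at 1, order-preserving).

## Pipeline and reproducibility

`run_pipeline()` executes simulate → filter → fit → summarize → response →
associations, with per-stage seeds derived from one global seed, writes every
stage's outputs (CSV/TSV/GMT), and returns a manifest with per-file MD5
hashes, row counts and the config hash; identical configurations give
bit-identical outputs.  Configurations round-trip through YAML
(`write_pipeline_config()` / `read_pipeline_config()`).  A failed stage
leaves a `FAILED` marker naming the stage and retains earlier outputs.

## Problem sizes used in the checks

The package's own verification uses: full-size fits (4 × 10,000 iterations)
for the headline-reduction checks, averaged over a handful of seeded
cohorts; 50-replicate operating-characteristic sweeps with short fits
(2 × 1,500) for null calibration, power monotonicity and power at the
published summaries; 200 replicates for credible-interval coverage; 40
simulation-based-calibration replicates (63 retained thinned draws each)
for rank uniformity; 10⁶-draw Monte-Carlo checks of the moment matching;
and 2,000-gene null matrices for p-value calibration.  These sizes give
binomial/Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

- The hierarchical structure is a reconstruction: the original analysis
  cites its model without equations.  The two-source commensurate structure
  here is the minimal one consistent with dynamic borrowing; whether the
  original borrowed at the observation level, pooled control variances, or
  used different hyperparameters is unknown.
- With two control sources, $\tau^2$ — and through it the borrowing
  strength and the credible-interval width — remains prior-sensitive;
  `sweep_tau_prior()` should accompany any real analysis.
- The per-gene association engine is linear-Gaussian on log expression;
  count-level dispersion, library-size normalization and covariate
  adjustment (histology, treatment status) are out of scope.
- Operating characteristics are computed under the generator's lognormal
  truth; they are not a validation of the original design's unreported
  simulation assumptions.
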