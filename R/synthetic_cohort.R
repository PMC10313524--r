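# Synthetic-cohort generator: rosters, lognormal 2-HG, coupled biomarkers,
# expression matrices with a planted 2-HG signature, and SPD lesion series.
# Defaults reproduce the trial's layout: cohort 1 randomized 2:2:1
# (IVO500 : VOR50 : untreated), cohort 2 randomized 1:1 (IVO250 : VOR10),
# evaluable arm sizes and per-arm 2-HG means/s.d.s as published.

local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}

#' Moment-match a base-10 lognormal to an arithmetic mean and s.d.
#'
#' Published arm summaries are arithmetic means and standard deviations of
#' concentrations, while the model works on log10 concentration.  This
#' returns the location and scale (both in log10 units) of the lognormal
#' whose arithmetic moments equal the inputs:
#' `scale^2 = log(1 + sd^2/mean^2) / log(10)^2` and
#' `location = log10(mean) - (log(10)/2) * scale^2`.
#'
#' @param mean Arithmetic mean, must be positive (vectorised).
#' @param sd Arithmetic standard deviation, nonnegative.
#' @return A tibble with columns `location` and `scale` (log10 units).
#' @export
moment_match_lognormal <- function(mean, sd) {
  if (any(mean <= 0)) abort("mean must be positive", class = "hg_domain_error")
  if (any(sd < 0)) abort("sd must be nonnegative", class = "hg_domain_error")
  scale2 <- log1p(sd^2 / mean^2) / log(10)^2
  tibble::tibble(
    location = log10(mean) - (log(10) / 2) * scale2,
    scale = sqrt(scale2)
  )
}

#' Per-arm generative specification
#'
#' @param arm Arm label.
#' @param n Number of subjects (or banked samples) to generate.
#' @param target_mean,target_sd Arithmetic mean and s.d. of tumor 2-HG
#'   (ug/g) the generated values should match.
#' @return A one-row tibble.
#' @export
arm_spec <- function(arm, n, target_mean, target_sd) {
  stopifnot(n >= 0, target_mean > 0, target_sd >= 0)
  tibble::tibble(arm = arm, n = as.integer(n),
                 target_mean = target_mean, target_sd = target_sd)
}

#' Default arm specifications
#'
#' Evaluable arm sizes and the published per-arm tumor 2-HG arithmetic
#' means and s.d.s (ug/g): treated arms 8.9 (4.1), 67.5 (65.4), 20.9
#' (30.7), 16.8 (18.1); concurrent untreated controls 154.9 (146.9);
#' banked external mIDH1 controls 276.8 (231.4) and IDH wild-type 3.7
#' (3.1).
#'
#' @return A tibble of arm specs with a `role` column
#'   (`treated`/`internal_control`/`external_mIDH1`/`external_WT`).
#' @export
default_arm_specs <- function() {
  dplyr::bind_rows(
    dplyr::mutate(arm_spec("VOR50", 11, 8.9, 4.1), role = "treated"),
    dplyr::mutate(arm_spec("VOR10", 7, 67.5, 65.4), role = "treated"),
    dplyr::mutate(arm_spec("IVO500", 10, 20.9, 30.7), role = "treated"),
    dplyr::mutate(arm_spec("IVO250", 7, 16.8, 18.1), role = "treated"),
    dplyr::mutate(arm_spec("UNTREATED", 5, 154.9, 146.9), role = "internal_control"),
    dplyr::mutate(arm_spec("EXT_MIDH1", 61, 276.8, 231.4), role = "external_mIDH1"),
    dplyr::mutate(arm_spec("EXT_WT", 20, 3.7, 3.1), role = "external_WT")
  )
}

#' Generator configuration
#'
#' Collects everything the synthetic-cohort generator needs: arm specs,
#' randomization ratios (cohort 1 = 2:2:1, cohort 2 = 1:1, recorded for
#' provenance; arm sizes come from the specs), linear couplings of each
#' biomarker to log10 2-HG, exclusion-flag probabilities, the expression
#' spec, and the SPD trajectory spec.
#'
#' @param arm_specs Tibble from [default_arm_specs()] or built with
#'   [arm_spec()] plus a `role` column.
#' @param ratios Named list of randomization ratios by cohort.
#' @param biomarkers Tibble with columns `biomarker`, `intercept`, `slope`,
#'   `noise_sd`: each biomarker is `intercept + slope * log10(2-HG) +
#'   N(0, noise_sd^2)`, truncated at 0.  5hmC couples negatively (it rises
#'   as 2-HG falls).
#' @param exclusion_probs Named list of per-subject flag probabilities
#'   (`insufficient_tissue`, `midh1_not_confirmed`, `incorrect_dosing`,
#'   `missed_doses`).  Defaults are 0 so the default roster is fully
#'   evaluable.
#' @param expression List: `n_genes`, `n_signature`, `effect` (log2 units
#'   per s.d. of the covariate), `noise_sd` (log2 units), `base_mean`
#'   (log2 units).
#' @param spd List: `visits`, `visit_spacing_days`, `baseline_mean_cm2`,
#'   `drift` (per-visit multiplicative change, e.g. -0.1 for -10%/visit),
#'   `noise_sd` (log-scale s.d. per visit), `no_residual_fraction`.
#' @return A list of class `hg_generator_config`.
#' @export
generator_config <- function(
    arm_specs = default_arm_specs(),
    ratios = list(cohort1 = c(IVO500 = 2, VOR50 = 2, UNTREATED = 1),
                  cohort2 = c(IVO250 = 1, VOR10 = 1)),
    biomarkers = default_biomarker_couplings(),
    exclusion_probs = list(insufficient_tissue = 0, midh1_not_confirmed = 0,
                           incorrect_dosing = 0, missed_doses = 0),
    expression = list(n_genes = 2000, n_signature = 50, effect = 1,
                      noise_sd = 1, base_mean = 6),
    spd = list(visits = 6, visit_spacing_days = 56, baseline_mean_cm2 = 12,
               drift = -0.05, noise_sd = 0.05, no_residual_fraction = 0.25)) {
  stopifnot(all(unlist(ratios) > 0), all(biomarkers$noise_sd >= 0),
            expression$n_signature <= expression$n_genes)
  structure(
    list(arm_specs = arm_specs, ratios = ratios, biomarkers = biomarkers,
         exclusion_probs = exclusion_probs, expression = expression, spd = spd),
    class = "hg_generator_config"
  )
}

#' Default biomarker-to-2-HG couplings
#'
#' Linear couplings on log10 2-HG chosen to mirror the direction and rough
#' magnitude of the observed pharmacodynamic associations: proliferation
#' (Ki-67) and T-cell densities fall as 2-HG falls only weakly, while DNA
#' hydroxymethylation (5hmC percent) rises as 2-HG falls (negative slope).
#'
#' @return Tibble with `biomarker`, `intercept`, `slope`, `noise_sd`.
#' @export
default_biomarker_couplings <- function() {
  tibble::tribble(
    ~biomarker,    ~intercept, ~slope, ~noise_sd,
    "ki67_pct",     2,          3,      2,
    "hmc5_pct",     1.2,       -0.35,   0.15,
    "cd3_density",  50,         80,     40,
    "cd8_density",  20,         30,     15
  )
}

#' Simulate a synthetic trial cohort
#'
#' Generates subject rosters for all arms and the banked external-control
#' table.  Tumor 2-HG is drawn from the base-10 lognormal moment-matched
#' to each arm's target mean/s.d.; biomarkers are coupled linearly to
#' log10 2-HG via [simulate_biomarkers()]; evaluability flags are
#' independent Bernoulli draws at the configured rates.  Identical seeds
#' give identical output.
#'
#' @param config An [generator_config()] object.
#' @param seed Integer seed.
#' @return List with `subjects` (tibble per [cohort_schema()]) and
#'   `externals` (tibble of banked samples).
#' @export
simulate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "hg_generator_config"))
  local_seed(seed)
  specs <- config$arm_specs
  trial <- specs[specs$role %in% c("treated", "internal_control"), , drop = FALSE]
  ext <- specs[startsWith(specs$role, "external"), , drop = FALSE]

  subjects <- purrr::pmap_dfr(trial, function(arm, n, target_mean, target_sd, role) {
    if (n == 0) return(NULL)
    lp <- moment_match_lognormal(target_mean, target_sd)
    hg <- 10^rnorm(n, lp$location, lp$scale)
    treated <- role == "treated"
    ep <- config$exclusion_probs
    tibble::tibble(
      subject_id = sprintf("%s-%02d", arm, seq_len(n)),
      cohort = if (arm %in% c("VOR10", "IVO250")) 2L else 1L,
      arm = arm,
      treated_presurgery = treated,
      missed_doses_2wk = if (treated) {
        ifelse(rbinom(n, 1, ep$missed_doses) == 1, 2L, 0L)
      } else 0L,
      midh1_confirmed = rbinom(n, 1, ep$midh1_not_confirmed) == 0,
      tissue_sufficient = rbinom(n, 1, ep$insufficient_tissue) == 0,
      dosing_correct = if (treated) rbinom(n, 1, ep$incorrect_dosing) == 0 else TRUE,
      tumor_2hg = hg,
      cellularity = pmin(1, pmax(0.05, rnorm(n, 0.6, 0.15)))
    )
  })
  bm <- simulate_biomarkers(log10(subjects$tumor_2hg), config)
  subjects <- dplyr::bind_cols(subjects, bm)
  subjects <- subjects[names(cohort_schema())]

  externals <- purrr::pmap_dfr(ext, function(arm, n, target_mean, target_sd, role) {
    if (n == 0) return(NULL)
    lp <- moment_match_lognormal(target_mean, target_sd)
    tibble::tibble(
      sample_id = sprintf("%s-%02d", arm, seq_len(n)),
      idh_status = if (role == "external_WT") "WT" else "mIDH1",
      tumor_2hg = 10^rnorm(n, lp$location, lp$scale)
    )
  })
  list(subjects = subjects, externals = externals)
}

#' Simulate biomarkers coupled to log10 2-HG
#'
#' Each biomarker is `intercept + slope * log10_2hg + N(0, noise_sd^2)`,
#' truncated at zero.  The 5hmC percent (negative slope by default) is
#' converted back to nucleoside counts against a fixed unmodified-cytosine
#' denominator so that [compute_5hmc_percent()] recovers it.
#'
#' @param log10_2hg Vector of log10 2-HG values.
#' @param config An [generator_config()] object (uses `$biomarkers`).
#' @param seed Optional seed; by default draws from the current RNG
#'   stream (so [simulate_cohort()] stays single-seeded).
#' @return Tibble with `ki67_pct`, `cd3_density`, `cd8_density`, and
#'   nucleoside counts `c_5hmc`, `c_5mc`, `c_c`.
#' @export
simulate_biomarkers <- function(log10_2hg, config = generator_config(), seed = NULL) {
  local_seed(seed)
  n <- length(log10_2hg)
  cpl <- config$biomarkers
  draw <- function(name) {
    row <- cpl[cpl$biomarker == name, ]
    pmax(0, row$intercept + row$slope * log10_2hg + rnorm(n, 0, row$noise_sd))
  }
  hmc_pct <- draw("hmc5_pct")
  c_c <- rep(1e5, n)
  tibble::tibble(
    c_5hmc = hmc_pct / 100 * c_c,
    c_5mc = pmax(0, rnorm(n, 4000, 500)),
    c_c = c_c,
    ki67_pct = draw("ki67_pct"),
    cd3_density = draw("cd3_density"),
    cd8_density = draw("cd8_density")
  )
}

#' Simulate an expression matrix with a 2-HG-coupled signature
#'
#' Background genes are independent of the covariate; signature genes are
#' linear in the z-scored covariate (population-n z-score) with the
#' configured log2 effect per covariate s.d.  Values are generated on the
#' log2 scale and exponentiated, so the returned matrix is strictly
#' positive.
#'
#' @param config An [generator_config()] object (uses `$expression`).
#' @param covariate Per-sample covariate (e.g. log10 tumor 2-HG).
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples, dimnamed) and
#'   `signature_genes` (character).
#' @export
simulate_expression <- function(config = generator_config(), covariate, seed = 1) {
  local_seed(seed)
  ex <- config$expression
  n_s <- length(covariate)
  z <- zscore_pop(covariate)
  gene_ids <- sprintf("G%05d", seq_len(ex$n_genes))
  sig <- gene_ids[seq_len(ex$n_signature)]
  logmat <- matrix(rnorm(ex$n_genes * n_s, ex$base_mean, ex$noise_sd),
                   nrow = ex$n_genes,
                   dimnames = list(gene_ids, sprintf("S%03d", seq_len(n_s))))
  if (ex$n_signature > 0) {
    signs <- rep_len(c(1, -1), ex$n_signature)  # half up-, half down-coupled
    logmat[seq_len(ex$n_signature), ] <- logmat[seq_len(ex$n_signature), ] +
      (signs * ex$effect) %o% z
  }
  list(matrix = 2^logmat, signature_genes = sig)
}

zscore_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) abort("covariate is constant; cannot z-score", class = "hg_domain_error")
  (x - mean(x)) / s
}

#' Simulate post-operative SPD lesion series
#'
#' Baseline SPD (day 0) is lognormal around the configured mean except for
#' a configurable fraction of subjects with no residual disease (complete
#' resection, baseline SPD 0).  Subsequent visits follow a per-visit
#' multiplicative drift with lognormal noise at the configured spacing.
#'
#' @param config An [generator_config()] object (uses `$spd`).
#' @param subject_ids Character vector of subjects to simulate.
#' @param seed Integer seed.
#' @return Tibble `subject_id`, `day`, `spd` (day 0 = postoperative
#'   baseline); subjects with no residual disease have baseline 0.
#' @export
simulate_spd_series <- function(config = generator_config(), subject_ids, seed = 1) {
  local_seed(seed)
  sp <- config$spd
  purrr::map_dfr(subject_ids, function(id) {
    no_res <- runif(1) < sp$no_residual_fraction
    base <- if (no_res) 0 else sp$baseline_mean_cm2 * exp(rnorm(1, 0, 0.3))
    days <- c(0, seq_len(sp$visits) * sp$visit_spacing_days)
    mult <- cumprod(c(1, (1 + sp$drift) * exp(rnorm(sp$visits, 0, sp$noise_sd))))
    tibble::tibble(subject_id = id, day = days, spd = base * mult)
  })
}
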