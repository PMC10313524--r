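# Fixtures built in code: rosters, lesion series, and hand-made fit
# objects for summary-level tests.

make_test_roster <- function(n = 10, arm = "VOR50", tumor_2hg = 50,
                             cellularity = 0.6) {
  tibble::tibble(
    subject_id = sprintf("%s-%02d", arm, seq_len(n)),
    cohort = 1L,
    arm = arm,
    treated_presurgery = arm != "UNTREATED",
    missed_doses_2wk = 0L,
    midh1_confirmed = TRUE,
    tissue_sufficient = TRUE,
    dosing_correct = TRUE,
    tumor_2hg = tumor_2hg,
    cellularity = cellularity,
    c_5hmc = 1000,
    c_5mc = 4000,
    c_c = 1e5,
    ki67_pct = 5,
    cd3_density = 100,
    cd8_density = 40
  )
}

# A roster reproducing the trial's enrollment layout: 49 subjects across
# the four dose arms and the untreated controls, with exclusion flags set
# on specific subjects.
make_enrollment_roster <- function() {
  dplyr::bind_rows(
    make_test_roster(14, "VOR50", 9),
    make_test_roster(10, "VOR10", 70),
    make_test_roster(15, "IVO500", 20),
    make_test_roster(5, "IVO250", 17),
    make_test_roster(5, "UNTREATED", 150)
  )
}

make_lesions <- function(subject_id, spds, days = NULL) {
  days <- days %||% (seq_along(spds) - 1) * 56
  tibble::tibble(subject_id = subject_id, day = days, spd = spds)
}

# Minimal hg_fit with externally supplied draws for one treated arm, for
# testing the summary operations in isolation from the sampler.
make_fake_fit <- function(delta, arm = "VOR50") {
  draws <- cbind(
    `theta[VOR50]` = delta, mu_c = rep(0, length(delta)), tau2 = 1,
    `sigma2[VOR50]` = 1,
    `reduction[VOR50]` = 100 * (1 - 10^delta)
  )
  colnames(draws)[1] <- paste0("theta[", arm, "]")
  colnames(draws)[5] <- paste0("reduction[", arm, "]")
  structure(
    list(draws = list(draws), groups = c(arm, "CTRL_INTERNAL", "CTRL_EXTERNAL"),
         treated = arm, config = model_config(chains = 1),
         n_g = c(10, 5, 61)),
    class = "hg_fit"
  )
}

# Balanced two-source control + one treated arm group data with known
# moments, for sampler tests.
make_group_fixture <- function(seed = 1, n_t = 12, n_int = 6, n_ext = 30,
                               loc_t = 1, loc_c = 2, scale = 0.2) {
  withr::with_seed(seed, {
    tibble::tibble(
      group = c(rep("VOR50", n_t), rep("CTRL_INTERNAL", n_int),
                rep("CTRL_EXTERNAL", n_ext)),
      value = c(rnorm(n_t, loc_t, scale), rnorm(n_int, loc_c, scale),
                rnorm(n_ext, loc_c, scale))
    )
  })
}

# Exhaustive weighted-KS running sum over every position in the ranked
# list; the independent oracle for the enrichment score.
brute_force_es <- function(rank_scores, set_genes) {
  ord <- order(rank_scores, decreasing = TRUE)
  r <- rank_scores[ord]
  genes <- names(r)
  r <- unname(r)
  inset <- genes %in% set_genes
  nr <- sum(abs(r[inset]))
  n_miss <- sum(!inset)
  running <- 0
  best <- 0
  for (i in seq_along(r)) {
    if (inset[i]) {
      running <- running + abs(r[i]) / nr
    } else {
      running <- running - 1 / n_miss
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}
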