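# Operating-characteristics simulator for the design's simulation-based
# sample-size logic: repeated synthetic trials are generated under a
# stated truth, the borrowing model is refitted to each, and detection
# rate, bias, coverage and interval width are aggregated.

#' Truth specification for operating-characteristics runs
#'
#' A truth is a per-group generative table on the arithmetic scale:
#' `group`, `n`, `mean`, `sd` (ug/g).  It must contain `CTRL_INTERNAL`
#' and `CTRL_EXTERNAL` rows plus at least one treated group.  The implied
#' true percent reduction for a treated arm takes the true combined
#' control level as the unweighted mean of the two control-source log10
#' locations (the model's `mu_c` under its exchangeability assumption).
#'
#' @param truth Truth tibble.
#' @return Tibble `arm`, `true_reduction` (%).
#' @export
true_reduction <- function(truth) {
  lp <- moment_match_lognormal(truth$mean, truth$sd)
  loc <- setNames(lp$location, truth$group)
  ctrl <- mean(loc[CONTROL_GROUPS])
  arms <- setdiff(truth$group, CONTROL_GROUPS)
  tibble::tibble(arm = arms,
                 true_reduction = unname(100 * (1 - 10^(loc[arms] - ctrl))))
}

#' Default operating-characteristics truth: the published arm summaries
#'
#' Treated arms at the published evaluable means/s.d.s against internal
#' controls 154.9 (146.9), n = 5, and external mIDH1 controls 276.8
#' (231.4), n = 61.
#'
#' @param arms Which treated arms to include.
#' @return A truth tibble for [operating_characteristics()].
#' @export
published_truth <- function(arms = c("VOR50", "IVO500")) {
  specs <- default_arm_specs()
  specs$group <- dplyr::recode(specs$role,
                               internal_control = "CTRL_INTERNAL",
                               external_mIDH1 = "CTRL_EXTERNAL",
                               .default = specs$arm)
  keep <- specs$group %in% c(arms, CONTROL_GROUPS)
  tibble::tibble(group = specs$group[keep], n = specs$n[keep],
                 mean = specs$target_mean[keep], sd = specs$target_sd[keep])
}

#' Operating-characteristics configuration
#'
#' @param truths Named list of truth tibbles (see [published_truth()]).
#' @param p_star Posterior-probability detection threshold: detection is
#'   declared when `Pr(theta_t < mu_c | data) > p_star`.  Default 0.975.
#' @param replicates Simulated trials per truth x n cell.
#' @param n_scale Multipliers applied to every group's `n` (rounded up),
#'   giving the per-arm sample-size grid.
#' @param base_seed Base seed; replicate r uses `base_seed + r`.
#' @param model [model_config()] used for every refit (default: a short
#'   2-chain run sized for repeated fitting).
#' @param level Credible level for coverage/width summaries.
#' @return List of class `hg_oc_config`.
#' @export
oc_config <- function(truths = list(published = published_truth()),
                      p_star = 0.975, replicates = 200, n_scale = 1,
                      base_seed = 1,
                      model = model_config(chains = 2, iterations = 3000,
                                           burnin = 1000),
                      level = 0.95) {
  stopifnot(replicates >= 1, p_star > 0.5, p_star < 1)
  structure(list(truths = truths, p_star = p_star,
                 replicates = as.integer(replicates), n_scale = n_scale,
                 base_seed = as.integer(base_seed), model = model,
                 level = level),
            class = "hg_oc_config")
}

#' Simulate one trial and test for detection
#'
#' Generates one synthetic trial from the truth (per-group moment-matched
#' lognormal 2-HG), fits the borrowing model, and declares detection for
#' each treated arm iff the posterior probability that the arm's 2-HG is
#' below the combined control level exceeds `p_star`.
#'
#' @param truth Truth tibble (`group`, `n`, `mean`, `sd`).
#' @param model A [model_config()].
#' @param seed Integer seed (drives both data generation and the fit).
#' @param p_star Detection threshold.
#' @param level Credible level for the reported summary.
#' @return Tibble, one row per treated arm: `arm`, `detected`,
#'   `prob_lower`, `mean`, `lower`, `upper`.
#' @export
simulate_trial_once <- function(truth, model = model_config(chains = 2,
                                                            iterations = 3000,
                                                            burnin = 1000),
                                seed = 1, p_star = 0.975, level = 0.95) {
  local_seed(seed)
  lp <- moment_match_lognormal(truth$mean, truth$sd)
  groups <- purrr::pmap_dfr(
    list(truth$group, truth$n, lp$location, lp$scale),
    function(g, n, loc, sc) tibble::tibble(group = g, value = rnorm(n, loc, sc))
  )
  cfg <- model
  cfg$seed <- as.integer(seed)
  fit <- fit_borrowing_model(groups, cfg)
  purrr::map_dfr(fit$treated, function(a) {
    s <- summarize_reduction(fit, a, level)
    pl <- prob_treatment_lower(fit, a)
    tibble::tibble(arm = a, detected = pl > p_star, prob_lower = pl,
                   mean = s$mean, lower = s$lower, upper = s$upper)
  })
}

#' Run the operating-characteristics simulation
#'
#' For every truth x sample-size cell, simulates `replicates` trials with
#' deterministic per-replicate seeds (`base_seed + replicate`) and
#' aggregates: detection rate with binomial standard error, mean posterior
#' mean reduction, credible-interval coverage of the implied true
#' reduction, and mean interval width.
#'
#' @param config An [oc_config()].
#' @param progress Print a line per cell.
#' @return Tibble, one row per truth x n_scale x treated arm.
#' @export
operating_characteristics <- function(config = oc_config(), progress = FALSE) {
  stopifnot(inherits(config, "hg_oc_config"))
  cells <- tidyr::expand_grid(truth_name = names(config$truths),
                              n_scale = config$n_scale)
  purrr::pmap_dfr(cells, function(truth_name, n_scale) {
    truth <- config$truths[[truth_name]]
    truth$n <- as.integer(ceiling(truth$n * n_scale))
    tr <- true_reduction(truth)
    if (progress) {
      message("OC cell: ", truth_name, " x n_scale ", n_scale,
              " (", config$replicates, " replicates)")
    }
    reps <- purrr::map_dfr(seq_len(config$replicates), function(r) {
      out <- simulate_trial_once(truth, config$model,
                                 seed = config$base_seed + r,
                                 p_star = config$p_star, level = config$level)
      dplyr::mutate(out, replicate = r, seed = config$base_seed + r)
    })
    reps |>
      dplyr::left_join(tr, by = "arm") |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(
        true_reduction = .data$true_reduction[1],
        detection_rate = mean(.data$detected),
        detection_se = sqrt(.data$detection_rate * (1 - .data$detection_rate) /
                              dplyr::n()),
        mean_posterior_reduction = mean(.data$mean),
        coverage = mean(.data$lower <= .data$true_reduction[1] &
                          .data$true_reduction[1] <= .data$upper),
        mean_ci_width = mean(.data$upper - .data$lower),
        replicates = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(truth = truth_name, n_scale = n_scale, .before = 1)
  })
}
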