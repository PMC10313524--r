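test_that("lognormal moment matching reproduces arithmetic moments", {
  # degenerate: zero spread collapses to a point mass at log10(mean)
  p0 <- moment_match_lognormal(8.9, 0)
  expect_equal(p0$location, log10(8.9))
  expect_equal(p0$scale, 0)

  # Monte-Carlo oracle: large samples from the matched distribution must
  # recover the requested arithmetic mean and s.d.
  for (ms in list(c(276.8, 231.4), c(8.9, 4.1), c(154.9, 146.9))) {
    p <- moment_match_lognormal(ms[1], ms[2])
    x <- withr::with_seed(99, 10^rnorm(1e6, p$location, p$scale))
    expect_equal(mean(x), ms[1], tolerance = 0.01)
    expect_equal(sd(x), ms[2], tolerance = 0.02)
  }
  # frozen closed-form values for the two arms quoted most often
  pe <- moment_match_lognormal(276.8, 231.4)
  expect_equal(pe$location, 2.32709, tolerance = 1e-4)
  expect_equal(pe$scale, 0.31616, tolerance = 1e-4)
  pv <- moment_match_lognormal(8.9, 4.1)
  expect_equal(pv$location, 0.90760, tolerance = 1e-4)
  expect_equal(pv$scale, 0.19052, tolerance = 1e-4)

  expect_error(moment_match_lognormal(0, 1), class = "hg_domain_error")
})

test_that("cohort simulation honors arm sizes, targets and the seed", {
  cfg <- generator_config()
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cfg, seed = 6)))

  counts <- table(a$subjects$arm)
  expect_equal(unname(counts[c("VOR50", "VOR10", "IVO500", "IVO250", "UNTREATED")]),
               c(11, 7, 10, 7, 5), ignore_attr = TRUE)
  expect_equal(sum(a$externals$idh_status == "mIDH1"), 61)
  expect_true(all(a$subjects$tumor_2hg >= 0))
  expect_true(all(a$subjects$cellularity > 0 & a$subjects$cellularity <= 1))

  # an arm with n = 0 simply vanishes
  cfg0 <- generator_config(arm_specs = dplyr::mutate(
    default_arm_specs(), n = ifelse(arm == "VOR10", 0L, n)))
  expect_false("VOR10" %in% simulate_cohort(cfg0, seed = 1)$subjects$arm)

  # law of large numbers: a 10^4-subject arm matches its target within 2%
  big <- generator_config(arm_specs = dplyr::bind_rows(
    dplyr::mutate(arm_spec("VOR50", 1e4, 8.9, 4.1), role = "treated"),
    dplyr::mutate(arm_spec("UNTREATED", 10, 154.9, 146.9), role = "internal_control"),
    dplyr::mutate(arm_spec("EXT_MIDH1", 10, 276.8, 231.4), role = "external_mIDH1")
  ))
  sim <- simulate_cohort(big, seed = 2)
  m <- mean(sim$subjects$tumor_2hg[sim$subjects$arm == "VOR50"])
  expect_lt(abs(m - 8.9) / 8.9, 0.02)
})

test_that("biomarker couplings have the configured slope and sign", {
  cfg <- generator_config()
  # zero slope, zero noise -> constant at the intercept
  flat <- cfg
  flat$biomarkers$slope <- 0
  flat$biomarkers$noise_sd <- 0
  bm <- simulate_biomarkers(c(0.5, 1.5, 2.5), flat, seed = 1)
  expect_equal(bm$ki67_pct, rep(2, 3))

  # slope recovery: fitted regression within 3 s.e. of the truth
  x <- withr::with_seed(3, runif(200, 0.5, 2.5))
  bm <- simulate_biomarkers(x, cfg, seed = 4)
  fit <- simple_linear_regression(x, bm$ki67_pct)
  truth <- cfg$biomarkers$slope[cfg$biomarkers$biomarker == "ki67_pct"]
  expect_lt(abs(fit$slope - truth), 3 * fit$se_slope)

  # 5hmC couples negatively to 2-HG
  hmc <- compute_5hmc_percent(bm$c_5hmc, bm$c_c)
  expect_lt(cor(x, hmc), 0)
  expect_true(all(bm$ki67_pct >= 0) && all(bm$cd3_density >= 0))
})

test_that("expression generator plants a recoverable signature", {
  covar <- withr::with_seed(8, rnorm(40, 1.5, 0.6))

  # null: association p-values are uniform
  null_cfg <- generator_config(expression = list(
    n_genes = 500, n_signature = 0, effect = 0, noise_sd = 1, base_mean = 6))
  ex0 <- simulate_expression(null_cfg, covar, seed = 1)
  p0 <- per_gene_association(ex0$matrix, covar)$p_value
  expect_gt(stats::ks.test(p0, "punif")$p.value, 0.01)

  # strong effect: >=90% of the 50 signature genes reach the top 100
  sig_cfg <- generator_config(expression = list(
    n_genes = 2000, n_signature = 50, effect = 1.5, noise_sd = 1, base_mean = 6))
  ex1 <- simulate_expression(sig_cfg, covar, seed = 2)
  gs <- per_gene_association(ex1$matrix, covar)
  top100 <- gs$gene[order(abs(gs$rank), decreasing = TRUE)][1:100]
  expect_gte(mean(ex1$signature_genes %in% top100), 0.9)

  expect_identical(ex1$matrix, simulate_expression(sig_cfg, covar, seed = 2)$matrix)
  expect_true(all(ex1$matrix > 0))
})

test_that("SPD series follow the configured drift and resection fraction", {
  base <- generator_config(spd = list(visits = 6, visit_spacing_days = 56,
                                      baseline_mean_cm2 = 12, drift = 0,
                                      noise_sd = 0, no_residual_fraction = 0))
  s <- simulate_spd_series(base, c("A", "B"), seed = 1)
  chg <- classify_responses(s)
  expect_equal(chg$best_percent_change, c(0, 0))

  # -10%/visit with no noise compounds to (0.9^6 - 1) = -46.9%
  drift <- base
  drift$spd$drift <- -0.10
  s <- simulate_spd_series(drift, sprintf("S%d", 1:20), seed = 2)
  bests <- vapply(split(s, s$subject_id),
                  function(d) best_percent_change(d), numeric(1))
  expect_equal(unname(bests), rep(100 * (0.9^6 - 1), 20), tolerance = 1e-10)
  expect_true(all(bests <= -40))

  # resection fraction 1 -> every baseline is zero residual disease
  res <- base
  res$spd$no_residual_fraction <- 1
  s <- simulate_spd_series(res, c("A", "B", "C"), seed = 3)
  expect_true(all(s$spd == 0))
  expect_identical(simulate_spd_series(res, c("A", "B", "C"), seed = 3), s)
})
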