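test_that("Gibbs posterior matches the conjugate closed form (known variance, flat prior)", {
  groups <- make_group_fixture(seed = 1)
  y <- groups$value[groups$group == "VOR50"]
  sigma2 <- 0.04
  cfg <- model_config(v0 = 1e12, chains = 2, iterations = 6000, burnin = 1000,
                      seed = 3,
                      fix_sigma2 = c(VOR50 = sigma2))
  fit <- fit_borrowing_model(groups, cfg)
  th <- unlist(lapply(fit$draws, function(m) m[, "theta[VOR50]"]))
  # analytic posterior in the v0 -> Inf limit: N(ybar, sigma2 / n)
  post_mean <- mean(y)
  post_sd <- sqrt(sigma2 / length(y))
  ess <- hgborrow:::ess_draws(lapply(fit$draws, function(m) m[, "theta[VOR50]"]))
  expect_lt(abs(mean(th) - post_mean), 3 * post_sd / sqrt(ess))
  expect_equal(sd(th), post_sd, tolerance = 0.1)
})

test_that("no treatment effect gives a reduction posterior centred near zero", {
  ctrl <- withr::with_seed(2, rnorm(30, 2, 0.2))
  groups <- tibble::tibble(
    group = c(rep("VOR50", 30), rep("CTRL_INTERNAL", 15), rep("CTRL_EXTERNAL", 15)),
    value = c(ctrl, ctrl[1:15], ctrl[16:30])
  )
  fit <- fit_borrowing_model(groups, model_config(chains = 2, iterations = 4000,
                                                  burnin = 1000, seed = 4))
  s <- summarize_reduction(fit, "VOR50")
  expect_lt(abs(s$mean), (s$upper - s$lower) / 2)
})

test_that("the control hypermean shrinks between the two control source means", {
  for (seed in 1:5) {
    groups <- make_group_fixture(seed = seed, loc_c = 2, scale = 0.3)
    # shift the internal controls so the sources genuinely disagree
    groups$value[groups$group == "CTRL_INTERNAL"] <-
      groups$value[groups$group == "CTRL_INTERNAL"] - 0.4
    fit <- fit_borrowing_model(groups, model_config(chains = 2, iterations = 3000,
                                                    burnin = 1000, seed = seed))
    mu <- mean(unlist(lapply(fit$draws, function(m) m[, "mu_c"])))
    m_int <- mean(groups$value[groups$group == "CTRL_INTERNAL"])
    m_ext <- mean(groups$value[groups$group == "CTRL_EXTERNAL"])
    expect_gt(mu, min(m_int, m_ext))
    expect_lt(mu, max(m_int, m_ext))
  }
})

test_that("lowering treated observations never decreases the posterior reduction", {
  groups <- make_group_fixture(seed = 7)
  shifts <- c(0, -0.3, -0.6)
  means <- vapply(shifts, function(s) {
    g <- groups
    g$value[g$group == "VOR50"] <- g$value[g$group == "VOR50"] + s
    fit <- fit_borrowing_model(g, model_config(chains = 2, iterations = 3000,
                                               burnin = 1000, seed = 11))
    summarize_reduction(fit, "VOR50")$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("reduction summaries are exact transforms of the contrast draws", {
  # constant contrast of -1 is a 10-fold drop: 90% reduction, degenerate CrI
  fit <- make_fake_fit(rep(-1, 1000))
  s <- summarize_reduction(fit, "VOR50")
  expect_equal(s$mean, 90)
  expect_equal(c(s$lower, s$upper), c(90, 90))

  # zero contrast: 0% reduction
  s0 <- summarize_reduction(make_fake_fit(rep(0, 500)), "VOR50")
  expect_equal(c(s0$mean, s0$lower, s0$upper), c(0, 0, 0))

  # quantile-transform oracle: with delta ~ N(-1, 0.1^2) the reduction
  # quantiles are the transformed normal quantiles (reduction is a
  # monotone decreasing transform of delta)
  delta <- withr::with_seed(5, rnorm(20000, -1, 0.1))
  s1 <- summarize_reduction(make_fake_fit(delta), "VOR50")
  expect_equal(s1$mean, mean(100 * (1 - 10^delta)), tolerance = 1e-10)
  expect_equal(s1$lower, 100 * (1 - 10^quantile(delta, 0.975, names = FALSE)),
               tolerance = 0.01)
  expect_equal(s1$upper, 100 * (1 - 10^quantile(delta, 0.025, names = FALSE)),
               tolerance = 0.01)
  expect_lte(s1$upper, 100)
})

test_that("prob_treatment_lower counts draws below the control hypermean", {
  listed <- c(-0.5, -0.2, 0.1, -0.4, 0.3, -0.1, -0.6, 0.2, -0.3, -0.05)
  fit <- make_fake_fit(listed)
  expect_equal(prob_treatment_lower(fit, "VOR50"), 7 / 10)
  expect_equal(prob_treatment_lower(make_fake_fit(rep(-1, 50)), "VOR50"), 1)

  symm <- withr::with_seed(6, rnorm(20000, 0, 0.3))
  expect_equal(prob_treatment_lower(make_fake_fit(symm), "VOR50"), 0.5,
               tolerance = 0.02)
})

test_that("configuration and key errors are raised", {
  groups <- make_group_fixture()
  no_ext <- groups[groups$group != "CTRL_EXTERNAL", ]
  expect_error(fit_borrowing_model(no_ext), class = "hg_config_error")
  only_ctrl <- groups[groups$group != "VOR50", ]
  expect_error(fit_borrowing_model(only_ctrl), class = "hg_config_error")
  fit <- make_fake_fit(rep(-1, 10))
  expect_error(summarize_reduction(fit, "IVO500"), class = "hg_key_error")
  expect_error(prob_treatment_lower(fit, "NOPE"), class = "hg_key_error")
})

test_that("tidy and glance expose draws and convergence", {
  groups <- make_group_fixture(seed = 3)
  fit <- fit_borrowing_model(groups, model_config(chains = 2, iterations = 2000,
                                                  burnin = 500, seed = 2))
  td <- tidy(fit)
  expect_setequal(unique(td$chain), 1:2)
  expect_true(all(c("chain", "draw", "parameter", "value") %in% names(td)))
  expect_equal(nrow(td), 2 * 1500 * ncol(fit$draws[[1]]))
  gl <- glance(fit)
  expect_lt(gl$max_rhat, 1.1)
  expect_gt(gl$min_ess, 100)
})

test_that("tau2 prior sweep reports one summary per grid point and arm", {
  groups <- make_group_fixture(seed = 9)
  sw <- sweep_tau_prior(groups, model_config(chains = 1, iterations = 1500,
                                             burnin = 500, seed = 1),
                        grid = tibble::tibble(a_tau = c(0.5, 2),
                                              b_tau = c(0.01, 0.1)))
  expect_equal(nrow(sw), 2)
  expect_true(all(sw$mean <= 100))
})
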