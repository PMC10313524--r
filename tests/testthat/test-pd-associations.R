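test_that("simple linear regression matches stats::lm on a worked set", {
  x <- c(0.2, 0.8, 1.1, 1.9, 2.4, 3.0)
  y <- c(5.1, 4.2, 4.9, 3.1, 2.2, 1.8)
  ours <- simple_linear_regression(x, y)
  ref <- summary(stats::lm(y ~ x))
  expect_equal(ours$slope, unname(ref$coefficients["x", "Estimate"]), tolerance = 1e-10)
  expect_equal(ours$intercept, unname(ref$coefficients["(Intercept)", "Estimate"]),
               tolerance = 1e-10)
  expect_equal(ours$se_slope, unname(ref$coefficients["x", "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(ours$p_value, unname(ref$coefficients["x", "Pr(>|t|)"]),
               tolerance = 1e-10)
  expect_equal(ours$r_squared, ref$r.squared, tolerance = 1e-10)

  exact <- simple_linear_regression(x, 2 * x)
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$p_value, 0)

  flat <- simple_linear_regression(x, rep(3, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)

  expect_error(simple_linear_regression(rep(1, 5), rnorm(5)),
               class = "hg_degenerate_error")
})

test_that("pooled t-test matches stats::t.test and is shift invariant", {
  a <- c(3.1, 4.5, 2.2, 5.0, 3.8)
  b <- c(6.2, 5.1, 7.4, 6.6, 5.9)
  ours <- two_group_ttest(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter))

  shifted <- two_group_ttest(a + 100, b + 100)
  expect_equal(shifted$t, ours$t, tolerance = 1e-12)
  expect_equal(shifted$p_value, ours$p_value, tolerance = 1e-12)

  same <- two_group_ttest(c(1, 1, 1), c(1, 1))
  expect_equal(c(same$t, same$p_value), c(0, 1))
  degen <- two_group_ttest(c(1, 1), c(2, 2))
  expect_equal(degen$p_value, 0)
})

test_that("the rank statistic is the signed -log10 p and clamps p = 0", {
  expect_equal(rank_statistic(0.01, 1.5), 2)
  expect_equal(rank_statistic(0.001, -0.2), -3)
  expect_equal(rank_statistic(1, 7), 0)
  expect_equal(rank_statistic(1, -7), 0)
  expect_equal(rank_statistic(0.05, 0), 0)
  # antisymmetric under coefficient sign flip
  p <- c(0.3, 0.01, 0.8)
  fc <- c(1.2, -0.5, 0.1)
  expect_equal(rank_statistic(p, fc), -rank_statistic(p, -fc))
  expect_warning(r0 <- rank_statistic(0, 2), "clamped")
  expect_true(is.finite(r0) && r0 > 300)
  expect_error(rank_statistic(1.2, 1), class = "hg_domain_error")
})

test_that("BH adjustment reproduces the step-up and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- withr::with_seed(1, runif(100)^2)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # order-preserving: smaller raw p never gets a larger adjusted value
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.7)), class = "hg_domain_error")
})

test_that("per-gene association recovers planted signal and respects invariance", {
  covar <- withr::with_seed(10, rnorm(36, 1.5, 0.5))
  cfg <- generator_config(expression = list(n_genes = 1000, n_signature = 40,
                                            effect = 1.5, noise_sd = 1,
                                            base_mean = 6))
  ex <- simulate_expression(cfg, covar, seed = 3)
  gs <- per_gene_association(ex$matrix, covar)
  expect_equal(nrow(gs), 1000)
  top <- gs$gene[order(abs(gs$rank), decreasing = TRUE)][1:80]
  expect_gte(mean(ex$signature_genes %in% top), 0.9)
  # the rank is zero iff p is one; its sign follows the coefficient
  expect_true(all(sign(gs$rank) == sign(gs$log2fc) | gs$p_value == 1))

  # permuting samples and covariate together leaves the output unchanged
  perm <- withr::with_seed(4, sample(ncol(ex$matrix)))
  gs_perm <- per_gene_association(ex$matrix[, perm], covar[perm])
  expect_equal(gs_perm, gs, tolerance = 1e-9)

  # per-gene results agree with stats::lm for a sampled gene
  g <- ex$matrix[17, ]
  z <- (covar - mean(covar)) / sqrt(mean((covar - mean(covar))^2))
  ref <- summary(stats::lm(log2(g) ~ z))
  expect_equal(gs$log2fc[17], unname(ref$coefficients["z", "Estimate"]),
               tolerance = 1e-9)
  expect_equal(gs$p_value[17], unname(ref$coefficients["z", "Pr(>|t|)"]),
               tolerance = 1e-9)

  # a constant gene yields a null result, not an error
  m2 <- ex$matrix[1:5, ]
  m2[3, ] <- 2
  gs2 <- per_gene_association(m2, covar)
  expect_equal(gs2$p_value[3], 1)
  expect_equal(gs2$log2fc[3], 0)
})

test_that("top-split clustering separates distinct sample groups", {
  withr::local_seed(12)
  blob <- cbind(matrix(rnorm(50 * 10, 0), 50), matrix(rnorm(50 * 10, 4), 50))
  colnames(blob) <- sprintf("S%02d", 1:20)
  truth <- rep(1:2, each = 10)
  variable <- rnorm(20) + 2 * truth
  out <- top_split_clusters(blob, variable)
  expect_equal(length(unique(out$membership$cluster[1:10])), 1)
  expect_equal(length(unique(out$membership$cluster[11:20])), 1)
  expect_false(out$membership$cluster[1] == out$membership$cluster[20])
  expect_lt(out$test$p_value, 0.05)

  expect_error(top_split_clusters(blob[, 1, drop = FALSE], 1),
               class = "hg_domain_error")
  same <- matrix(rep(rnorm(30), 4), ncol = 4,
                 dimnames = list(NULL, paste0("S", 1:4)))
  expect_error(top_split_clusters(same, 1:4), class = "hg_degenerate_error")
})
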