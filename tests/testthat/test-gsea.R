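toy_ranks <- function(seed = 1, n = 20) {
  withr::with_seed(seed, {
    r <- rnorm(n)
    names(r) <- sprintf("g%02d", seq_len(n))
    r
  })
}

test_that("enrichment score equals the exhaustive running-sum oracle", {
  for (seed in 1:5) {
    r <- toy_ranks(seed)
    set_genes <- withr::with_seed(seed + 100, sample(names(r), 5))
    ord <- order(r, decreasing = TRUE)
    pos <- which(names(r)[ord] %in% set_genes)
    ours <- hgborrow:::es_running_sum(abs(r[ord]), pos)
    oracle <- brute_force_es(r, set_genes)
    expect_equal(ours, oracle, tolerance = 1e-12)
    expect_lte(abs(ours), 1)
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  r <- toy_ranks(3, n = 100)
  set_genes <- names(sort(r, decreasing = TRUE))[6:25]  # a high-ranking set
  ord <- order(r, decreasing = TRUE)
  ours <- hgborrow:::es_running_sum(abs(r[ord]),
                                    which(names(r)[ord] %in% set_genes))
  ref <- fgsea::calcGseaStat(sort(r, decreasing = TRUE),
                             selectedStats = which(names(sort(r, decreasing = TRUE))
                                                   %in% set_genes))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("a set of the top-ranked genes scores near the attainable maximum", {
  r <- toy_ranks(7, n = 200)
  top <- names(sort(r, decreasing = TRUE))[1:20]
  res <- preranked_gsea(r, list(TOP = top), n_perm = 200, min_size = 10, seed = 1)
  expect_gt(res$es, 0.9)
  expect_lt(res$p_value, 0.02)
})

test_that("size bounds, skipping and sign behavior follow the contract", {
  r <- toy_ranks(2, n = 300)
  sets <- list(
    TINY = names(r)[1:5],                       # below min size -> dropped
    MID = names(r)[10:60],
    ALIEN = c("x1", "x2", "x3")                 # empty intersection -> skipped
  )
  expect_message(res <- preranked_gsea(r, sets, n_perm = 100, seed = 1),
                 "ALIEN")
  expect_equal(res$set, "MID")

  # negating every rank score flips the enrichment score
  res_pos <- preranked_gsea(r, sets["MID"], n_perm = 100, seed = 1)
  res_neg <- preranked_gsea(-r, sets["MID"], n_perm = 100, seed = 1)
  expect_equal(res_neg$es, -res_pos$es, tolerance = 1e-12)

  # the permutation p-value is seed-deterministic
  again <- preranked_gsea(r, sets["MID"], n_perm = 100, seed = 1)
  expect_identical(res_pos$p_value, again$p_value)
  expect_false(identical(
    res_pos$p_value,
    preranked_gsea(r, sets["MID"], n_perm = 100, seed = 2)$p_value
  ))
})

test_that("a planted signature is detected with a sensible NES and q-value", {
  covar <- withr::with_seed(21, rnorm(40, 1.5, 0.6))
  cfg <- generator_config(expression = list(n_genes = 1500, n_signature = 60,
                                            effect = 1.2, noise_sd = 1,
                                            base_mean = 6))
  ex <- simulate_expression(cfg, covar, seed = 5)
  gs <- per_gene_association(ex$matrix, covar)
  # the planted signature couples half up/half down; test the up half
  up <- ex$signature_genes[seq(1, 60, by = 2)]
  random_sets <- withr::with_seed(22, lapply(1:10, function(i) sample(gs$gene, 30)))
  names(random_sets) <- sprintf("R%02d", 1:10)
  res <- preranked_gsea(gs, c(list(UP = up), random_sets), n_perm = 1000, seed = 3)
  up_row <- res[res$set == "UP", ]
  expect_gt(up_row$nes, 1)
  expect_lt(up_row$q_value, 0.05)
  expect_gt(min(res$q_value[res$set != "UP"]), 0.05)
})

test_that("GMT files round-trip and match the fgsea reader", {
  sets <- list(ALPHA = c("g1", "g2", "g3"), BETA = sprintf("h%d", 1:20))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  expect_equal(lapply(fgsea::gmtPathways(path), unname), sets)
})
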