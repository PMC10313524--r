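# Pharmacodynamic association statistics: simple linear regression,
# pooled two-sample t-test, the signed -log10(p) gene-ranking statistic,
# per-gene linear association across an expression matrix, BH adjustment,
# and the top-split cluster comparison.  The per-gene closed forms are
# vectorised across genes so a few thousand genes fit in milliseconds;
# stats::lm / stats::t.test serve as independent oracles in the tests.

#' Simple linear regression of y on x
#'
#' Ordinary least squares with the two-sided slope p-value from the t
#' reference with `n - 2` degrees of freedom.  A constant response gives
#' slope 0 and p = 1; an exact fit gives p = 0.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must vary.
#' @return One-row tibble: `slope`, `intercept`, `se_slope`, `p_value`,
#'   `r_squared`.
#' @export
simple_linear_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    abort("need >= 3 complete (x, y) pairs", class = "hg_domain_error")
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) abort("x is constant", class = "hg_degenerate_error")
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    return(tibble::tibble(slope = 0, intercept = mean(y), se_slope = 0,
                          p_value = 1, r_squared = 0))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  rss <- max(rss, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- if (se == 0) sign(slope) * Inf else slope / se
  tibble::tibble(
    slope = slope, intercept = intercept, se_slope = se,
    p_value = if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2),
    r_squared = 1 - rss / syy
  )
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with `n_a + n_b - 2` degrees of freedom and a two-sided
#' p-value.  With zero pooled variance the statistic degenerates: equal
#' means give p = 1, unequal means give p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_diff`.
#' @export
two_group_ttest <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs >= 2 observations", class = "hg_domain_error")
  }
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    tstat <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    tstat <- diff / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  tibble::tibble(
    t = tstat, df = df,
    p_value = if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = df),
    mean_diff = diff
  )
}

#' Signed significance rank statistic for gene ordering
#'
#' `rank = -log10(p) * sign(log2fc)`: genes are ordered by the
#' significance and the direction of their association.  `p = 1` or a
#' zero coefficient gives rank 0; `p = 0` is clamped to `p_floor` with a
#' warning so the statistic stays finite.
#'
#' @param p Unadjusted p-values in (0, 1] (vectorised).
#' @param log2fc Association coefficients on the log2 scale.
#' @param p_floor Smallest admissible p-value for clamping.
#' @return Numeric rank scores.
#' @export
rank_statistic <- function(p, log2fc, p_floor = .Machine$double.xmin) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "hg_domain_error")
  }
  if (any(p == 0, na.rm = TRUE)) {
    warn(paste0("p-values of 0 clamped to ", format(p_floor)))
    p[p == 0] <- p_floor
  }
  -log10(p) * sign(log2fc)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (monotone step-up, capped at 1),
#' via [stats::p.adjust()].
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "hg_domain_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene linear association with a covariate
#'
#' For each gene, the simple linear regression of log2 expression on the
#' z-scored covariate (population-n z-score).  The coefficient is the
#' log2 change per covariate standard deviation ("log2 fold-change-like"),
#' p-values are BH-adjusted across genes, and signed rank scores are
#' attached.  This is a deliberately simple association engine for
#' exercising the ranking/enrichment machinery, not a count-model
#' differential-expression method.
#'
#' @param mat Strictly positive expression matrix, genes x samples, with
#'   rownames.
#' @param covariate Per-sample covariate (e.g. log10 tumor 2-HG), length
#'   `ncol(mat)`.
#' @param log_transform Take log2 of the matrix first (set `FALSE` if the
#'   matrix is already on a log scale).
#' @return Tibble, one row per gene: `gene`, `log2fc`, `p_value`,
#'   `p_adjusted`, `rank`.  Zero-variance genes get coefficient 0 and
#'   p = 1.
#' @export
per_gene_association <- function(mat, covariate, log_transform = TRUE) {
  if (ncol(mat) != length(covariate)) {
    abort("covariate length must equal the sample count", class = "hg_domain_error")
  }
  n <- length(covariate)
  if (n < 3) abort("need >= 3 samples", class = "hg_domain_error")
  z <- zscore_pop(covariate)
  y <- if (log_transform) log2(mat) else mat
  # vectorised OLS across genes: x is shared, centred
  xc <- z - mean(z)
  sxx <- sum(xc^2)
  ybar <- rowMeans(y)
  sxy <- as.vector(y %*% xc)
  slope <- sxy / sxx
  syy <- rowSums((y - ybar)^2)
  rss <- pmax(syy - slope * sxy, 0)
  se2 <- rss / (n - 2) / sxx
  tstat <- ifelse(se2 > 0, slope / sqrt(se2), ifelse(slope == 0, 0, Inf))
  p <- ifelse(is.infinite(tstat), 0, 2 * pt(-abs(tstat), df = n - 2))
  zero_var <- syy == 0
  slope[zero_var] <- 0
  p[zero_var] <- 1
  p_rank <- pmax(p, .Machine$double.xmin)
  tibble::tibble(
    gene = rownames(mat),
    log2fc = unname(slope),
    p_value = unname(p),
    p_adjusted = unname(bh_adjust(p)),
    rank = unname(-log10(p_rank) * sign(slope))
  )
}

#' Split samples at the top of a complete-linkage dendrogram
#'
#' Rows are z-scored (population-n), columns are clustered by
#' complete-linkage agglomeration on Euclidean distance, the tree is cut
#' at the root into two groups, and a supplied per-sample variable is
#' compared between the groups with the pooled t-test.
#'
#' @param mat Numeric matrix, genes x samples (>= 2 samples), with
#'   colnames.
#' @param variable Per-sample variable to compare between the two topmost
#'   clusters (e.g. log10 tumor 2-HG).
#' @return List: `membership` (tibble `sample`, `cluster`), `test`
#'   (pooled t-test tibble), `tree` (the `hclust` object).
#' @export
top_split_clusters <- function(mat, variable) {
  if (ncol(mat) < 2) abort("need >= 2 samples", class = "hg_domain_error")
  rs <- apply(mat, 1, function(r) sqrt(mean((r - mean(r))^2)))
  keep <- rs > 0
  zmat <- (mat[keep, , drop = FALSE] - rowMeans(mat[keep, , drop = FALSE])) /
    rs[keep]
  d <- dist(t(zmat))
  if (nrow(zmat) == 0 || all(d == 0)) {
    abort("all samples identical; linkage is degenerate",
          class = "hg_degenerate_error")
  }
  tree <- hclust(d, method = "complete")
  cl <- cutree(tree, k = 2)
  membership <- tibble::tibble(sample = colnames(mat), cluster = unname(cl))
  test <- two_group_ttest(variable[cl == 1], variable[cl == 2])
  list(membership = membership, test = test, tree = tree)
}
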