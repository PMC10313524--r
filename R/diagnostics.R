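# MCMC convergence diagnostics: split-chain potential scale reduction
# (R-hat) and autocovariance-based effective sample size, computed from
# the retained draws of an hg_fit.

split_chains <- function(chains) {
  unlist(lapply(chains, function(x) {
    n <- length(x)
    h <- n %/% 2
    list(x[seq_len(h)], x[(n - h + 1):n])
  }), recursive = FALSE)
}

rhat_draws <- function(chains) {
  sp <- split_chains(chains)
  n <- min(lengths(sp))
  sp <- lapply(sp, function(x) x[seq_len(n)])
  m <- length(sp)
  means <- vapply(sp, mean, numeric(1))
  vars <- vapply(sp, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(if (b == 0) 1 else Inf)
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

ess_draws <- function(chains) {
  if (!all(is.finite(unlist(chains)))) return(NA_real_)
  sp <- split_chains(chains)
  n <- min(lengths(sp))
  sp <- lapply(sp, function(x) x[seq_len(n)])
  m <- length(sp)
  means <- vapply(sp, mean, numeric(1))
  vars <- vapply(sp, var, numeric(1))
  w <- mean(vars)
  var_plus <- (n - 1) / n * w + var(means)
  if (var_plus == 0) return(NA_real_)
  max_lag <- min(n - 2, 500)
  # mean within-chain autocovariance at each lag
  acov <- sapply(sp, function(x) {
    a <- acf(x, lag.max = max_lag, plot = FALSE, type = "covariance",
             demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (w - mean_acov[-1]) / var_plus
  # Geyer initial positive sequence over paired lags
  total <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    total <- total + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * total)
  min(ess, m * n)
}

#' Convergence diagnostics for a borrowing-model fit
#'
#' Split-chain potential scale reduction (R-hat) and effective sample size
#' for every scalar parameter of the fit.  With a single chain R-hat is
#' still computed from the two split halves, but a warning notes that
#' between-chain mixing is unassessed.
#'
#' @param fit An `hg_fit`.
#' @param rhat_threshold Flag parameters with R-hat above this value.
#' @return Tibble `parameter`, `rhat`, `ess`, `flagged`.
#' @export
diagnostics <- function(fit, rhat_threshold = 1.05) {
  stopifnot(inherits(fit, "hg_fit"))
  if (length(fit$draws) < 2) {
    warn("single chain: R-hat computed from split halves only")
  }
  pars <- colnames(fit$draws[[1]])
  purrr::map_dfr(pars, function(p) {
    ch <- lapply(fit$draws, function(m) m[, p])
    r <- rhat_draws(ch)
    tibble::tibble(parameter = p, rhat = r, ess = ess_draws(ch),
                   flagged = is.finite(r) & r > rhat_threshold)
  })
}
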