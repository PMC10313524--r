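# RANO-LGG best-overall-response classification from SPD lesion series
# and exact binomial inference for the objective response rate.
#
# Categories from percent change in SPD (sum of products of perpendicular
# lesion diameters) versus the postoperative baseline scan:
#   CR  disappearance of all lesions (SPD 0), confirmed
#   PR  <= -50%, confirmed
#   mR  <= -25% and > -50%, confirmed
#   PD  >= +25% from nadir (smallest SPD so far, including baseline)
#   SD  otherwise, including unconfirmed qualifying decreases
# Subjects resected to no measurable disease are SD unless new measurable
# disease appears (PD).

#' Response classification thresholds
#'
#' @param pr_pct,mr_pct Decrease thresholds (%) for partial and minor
#'   response.
#' @param pd_pct Increase threshold (%) from nadir for progression.
#' @param confirm Require the qualifying decrease to persist (same
#'   category threshold met) at the immediately next visit.
#' @return A list of rules.
#' @export
response_rules <- function(pr_pct = -50, mr_pct = -25, pd_pct = 25,
                           confirm = TRUE) {
  stopifnot(pr_pct < mr_pct, mr_pct < 0, pd_pct > 0)
  list(pr_pct = pr_pct, mr_pct = mr_pct, pd_pct = pd_pct, confirm = confirm)
}

series_parts <- function(series) {
  series <- dplyr::arrange(tibble::as_tibble(series), .data$day)
  list(baseline = series$spd[1], visits = series$spd[-1])
}

#' Best percent change in SPD from baseline
#'
#' Minimum over post-baseline visits of `100 * (spd - baseline) /
#' baseline`.  Returns `NA` when there are no post-baseline visits (not
#' evaluable) or when the baseline shows no residual disease (percent
#' change from zero is undefined).
#'
#' @param series Tibble `day`, `spd` for one subject; the earliest day is
#'   the postoperative baseline.
#' @return Percent change (negative = shrinkage), or `NA`.
#' @export
best_percent_change <- function(series) {
  p <- series_parts(series)
  if (length(p$visits) == 0 || is.na(p$baseline) || p$baseline <= 0) {
    return(NA_real_)
  }
  min(100 * (p$visits - p$baseline) / p$baseline)
}

#' Classify best overall response for one subject
#'
#' Applies the category thresholds with confirmation: a qualifying
#' decrease (or CR) counts only if the same threshold is still met at the
#' immediately next visit; an unconfirmed qualifying decrease is stable
#' disease.  Progression is a `pd_pct` percent increase over the nadir
#' (the smallest SPD seen so far, baseline included); once the nadir is
#' zero any regrowth is progression.  A confirmed response takes
#' precedence over later progression in the best-response summary.
#'
#' @param series Tibble `day`, `spd` for one subject.
#' @param rules A [response_rules()] list.
#' @return One-row tibble: `category` (CR/PR/mR/SD/PD/NE),
#'   `best_percent_change` (`NA` for no-residual-disease subjects without
#'   progression and for NE).
#' @export
classify_best_response <- function(series, rules = response_rules()) {
  p <- series_parts(series)
  v <- p$visits
  if (length(v) == 0 || is.na(p$baseline)) {
    return(tibble::tibble(category = "NE", best_percent_change = NA_real_))
  }
  if (p$baseline <= 0) {
    # complete resection: SD unless measurable disease appears
    cat <- if (any(v > 0)) "PD" else "SD"
    return(tibble::tibble(category = cat, best_percent_change = NA_real_))
  }
  pct <- 100 * (v - p$baseline) / p$baseline
  nadir <- cummin(c(p$baseline, head(v, -1)))
  pd_hit <- ifelse(nadir == 0, v > 0, 100 * (v - nadir) / nadir >= rules$pd_pct)

  meets <- function(i, cat) {
    switch(cat,
      CR = v[i] == 0,
      PR = pct[i] <= rules$pr_pct,
      mR = pct[i] <= rules$mr_pct
    )
  }
  first_pd <- if (any(pd_hit)) which(pd_hit)[1] else Inf
  confirmed <- function(cat) {
    for (i in seq_along(v)) {
      if (i >= first_pd) break  # responses only count before progression
      if (meets(i, cat)) {
        if (!rules$confirm) return(TRUE)
        if (i < length(v) && meets(i + 1, cat)) return(TRUE)
      }
    }
    FALSE
  }
  category <- if (confirmed("CR")) "CR"
    else if (confirmed("PR")) "PR"
    else if (confirmed("mR")) "mR"
    else if (any(pd_hit)) "PD"
    else "SD"
  tibble::tibble(category = category, best_percent_change = min(pct))
}

#' Classify best overall response for a long lesion table
#'
#' @param lesions Tibble `subject_id`, `day`, `spd` (see
#'   [read_lesion_table()]).
#' @param rules A [response_rules()] list.
#' @return Tibble, one row per subject: `subject_id`, `category`,
#'   `best_percent_change`.
#' @export
classify_responses <- function(lesions, rules = response_rules()) {
  lesions |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~classify_best_response(.x, rules)) |>
    dplyr::ungroup()
}

#' Exact binomial (Clopper-Pearson) confidence interval, in percent
#'
#' Inverts the binomial tail probabilities through Beta quantiles:
#' `lower = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2, x + 1, n - x)` (100% when `x = n`).
#'
#' @param x Number of successes.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level in (0, 1).
#' @return Named numeric `c(lower, upper)`, percent scale.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    abort("need integer counts with 0 <= x <= n, n >= 1",
          class = "hg_domain_error")
  }
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Objective response rate with exact confidence interval
#'
#' Responders are subjects with best overall response CR, PR or mR.
#'
#' @param responses Character vector of categories, or a tibble with a
#'   `category` column (e.g. from [classify_responses()]).
#' @param level Confidence level.
#' @return One-row tibble: `responders`, `n`, `orr` (%), `lower`, `upper`,
#'   `level`.
#' @export
orr <- function(responses, level = 0.95) {
  if (is.data.frame(responses)) responses <- responses$category
  if (length(responses) == 0) {
    abort("no responses supplied", class = "hg_domain_error")
  }
  x <- sum(responses %in% c("CR", "PR", "mR"))
  n <- length(responses)
  ci <- clopper_pearson(x, n, level)
  tibble::tibble(responders = x, n = n, orr = 100 * x / n,
                 lower = ci[["lower"]], upper = ci[["upper"]], level = level)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (the convention used
#' for printed percent values), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
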