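# Plot methods for the main result types.

#' Posterior densities of percent 2-HG reduction
#'
#' @param object An `hg_fit`.
#' @param ... Unused.
#' @return A ggplot: one density per treated arm.
#' @export
autoplot.hg_fit <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::filter(startsWith(.data$parameter, "reduction[")) |>
    dplyr::mutate(arm = gsub("^reduction\\[|\\]$", "", .data$parameter))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, fill = .data$arm)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::coord_cartesian(xlim = c(min(0, quantile(d$value, 0.001)), 100)) +
    ggplot2::labs(x = "posterior percent reduction in tumor 2-HG",
                  y = "density", fill = "arm") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of best percent change in SPD
#'
#' @param responses Tibble from [classify_responses()] (optionally with an
#'   `arm` column for fill).
#' @return A ggplot of sorted best percent changes, one bar per subject
#'   with measurable disease.
#' @export
plot_waterfall <- function(responses) {
  d <- responses |>
    dplyr::filter(!is.na(.data$best_percent_change)) |>
    dplyr::arrange(dplyr::desc(.data$best_percent_change)) |>
    dplyr::mutate(pos = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$best_percent_change,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-50, -25, 25), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "best % change in SPD from baseline",
                  fill = "best response") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Tumor 2-HG by arm, log scale
#'
#' @param subjects Subject tibble (needs `arm`, `tumor_2hg`).
#' @param externals Optional external-control tibble (`idh_status`,
#'   `tumor_2hg`).
#' @return A ggplot boxplot of tumor 2-HG on a log10 axis.
#' @export
plot_2hg_by_arm <- function(subjects, externals = NULL) {
  d <- tibble::tibble(group = subjects$arm, tumor_2hg = subjects$tumor_2hg)
  if (!is.null(externals)) {
    d <- dplyr::bind_rows(d, tibble::tibble(
      group = paste0("EXT_", externals$idh_status),
      tumor_2hg = externals$tumor_2hg
    ))
  }
  d <- dplyr::filter(d, !is.na(.data$tumor_2hg) & .data$tumor_2hg > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$tumor_2hg)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "tumor 2-HG (ug/g)") +
    ggplot2::theme_minimal()
}

#' Bar chart of normalized enrichment scores
#'
#' @param enrichment Tibble from [preranked_gsea()].
#' @param q_cutoff Sets with `q_value` at or below this are highlighted.
#' @return A ggplot of NES per gene set.
#' @export
plot_enrichment <- function(enrichment, q_cutoff = 0.05) {
  d <- enrichment |>
    dplyr::filter(!is.na(.data$nes)) |>
    dplyr::arrange(.data$nes) |>
    dplyr::mutate(set = factor(.data$set, levels = .data$set),
                  significant = .data$q_value <= q_cutoff)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nes, y = .data$set,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  fill = paste0("q <= ", q_cutoff)) +
    ggplot2::theme_minimal()
}
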