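# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment score (weight |rank|^1), gene-sampling permutation null,
# sign-matched NES normalization, permutation p-values with +1 continuity,
# and BH adjustment across retained sets.

#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path), class = "hg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                        character(1))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(name, desc, genes) {
    paste(c(name, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

# Weighted KS enrichment score for member positions `pos` (1-based, in the
# ranked list ordered by decreasing rank score) with weights |r|^1.
# The running sum increments by |r_i|/sum(|r_members|) at members and
# decrements by 1/(N - k) elsewhere; ES is the deviation of largest
# magnitude.  Only member positions need to be visited.
es_running_sum <- function(abs_r, pos) {
  n <- length(abs_r)
  k <- length(pos)
  pos <- sort(pos)
  w <- abs_r[pos]
  denom_hit <- sum(w)
  if (denom_hit == 0) return(0)
  miss_inc <- 1 / (n - k)
  cum_hit <- cumsum(w) / denom_hit
  misses_before <- (pos - seq_len(k)) * miss_inc  # misses strictly before pos_i
  peak <- cum_hit - misses_before                 # value just after each hit
  dip <- c(0, cum_hit[-k]) - misses_before        # value just before each hit
  hi <- max(peak)
  lo <- min(dip)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are ordered by decreasing rank score; each set's enrichment score
#' (ES) is the extreme deviation of the weighted Kolmogorov-Smirnov
#' running sum with weight `|rank|^1`.  The null distribution is built
#' from `n_perm` seeded random draws of equally sized gene sets from the
#' ranked list; NES divides the ES by the mean magnitude of the null ESs
#' with matching sign, and the permutation p-value uses the sign-matched
#' null with +1 continuity.  Sets whose intersection with the ranked list
#' falls outside `[min_size, max_size]` are dropped; genes absent from the
#' ranked list are ignored.
#'
#' @param ranked Tibble from [per_gene_association()] (columns `gene`,
#'   `rank`), or a named numeric vector of rank scores.
#' @param sets Named list of character vectors (see [read_gmt()]).
#' @param n_perm Number of null permutations.
#' @param min_size,max_size Retained set-size bounds after intersection.
#' @param seed Integer seed for the permutation draws.
#' @return Tibble, one row per retained set: `set`, `size`, `es`, `nes`,
#'   `p_value`, `q_value` (BH across retained sets).
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000,
                           min_size = 15, max_size = 500, seed = 1) {
  if (is.data.frame(ranked)) {
    r <- setNames(ranked$rank, ranked$gene)
  } else {
    r <- ranked
  }
  if (any(!is.finite(r))) {
    abort("rank scores must be finite", class = "hg_domain_error")
  }
  ord <- order(r, decreasing = TRUE)
  r <- r[ord]
  abs_r <- abs(r)
  genes <- names(r)
  n <- length(r)

  sizes <- vapply(sets, function(s) sum(s %in% genes), integer(1))
  skipped <- names(sets)[sizes == 0]
  if (length(skipped) > 0) {
    message("skipping set(s) with empty intersection: ",
            paste(skipped, collapse = ", "))
  }
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  sets <- sets[keep]
  sizes <- sizes[keep]
  if (length(sets) == 0) {
    return(tibble::tibble(set = character(), size = integer(), es = numeric(),
                          nes = numeric(), p_value = numeric(),
                          q_value = numeric()))
  }

  es_obs <- vapply(seq_along(sets), function(i) {
    es_running_sum(abs_r, which(genes %in% sets[[i]]))
  }, numeric(1))

  local_seed(seed)
  uniq_sizes <- sort(unique(sizes))
  null_by_size <- lapply(uniq_sizes, function(k) {
    vapply(seq_len(n_perm), function(p) {
      es_running_sum(abs_r, sample.int(n, k))
    }, numeric(1))
  })
  names(null_by_size) <- as.character(uniq_sizes)

  stats_tbl <- purrr::map_dfr(seq_along(sets), function(i) {
    null <- null_by_size[[as.character(sizes[i])]]
    es <- es_obs[i]
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    mean_same <- mean(abs(same))
    nes <- if (length(same) == 0 || mean_same == 0) NA_real_ else es / mean_same
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    tibble::tibble(set = names(sets)[i], size = sizes[i], es = es,
                   nes = nes, p_value = p)
  })
  dplyr::mutate(stats_tbl, q_value = bh_adjust(.data$p_value))
}
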