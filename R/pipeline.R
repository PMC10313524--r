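# End-to-end orchestration of the synthetic trial analysis:
# simulate -> filter -> fit -> summarize -> response -> associations,
# with per-stage seeds derived from the global seed, CSV outputs, and a
# manifest recording config hash, seeds, row counts and file hashes.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with a single global seed from
#' which every stochastic stage derives its own seed (simulate: seed,
#' lesions: seed + 1, expression: seed + 2, model: seed + 3,
#' enrichment: seed + 4).
#'
#' @param seed Global integer seed.
#' @param outdir Output directory (created if needed).
#' @param generator A [generator_config()].
#' @param model A [model_config()]; its `seed` is overridden by the
#'   derived stage seed.
#' @param response List: `level`, `rules` (a [response_rules()]).
#' @param associations List: `n_perm`, `min_size`, `max_size`,
#'   `n_random_sets`, `set_size` (random background sets are generated
#'   alongside the planted signature set so enrichment has a null field).
#' @param level Credible level for the model summaries.
#' @return List of class `hg_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            outdir = tempfile("hgrun"),
                            generator = generator_config(),
                            model = model_config(chains = 2, iterations = 4000,
                                                 burnin = 1000),
                            response = list(level = 0.95,
                                            rules = response_rules()),
                            associations = list(n_perm = 200, min_size = 15,
                                                max_size = 500,
                                                n_random_sets = 20,
                                                set_size = 30),
                            level = 0.95) {
  structure(
    list(seed = as.integer(seed), outdir = outdir, generator = generator,
         model = model, response = response, associations = associations,
         level = level),
    class = "hg_pipeline_config"
  )
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) {
    abort("pipeline config must be a list", class = "hg_validation_error")
  }
  for (section in c("seed", "outdir", "generator", "model", "response",
                    "associations")) {
    if (is.null(config[[section]])) {
      abort(paste0("pipeline config is missing section: ", section),
            class = "hg_validation_error")
    }
  }
  if (!inherits(config$generator, "hg_generator_config")) {
    abort("section 'generator' must be a generator_config()",
          class = "hg_validation_error")
  }
  if (!inherits(config$model, "hg_model_config")) {
    abort("section 'model' must be a model_config()",
          class = "hg_validation_error")
  }
  invisible(config)
}

#' Serialize / restore a pipeline configuration as YAML
#'
#' The YAML form is plain scalars and tables, so a configuration
#' round-trips through disk: `read_pipeline_config(write_pipeline_config(cfg, p))`
#' rebuilds an equivalent configuration.
#'
#' @param config An [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (writer) / the restored config (reader).
#' @export
write_pipeline_config <- function(config, path) {
  g <- config$generator
  lst <- list(
    seed = config$seed,
    outdir = config$outdir,
    level = config$level,
    generator = list(
      arm_specs = lapply(seq_len(nrow(g$arm_specs)), function(i) as.list(g$arm_specs[i, ])),
      ratios = lapply(g$ratios, as.list),
      biomarkers = lapply(seq_len(nrow(g$biomarkers)), function(i) as.list(g$biomarkers[i, ])),
      exclusion_probs = g$exclusion_probs,
      expression = g$expression,
      spd = g$spd
    ),
    model = unclass(config$model),
    response = list(level = config$response$level,
                    rules = config$response$rules),
    associations = config$associations
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  g <- lst$generator
  gen <- generator_config(
    arm_specs = dplyr::bind_rows(lapply(g$arm_specs, tibble::as_tibble)),
    ratios = lapply(g$ratios, unlist),
    biomarkers = dplyr::bind_rows(lapply(g$biomarkers, tibble::as_tibble)),
    exclusion_probs = g$exclusion_probs,
    expression = g$expression,
    spd = g$spd
  )
  m <- lst$model
  mdl <- model_config(m0 = m$m0, v0 = m$v0, a_tau = m$a_tau, b_tau = m$b_tau,
                      a_sigma = m$a_sigma, b_sigma = m$b_sigma,
                      chains = m$chains, iterations = m$iterations,
                      burnin = m$burnin, thin = m$thin, seed = m$seed,
                      fix_sigma2 = if (!is.null(m$fix_sigma2)) unlist(m$fix_sigma2))
  pipeline_config(
    seed = lst$seed, outdir = lst$outdir, generator = gen, model = mdl,
    response = list(level = lst$response$level,
                    rules = do.call(response_rules, lst$response$rules[
                      c("pr_pct", "mr_pct", "pd_pct", "confirm")])),
    associations = lst$associations, level = lst$level
  )
}

#' Write / read an expression matrix as TSV
#'
#' Genes x samples, tab-separated, header row of sample ids, first column
#' `gene`.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path TSV path.
#' @return `path` (writer) / the matrix (reader).
#' @export
write_expression_matrix <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$gene
  mat
}

write_stage_csv <- function(df, outdir, stage, name, manifest) {
  path <- file.path(outdir, paste0(name, ".csv"))
  readr::write_csv(df, path, na = "", progress = FALSE)
  dplyr::bind_rows(manifest, tibble::tibble(
    stage = stage, file = basename(path), rows = nrow(df),
    md5 = unname(tools::md5sum(path))
  ))
}

#' Run the full synthetic-trial analysis pipeline
#'
#' Executes simulate, filter, fit, summarize, response and associations in
#' order, writing each stage's outputs as CSV/TSV/GMT under
#' `config$outdir`.  Identical configurations produce identical outputs.
#' On a stage failure a `FAILED` marker naming the stage is written and
#' the error is re-signalled with the stage label; earlier outputs are
#' retained.
#'
#' @param config An [pipeline_config()].
#' @return A run manifest: list with `stages` (tibble `stage`, `status`),
#'   `files` (tibble `stage`, `file`, `rows`, `md5`), `seed`,
#'   `config_hash`, `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- tibble::tibble(stage = character(), file = character(),
                             rows = integer(), md5 = character())
  stages <- character()
  current <- "simulate"
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    current <<- stage
    fun()
    stages <<- c(stages, stage)
  }

  tryCatch({
    run_stage("simulate", function() {
      sim <- simulate_cohort(config$generator, seed = config$seed)
      state$subjects <- sim$subjects
      state$externals <- sim$externals
      treated_ids <- sim$subjects$subject_id[sim$subjects$arm != "UNTREATED"]
      state$lesions <- simulate_spd_series(config$generator, treated_ids,
                                           seed = config$seed + 1)
      covar_ok <- !is.na(sim$subjects$tumor_2hg) & sim$subjects$tumor_2hg > 0
      state$expr_subjects <- sim$subjects$subject_id[covar_ok]
      state$covariate <- log10(sim$subjects$tumor_2hg[covar_ok])
      ex <- simulate_expression(config$generator, state$covariate,
                                seed = config$seed + 2)
      colnames(ex$matrix) <- state$expr_subjects
      state$expr <- ex
      # planted signature plus seeded random background sets
      local_seed(config$seed + 2)
      genes <- rownames(ex$matrix)
      asc <- config$associations
      sets <- c(list(SIGNATURE_2HG = ex$signature_genes),
                setNames(lapply(seq_len(asc$n_random_sets), function(i) {
                  sample(genes, asc$set_size)
                }), sprintf("RANDOM_%02d", seq_len(asc$n_random_sets))))
      state$sets <- sets
      write_cohort_table(sim$subjects, file.path(config$outdir, "cohort.csv"))
      write_external_table(sim$externals, file.path(config$outdir, "externals.csv"))
      write_lesion_table(state$lesions, file.path(config$outdir, "lesions.csv"))
      write_expression_matrix(ex$matrix, file.path(config$outdir, "expression.tsv"))
      write_gmt(sets, file.path(config$outdir, "genesets.gmt"))
      for (f in c("cohort", "externals", "lesions")) {
        df <- switch(f, cohort = sim$subjects, externals = sim$externals,
                     lesions = state$lesions)
        manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
          stage = "simulate", file = paste0(f, ".csv"), rows = nrow(df),
          md5 = unname(tools::md5sum(file.path(config$outdir, paste0(f, ".csv"))))
        ))
      }
      for (f in c("expression.tsv", "genesets.gmt")) {
        manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
          stage = "simulate", file = f, rows = NA_integer_,
          md5 = unname(tools::md5sum(file.path(config$outdir, f)))
        ))
      }
    })

    run_stage("filter", function() {
      aset <- eligibility_filter(state$subjects)
      state$included <- aset$included
      manifest <<- write_stage_csv(aset$included, config$outdir, "filter",
                                   "included", manifest)
      manifest <<- write_stage_csv(aset$exclusions, config$outdir, "filter",
                                   "exclusions", manifest)
    })

    run_stage("fit", function() {
      groups <- make_group_data(state$included, state$externals)
      mcfg <- config$model
      mcfg$seed <- config$seed + 3L
      state$fit <- fit_borrowing_model(groups, mcfg)
      manifest <<- write_stage_csv(tidy(state$fit), config$outdir, "fit",
                                   "draws", manifest)
    })

    run_stage("summarize", function() {
      smry <- purrr::map_dfr(state$fit$treated, function(a) {
        dplyr::mutate(summarize_reduction(state$fit, a, config$level),
                      prob_lower = prob_treatment_lower(state$fit, a))
      })
      manifest <<- write_stage_csv(smry, config$outdir, "summarize",
                                   "reduction_summary", manifest)
      manifest <<- write_stage_csv(diagnostics(state$fit), config$outdir,
                                   "summarize", "diagnostics", manifest)
      state$summary <- smry
    })

    run_stage("response", function() {
      resp <- classify_responses(state$lesions, config$response$rules)
      resp <- dplyr::left_join(
        resp, state$subjects[c("subject_id", "arm")], by = "subject_id"
      )
      orrs <- resp |>
        dplyr::group_by(.data$arm) |>
        dplyr::group_modify(~orr(.x$category, config$response$level)) |>
        dplyr::ungroup()
      manifest <<- write_stage_csv(resp, config$outdir, "response",
                                   "responses", manifest)
      manifest <<- write_stage_csv(orrs, config$outdir, "response",
                                   "orr", manifest)
      state$responses <- resp
    })

    run_stage("associations", function() {
      asc <- config$associations
      gs <- per_gene_association(state$expr$matrix, state$covariate)
      enr <- preranked_gsea(gs, state$sets, n_perm = asc$n_perm,
                            min_size = asc$min_size, max_size = asc$max_size,
                            seed = config$seed + 4)
      sig_mat <- state$expr$matrix[state$expr$signature_genes, , drop = FALSE]
      cl <- top_split_clusters(log2(sig_mat), state$covariate)
      manifest <<- write_stage_csv(gs, config$outdir, "associations",
                                   "gene_stats", manifest)
      manifest <<- write_stage_csv(enr, config$outdir, "associations",
                                   "enrichment", manifest)
      manifest <<- write_stage_csv(cl$membership, config$outdir, "associations",
                                   "clusters", manifest)
    })
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", current, "\n", conditionMessage(e)),
               file.path(config$outdir, "FAILED"))
    abort(paste0("pipeline failed at stage '", current, "': ",
                 conditionMessage(e)), class = "hg_pipeline_error")
  })

  out <- list(
    stages = tibble::tibble(stage = stages, status = "completed"),
    files = manifest,
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    outdir = config$outdir
  )
  manifest_df <- dplyr::mutate(manifest, seed = config$seed,
                               config_hash = out$config_hash)
  readr::write_csv(manifest_df, file.path(config$outdir, "manifest.csv"),
                   progress = FALSE)
  out
}
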