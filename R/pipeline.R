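# Stable per-stage sub-seeding: one user seed drives every stage's stream
# independently of execution order.
stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 2654L) %% .Machine$integer.max
}

#' Assemble a run configuration
#'
#' @param counts_path,metadata_path Input TSVs; leave `NULL` to simulate a
#'   dataset instead (with [simulation_config()] defaults overridden by
#'   `simulate`).
#' @param out_dir Output directory (created if needed).
#' @param rng_seed Single seed; per-stage streams are derived from it.
#' @param simulate Named list of [simulation_config()] overrides.
#' @param css_quantile CSS quantile for normalization.
#' @param transfer_mode `"chain"` or `"seed_baseline"` for the transfer
#'   tables.
#' @param min_count,min_prevalence Detection rule for presence sets.
#' @param heritability_B,permanova_B Permutation counts.
#' @param glm_terms Fixed-effect terms for the transfer model.
#' @param robust_cluster Optional cluster column for robust errors.
#' @return A `tt_run_config` list.
#' @export
run_config <- function(counts_path = NULL, metadata_path = NULL,
                       out_dir = "tubertrace_out", rng_seed = 1L,
                       simulate = list(), css_quantile = 0.5,
                       transfer_mode = c("chain", "seed_baseline"),
                       min_count = 1L, min_prevalence = 1L,
                       heritability_B = 199L, permanova_B = 199L,
                       glm_terms = c("compartment", "cultivar", "transition"),
                       robust_cluster = NULL) {
  transfer_mode <- match.arg(transfer_mode)
  if (!is.null(counts_path) && !file.exists(counts_path)) {
    abort(paste0("counts file not found: ", counts_path))
  }
  if (!is.null(metadata_path) && !file.exists(metadata_path)) {
    abort(paste0("metadata file not found: ", metadata_path))
  }
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 out_dir = out_dir, rng_seed = as.integer(rng_seed),
                 simulate = simulate, css_quantile = css_quantile,
                 transfer_mode = transfer_mode, min_count = min_count,
                 min_prevalence = min_prevalence,
                 heritability_B = as.integer(heritability_B),
                 permanova_B = as.integer(permanova_B),
                 glm_terms = glm_terms, robust_cluster = robust_cluster),
            class = "tt_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key/value document mirroring [run_config()] arguments; a `simulate:`
#' block maps onto [simulation_config()] overrides.
#'
#' @param path YAML file path.
#' @return A `tt_run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) abort("the yaml package is required to read config files")
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Chains the stages in dependency order — load or simulate a dataset,
#' CSS-normalize, classify transfer and compute flows, build trials and fit
#' the binomial transfer model, screen heritability on the chain-vertical
#' taxa per context, compute alpha diversity, and run PERMANOVA on
#' Bray-Curtis dissimilarities of the normalized table. Every result TSV
#' carries a provenance comment header, and a machine-readable JSON manifest
#' records inputs, parameters, seed, and output checksums. Logging goes to
#' standard error; results go to files only.
#'
#' @param config A `tt_run_config` from [run_config()] or
#'   [read_run_config()].
#' @return Invisibly, a list with the in-memory results and the manifest;
#'   files are written under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "tt_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[tubertrace] ", ...)
  outputs <- character()
  emit <- function(x, name, stage) {
    path <- file.path(config$out_dir, name)
    drop_cols <- names(x)[vapply(x, is.list, logical(1L))]
    write_result_tsv(x[setdiff(names(x), drop_cols)], path, stage)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }

  status <- "ok"
  results <- list()
  tryCatch({
    if (is.null(config$counts_path)) {
      log_msg("simulating dataset")
      sim_args <- modifyList(list(rng_seed = stage_seed(config$rng_seed, "simulate")),
                             config$simulate)
      sim <- simulate_dataset(do.call(simulation_config, sim_args))
      ds <- sim$dataset
      write_count_table(ds$counts, file.path(config$out_dir, "counts.tsv"))
      write_metadata(ds$metadata, file.path(config$out_dir, "metadata.tsv"))
      emit(truth_report(sim$truth), "truth.tsv", "simulate")
      outputs <- c(outputs, file.path(config$out_dir, c("counts.tsv", "metadata.tsv")))
      results$truth <- sim$truth
    } else {
      log_msg("reading dataset")
      ds <- validate_dataset(read_count_table(config$counts_path),
                             read_metadata(config$metadata_path))
    }
    results$dataset <- ds

    log_msg("CSS normalization")
    norm <- css_normalize(ds$counts, quantile = config$css_quantile)
    emit(norm, "normalized.tsv", "normalize")
    results$normalized <- norm

    log_msg("transfer classification")
    pres <- presence_sets(ds, min_count = config$min_count,
                          min_prevalence = config$min_prevalence)
    contexts <- distinct(ds$metadata[ds$metadata$generation != "seed" &
                                       ds$metadata$compartment != "tare_soil",
                                     c("compartment", "cultivar")])
    cls <- purrr::pmap(contexts, function(compartment, cultivar) {
      classify_transfer(pres, compartment = as.character(compartment),
                        cultivar = cultivar, mode = config$transfer_mode)
    })
    cls_tbl <- dplyr::bind_rows(cls)
    emit(cls_tbl, "transfer.tsv", "transfer")
    results$transfer <- cls_tbl

    flow_tbl <- purrr::pmap(contexts, function(compartment, cultivar) {
      stages <- tibble(generation = tt_generation_levels,
                       compartment = as.character(compartment), cultivar = cultivar)
      fl <- flow_proportions(pres, stages)
      fl
    }) |> dplyr::bind_rows()
    emit(flow_tbl, "flow.tsv", "flow")
    results$flow <- flow_tbl

    log_msg("transfer-probability model")
    seed_sizes <- purrr::pmap(contexts, function(compartment, cultivar) {
      tibble(compartment = as.character(compartment), cultivar = cultivar,
             n_seed = length(presence_lookup(pres, "seed", as.character(compartment),
                                             cultivar, field = tt_no_field)))
    }) |> dplyr::bind_rows()
    trials <- build_trials(cls_tbl, seed_sizes)
    glm_terms <- intersect(config$glm_terms, names(trials))
    glm_terms <- glm_terms[vapply(glm_terms, function(v) length(unique(trials[[v]])) > 1L, logical(1L))]
    model <- fit_binomial_glm(trials, terms = glm_terms,
                              robust_cluster = config$robust_cluster)
    emit(tidy(model), "model_coefficients.tsv", "transfer-model")
    emit(model$wald, "model_wald.tsv", "transfer-model")
    emit(model$emmeans, "model_emmeans.tsv", "transfer-model")
    results$trials <- trials
    results$model <- model

    log_msg("heritability screen")
    h2 <- purrr::pmap(contexts, function(compartment, cultivar) {
      ctx_cls <- cls_tbl[cls_tbl$compartment == as.character(compartment) &
                           cls_tbl$cultivar == cultivar &
                           cls_tbl$generation == "granddaughter", ]
      taxa <- unlist(ctx_cls$vertical_taxa)
      res <- heritability_screen(ds, taxa, cultivar = cultivar,
                                 compartment = as.character(compartment),
                                 B = config$heritability_B,
                                 rng_seed = stage_seed(config$rng_seed, "heritability"))
      if (nrow(res) > 0L) {
        res$compartment <- as.character(compartment)
        res$cultivar <- cultivar
      }
      res
    }) |> dplyr::bind_rows()
    emit(h2, "heritability.tsv", "heritability")
    results$heritability <- h2

    log_msg("alpha diversity")
    alpha <- alpha_diversity(ds$counts) |> left_join(ds$metadata, by = "sample_id")
    emit(alpha, "alpha_diversity.tsv", "diversity")
    results$alpha <- alpha

    log_msg("PERMANOVA")
    d <- bray_curtis(norm)
    pmv_terms <- c("generation", "compartment", "cultivar")
    pmv_terms <- pmv_terms[vapply(pmv_terms, function(v) {
      length(unique(as.character(ds$metadata[[v]]))) > 1L
    }, logical(1L))]
    pmv <- permanova(d, ds$metadata,
                     terms = pmv_terms,
                     permutations = config$permanova_B,
                     rng_seed = stage_seed(config$rng_seed, "permanova"))
    emit(pmv, "permanova.tsv", "permanova")
    results$permanova <- pmv
  }, error = function(e) {
    status <<- paste0("failed: ", conditionMessage(e))
    log_msg("pipeline error: ", conditionMessage(e))
  })

  manifest <- list(
    package = "tubertrace",
    version = as.character(packageVersion("tubertrace")),
    status = status,
    rng_seed = config$rng_seed,
    parameters = config[setdiff(names(config), c("counts_path", "metadata_path", "out_dir"))],
    inputs = list(counts = config$counts_path, metadata = config$metadata_path),
    outputs = lapply(setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (status != "ok") abort(status)
  invisible(list(results = results, manifest = manifest))
}
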