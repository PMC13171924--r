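#' Configuration for the multi-generation community simulator
#'
#' Defaults emulate a scaled-down field-trial design: three ordered tuber
#' generations (seed, daughter, granddaughter), flesh and peel compartments
#' plus granddaughter tare soil, two cultivars, two fields, and ten replicate
#' tubers per group. A small vertically retained core of seed taxa carries a
#' generation-stable log-abundance signal; a much larger, generation-increasing
#' horizontally acquired fraction is injected per field, larger in peel than
#' in flesh, with the tare-soil pool partially overlapping the peel pool.
#'
#' @param seed_richness_flesh,seed_richness_peel Number of taxa founding each
#'   seed-tuber compartment community (per cultivar).
#' @param retention_prob Named probabilities (per compartment) that a taxon
#'   present at one generation persists into the next; applied independently
#'   at each transition, so chained across generations.
#' @param horizontal_pool_size Named list `daughter`/`granddaughter`, each a
#'   named vector by compartment: number of newly acquired taxa injected per
#'   (generation, compartment, field).
#' @param tare_soil_pool_size Taxa per field in the granddaughter tare-soil
#'   community.
#' @param tare_peel_overlap Fraction of each field's tare-soil pool drawn from
#'   that field's granddaughter peel horizontal pool.
#' @param n_replicates Replicate tubers per group.
#' @param cultivars,fields Level names.
#' @param vg,ve Between-generation and residual variance components of log10
#'   relative abundance for vertically retained (non-null) taxa; the true
#'   broad-sense heritability of such a taxon is `vg / (vg + ve)`.
#' @param null_fraction Fraction of retained taxa simulated with no
#'   generation effect (true H2 = 0).
#' @param base_log10_mean,base_log10_sd Normal distribution of baseline
#'   log10 relative abundances.
#' @param library_size_mean,library_size_shape Gamma library-size model
#'   (mean and shape); drawn per sample.
#' @param dispersion Gamma-Poisson (negative binomial) overdispersion size
#'   parameter for counts.
#' @param detection_guarantee If `TRUE` (default), every taxon marked present
#'   in a group is observed with count >= 1 in every sample of that group,
#'   separating classification logic from stochastic detection noise.
#' @param rng_seed Integer seed; identical configs and seeds give
#'   byte-identical output.
#' @return A `tt_sim_config` list.
#' @export
simulation_config <- function(seed_richness_flesh = 100,
                              seed_richness_peel = 200,
                              retention_prob = c(flesh = 0.20, peel = 0.12),
                              horizontal_pool_size = list(
                                daughter = c(flesh = 150, peel = 300),
                                granddaughter = c(flesh = 250, peel = 500)
                              ),
                              tare_soil_pool_size = 400,
                              tare_peel_overlap = 0.3,
                              n_replicates = 10,
                              cultivars = c("Nadine", "RoyalBlue"),
                              fields = c("F1", "F2"),
                              vg = 0.4,
                              ve = 0.1,
                              null_fraction = 0.3,
                              base_log10_mean = -3,
                              base_log10_sd = 0.7,
                              library_size_mean = 30000,
                              library_size_shape = 8,
                              dispersion = 5,
                              detection_guarantee = TRUE,
                              rng_seed = 1L) {
  cfg <- list(
    seed_richness_flesh = seed_richness_flesh,
    seed_richness_peel = seed_richness_peel,
    retention_prob = retention_prob,
    horizontal_pool_size = horizontal_pool_size,
    tare_soil_pool_size = tare_soil_pool_size,
    tare_peel_overlap = tare_peel_overlap,
    n_replicates = n_replicates,
    cultivars = cultivars,
    fields = fields,
    vg = vg, ve = ve,
    null_fraction = null_fraction,
    base_log10_mean = base_log10_mean,
    base_log10_sd = base_log10_sd,
    library_size_mean = library_size_mean,
    library_size_shape = library_size_shape,
    dispersion = dispersion,
    detection_guarantee = detection_guarantee,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    seed_richness_flesh >= 1, seed_richness_peel >= 1,
    all(retention_prob >= 0 & retention_prob <= 1),
    all(c("flesh", "peel") %in% names(retention_prob)),
    n_replicates >= 1, vg >= 0, ve >= 0, vg + ve > 0,
    null_fraction >= 0, null_fraction <= 1,
    tare_peel_overlap >= 0, tare_peel_overlap <= 1,
    library_size_mean > 0, library_size_shape > 0, dispersion > 0
  )
  structure(cfg, class = "tt_sim_config")
}

#' Simulate a multi-generation, multi-compartment ASV dataset
#'
#' Generates counts by the following scheme, per cultivar: (i) seed-compartment
#' communities with baseline log10 relative abundances drawn from a normal;
#' (ii) each seed taxon independently retained into the next generation's same
#' compartment with probability `retention_prob[compartment]`, chained across
#' the two transitions; (iii) `horizontal_pool_size` new taxa injected per
#' (generation, compartment, field), plus a field-specific tare-soil pool
#' overlapping the peel pool; (iv) for retained non-null taxa, a per-(taxon,
#' generation) offset `~ Normal(0, vg)` shared by all samples of that
#' generation plus a per-sample residual `~ Normal(0, ve)`, on the log10
#' scale; (v) per-sample renormalization to proportions and gamma-Poisson
#' count draws given a gamma library size; (vi) optionally, guaranteed
#' detection (count >= 1) wherever a taxon is marked present.
#'
#' @param config A [simulation_config()].
#' @return A list with `dataset` (a `tt_dataset`) and `truth`, a per-taxon
#'   ground-truth tibble: origin label (`vertical_core` / `horizontal`),
#'   origin generation, cultivar, compartment, field pool (horizontal taxa),
#'   retention indicators per generation, and `true_h2` (NA for horizontal
#'   taxa, 0 for null-fraction taxa). The truth tibble carries the configured
#'   per-compartment retention probabilities as attribute `retention_prob`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "tt_sim_config"))
  cfg <- config
  set.seed(cfg$rng_seed)
  gens <- tt_generation_levels

  truth_rows <- list()
  # presence[[cultivar]][[group_label]] -> character vector of taxon ids
  presence <- list()
  taxon_attr <- list()  # per taxon: base, null, compartment etc.

  group_label <- function(gen, comp, field) paste(gen, comp, field, sep = "|")

  for (cv in cfg$cultivars) {
    pres <- list()
    for (comp in c("flesh", "peel")) {
      n_seed <- if (comp == "flesh") cfg$seed_richness_flesh else cfg$seed_richness_peel
      ids <- sprintf("ASV_%s_%s_seed_%04d", cv, comp, seq_len(n_seed))
      base <- rnorm(n_seed, cfg$base_log10_mean, cfg$base_log10_sd)
      is_null <- runif(n_seed) < cfg$null_fraction
      ret1 <- runif(n_seed) < cfg$retention_prob[[comp]]
      ret2 <- ret1 & (runif(n_seed) < cfg$retention_prob[[comp]])
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        taxon_id = ids, cultivar = cv, compartment = comp,
        origin = "vertical_core", origin_generation = "seed",
        field_pool = NA_character_,
        present_seed = TRUE, retained_daughter = ret1, retained_granddaughter = ret2,
        null_taxon = is_null,
        true_h2 = ifelse(is_null, 0, cfg$vg / (cfg$vg + cfg$ve))
      )
      # Generation offsets: per (taxon, generation), shared across fields and
      # replicates, zero for null taxa -> one-way random-effects generating model.
      offs <- matrix(0, n_seed, length(gens), dimnames = list(ids, gens))
      active <- !is_null
      offs[active, ] <- rnorm(sum(active) * length(gens), 0, sqrt(cfg$vg))
      for (k in seq_len(n_seed)) {
        taxon_attr[[ids[[k]]]] <- list(base = base[[k]], offsets = offs[k, ],
                                       resid_sd = if (is_null[[k]]) sqrt(cfg$vg + cfg$ve) else sqrt(cfg$ve))
      }
      pres[[group_label("seed", comp, tt_no_field)]] <- ids
      for (f in cfg$fields) {
        pres[[group_label("daughter", comp, f)]] <- ids[ret1]
        pres[[group_label("granddaughter", comp, f)]] <- ids[ret2]
      }
    }
    # Horizontally acquired taxa: new per (generation, compartment, field)
    for (gen in c("daughter", "granddaughter")) {
      for (comp in c("flesh", "peel")) {
        n_h <- cfg$horizontal_pool_size[[gen]][[comp]]
        for (f in cfg$fields) {
          if (n_h < 1) next
          ids <- sprintf("ASV_%s_%s_%s_%s_h%04d", cv, comp, gen, f, seq_len(n_h))
          base <- rnorm(n_h, cfg$base_log10_mean, cfg$base_log10_sd)
          truth_rows[[length(truth_rows) + 1L]] <- tibble(
            taxon_id = ids, cultivar = cv, compartment = comp,
            origin = "horizontal", origin_generation = gen, field_pool = f,
            present_seed = FALSE, retained_daughter = gen == "daughter",
            retained_granddaughter = gen == "granddaughter",
            null_taxon = NA, true_h2 = NA_real_
          )
          for (k in seq_len(n_h)) {
            taxon_attr[[ids[[k]]]] <- list(base = base[[k]],
                                           offsets = setNames(numeric(length(gens)), gens),
                                           resid_sd = sqrt(cfg$vg + cfg$ve))
          }
          pres[[group_label(gen, comp, f)]] <- c(pres[[group_label(gen, comp, f)]], ids)
        }
      }
    }
    # Tare soil: field-specific pool with configurable overlap with that
    # field's granddaughter peel horizontal pool.
    for (f in cfg$fields) {
      n_t <- cfg$tare_soil_pool_size
      if (n_t >= 1) {
        peel_pool <- grep(sprintf("ASV_%s_peel_granddaughter_%s_h", cv, f),
                          names(taxon_attr), value = TRUE, fixed = TRUE)
        n_overlap <- min(length(peel_pool), round(cfg$tare_peel_overlap * n_t))
        shared <- if (n_overlap > 0) sample(peel_pool, n_overlap) else character(0)
        n_new <- n_t - n_overlap
        new_ids <- if (n_new > 0) sprintf("ASV_%s_tare_%s_s%04d", cv, f, seq_len(n_new)) else character(0)
        if (n_new > 0) {
          base <- rnorm(n_new, cfg$base_log10_mean, cfg$base_log10_sd)
          truth_rows[[length(truth_rows) + 1L]] <- tibble(
            taxon_id = new_ids, cultivar = cv, compartment = "tare_soil",
            origin = "horizontal", origin_generation = "granddaughter",
            field_pool = f, present_seed = FALSE, retained_daughter = FALSE,
            retained_granddaughter = TRUE, null_taxon = NA, true_h2 = NA_real_
          )
          for (k in seq_len(n_new)) {
            taxon_attr[[new_ids[[k]]]] <- list(base = base[[k]],
                                               offsets = setNames(numeric(length(gens)), gens),
                                               resid_sd = sqrt(cfg$vg + cfg$ve))
          }
        }
        pres[[group_label("granddaughter", "tare_soil", f)]] <- c(shared, new_ids)
      }
    }
    presence[[cv]] <- pres
  }

  truth <- dplyr::bind_rows(truth_rows)
  all_taxa <- truth$taxon_id
  if (anyDuplicated(all_taxa)) abort("internal error: duplicate simulated taxon ids")

  # Sample sheet
  md_rows <- list()
  for (cv in cfg$cultivars) {
    for (comp in c("flesh", "peel")) {
      md_rows[[length(md_rows) + 1L]] <- tidyr::expand_grid(
        generation = "seed", compartment = comp, cultivar = cv,
        field = tt_no_field, replicate = seq_len(cfg$n_replicates))
      md_rows[[length(md_rows) + 1L]] <- tidyr::expand_grid(
        generation = c("daughter", "granddaughter"), compartment = comp,
        cultivar = cv, field = cfg$fields, replicate = seq_len(cfg$n_replicates))
    }
    if (cfg$tare_soil_pool_size >= 1) {
      md_rows[[length(md_rows) + 1L]] <- tidyr::expand_grid(
        generation = "granddaughter", compartment = "tare_soil", cultivar = cv,
        field = cfg$fields, replicate = seq_len(cfg$n_replicates))
    }
  }
  md <- dplyr::bind_rows(md_rows)
  if (nrow(md) == 0L) abort("configuration yields zero samples")
  md$sample_id <- sprintf("S%04d_%s_%s_%s_%s_r%02d", seq_len(nrow(md)),
                          substr(md$generation, 1, 2), md$compartment,
                          md$cultivar, gsub("[^A-Za-z0-9]", "", md$field), md$replicate)

  counts <- matrix(0L, nrow = length(all_taxa), ncol = nrow(md),
                   dimnames = list(all_taxa, md$sample_id))
  base_vec <- vapply(taxon_attr, `[[`, numeric(1L), "base")[all_taxa]
  resid_sd_vec <- vapply(taxon_attr, `[[`, numeric(1L), "resid_sd")[all_taxa]
  offsets_mat <- t(vapply(taxon_attr, `[[`, setNames(numeric(3), gens), "offsets"))[all_taxa, , drop = FALSE]

  for (j in seq_len(nrow(md))) {
    gl <- group_label(md$generation[[j]], as.character(md$compartment[[j]]), md$field[[j]])
    taxa_j <- presence[[md$cultivar[[j]]]][[gl]]
    if (length(taxa_j) == 0L) next
    idx <- match(taxa_j, all_taxa)
    log_ab <- base_vec[idx] + offsets_mat[idx, md$generation[[j]]] +
      rnorm(length(idx), 0, resid_sd_vec[idx])
    w <- 10^log_ab
    p <- w / sum(w)
    lib <- max(1000, round(rgamma(1L, shape = cfg$library_size_shape,
                                  scale = cfg$library_size_mean / cfg$library_size_shape)))
    # gamma-Poisson mixture -> negative binomial marginal counts
    lambda <- lib * p * rgamma(length(p), shape = cfg$dispersion, rate = cfg$dispersion)
    cts <- rpois(length(p), lambda)
    if (cfg$detection_guarantee) cts <- pmax(cts, 1L)
    counts[idx, j] <- as.integer(cts)
  }

  ds <- validate_dataset(counts, md[, c("sample_id", "generation", "compartment",
                                        "cultivar", "field", "replicate")])
  attr(truth, "retention_prob") <- cfg$retention_prob
  list(dataset = ds, truth = truth)
}

#' Flatten a simulation truth ledger for TSV output
#'
#' @param truth The truth tibble from [simulate_dataset()].
#' @return A flat tibble with one row per simulated taxon, suitable for
#'   [write_result_tsv()] and exact round-tripping through TSV.
#' @export
truth_report <- function(truth) {
  stopifnot(is.data.frame(truth), "taxon_id" %in% names(truth))
  as_tibble(truth) |>
    select(all_of(c("taxon_id", "cultivar", "compartment", "origin",
                    "origin_generation", "field_pool", "present_seed",
                    "retained_daughter", "retained_granddaughter",
                    "null_taxon", "true_h2")))
}

#' Simulate per-taxon abundance under the one-way generation model
#'
#' Draws transformed abundances from `mu + G_i + e_ijk` with
#' `G_i ~ N(0, vg)` per generation and `e_ijk ~ N(0, ve)` per observation —
#' the generating model whose variance decomposition the heritability
#' estimator targets, with true H2 `= vg / (vg + ve)`.
#'
#' @param n_generations Number of generation levels.
#' @param n_replicates Observations per generation.
#' @param vg,ve Variance components.
#' @param mu Grand mean.
#' @return A tibble with columns `generation` (factor) and `value`.
#' @export
simulate_taxon_abundance <- function(n_generations = 3, n_replicates = 10,
                                     vg = 0.4, ve = 0.1, mu = 0) {
  g_eff <- rnorm(n_generations, 0, sqrt(vg))
  tibble(
    generation = factor(rep(seq_len(n_generations), each = n_replicates)),
    value = mu + rep(g_eff, each = n_replicates) +
      rnorm(n_generations * n_replicates, 0, sqrt(ve))
  )
}
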