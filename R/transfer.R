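#' Per-group taxon presence sets
#'
#' Presence is decided on RAW counts: a taxon is present in a group when it
#' has at least `min_count` reads in at least `min_prevalence` samples of
#' that group. The default (1 read in 1 sample) is the weakest rule and makes
#' reported set sizes plain counts of detected taxa.
#'
#' @param ds A `tt_dataset`.
#' @param by Grouping factors, as in [group_samples()].
#' @param min_count Minimum reads per sample for detection.
#' @param min_prevalence Minimum number of qualifying samples.
#' @return A `tt_presence` tibble: grouping columns, `n_samples`, `n_taxa`,
#'   and a `taxa` list-column of taxon-id character vectors. Empty groups map
#'   to empty sets.
#' @export
presence_sets <- function(ds, by = c("generation", "compartment", "cultivar", "field"),
                          min_count = 1L, min_prevalence = 1L) {
  stopifnot(inherits(ds, "tt_dataset"), min_count >= 1L, min_prevalence >= 1L)
  groups <- group_samples(ds, by)
  taxa_sets <- purrr::map(groups$sample_ids, function(ids) {
    sub <- ds$counts[, ids, drop = FALSE]
    hits <- rowSums(sub >= min_count)
    rownames(sub)[hits >= min_prevalence]
  })
  out <- groups |>
    mutate(n_taxa = lengths(taxa_sets), taxa = taxa_sets)
  attr(out, "min_count") <- min_count
  attr(out, "min_prevalence") <- min_prevalence
  class(out) <- c("tt_presence", class(out))
  out
}

presence_lookup <- function(presence, generation, compartment = NULL,
                            cultivar = NULL, field = NULL) {
  sel <- rep(TRUE, nrow(presence))
  if ("generation" %in% names(presence)) sel <- sel & as.character(presence$generation) == generation
  if (!is.null(compartment) && "compartment" %in% names(presence)) {
    sel <- sel & as.character(presence$compartment) == compartment
  }
  if (!is.null(cultivar) && "cultivar" %in% names(presence)) {
    sel <- sel & presence$cultivar == cultivar
  }
  if (!is.null(field) && "field" %in% names(presence)) {
    sel <- sel & presence$field == field
  }
  unique(unlist(presence$taxa[sel]))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Classify taxa as vertically transferred or horizontally acquired
#'
#' For each post-seed generation `g` with present set `A_g` and seed set
#' `A_0`: in `seed_baseline` mode vertical taxa are `A_g` intersected with
#' `A_0`; in `chain` mode they must additionally be present at every
#' intermediate generation (`A_g` intersected with all prior generations'
#' sets). Horizontal taxa are the remainder of `A_g`, so the two sets
#' partition the generation's community. Percentages are set size over
#' `|A_g|` times 100. Seed tubers predate the field trials, so when the
#' context names a field the seed set is taken from the field-missing seed
#' group of the same cultivar and compartment.
#'
#' @param presence A `tt_presence` from [presence_sets()].
#' @param compartment,cultivar,field Context; `field = NULL` pools fields.
#' @param mode `"seed_baseline"` (default, per-generation percentages) or
#'   `"chain"` (presence required in every prior generation).
#' @return A `tt_transfer` tibble with one row per post-seed generation:
#'   context columns, `n_present`, `n_vertical`, `n_horizontal`,
#'   `vertical_pct`, `horizontal_pct` (exact), rounded integer percentages
#'   (half away from zero), and `vertical_taxa` / `horizontal_taxa`
#'   list-columns. Percentages are `NA` (with a warning) for empty
#'   generations.
#' @export
classify_transfer <- function(presence, compartment, cultivar = NULL, field = NULL,
                              mode = c("seed_baseline", "chain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(presence, "tt_presence"))
  seed_set <- presence_lookup(presence, "seed", compartment, cultivar, field = tt_no_field)
  if (length(seed_set) == 0L) {
    seed_set <- presence_lookup(presence, "seed", compartment, cultivar, field = NULL)
  }
  if (length(seed_set) == 0L) {
    abort(paste0("seed-generation set is empty for compartment '", compartment, "'",
                 if (!is.null(cultivar)) paste0(", cultivar '", cultivar, "'") else ""))
  }
  later <- tt_generation_levels[-1L]
  cum_prior <- seed_set
  rows <- purrr::map(later, function(gen) {
    a_g <- presence_lookup(presence, gen, compartment, cultivar, field)
    vertical <- if (mode == "seed_baseline") intersect(a_g, seed_set) else intersect(a_g, cum_prior)
    horizontal <- setdiff(a_g, vertical)
    if (mode == "chain") cum_prior <<- vertical
    n <- length(a_g)
    if (n == 0L) {
      warn(paste0("no taxa present at generation '", gen, "' in this context; percentages are NA"))
      vp <- hp <- NA_real_
    } else {
      vp <- 100 * length(vertical) / n
      hp <- 100 * length(horizontal) / n
    }
    tibble(
      generation = gen, compartment = compartment,
      cultivar = cultivar %||% NA_character_, field = field %||% NA_character_,
      mode = mode, n_present = n,
      n_vertical = length(vertical), n_horizontal = length(horizontal),
      vertical_pct = vp, horizontal_pct = hp,
      vertical_pct_rounded = round_half_away(vp),
      horizontal_pct_rounded = round_half_away(hp),
      vertical_taxa = list(sort(vertical)), horizontal_taxa = list(sort(horizontal))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tt_transfer", class(out))
  out
}

#' Stage-wise retention flow proportions
#'
#' Follows one taxon set through an ordered sequence of groups, the way a
#' Sankey diagram does: the first stage's entering set is the first group's
#' present taxa; each later stage's entering set is the previous stage's
#' retained set, and its retained set is the intersection with that stage's
#' present taxa. Each stage's percentage is retained over entering, reported
#' exact and rounded to the nearest integer (half away from zero).
#'
#' @param presence A `tt_presence` built with grouping factors matching the
#'   columns used in `stages`.
#' @param stages A data frame of ordered stage keys; columns must name
#'   grouping factors present in `presence` (e.g. `generation`,
#'   `compartment`, `cultivar`, `field`). At least 2 rows.
#' @return A `tt_flow` tibble with per-stage `n_entering`, `n_retained`,
#'   `stage_pct` (exact) and `stage_pct_rounded`, plus a `retained_taxa`
#'   list-column. An empty entering set gives `NA` percentages with a
#'   warning.
#' @export
flow_proportions <- function(presence, stages) {
  stopifnot(inherits(presence, "tt_presence"))
  stages <- as_tibble(stages)
  if (nrow(stages) < 2L) abort("flow needs at least 2 stages")
  stage_set <- function(i) {
    args <- as.list(stages[i, , drop = FALSE])
    presence_lookup(presence,
                    generation = as.character(args$generation),
                    compartment = if (!is.null(args$compartment)) as.character(args$compartment) else NULL,
                    cultivar = if (!is.null(args$cultivar)) as.character(args$cultivar) else NULL,
                    field = if (!is.null(args$field)) as.character(args$field) else NULL)
  }
  entering <- stage_set(1L)
  rows <- list()
  for (i in 2:nrow(stages)) {
    present_i <- stage_set(i)
    retained <- intersect(entering, present_i)
    if (length(entering) == 0L) {
      warn(paste0("entering set empty at stage ", i, "; stage_pct is NA"))
      pct <- NA_real_
    } else {
      pct <- 100 * length(retained) / length(entering)
    }
    rows[[i - 1L]] <- dplyr::bind_cols(
      stages[i, , drop = FALSE],
      tibble(stage = i - 1L, n_entering = length(entering),
             n_retained = length(retained), stage_pct = pct,
             stage_pct_rounded = round_half_away(pct),
             retained_taxa = list(sort(retained)))
    )
    entering <- retained
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tt_flow", class(out))
  out
}

#' Shared and unique taxa across groups (Venn set sizes)
#'
#' For every nonempty subset of the supplied groups, counts the taxa present
#' in exactly those groups; the counts over all subsets sum to the size of
#' the union.
#'
#' @param sets A named list of 2-6 taxon-id character vectors, or a
#'   `tt_presence` subset with 2-6 rows (group labels are built from its
#'   grouping columns).
#' @return A tibble with `members` (a `+`-joined label of the groups in the
#'   subset), one logical column per group, and `n_taxa`.
#' @export
shared_unique <- function(sets) {
  if (inherits(sets, "tt_presence")) {
    labels <- apply(sets[setdiff(names(sets), c("n_samples", "sample_ids", "n_taxa", "taxa"))],
                    1L, function(r) paste(r[!is.na(r) & r != ""], collapse = ":"))
    sets <- setNames(sets$taxa, labels)
  }
  if (!is.list(sets) || is.null(names(sets))) abort("sets must be a named list of taxon-id vectors")
  k <- length(sets)
  if (k < 2L || k > 6L) abort("shared_unique supports 2-6 groups")
  all_taxa <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_taxa %in% s, logical(length(all_taxa)))
  if (length(all_taxa) == 1L) member <- matrix(member, nrow = 1L, dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == p)))
  })
  out <- as_tibble(patterns)
  out$members <- apply(patterns, 1L, function(p) paste(names(sets)[as.logical(p)], collapse = "+"))
  out$n_taxa <- as.integer(counts)
  select(out, all_of(c("members", names(sets), "n_taxa")))
}
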