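# One-way random-effects layout summaries used by both the REML fit and the
# closed-form ANOVA (method-of-moments) route.
oneway_sums <- function(values, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2L) abort("need at least 2 generations")
  n_i <- as.vector(table(g))
  if (any(n_i < 2L)) abort("every generation needs at least 2 observations")
  means <- tapply(values, g, mean)
  ssw <- sum((values - means[as.integer(g)])^2)
  list(g = g, n_i = n_i, means = as.numeric(means), ssw = ssw,
       N = length(values), a = nlevels(g))
}

# Truncated ANOVA estimator; equals REML on balanced layouts (interior
# solutions coincide; at the boundary both give vg = 0, hence H2 = 0).
anova_components <- function(values, labels) {
  s <- oneway_sums(values, labels)
  grand <- mean(values)
  ssb <- sum(s$n_i * (s$means - grand)^2)
  msb <- ssb / (s$a - 1)
  msw <- s$ssw / (s$N - s$a)
  n0 <- (s$N - sum(s$n_i^2) / s$N) / (s$a - 1)
  vg <- max(0, (msb - msw) / n0)
  list(mu = grand, vg = vg, ve = msw, msb = msb, msw = msw, n0 = n0)
}

h2_from_components <- function(vg, ve) {
  if (vg + ve <= 0) 0 else vg / (vg + ve)
}

#' One-way REML variance components of transformed abundance
#'
#' Fits the random-generation model `value_ijk = mu + G_i + e_ijk` with
#' `G_i ~ N(0, vg)` and `e_ijk ~ N(0, ve)` by restricted maximum likelihood.
#' The REML criterion is profiled down to the single ratio
#' `lambda = vg / ve` and minimized by Brent search on `[0, 1e6]`
#' (tolerance 1e-10), truncating at the boundary `vg = 0`. On balanced
#' layouts with an interior optimum the REML solution coincides with the
#' ANOVA method-of-moments estimator `vg = (MSB - MSW) / n0`, `ve = MSW`,
#' and is computed by that closed form to avoid optimizer round-off.
#'
#' @param values Numeric vector of transformed abundances.
#' @param labels Generation label per value; at least 2 levels with at least
#'   2 observations each.
#' @return A `tt_varcomp` tibble (one row): `mu`, `vg`, `ve`, `h2`,
#'   `n_groups`, `group_sizes` (list-column).
#' @export
fit_variance_components <- function(values, labels) {
  s <- oneway_sums(values, labels)
  if (all(values == values[[1L]])) {
    warn("zero total variance; vg = ve = 0 and H2 = 0")
    return(tibble(mu = values[[1L]], vg = 0, ve = 0, h2 = 0,
                  n_groups = s$a, group_sizes = list(s$n_i)) |>
             structure(class = c("tt_varcomp", class(tibble()))))
  }
  balanced <- length(unique(s$n_i)) == 1L
  if (balanced) {
    # For the balanced one-way layout the REML solution has a closed form:
    # it coincides with the ANOVA estimator when interior, and truncates to
    # vg = 0 at the boundary. Using it avoids optimizer round-off.
    ac <- anova_components(values, labels)
    if (ac$msb > ac$msw) {
      return(tibble(mu = ac$mu, vg = ac$vg, ve = ac$ve,
                    h2 = h2_from_components(ac$vg, ac$ve),
                    n_groups = s$a, group_sizes = list(s$n_i)) |>
               structure(class = c("tt_varcomp", class(tibble()))))
    }
  }
  neg2_reml <- function(lambda) {
    w <- s$n_i / (1 + lambda * s$n_i)
    mu <- sum(w * s$means) / sum(w)
    q <- s$ssw + sum(w * (s$means - mu)^2)
    (s$N - 1) * log(q) + sum(log(1 + lambda * s$n_i)) + log(sum(w))
  }
  # Brent on the ratio; a log-scale pre-scan localizes the optimum so the
  # final bracketed search resolves small ratios to full precision.
  grid <- c(0, 10^seq(-6, 6, by = 0.25))
  vals <- vapply(grid, neg2_reml, numeric(1L))
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]
  hi <- min(1e6, grid[min(length(grid), k + 1L)])
  lambda <- if (k == 1L && vals[[1L]] <= vals[[2L]]) {
    0
  } else {
    opt <- optimize(neg2_reml, lower = lo, upper = hi, tol = 1e-10)
    if (neg2_reml(0) <= opt$objective) 0 else opt$minimum
  }
  w <- s$n_i / (1 + lambda * s$n_i)
  mu <- sum(w * s$means) / sum(w)
  q <- s$ssw + sum(w * (s$means - mu)^2)
  ve <- q / (s$N - 1)
  vg <- lambda * ve
  tibble(mu = mu, vg = vg, ve = ve, h2 = h2_from_components(vg, ve),
         n_groups = s$a, group_sizes = list(s$n_i)) |>
    structure(class = c("tt_varcomp", class(tibble())))
}

#' Broad-sense heritability from variance components
#'
#' `H2 = vg / (vg + ve)`: the fraction of variance in transformed abundance
#' attributable to the generation grouping — a generational-consistency
#' measure, not a claim of genetic inheritance. Defined as 0 when both
#' components are 0.
#'
#' @param vc A `tt_varcomp` row from [fit_variance_components()], or a list
#'   with elements `vg` and `ve`.
#' @return A number in \[0, 1\].
#' @export
heritability <- function(vc) {
  h2_from_components(vc$vg[[1L]], vc$ve[[1L]])
}

# Fast H2 for a balanced layout (identical to REML there); used inside the
# permutation loop, where label permutation preserves group sizes.
h2_balanced <- function(values, g_int, n_per, a) {
  means <- rowsum(values, g_int, reorder = TRUE) / n_per
  grand <- mean(values)
  msb <- n_per * sum((means - grand)^2) / (a - 1)
  ssw <- sum(values^2) - n_per * sum(means^2)
  msw <- ssw / (length(values) - a)
  vg <- max(0, (msb - msw) / n_per)
  if (vg + msw <= 0) 0 else vg / (vg + msw)
}

#' Permutation test for broad-sense heritability
#'
#' Recomputes H2 under `B` independent uniform permutations of the
#' generation-label vector and reports the empirical p-value
#' `(1 + #\{H2_perm >= H2_obs\}) / (1 + B)`; ties count as extreme, so the
#' p-value is always positive and valid. Balanced layouts use the
#' closed-form estimator inside the loop (identical to REML there);
#' unbalanced layouts refit REML per permutation.
#'
#' @inheritParams fit_variance_components
#' @param B Number of permutations (default 999).
#' @param rng_seed Integer seed for the permutation stream; results are
#'   deterministic given the seed.
#' @return A list with `h2_observed`, `p_empirical`, `permuted_h2`
#'   (length-B numeric), `B`, and the observed `components`.
#' @export
permutation_test <- function(values, labels, B = 999L, rng_seed = 1L) {
  vc <- fit_variance_components(values, labels)
  h2_obs <- vc$h2[[1L]]
  g <- factor(labels)
  n_i <- as.vector(table(g))
  balanced <- length(unique(n_i)) == 1L
  set.seed(rng_seed)
  permuted <- if (balanced) {
    g_int <- as.integer(g)
    vapply(seq_len(B), function(b) {
      h2_balanced(values, g_int[sample.int(length(values))], n_i[[1L]], nlevels(g))
    }, numeric(1L))
  } else {
    vapply(seq_len(B), function(b) {
      fit_variance_components(values, labels[sample.int(length(values))])$h2[[1L]]
    }, numeric(1L))
  }
  # ties count as extreme; the epsilon absorbs summation-order round-off so
  # permutations reproducing the observed grouping are counted as ties
  n_extreme <- sum(permuted >= h2_obs - 1e-9)
  list(h2_observed = h2_obs, p_empirical = (1 + n_extreme) / (1 + B),
       permuted_h2 = permuted, B = B, components = vc)
}

#' Heritability screen over a taxon set
#'
#' Per-taxon pipeline for one cultivar-compartment context: CSS-normalize
#' (optional), convert to per-sample relative abundance, `log10(x + 1e-6)`
#' transform, fit the one-way generation model, permutation-test H2, and
#' Benjamini-Hochberg adjust across the screened taxa. The taxon subset is
#' normally the chain-mode vertically transferred set for the context, and
#' generation is the only grouping factor, so granddaughter replicates pool
#' over fields.
#'
#' @param ds A `tt_dataset`.
#' @param taxa Character vector of taxon ids to screen.
#' @param cultivar,compartment Context; only samples matching both (all
#'   generations) enter the model.
#' @param css Logical; CSS-normalize before taking proportions (default
#'   `TRUE`). `FALSE` uses raw proportions.
#' @param css_quantile CSS quantile when `css = TRUE`.
#' @param pseudocount Shift for the log10 transform.
#' @param B Permutations per taxon.
#' @param rng_seed Seed; per-taxon streams are derived deterministically.
#' @param alpha Significance level for the `significant` flag (on adjusted
#'   p-values).
#' @return A `tt_heritability` tibble: per taxon `mu`, `vg`, `ve`, `h2`,
#'   `B`, `n_extreme`, `p_empirical`, `p_adjusted`, `significant`. Attribute
#'   `fraction_significant` summarizes the screen. Taxa absent from every
#'   context sample are skipped with a warning.
#' @export
heritability_screen <- function(ds, taxa, cultivar, compartment,
                                css = TRUE, css_quantile = 0.5,
                                pseudocount = 1e-6, B = 999L, rng_seed = 1L,
                                alpha = 0.05) {
  stopifnot(inherits(ds, "tt_dataset"))
  md <- ds$metadata
  keep <- md$cultivar == cultivar & as.character(md$compartment) == compartment
  if (!any(keep)) abort("no samples match the requested cultivar/compartment context")
  sub <- ds$counts[, md$sample_id[keep], drop = FALSE]
  gen <- md$generation[keep]
  mat <- if (css) {
    as_count_matrix(css_normalize(sub, quantile = css_quantile))
  } else {
    sub
  }
  rel <- sweep(mat, 2L, colSums(mat), "/")
  if (length(taxa) == 0L) {
    return(structure(tibble(taxon_id = character(), mu = numeric(), vg = numeric(),
                            ve = numeric(), h2 = numeric(), B = integer(),
                            n_extreme = integer(), p_empirical = numeric(),
                            p_adjusted = numeric(), significant = logical()),
                     fraction_significant = NA_real_,
                     class = c("tt_heritability", class(tibble()))))
  }
  missing_taxa <- setdiff(taxa, rownames(rel))
  present_mask <- taxa %in% rownames(rel)
  absent <- taxa[present_mask][rowSums(rel[taxa[present_mask], , drop = FALSE] > 0) == 0]
  skip <- union(missing_taxa, absent)
  if (length(skip) > 0L) {
    warn(paste0(length(skip), " taxa absent from all context samples; skipped"))
  }
  use <- setdiff(taxa, skip)
  rows <- purrr::imap(use, function(tx, i) {
    y <- log10_shift(rel[tx, ], pseudocount)
    pt <- permutation_test(y, gen, B = B,
                           rng_seed = (rng_seed + 7919L * i) %% .Machine$integer.max)
    tibble(taxon_id = tx, mu = pt$components$mu[[1L]], vg = pt$components$vg[[1L]],
           ve = pt$components$ve[[1L]], h2 = pt$h2_observed, B = as.integer(B),
           n_extreme = as.integer(round(pt$p_empirical * (1 + B) - 1)),
           p_empirical = pt$p_empirical)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_empirical)
  out$significant <- out$p_adjusted < alpha
  attr(out, "fraction_significant") <- mean(out$significant)
  class(out) <- c("tt_heritability", class(out))
  out
}
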