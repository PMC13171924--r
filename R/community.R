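#' Per-sample alpha diversity
#'
#' Richness is the number of taxa with a positive value; Shannon diversity
#' `H = -sum p_i log p_i` uses natural log over the sample's nonzero
#' proportions; Pielou evenness is `H / log(richness)`, `NA` for single-taxon
#' samples. Computed on raw counts by default — pass a normalized table to
#' compute on normalized values.
#'
#' @param counts Counts tibble or taxa-by-samples matrix.
#' @param metrics Any of `"richness"`, `"shannon"`, `"pielou"`.
#' @return A tibble with `sample_id` and one column per requested metric.
#' @export
alpha_diversity <- function(counts, metrics = c("richness", "shannon", "pielou")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  mat <- as_count_matrix(counts)
  rich <- colSums(mat > 0)
  out <- tibble(sample_id = colnames(mat))
  if (any(c("shannon", "pielou") %in% metrics) && any(colSums(mat) == 0)) {
    abort(paste0("all-zero sample(s) for Shannon/Pielou: ",
                 paste(colnames(mat)[colSums(mat) == 0], collapse = ", ")))
  }
  if ("richness" %in% metrics) out$richness <- as.integer(rich)
  if (any(c("shannon", "pielou") %in% metrics)) {
    h <- vegan::diversity(t(mat), index = "shannon")
    if ("shannon" %in% metrics) out$shannon <- unname(h)
    if ("pielou" %in% metrics) {
      out$pielou <- ifelse(rich > 1, unname(h) / log(rich), NA_real_)
    }
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_jk = sum |x_ij - x_ik| / sum (x_ij + x_ik)`; typically computed on
#' CSS-normalized values. A pair of all-zero samples has undefined
#' dissimilarity and yields `NA` with a warning.
#'
#' @param counts Counts tibble or taxa-by-samples matrix (raw or normalized).
#' @return A `dist` object over samples with values in \[0, 1\].
#' @export
bray_curtis <- function(counts) {
  mat <- as_count_matrix(counts)
  if (ncol(mat) < 2L) abort("need at least 2 samples")
  zero <- colSums(mat) == 0
  d <- suppressWarnings(vegan::vegdist(t(mat), method = "bray"))
  if (sum(zero) >= 2L) {
    warn("pair(s) of all-zero samples; their dissimilarity is NA")
    dm <- as.matrix(d)
    dm[zero, zero] <- NA_real_
    diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  d
}

# Trace-based sums of squares for one hat matrix applied to the Gower-centered
# inner-product matrix G.
permanova_ss <- function(G, hats) {
  vapply(hats, function(H) sum(H * G), numeric(1L))  # tr(HG), H symmetric
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the squared dissimilarities among model terms following the
#' distance-based ANOVA construction: the dissimilarity matrix is converted
#' to the Gower-centered inner-product matrix `G`, each term's sum of
#' squares is the sequential (Type-I) increment `tr(H_k G) - tr(H_{k-1} G)`
#' of cumulative projection (hat) matrices in model-formula order, and
#' pseudo-F per term is its mean square over the residual mean square.
#' Significance comes from permuting samples (rows and columns of the
#' dissimilarity matrix): with `permutations` an integer `B`, p =
#' `(1 + #extreme) / (1 + B)` over random permutations; with an explicit
#' permutation matrix (one permutation per row, taken as the complete null,
#' e.g. full enumeration), p is the fraction of enumerated statistics at or
#' above the observed.
#'
#' @param d A `dist` or symmetric matrix of dissimilarities.
#' @param metadata Data frame with one row per sample in the order of `d`.
#' @param terms Character vector of metadata columns, in model order;
#'   interactions may be given as `"a:b"`.
#' @param permutations Integer number of random permutations (default 999)
#'   or an integer matrix of permutation index rows.
#' @param rng_seed Seed for random permutations.
#' @return A `tt_permanova` tibble: per term and residual/total rows, `df`,
#'   `ss`, `r2`, `pseudo_f`, `p_value`, and attribute `n_permutations`.
#' @export
permanova <- function(d, metadata, terms, permutations = 999L, rng_seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3L) abort("PERMANOVA needs at least 3 samples")
  md <- as.data.frame(metadata)
  if (nrow(md) != n) abort("metadata rows must match the dissimilarity matrix order")
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in base_vars) {
    md[[v]] <- factor(md[[v]])
    if (nlevels(droplevels(md[[v]])) < 2L) {
      abort(paste0("term '", v, "' has a single level"))
    }
  }
  A <- -0.5 * dm^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))

  hat_of <- function(fml_terms) {
    fml <- as.formula(paste("~", paste(c("1", fml_terms), collapse = " + ")))
    X <- model.matrix(fml, data = md)
    qx <- qr(X)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    Q %*% t(Q)
  }
  hats <- vector("list", length(terms) + 1L)
  hats[[1L]] <- matrix(1 / n, n, n)  # intercept only
  for (k in seq_along(terms)) hats[[k + 1L]] <- hat_of(terms[seq_len(k)])
  df_model <- vapply(seq_along(terms), function(k) {
    qr(model.matrix(as.formula(paste("~", paste(terms[seq_len(k)], collapse = "+"))), md))$rank - 1L
  }, numeric(1L))
  df_terms <- diff(c(0, df_model))
  df_resid <- n - 1L - sum(df_terms)

  stat_fun <- function(Gp) {
    tr <- permanova_ss(Gp, hats)
    ss_cum <- tr - tr[[1L]]
    ss_terms <- diff(c(0, ss_cum[-1L]))
    ss_res <- sum(diag(Gp)) - tr[[1L]] - sum(ss_terms)
    list(ss_terms = ss_terms, ss_res = ss_res,
         f = (ss_terms / df_terms) / (ss_res / df_resid))
  }
  obs <- stat_fun(G)

  if (is.matrix(permutations)) {
    perms <- permutations
    f_perm <- t(apply(perms, 1L, function(p) stat_fun(G[p, p])$f))
    if (length(terms) == 1L) f_perm <- matrix(f_perm, ncol = 1L)
    p_vals <- vapply(seq_along(terms), function(k) {
      mean(f_perm[, k] >= obs$f[[k]] - 1e-12)
    }, numeric(1L))
    n_perm <- nrow(perms)
  } else {
    B <- as.integer(permutations)
    set.seed(rng_seed)
    extreme <- numeric(length(terms))
    for (b in seq_len(B)) {
      p <- sample.int(n)
      fb <- stat_fun(G[p, p])$f
      extreme <- extreme + (fb >= obs$f - 1e-12)
    }
    p_vals <- (1 + extreme) / (1 + B)
    n_perm <- B
  }

  out <- tibble(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_resid, n - 1L),
    ss = c(obs$ss_terms, obs$ss_res, ss_total),
    r2 = c(obs$ss_terms, obs$ss_res, ss_total) / ss_total,
    pseudo_f = c(obs$f, NA_real_, NA_real_),
    p_value = c(p_vals, NA_real_, NA_real_)
  )
  attr(out, "n_permutations") <- n_perm
  class(out) <- c("tt_permanova", class(out))
  out
}

#' Tidy a PERMANOVA table
#' @param x A `tt_permanova`.
#' @param ... Unused.
#' @export
tidy.tt_permanova <- function(x, ...) as_tibble(x)

#' One-row PERMANOVA summary
#' @param x A `tt_permanova`.
#' @param ... Unused.
#' @export
glance.tt_permanova <- function(x, ...) {
  tibble(n_terms = sum(!x$term %in% c("Residual", "Total")),
         ss_total = x$ss[x$term == "Total"],
         r2_model = sum(x$r2[!x$term %in% c("Residual", "Total")]),
         n_permutations = attr(x, "n_permutations"))
}

#' Kruskal-Wallis rank-sum test
#'
#' Standard rank statistic with tie correction and a chi-square reference
#' distribution.
#'
#' @param values Numeric vector.
#' @param groups Group label per value; at least 2 groups.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(droplevels(g)) < 2L) abort("need at least 2 groups")
  ht <- kruskal.test(values, g)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from pooled-rank means with the tie correction,
#' two-sided p-values, and Benjamini-Hochberg adjustment across pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjust Currently `"bh"`.
#' @return A tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "bh") {
  adjust <- match.arg(adjust, "bh")
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2L) abort("need at least 2 groups")
  r <- rank(values)
  N <- length(values)
  n_i <- as.vector(table(g))
  rbar <- tapply(r, g, mean)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    na <- n_i[[match(a, levels(g))]]; nb <- n_i[[match(b, levels(g))]]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / na + 1 / nb))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    tibble(group1 = a, group2 = b, z = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
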