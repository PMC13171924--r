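#' Cumulative sum scaling factors
#'
#' For each sample, the scaling factor is the sum of counts over taxa whose
#' nonzero count is at or below the sample's empirical quantile of nonzero
#' counts at level `quantile`. The quantile uses the nearest-rank convention:
#' the value at 1-based index `ceiling(quantile * m)` of the sample's sorted
#' nonzero counts (`m` nonzero values). This makes the factor a deterministic
#' function of the count distribution and robust to dominant taxa.
#'
#' @param counts Counts tibble or taxa-by-samples matrix.
#' @param quantile Quantile level in (0, 1); default 0.5.
#' @return A tibble with columns `sample_id` and `scaling_factor`.
#' @export
css_scaling_factors <- function(counts, quantile = 0.5) {
  mat <- as_count_matrix(counts)
  if (quantile <= 0 || quantile >= 1) abort("quantile must be in (0, 1)")
  s <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    nz <- x[x > 0]
    if (length(nz) == 0L) {
      abort(paste0("sample '", colnames(mat)[[j]], "' has no nonzero counts"))
    }
    q <- sort(nz)[ceiling(quantile * length(nz))]
    sum(x[x <= q & x > 0])
  }, numeric(1L))
  tibble(sample_id = colnames(mat), scaling_factor = s)
}

#' Cumulative sum scaling normalization
#'
#' Divides each sample's counts by its CSS scaling factor and multiplies by a
#' global rescale `R` (the median scaling factor by default, or a fixed 1000)
#' so normalized magnitudes stay comparable to counts. The quantile level is
#' not fixed by convention across implementations; results from other CSS
#' implementations may differ.
#'
#' @inheritParams css_scaling_factors
#' @param rescale `"median"` (default) or `"fixed_1000"`.
#' @return A tibble shaped like the input counts (`taxon_id` + sample
#'   columns) holding nonnegative reals, with attributes `scaling_factors`
#'   (tibble), `css_quantile`, and `rescale_value`.
#' @export
css_normalize <- function(counts, quantile = 0.5, rescale = c("median", "fixed_1000")) {
  rescale <- match.arg(rescale)
  mat <- as_count_matrix(counts)
  sf <- css_scaling_factors(mat, quantile)
  R <- if (rescale == "median") median(sf$scaling_factor) else 1000
  norm <- sweep(mat, 2L, sf$scaling_factor, "/") * R
  out <- count_matrix_to_tbl(norm)
  attr(out, "scaling_factors") <- sf
  attr(out, "css_quantile") <- quantile
  attr(out, "rescale_value") <- R
  out
}

#' Choose a CSS quantile adaptively
#'
#' Scans candidate quantile levels in ascending order and returns the
#' smallest level at which the median relative change in scaling factors
#' between successive levels exceeds the instability threshold — the point
#' where the cumulative sums start diverging across samples. Falls back to
#' the highest candidate when no level is unstable.
#'
#' @inheritParams css_scaling_factors
#' @param candidates Ascending quantile levels to scan.
#' @param threshold Median relative-change threshold (default 0.1).
#' @return A single quantile level.
#' @export
css_choose_quantile <- function(counts, candidates = seq(0.25, 0.95, by = 0.05),
                                threshold = 0.1) {
  mat <- as_count_matrix(counts)
  sf <- vapply(candidates, function(q) css_scaling_factors(mat, q)$scaling_factor,
               numeric(ncol(mat)))
  if (is.null(dim(sf))) sf <- matrix(sf, nrow = 1L)
  for (k in seq_along(candidates)[-1L]) {
    rel <- abs(sf[, k] - sf[, k - 1L]) / pmax(sf[, k - 1L], 1e-12)
    if (median(rel) > threshold) return(candidates[[k]])
  }
  candidates[[length(candidates)]]
}

#' Per-sample relative abundance
#'
#' @param counts Counts tibble or taxa-by-samples matrix (raw or normalized).
#' @return A tibble shaped like the input where every sample column sums to 1.
#' @export
relative_abundance <- function(counts) {
  mat <- as_count_matrix(counts)
  tot <- colSums(mat)
  zero <- colnames(mat)[tot == 0]
  if (length(zero) > 0L) {
    abort(paste0("all-zero sample(s): ", paste(zero, collapse = ", ")))
  }
  count_matrix_to_tbl(sweep(mat, 2L, tot, "/"))
}

#' Shifted log10 transform
#'
#' `log10(x + pseudocount)` elementwise; the default pseudocount of 1e-6 maps
#' an absent taxon (relative abundance 0) to -6.
#'
#' @param values Nonnegative numeric vector or matrix.
#' @param pseudocount Positive shift; default `1e-6`.
#' @return Transformed values, same shape as input.
#' @export
log10_shift <- function(values, pseudocount = 1e-6) {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  v <- if (is.data.frame(values)) as_count_matrix(values) else values
  if (any(v < 0, na.rm = TRUE)) abort("log10_shift requires nonnegative input")
  log10(v + pseudocount)
}
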