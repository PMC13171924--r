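#' Build transfer trials from classification results
#'
#' Turns per-context classifications into one binomial observation per
#' context and generation transition: `trials` is the number of taxa present
#' at the baseline generation, `successes` the number of those detected in
#' the next generation (the vertical set under chain logic, where the
#' entering set of each transition is the previously retained set).
#'
#' @param classifications A list of `tt_transfer` tibbles (chain mode
#'   recommended) or a single tibble binding them, each carrying context
#'   columns and `n_vertical` per generation; the seed set size is recovered
#'   from attribute-free arithmetic, so supply `seed_sizes` keyed by context.
#' @param seed_sizes A tibble with the context columns (`compartment`,
#'   `cultivar`, `field`) and `n_seed`, the baseline seed set size per
#'   context.
#' @return A tibble with one row per context and transition: `transition`
#'   (`"seed_to_daughter"` / `"daughter_to_granddaughter"`), context columns,
#'   `successes`, `trials`. Contexts with an empty baseline are dropped with
#'   a warning.
#' @export
build_trials <- function(classifications, seed_sizes) {
  cls <- if (is.data.frame(classifications)) as_tibble(classifications) else dplyr::bind_rows(classifications)
  ctx_cols <- intersect(c("compartment", "cultivar", "field"), names(seed_sizes))
  cls <- left_join(cls, seed_sizes, by = ctx_cols)
  rows <- list()
  for (key in split(seq_len(nrow(cls)), interaction(cls[ctx_cols], drop = TRUE))) {
    sub <- cls[key, , drop = FALSE]
    sub <- sub[order(match(sub$generation, tt_generation_levels)), , drop = FALSE]
    baseline <- sub$n_seed[[1L]]
    for (i in seq_len(nrow(sub))) {
      gen <- sub$generation[[i]]
      prev_gen <- tt_generation_levels[match(gen, tt_generation_levels) - 1L]
      if (baseline < 1L || is.na(baseline)) {
        warn(paste0("context with empty baseline at transition into '", gen, "' excluded"))
      } else {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          sub[i, ctx_cols, drop = FALSE],
          tibble(transition = paste0(prev_gen, "_to_", gen),
                 successes = sub$n_vertical[[i]], trials = as.integer(baseline))
        )
      }
      baseline <- sub$n_vertical[[i]]
    }
  }
  if (length(rows) == 0L) {
    warn("no usable contexts; returning empty trials table")
    return(tibble(transition = character(), successes = integer(), trials = integer()))
  }
  out <- dplyr::bind_rows(rows)
  if (any(out$successes > out$trials)) abort("successes exceed trials; classification inputs inconsistent")
  out
}

check_separation <- function(fit) {
  mu <- fitted(fit)
  eps <- 1e-8
  if (any(mu < eps | mu > 1 - eps) && any(abs(coef(fit)) > 10)) {
    abort(paste0("fitted probabilities are numerically pinned at 0 or 1 ",
                 "(separation); consider bias_reduced_fit() for a finite ",
                 "penalized-likelihood fit"))
  }
  invisible(fit)
}

term_wald <- function(beta, V, assign, terms) {
  purrr::map_dfr(seq_along(terms), function(k) {
    idx <- which(assign == k)
    b <- beta[idx]
    Vk <- V[idx, idx, drop = FALSE]
    stat <- tryCatch(drop(t(b) %*% solve(Vk, b)), error = function(e) NA_real_)
    tibble(term = terms[[k]], df = length(idx), wald_chisq = stat,
           p_value = pchisq(stat, df = length(idx), lower.tail = FALSE))
  })
}

#' Binomial GLM for vertical-transfer probability
#'
#' Fits a logit-link binomial regression of successes/trials on the supplied
#' factors by iteratively reweighted least squares (convergence when the
#' deviance change is below 1e-8, at most 100 iterations). Factors are coded
#' sum-to-zero, so per-term Wald chi-square statistics are Type-III style and
#' invariant to reference-level choice. Standard errors are model-based, or
#' cluster-robust (sandwich estimator with the usual small-cluster
#' correction) when `robust_cluster` names a column — the fixed-effects
#' analogue of a random intercept on that factor. Marginal transfer
#' probabilities per level of each model factor are estimated marginal means
#' on the response scale with delta-method 95% confidence intervals computed
#' on the logit scale.
#'
#' @param trials A tibble from [build_trials()] with `successes`, `trials`,
#'   and factor columns.
#' @param terms Character vector of factor column names to fit as fixed
#'   effects (e.g. `c("compartment", "cultivar", "transition")`).
#' @param robust_cluster Optional column name to cluster robust standard
#'   errors on (e.g. `"field"`), or `NULL` for model-based errors.
#' @param dispersion `"binomial"` (default) or `"quasibinomial"` to scale the
#'   covariance by a Pearson dispersion estimate (overdispersion control).
#' @return A `tt_transfer_model` list: `fit` (the glm object), `coefficients`
#'   tibble (logit scale), `wald` tibble (per-term chi-square tests),
#'   `emmeans` tibble (per factor level: probability, 95% CI), `vcov_type`.
#' @export
fit_binomial_glm <- function(trials, terms, robust_cluster = NULL,
                             dispersion = c("binomial", "quasibinomial")) {
  dispersion <- match.arg(dispersion)
  dat <- as.data.frame(trials)
  if (nrow(dat) == 0L) abort("empty trials table")
  for (tm in terms) dat[[tm]] <- factor(dat[[tm]])
  contr <- setNames(rep(list("contr.sum"), length(terms)), terms)
  fml <- if (length(terms) == 0L) {
    cbind(successes, trials - successes) ~ 1
  } else {
    as.formula(paste("cbind(successes, trials - successes) ~", paste(terms, collapse = " + ")))
  }
  fit <- glm(fml, family = binomial("logit"), data = dat,
             contrasts = if (length(terms) > 0L) contr else NULL,
             control = list(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) abort("IRLS did not converge in 100 iterations")
  if (any(is.na(coef(fit)))) {
    abort(paste0("rank-deficient design; aliased term(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  check_separation(fit)
  V <- if (!is.null(robust_cluster)) {
    sandwich::vcovCL(fit, cluster = dat[[robust_cluster]])
  } else if (dispersion == "quasibinomial") {
    phi <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
    vcov(fit) * phi
  } else {
    vcov(fit)
  }
  beta <- coef(fit)
  se <- sqrt(diag(V))
  coefs <- tibble(term = names(beta), estimate = unname(beta), std_error = unname(se),
                  z = unname(beta / se),
                  p_value = 2 * stats::pnorm(-abs(unname(beta / se))))
  assign <- attr(model.matrix(fit), "assign")
  wald <- if (length(terms) > 0L) term_wald(beta, V, assign, terms) else
    tibble(term = character(), df = integer(), wald_chisq = numeric(), p_value = numeric())
  emm <- if (length(terms) > 0L) {
    purrr::map_dfr(terms, function(tm) {
      g <- emmeans::emmeans(fit, specs = tm, vcov. = V)
      s <- as.data.frame(summary(g, type = "response"))
      tibble(term = tm, level = as.character(s[[1L]]),
             probability = s$prob, ci_lower = s$asymp.LCL, ci_upper = s$asymp.UCL)
    })
  } else {
    ci <- beta[[1L]] + c(-1, 1) * qnorm(0.975) * se[[1L]]
    tibble(term = "(Intercept)", level = "overall",
           probability = stats::plogis(beta[[1L]]),
           ci_lower = stats::plogis(ci[[1L]]), ci_upper = stats::plogis(ci[[2L]]))
  }
  structure(list(fit = fit, coefficients = coefs, wald = wald, emmeans = emm,
                 vcov = V,
                 vcov_type = if (!is.null(robust_cluster)) paste0("cluster(", robust_cluster, ")") else dispersion),
            class = "tt_transfer_model")
}

#' @export
print.tt_transfer_model <- function(x, ...) {
  cat("<tt_transfer_model> binomial logit fit, vcov:", x$vcov_type, "\n")
  print(x$wald)
  print(x$emmeans)
  invisible(x)
}

#' Tidy a transfer model: coefficient table on the log-odds scale
#' @param x A `tt_transfer_model`.
#' @param ... Unused.
#' @export
tidy.tt_transfer_model <- function(x, ...) x$coefficients

#' One-row model summary for a transfer model
#' @param x A `tt_transfer_model`.
#' @param ... Unused.
#' @export
glance.tt_transfer_model <- function(x, ...) {
  tibble(null_deviance = x$fit$null.deviance, deviance = x$fit$deviance,
         df_residual = x$fit$df.residual, aic = x$fit$aic,
         n = length(x$fit$y), vcov_type = x$vcov_type)
}

#' Firth-type bias-reduced binomial fit
#'
#' Penalized-likelihood logistic regression with the Jeffreys-prior score
#' adjustment: at each IRLS step the working response is corrected by the
#' hat-diagonal term `h_i (1/2 - p_i)`, which keeps coefficients finite even
#' under complete separation and removes the O(1/n) bias of maximum
#' likelihood.
#'
#' @inheritParams fit_binomial_glm
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   max absolute coefficient change.
#' @return A `tt_transfer_model` (penalized fit; no emmeans component beyond
#'   per-level probabilities derived from the coefficients).
#' @export
bias_reduced_fit <- function(trials, terms, max_iter = 200, tol = 1e-10) {
  dat <- as.data.frame(trials)
  for (tm in terms) dat[[tm]] <- factor(dat[[tm]])
  contr <- setNames(rep(list("contr.sum"), length(terms)), terms)
  fml <- if (length(terms) == 0L) ~1 else as.formula(paste("~", paste(terms, collapse = "+")))
  X <- model.matrix(fml, data = dat, contrasts.arg = if (length(terms) > 0L) contr else NULL)
  if (qr(X)$rank < ncol(X)) abort("rank-deficient design in bias_reduced_fit")
  y <- dat$successes
  m <- dat$trials
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- m * p * (1 - p)
    w <- pmax(w, 1e-12)
    XtW <- t(X * w)
    info <- XtW %*% X
    # hat diagonal of the weighted design
    U <- chol(info)
    Xi <- X %*% backsolve(U, diag(ncol(X)))
    h <- rowSums(Xi^2) * w
    score <- drop(t(X) %*% (y - m * p + h * (0.5 - p)))
    delta <- solve(info, score)
    beta_new <- beta + delta
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- m * p * (1 - p)
  V <- solve(t(X * w) %*% X)
  se <- sqrt(diag(V))
  beta <- unname(beta)
  coefs <- tibble(term = colnames(X), estimate = beta, std_error = unname(se),
                  z = beta / se, p_value = 2 * stats::pnorm(-abs(beta / se)))
  assign <- attr(X, "assign")
  wald <- if (length(terms) > 0L) term_wald(beta, V, assign, terms) else
    tibble(term = character(), df = integer(), wald_chisq = numeric(), p_value = numeric())
  structure(list(fit = list(coefficients = setNames(beta, colnames(X)), X = X,
                            fitted = p, y = y, trials = m),
                 coefficients = coefs, wald = wald,
                 emmeans = tibble(term = character(), level = character(),
                                  probability = numeric(), ci_lower = numeric(),
                                  ci_upper = numeric()),
                 vcov = V, vcov_type = "firth"),
            class = "tt_transfer_model")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences; zero differences are
#' dropped. The p-value is exact (full enumeration of sign assignments) when
#' the effective sample is small and tie-free, otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A tibble with `statistic` (V), `p_value`, `n_effective`, `method`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 1L) abort("need at least one pair")
  d <- x - y
  d_nz <- d[d != 0]
  if (length(d_nz) == 0L) {
    warn("all paired differences are zero; p = 1")
    return(tibble(statistic = 0, p_value = 1, n_effective = 0L, method = "degenerate"))
  }
  ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, correct = TRUE))
  exact_used <- length(d_nz) < 50 && !any(duplicated(abs(d_nz))) && all(d != 0)
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n_effective = length(d_nz),
         method = if (exact_used) "exact" else "normal_approximation")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; validates the input range and
#' returns adjusted values in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
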