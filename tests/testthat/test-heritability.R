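test_that("variance components handle the trivial boundary layouts", {
  # zero residual variance: all variance is between generations -> H2 = 1
  vals <- c(1, 1, 1, 1, 4, 4)
  labs <- rep(c("g1", "g2", "g3"), each = 2)
  vc <- fit_variance_components(vals, labs)
  expect_equal(vc$ve, 0, tolerance = 1e-9)
  expect_gt(vc$vg, 0)
  expect_equal(vc$h2, 1, tolerance = 1e-8)
  expect_equal(heritability(vc), vc$h2)

  # all equal -> vg = 0, H2 = 0 with warning
  expect_warning(vc0 <- fit_variance_components(rep(2, 6), labs), "zero total variance")
  expect_identical(vc0$h2, 0)

  # layout validation
  expect_error(fit_variance_components(1:4, c("a", "a", "a", "a")), "2 generations")
  expect_error(fit_variance_components(1:4, c("a", "a", "b", "c")), "2 observations")
})

test_that("heritability ratio follows directly from the components", {
  expect_equal(h2 <- heritability(list(vg = 3, ve = 1)), 0.75)
  expect_equal(heritability(list(vg = 0, ve = 2)), 0)
  expect_equal(heritability(list(vg = 2, ve = 0)), 1)
  expect_equal(heritability(list(vg = 0, ve = 0)), 0)
})

test_that("REML equals the ANOVA method-of-moments oracle on balanced interior cases", {
  set.seed(61)
  n_checked <- 0
  for (rep in 1:40) {
    d <- simulate_taxon_abundance(3, sample(4:10, 1), vg = runif(1, 0.1, 1),
                                  ve = runif(1, 0.05, 0.5))
    orc <- mom_oracle(d$value, d$generation)
    vc <- fit_variance_components(d$value, d$generation)
    if (orc$interior) {
      n_checked <- n_checked + 1
      expect_equal(vc$vg, orc$vg, tolerance = 1e-8)
      expect_equal(vc$ve, orc$ve, tolerance = 1e-8)
      expect_equal(vc$h2, orc$h2, tolerance = 1e-8)
    } else {
      expect_equal(vc$h2, 0, tolerance = 1e-10)
    }
  }
  expect_gt(n_checked, 20)  # most draws give interior solutions
})

test_that("REML matches lme4 on balanced and unbalanced layouts", {
  set.seed(62)
  for (rep in 1:5) {
    d <- simulate_taxon_abundance(3, 8, vg = 0.5, ve = 0.2)
    # unbalance by dropping a few observations
    d <- d[-sample(nrow(d), 3), ]
    vc <- fit_variance_components(d$value, d$generation)
    m <- lme4::lmer(value ~ 1 + (1 | generation), data = d,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
    ref <- as.data.frame(lme4::VarCorr(m))$vcov
    expect_equal(vc$vg, ref[1], tolerance = 1e-5)
    expect_equal(vc$ve, ref[2], tolerance = 1e-5)
  }
})

test_that("H2 is invariant to affine transforms of the data", {
  set.seed(63)
  d <- simulate_taxon_abundance(3, 6, vg = 0.4, ve = 0.2)
  h0 <- fit_variance_components(d$value, d$generation)$h2
  h_shift <- fit_variance_components(d$value + 100, d$generation)$h2
  h_scale <- fit_variance_components(d$value * 7.3, d$generation)$h2
  expect_equal(h_shift, h0, tolerance = 1e-7)
  expect_equal(h_scale, h0, tolerance = 1e-7)
  expect_true(h0 >= 0 && h0 <= 1)
})

test_that("permutation p-values match exhaustive enumeration on a tiny layout", {
  # 2 generations x 2 observations: the balanced estimator depends on the
  # label assignment only through which pair is grouped; enumerate all
  # C(4,2)/... distinct assignments by brute force over all 4! permutations.
  vals <- c(0.3, 0.5, 2.1, 2.4)
  labs <- c("a", "a", "b", "b")
  h2_of <- function(perm) fit_variance_components(vals, labs[perm])$h2
  all_perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  all_perms <- all_perms[apply(all_perms, 1, function(r) length(unique(r)) == 4), ]
  h2_obs <- fit_variance_components(vals, labs)$h2
  null_h2 <- apply(all_perms, 1, h2_of)
  p_exhaustive <- mean(null_h2 >= h2_obs - 1e-12)
  # the package's B-permutation p converges to the enumerated null; with the
  # (1+extreme)/(1+B) convention and B covering the space many times over,
  # agreement is to within the Monte Carlo resolution
  pt <- permutation_test(vals, labs, B = 4999, rng_seed = 5)
  expect_lt(abs(pt$p_empirical - p_exhaustive), 0.02)
  # grouped pairs {1,2} vs {3,4} maximize separation: observed is extremal,
  # matched only by assignments preserving the partition (8 of 24), so
  # p_exhaustive = 1/3 exactly
  expect_equal(p_exhaustive, 1 / 3, tolerance = 1e-12)
})

test_that("extreme observed H2 gives the minimal attainable p-value", {
  vals <- c(1, 1.01, 5, 5.02, 9, 9.01)
  labs <- rep(c("g1", "g2", "g3"), each = 2)
  pt <- permutation_test(vals, labs, B = 999, rng_seed = 2)
  expect_equal(pt$h2_observed, fit_variance_components(vals, labs)$h2)
  expect_gte(pt$p_empirical, 1 / 1000)
  # constant data: every permuted H2 is 0 and equals the observed -> p = 1
  expect_warning(pt0 <- permutation_test(rep(3, 6), labs, B = 99, rng_seed = 3))
  expect_equal(pt0$p_empirical, 1)
  # determinism under a fixed seed
  pt_a <- permutation_test(vals, labs, B = 199, rng_seed = 11)
  pt_b <- permutation_test(vals, labs, B = 199, rng_seed = 11)
  expect_identical(pt_a$permuted_h2, pt_b$permuted_h2)
})

test_that("balanced fast path equals full REML across permutations", {
  set.seed(64)
  d <- simulate_taxon_abundance(3, 5, vg = 0.3, ve = 0.3)
  g <- factor(d$generation)
  for (rep in 1:20) {
    perm <- sample(nrow(d))
    fast <- tubertrace:::h2_balanced(d$value, as.integer(g)[perm], 5, 3)
    full <- fit_variance_components(d$value, d$generation[perm])$h2
    expect_equal(fast, full, tolerance = 1e-7)
  }
})

test_that("heritability screen runs the full per-taxon pipeline deterministically", {
  sim <- simulate_dataset(simulation_config(
    seed_richness_flesh = 40, seed_richness_peel = 40,
    retention_prob = c(flesh = 0.5, peel = 0.5),
    horizontal_pool_size = list(daughter = c(flesh = 20, peel = 20),
                                granddaughter = c(flesh = 30, peel = 30)),
    tare_soil_pool_size = 0, n_replicates = 5, cultivars = "Nadine",
    rng_seed = 65L))
  pres <- presence_sets(sim$dataset)
  cls <- classify_transfer(pres, "flesh", "Nadine", mode = "chain")
  taxa <- cls$vertical_taxa[[2]]
  expect_gt(length(taxa), 3)
  h2a <- heritability_screen(sim$dataset, taxa, "Nadine", "flesh", B = 49, rng_seed = 9)
  h2b <- heritability_screen(sim$dataset, taxa, "Nadine", "flesh", B = 49, rng_seed = 9)
  expect_identical(as.data.frame(h2a), as.data.frame(h2b))
  expect_true(all(h2a$h2 >= 0 & h2a$h2 <= 1))
  expect_true(all(h2a$p_adjusted >= h2a$p_empirical - 1e-15))
  # empty subset: empty result, no error
  h2e <- heritability_screen(sim$dataset, character(0), "Nadine", "flesh", B = 9)
  expect_identical(nrow(h2e), 0L)
  # unknown taxa are skipped with a warning
  expect_warning(
    h2s <- heritability_screen(sim$dataset, c(taxa[1], "ghost"), "Nadine", "flesh", B = 9),
    "skipped")
  expect_identical(nrow(h2s), 1L)
})
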