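test_that("alpha diversity matches the defining formulas", {
  mat <- cbind(uniform = c(5, 5, 5, 5), single = c(9, 0, 0, 0),
               mixed = c(1, 2, 3, 0))
  rownames(mat) <- paste0("t", 1:4)
  out <- alpha_diversity(mat)
  expect_identical(out$richness, c(4L, 1L, 3L))
  expect_equal(out$shannon[[1]], log(4), tolerance = 1e-12)
  expect_equal(out$pielou[[1]], 1, tolerance = 1e-12)
  expect_equal(out$shannon[[2]], 0, tolerance = 1e-12)
  expect_true(is.na(out$pielou[[2]]))
  p <- c(1, 2, 3) / 6
  expect_equal(out$shannon[[3]], -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(out$shannon[[3]], 1.01140, tolerance = 1e-5)
  # Shannon is invariant to taxon relabeling and maximal for uniform input
  shuf <- mat[sample(4), , drop = FALSE]
  expect_equal(alpha_diversity(shuf)$shannon, out$shannon)
  expect_true(all(out$shannon <= log(out$richness) + 1e-12))
  zero <- cbind(mat, empty = c(0, 0, 0, 0))
  expect_error(alpha_diversity(zero), "empty")
  expect_identical(alpha_diversity(zero, "richness")$richness[[4]], 0L)
})

test_that("Bray-Curtis matches hand-evaluated pairs and metric properties", {
  mat <- cbind(a = c(2, 2), b = c(1, 3), c = c(2, 2), d = c(1, 0), e = c(0, 1))
  rownames(mat) <- c("t1", "t2")
  d <- as.matrix(bray_curtis(mat))
  expect_equal(d["a", "b"], (1 + 1) / (4 + 4), tolerance = 1e-12)
  expect_equal(d["a", "c"], 0, tolerance = 1e-12)   # identical samples
  expect_equal(d["d", "e"], 1, tolerance = 1e-12)   # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("PERMANOVA pseudo-F and enumeration p match the brute-force oracle at N=6", {
  set.seed(71)
  for (rep in 1:5) {
    mat <- matrix(rpois(8 * 6, 10) + 1, 8, 6,
                  dimnames = list(paste0("t", 1:8), paste0("s", 1:6)))
    groups <- rep(c("g1", "g2"), each = 3)
    d <- bray_curtis(mat)
    dm <- as.matrix(d)
    # full enumeration of all 720 sample permutations (complete null)
    perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
    res <- permanova(d, data.frame(grp = groups), terms = "grp",
                     permutations = perms)
    f_obs <- res$pseudo_f[[1]]
    expect_equal(f_obs, permanova_oracle_f(dm, groups), tolerance = 1e-10)
    # oracle p: enumerate the 20 distinct assignments of 3+3 labels
    combs <- utils::combn(6, 3)
    f_null <- apply(combs, 2, function(idx) {
      g <- rep("g2", 6); g[idx] <- "g1"
      permanova_oracle_f(dm, g)
    })
    p_oracle <- mean(f_null >= f_obs - 1e-12)
    expect_equal(res$p_value[[1]], p_oracle, tolerance = 1e-12)
  }
})

test_that("PERMANOVA decomposition is additive and matches vegan::adonis2", {
  set.seed(72)
  mat <- matrix(rpois(20 * 16, 15) + 1, 20, 16,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:16)))
  md <- data.frame(grp = rep(c("a", "b"), each = 8),
                   fld = rep(c("x", "y"), 8))
  d <- bray_curtis(mat)
  res <- permanova(d, md, terms = c("grp", "fld"), permutations = 99, rng_seed = 1)
  ss <- res$ss
  expect_equal(sum(ss[1:3]), ss[[4]], tolerance = 1e-10)  # terms + resid = total
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  ref <- vegan::adonis2(t(mat) ~ grp + fld, data = md, method = "bray",
                        permutations = 9, by = "terms")
  expect_equal(res$pseudo_f[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(res$ss[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
})

test_that("perfect group separation yields R2 = 1 and degenerate inputs error", {
  dm <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  dm[1:2, 3:4] <- 1; dm[3:4, 1:2] <- 1
  md <- data.frame(grp = c("a", "a", "b", "b"))
  res <- permanova(stats::as.dist(dm), md, terms = "grp", permutations = 23)
  expect_equal(res$r2[[1]], 1, tolerance = 1e-10)
  expect_error(permanova(stats::as.dist(dm), data.frame(grp = rep("a", 4)),
                         terms = "grp"), "single level")
  expect_error(permanova(stats::as.dist(dm[1:2, 1:2]),
                         data.frame(grp = c("a", "b")), terms = "grp"),
               "at least 3")
})

test_that("Kruskal-Wallis reproduces hand rank arithmetic and rank invariance", {
  out <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(out$statistic, 3.857, tolerance = 1e-3)
  expect_identical(as.integer(out$df), 1L)
  # identical multisets: H near 0
  out0 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gt(out0$p_value, 0.9)
  # invariance under monotone transformation
  v <- c(3, 9, 1, 7, 2, 8)
  g <- rep(c("a", "b"), 3)
  expect_equal(kruskal_wallis(v, g)$statistic,
               kruskal_wallis(exp(v), g)$statistic, tolerance = 1e-12)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 groups")
})

test_that("Dunn post hoc matches hand-computed rank means and orders effects", {
  # groups (1,2,3) vs (4,5,6): rank means 2 and 5, no ties
  out <- dunn_posthoc(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  se <- sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(out$z[[1]], (2 - 5) / se, tolerance = 1e-12)
  # identical groups: z = 0, p = 1 (up to tie handling)
  out0 <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(out0$z[[1]], 0, tolerance = 1e-12)
  expect_equal(out0$p_value[[1]], 1, tolerance = 1e-12)
  # a far-shifted group has the smallest adjusted p in both its comparisons
  set.seed(73)
  v <- c(rnorm(8), rnorm(8), rnorm(8) + 50)
  g <- rep(c("a", "b", "c"), each = 8)
  out3 <- dunn_posthoc(v, g)
  with_c <- out3$group1 == "c" | out3$group2 == "c"
  expect_lt(max(out3$p_adjusted[with_c]), min(out3$p_adjusted[!with_c]))
})
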