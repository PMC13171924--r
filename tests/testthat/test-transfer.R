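test_that("presence sets follow the detection rule and are monotone in thresholds", {
  md <- tiny_metadata(n_rep = 3)
  md <- md[md$generation == "seed" & md$compartment == "flesh", ]
  counts <- matrix(c(0L, 0L, 1L,
                     2L, 2L, 2L,
                     0L, 0L, 0L), 3, 3, byrow = TRUE,
                   dimnames = list(c("rare", "common", "absent"), md$sample_id))
  ds <- validate_dataset(counts, md)
  p1 <- presence_sets(ds, by = "generation")
  expect_setequal(p1$taxa[[1]], c("rare", "common"))
  p2 <- presence_sets(ds, by = "generation", min_prevalence = 2L)
  expect_setequal(p2$taxa[[1]], "common")

  # monotone: higher prevalence threshold gives subsets
  set.seed(31)
  ds2 <- tiny_dataset(n_rep = 3)
  a <- presence_sets(ds2, by = c("generation", "compartment"))
  b <- presence_sets(ds2, by = c("generation", "compartment"), min_prevalence = 2L)
  for (i in seq_len(nrow(a))) expect_true(all(b$taxa[[i]] %in% a$taxa[[i]]))
})

test_that("classify_transfer performs the stated set algebra in both modes", {
  # hand-checked membership enumeration:
  # A0 = {a,b,c}; A1 = {b,c,d}; A2 = {c,d,e}
  md <- tiny_metadata(n_rep = 1, compartments = "flesh")
  counts <- matrix(0L, 5, 3, dimnames = list(letters[1:5], md$sample_id))
  s <- function(g) md$sample_id[md$generation == g]
  counts[c("a", "b", "c"), s("seed")] <- 1L
  counts[c("b", "c", "d"), s("daughter")] <- 1L
  counts[c("c", "d", "e"), s("granddaughter")] <- 1L
  ds <- validate_dataset(counts, md)
  pres <- presence_sets(ds, by = c("generation", "compartment", "cultivar", "field"))

  chain <- classify_transfer(pres, "flesh", "Nadine", mode = "chain")
  expect_setequal(chain$vertical_taxa[[1]], c("b", "c"))
  expect_setequal(chain$vertical_taxa[[2]], "c")
  expect_setequal(chain$horizontal_taxa[[2]], c("d", "e"))
  expect_equal(chain$vertical_pct, c(100 * 2 / 3, 100 * 1 / 3))
  expect_equal(chain$horizontal_pct[[2]], 100 * 2 / 3)

  sb <- classify_transfer(pres, "flesh", "Nadine", mode = "seed_baseline")
  # both modes agree here (c is in the seed and in every generation)
  expect_setequal(sb$vertical_taxa[[2]], "c")
  expect_equal(sb$vertical_pct + sb$horizontal_pct, c(100, 100))

  # partition property: vertical and horizontal are disjoint and exhaustive
  for (i in 1:2) {
    expect_length(intersect(chain$vertical_taxa[[i]], chain$horizontal_taxa[[i]]), 0)
    expect_identical(chain$n_vertical[[i]] + chain$n_horizontal[[i]], chain$n_present[[i]])
  }
})

test_that("identity and first-transition cases behave as direct set arithmetic", {
  md <- tiny_metadata(n_rep = 1, compartments = "flesh")
  counts <- matrix(0L, 5, 3, dimnames = list(letters[1:5], md$sample_id))
  s <- function(g) md$sample_id[md$generation == g]
  counts[c("a", "b", "c"), s("seed")] <- 1L
  counts[c("b", "c", "d", "e"), s("daughter")] <- 1L
  counts[c("a", "b", "c"), s("granddaughter")] <- 1L
  ds <- validate_dataset(counts, md)
  pres <- presence_sets(ds, by = c("generation", "compartment"))
  sb <- classify_transfer(pres, "flesh", mode = "seed_baseline")
  expect_equal(sb$vertical_pct[[1]], 50)
  expect_equal(sb$horizontal_pct[[1]], 50)
  # A_g = A_0 -> vertical 100%
  expect_equal(sb$vertical_pct[[2]], 100)
  expect_equal(sb$horizontal_pct[[2]], 0)
})

test_that("chain-mode vertical sets never grow across generations", {
  sim <- simulate_dataset(simulation_config(
    seed_richness_flesh = 50, seed_richness_peel = 50,
    horizontal_pool_size = list(daughter = c(flesh = 40, peel = 40),
                                granddaughter = c(flesh = 60, peel = 60)),
    tare_soil_pool_size = 0, n_replicates = 3, rng_seed = 37L))
  pres <- presence_sets(sim$dataset)
  for (cv in c("Nadine", "RoyalBlue")) {
    for (comp in c("flesh", "peel")) {
      cls <- classify_transfer(pres, comp, cv, mode = "chain")
      expect_true(all(cls$vertical_taxa[[2]] %in% cls$vertical_taxa[[1]]))
    }
  }
})

test_that("flow_proportions reproduces the printed retention arithmetic", {
  # constructed presence map replicating the published stage counts
  md <- tiny_metadata(n_rep = 1, compartments = "flesh")
  taxa <- paste0("v", 1:13)
  counts <- matrix(0L, 13, 3, dimnames = list(taxa, md$sample_id))
  s <- function(g) md$sample_id[md$generation == g]
  counts[, s("seed")] <- 1L
  counts[, s("daughter")] <- 1L          # all 13 reach the daughter
  counts[1:10, s("granddaughter")] <- 1L # 10 of 13 retained
  ds <- validate_dataset(counts, md)
  pres <- presence_sets(ds, by = c("generation", "compartment"))
  fl <- flow_proportions(pres, data.frame(generation = c("seed", "daughter", "granddaughter"),
                                          compartment = "flesh"))
  expect_identical(fl$n_entering, c(13L, 13L))
  expect_identical(fl$n_retained, c(13L, 10L))
  expect_equal(fl$stage_pct[[2]], 100 * 10 / 13)
  expect_identical(fl$stage_pct_rounded[[2]], 77)

  # chained entering sets: a taxon lost once cannot re-enter
  counts2 <- counts
  counts2[11, s("granddaughter")] <- 1L
  counts2[11, s("daughter")] <- 0L
  ds2 <- validate_dataset(counts2, md)
  pres2 <- presence_sets(ds2, by = c("generation", "compartment"))
  fl2 <- flow_proportions(pres2, data.frame(generation = c("seed", "daughter", "granddaughter"),
                                            compartment = "flesh"))
  expect_false("v11" %in% fl2$retained_taxa[[2]])
  expect_true(all(fl2$retained_taxa[[2]] %in% fl2$retained_taxa[[1]]))
})

test_that("shared_unique counts exact membership patterns that sum to the union", {
  # disjoint sets
  out <- shared_unique(list(A = c("x", "y"), B = c("p", "q", "r")))
  expect_identical(out$n_taxa[out$members == "A"], 2L)
  expect_identical(out$n_taxa[out$members == "B"], 3L)
  expect_identical(out$n_taxa[out$members == "A+B"], 0L)
  # identical sets: only the full intersection is nonzero
  out2 <- shared_unique(list(A = c("x", "y"), B = c("x", "y")))
  expect_identical(out2$n_taxa[out2$members == "A+B"], 2L)
  expect_identical(sum(out2$n_taxa), 2L)
  # conservation on random sets
  set.seed(41)
  for (rep in 1:10) {
    sets <- lapply(1:4, function(i) sample(paste0("t", 1:30), sample(5:20, 1)))
    names(sets) <- paste0("g", 1:4)
    out3 <- shared_unique(sets)
    expect_identical(sum(out3$n_taxa), length(unique(unlist(sets))))
  }
  expect_error(shared_unique(list(A = "x")), "2-6")
})
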