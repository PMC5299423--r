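test_that("simulate_tree yields rooted binary ultrametric labeled trees", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)

  expect_identical(write_newick(simulate_tree(16, seed = 3)),
                   write_newick(simulate_tree(16, seed = 3)))

  tr <- simulate_tree(64, seed = 7)
  expect_equal(length(tr$tip.label), 64)
  expect_equal(tr$Nnode, 63)  # binary rooted: n - 1 internal nodes
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-10)
  expect_identical(tr$tip.label, sprintf("sp%04d", 1:64))

  expect_error(simulate_tree(1), ">= 2")
})

test_that("evolve_niche_optima matches the Brownian closed form", {
  t4 <- balanced4()
  # zero rate: every tip equals the root value
  expect_equal(unname(evolve_niche_optima(t4, 0, 1, 3.5, seed = 1)),
               rep(3.5, 4))
  expect_error(evolve_niche_optima(t4, 1, 1.2), "\\[0, 1\\]")

  n_rep <- 1500
  X1 <- vapply(seq_len(n_rep),
               function(i) evolve_niche_optima(t4, 1, 1, 0, seed = i),
               numeric(4))
  # lambda = 1: tip variance = sigma2 * depth, sister covariance = depth of MRCA
  expect_equal(mean(apply(X1, 1, var)), 2, tolerance = 0.15)
  expect_equal(cov(X1["A", ], X1["B", ]), 1, tolerance = 0.15)
  # lambda = 0: star tree, sisters independent but depth preserved
  X0 <- vapply(seq_len(n_rep),
               function(i) evolve_niche_optima(t4, 1, 0, 0, seed = 5000 + i),
               numeric(4))
  expect_lt(abs(cov(X0["A", ], X0["B", ])), 0.15)
  expect_equal(mean(apply(X0, 1, var)), 2, tolerance = 0.15)
})

test_that("environment fields honor the requested spatial correlation", {
  env <- generate_environment(12, 8, 20, 40, seed = 2)
  expect_identical(generate_environment(12, 8, 20, 40, seed = 2)$data,
                   env$data)
  # standardized linear fields
  expect_equal(mean(env$data$elevation), 0, tolerance = 1e-12)
  expect_equal(sd(env$data$elevation), 1, tolerance = 1e-12)
  expect_true(all(env$data$aspect >= 0 & env$data$aspect < 360))

  lag1 <- function(env) {
    m <- matrix(env$data$elevation, env$n_rows, env$n_cols, byrow = TRUE)
    cor(as.vector(m[, -1]), as.vector(m[, -env$n_cols]))
  }
  expect_lt(abs(lag1(generate_environment(50, 20, 20, 1e-6, seed = 3))), 0.1)
  # range >> plot extent: near-constant field. After standardization the
  # residual is a smooth gradient whose neighbour correlation plateaus just
  # above ~0.9 (seed-dependent); assert strong autocorrelation at 0.85.
  expect_gt(lag1(generate_environment(50, 20, 20, 1e4, seed = 4)), 0.85)
  expect_error(generate_environment(10, 10, 20, 0), "autocorr_range")
})

test_that("place_individuals follows the Gaussian niche response", {
  env <- generate_environment(20, 10, 20, 40, seed = 6)
  opt <- setNames(c(0.5, -0.5), c("spA", "spB"))
  expect_equal(nrow(place_individuals(opt, env, mean_abundance = 0,
                                      seed = 1)$stems), 0)
  expect_error(place_individuals(opt, env, niche_breadth = 0), "niche_breadth")

  # wide niche: occupied-quadrat environment mean approaches the plot mean
  wide <- place_individuals(setNames(0, "spA"), env, "elevation",
                            niche_breadth = 100, mean_abundance = 2000,
                            seed = 8)
  idx <- nichesignal:::quadrat_index(wide$stems$row, wide$stems$col,
                                     env$n_cols)
  expect_lt(abs(mean(env$data$elevation[idx]) - mean(env$data$elevation)),
            0.1)
  # narrow niche: stems sit within one breadth of the optimum on average
  narrow <- place_individuals(setNames(0.8, "spA"), env, "elevation",
                              niche_breadth = 0.2, mean_abundance = 400,
                              seed = 9)
  idx <- nichesignal:::quadrat_index(narrow$stems$row, narrow$stems$col,
                                     env$n_cols)
  expect_lt(abs(mean(env$data$elevation[idx]) - 0.8), 0.2)
})

test_that("simulate_forest is deterministic and internally consistent", {
  cfg <- simulation_config(n_species = 10, grid_width = 8, grid_height = 5,
                           mean_abundance = 40, seedling_abundance = 15,
                           seed = 12)
  a <- simulate_forest(cfg)
  b <- simulate_forest(cfg)
  expect_identical(a$stems$stems, b$stems$stems)
  expect_identical(a$env$data, b$env$data)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_setequal(unique(a$stems$stems$stage), c("adult", "seedling"))
  expect_true(all(a$stems$stems$species %in% a$tree$tip.label))
  expect_equal(a$truth$species, a$tree$tip.label)
})

test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(conservatism_lambda = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(niche_breadth = 0), "niche_breadth")
  expect_error(simulation_config(quadrat_size = -1), "quadrat_size")
  expect_error(simulation_config(n_species = 1), "n_species")
})
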