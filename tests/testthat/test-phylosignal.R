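test_that("phylo_covariance reads shared branch lengths off the tree", {
  cherry <- parse_newick("(A:1,B:1);")
  expect_equal(unname(phylo_covariance(cherry)), diag(2))

  V <- phylo_covariance(balanced4())
  expect_equal(diag(V), c(A = 2, B = 2, C = 2, D = 2))
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)

  # agrees with ape's construction and stays PSD on random trees
  for (seed in 1:25) {
    set.seed(seed)
    tr <- random_tree(sample(4:20, 1))
    V <- phylo_covariance(tr)
    expect_equal(V, ape::vcv(tr)[rownames(V), colnames(V)], tolerance = 1e-12)
    expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("patristic distances match ape's cophenetic distances", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- random_tree(sample(4:15, 1))
    D <- patristic_distances(tr)
    expect_equal(D, ape::cophenetic.phylo(tr)[rownames(D), colnames(D)],
                 tolerance = 1e-10)
  }
})

test_that("blomberg_k matches the brute-force GLS oracle", {
  set.seed(42)
  for (i in 1:30) {
    tr <- random_tree(sample(5:15, 1))
    x <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
    expect_equal(blomberg_k(tr, x), oracle_blomberg_k(tr, x),
                 tolerance = 1e-10)
  }
})

test_that("K separates clade-concordant from clade-discordant traits", {
  t4 <- balanced4()
  concord <- setNames(c(0, 0, 10, 10), c("A", "B", "C", "D"))
  discord <- setNames(c(0, 10, 0, 10), c("A", "B", "C", "D"))
  expect_gt(blomberg_k(t4, concord), 1)
  expect_lt(blomberg_k(t4, discord), 1)
  expect_equal(blomberg_k(t4, concord), oracle_blomberg_k(t4, concord),
               tolerance = 1e-12)
})

test_that("K is invariant to affine traits, branch rescaling, tip order", {
  set.seed(7)
  tr <- random_tree(12)
  x <- setNames(rnorm(12), tr$tip.label)
  k0 <- blomberg_k(tr, x)
  expect_equal(blomberg_k(tr, 3 * x - 5), k0, tolerance = 1e-10)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 7.3
  expect_equal(blomberg_k(tr2, x), k0, tolerance = 1e-10)
  expect_equal(blomberg_k(tr, x[sample(names(x))]), k0, tolerance = 1e-12)
})

test_that("blomberg_k rejects degenerate input", {
  tr <- balanced4()
  expect_error(blomberg_k(tr, setNames(rep(1, 4), tr$tip.label)), "constant")
  expect_error(blomberg_k(tr, setNames(1:4, c("A", "B", "C", "X"))),
               "mismatch")
  expect_error(blomberg_k(tr, 1:4), "named")
  expect_error(blomberg_k(parse_newick("(A:1,B:1);"),
                          setNames(1:2, c("A", "B"))), ">= 3 tips")
})

test_that("the K permutation test detects clade structure and is seeded", {
  tr <- balanced_tree(32)
  trait <- setNames(as.numeric(grepl("^t([1-9]|1[0-6])$", tr$tip.label)),
                    tr$tip.label)
  # trait = indicator of one 16-tip clade: shuffles destroy the structure
  res <- k_permutation_test(tr, trait, n_perm = 999, seed = 5)
  expect_lte(res$p_value, 0.01)
  expect_gte(res$p_value, 1 / 1000)  # add-one lower bound
  res2 <- k_permutation_test(tr, trait, n_perm = 999, seed = 5)
  expect_identical(res2$p_value, res$p_value)
  expect_identical(res2$null, res$null)
})

test_that("sankoff_score matches exhaustive enumeration", {
  t4 <- balanced4()
  states <- c("v", "v", "r", "r")
  expect_equal(sankoff_score(t4, setNames(states, c("A", "B", "C", "D"))), 1)
  expect_equal(sankoff_score(t4, setNames(c("v", "r", "v", "r"),
                                          c("A", "B", "C", "D"))), 2)
  expect_equal(sankoff_score(t4, setNames(rep("v", 4),
                                          c("A", "B", "C", "D"))), 0)

  set.seed(11)
  n_cases <- 0
  for (i in 1:60) {
    n_states <- sample(2:3, 1)
    tr <- random_tree(sample(4:8, 1))
    alphabet <- letters[seq_len(n_states)]
    cost <- unit_cost(alphabet)
    if (i %% 3 == 0) {  # asymmetric non-unit costs exercise the DP fully
      cost[upper.tri(cost)] <- sample(1:4, sum(upper.tri(cost)), TRUE)
      cost[lower.tri(cost)] <- sample(1:4, sum(lower.tri(cost)), TRUE)
    }
    st <- setNames(sample(alphabet, length(tr$tip.label), replace = TRUE),
                   tr$tip.label)
    expect_equal(sankoff_score(tr, st, cost), oracle_sankoff(tr, st, cost))
    n_cases <- n_cases + 1
  }
  expect_gte(n_cases, 60)
})

test_that("sankoff input validation catches bad states and costs", {
  t4 <- balanced4()
  expect_error(sankoff_score(t4, setNames(c("v", "v", "r"), c("A", "B", "C"))),
               "without a state")
  bad_cost <- matrix(c(0, 1, 1, 1), 2, 2, dimnames = list(c("v", "r"),
                                                          c("v", "r")))
  expect_error(sankoff_score(t4, setNames(c("v", "v", "r", "r"),
                                          c("A", "B", "C", "D")), bad_cost),
               "diagonal")
  expect_error(sankoff_score(t4, setNames(c("v", "v", "r", "x"),
                                          c("A", "B", "C", "D")),
                             unit_cost(c("v", "r"))), "absent")
})

test_that("the Sankoff permutation test flags clade-partitioned states", {
  tr <- balanced_tree(32)
  states <- setNames(rep(c("v", "r"), each = 16), tr$tip.label)
  res <- sankoff_permutation_test(tr, states, n_perm = 999, seed = 9)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 0.01)
  # degenerate: one state everywhere -> score 0 always -> p = 1
  mono <- sankoff_permutation_test(tr, setNames(rep("v", 32), tr$tip.label),
                                   n_perm = 99, seed = 2)
  expect_equal(mono$observed, 0)
  expect_equal(mono$p_value, 1)
})

test_that("MPD and MNTD follow the worked 4-tip example", {
  t4 <- balanced4()
  expect_equal(pairwise_dispersion(t4, c("A", "B")),
               c(mpd = 2, mntd = 2))
  expect_equal(pairwise_dispersion(t4, c("A", "B", "C", "D")),
               c(mpd = 20 / 6, mntd = 2))
  expect_error(pairwise_dispersion(t4, "A"), ">= 2")
  # MNTD <= MPD over random groups
  set.seed(13)
  tr <- random_tree(20)
  for (i in 1:20) {
    g <- sample(tr$tip.label, sample(3:10, 1))
    d <- pairwise_dispersion(tr, g)
    expect_lte(d[["mntd"]], d[["mpd"]] + 1e-12)
  }
})

test_that("ses_dispersion signs follow clustering and overdispersion", {
  tr <- balanced_tree(16)
  clade <- c("t1", "t2", "t3", "t4")  # one 4-tip clade
  res <- ses_dispersion(tr, clade, n_null = 499, seed = 3)
  expect_gt(res$nri, 0)
  expect_gt(res$nti, 0)
  expect_lt(res$p_mpd, 0.05)

  # the two most distant tips: overdispersed
  D <- patristic_distances(tr)
  far <- rownames(D)[arrayInd(which.max(D), dim(D))[1, ]]
  res2 <- ses_dispersion(tr, far, n_null = 499, seed = 4)
  expect_lt(res2$nri, 0)

  expect_error(ses_dispersion(tr, tr$tip.label), "strict subset")
  expect_error(ses_dispersion(tr, c("t1", "ghost")), "subset")
})

test_that("uniform random groups have mean NRI near zero", {
  tr <- balanced_tree(16)
  D <- patristic_distances(tr)
  set.seed(19)
  nri <- vapply(1:300, function(i) {
    g <- sample(tr$tip.label, 6)
    ses_dispersion(tr, g, n_null = 99, seed = 100 + i,
                   dist_matrix = D)$nri
  }, 1)
  expect_lt(abs(mean(nri)), 0.1)
})
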