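test_that("classify_habitats recovers separable elevation groups", {
  env1 <- make_env(3, 4)
  m1 <- classify_habitats(env1, 1)
  expect_true(all(m1$labels == 1L))

  # two well-separated elevation levels, k = 2 -> labels match the groups
  elev <- rep(c(-5, 5), each = 10)
  env2 <- make_env(4, 5, elevation = elev,
                   convexity = rep(0.01 * (1:20)), slope = rep(0, 20),
                   aspect = rep(90, 20))
  m2 <- classify_habitats(env2, 2)
  lab <- as.vector(t(m2$labels))  # row-major, matches env$data order
  expect_equal(lab, rep(c(1L, 2L), each = 10))

  env3 <- make_env(5, 8)
  a <- classify_habitats(env3, 3)
  expect_identical(classify_habitats(env3, 3)$labels, a$labels)
  expect_setequal(a$names, c("valley", "slope", "ridge"))
  # valley is the lowest-elevation class
  by_class <- tapply(env3$data$elevation, as.vector(t(a$labels)), mean)
  expect_equal(a$names[as.integer(names(which.min(by_class)))], "valley")
  expect_error(classify_habitats(env3, 41), "exceeds")
})

test_that("habitat_relative_density counts stems per habitat quadrat", {
  fx <- stripe_fixture()
  # all 8 stems inside the 10-quadrat stripe
  expect_equal(habitat_relative_density(fx$stems, fx$map, "spA", "stripe"),
               8 / 10)
  expect_equal(habitat_relative_density(fx$stems, fx$map, "spA", "matrix"), 0)
  expect_error(habitat_relative_density(fx$stems, fx$map, "ghost", "stripe"),
               "no stems")
  expect_error(habitat_relative_density(fx$stems, fx$map, "spA", "bog"),
               "unknown habitat")

  # checkerboard habitat, uniform stems: density == overall stems/quadrat
  lab <- matrix(rep_len(c(1L, 2L), 16), 4, 4)
  map <- habitat_map(lab, c("black", "white"))
  grid <- expand.grid(row = 0:3, col = 0:3)
  sm <- stems_at(grid$row, grid$col, extent = c(80, 80))
  expect_equal(habitat_relative_density(sm, map, "spA", "black"), 1)
  expect_equal(habitat_relative_density(sm, map, "spA", "white"), 1)
})

test_that("degenerate one-habitat torus null is neutral at quantile ~0.5", {
  map <- habitat_map(matrix(1L, 4, 4), "all")
  sm <- stems_at(c(0, 1, 2), c(0, 1, 2), extent = c(80, 80))
  res <- torus_translation_test(sm, map, "spA", include_reflections = FALSE)
  n <- attr(res, "n_translations")
  expect_equal(n, 16)
  expect_equal(res$quantile, (n + 1) / (2 * n))  # all null values tie
  expect_equal(res$verdict, "neutral")
})

test_that("stripe fixture reproduces the hand-enumerated torus null", {
  # A vertical 2-column stripe is invariant under row translation, so each
  # of the 5 column offsets appears 5 times in the 25-shift null. With all
  # 8 stems in the stripe the null multiset is {0.8 x5, 0.4 x10, 0 x10} and
  # the observed 0.8 has mean-rank quantile (20 + (5 + 1)/2)/25 = 0.92.
  fx <- stripe_fixture()
  counts <- matrix(0, 5, 5)
  for (i in seq_len(nrow(fx$stems$stems))) {
    counts[fx$stems$stems$row[i] + 1, fx$stems$stems$col[i] + 1] <-
      counts[fx$stems$stems$row[i] + 1, fx$stems$stems$col[i] + 1] + 1
  }
  null <- c()
  for (dc in 0:4) {
    cols <- ((0:4 + dc) %% 5) + 1  # stripe occupies shifted columns
    null <- c(null, rep(sum(counts[, cols[1:2]]) / 10, 5))  # row shifts tie
  }
  expect_equal(max(null), 0.8)
  expect_equal(sum(null == 0.8), 5)
  hand_quantile <- (sum(null < 0.8) + (sum(null == 0.8) + 1) / 2) / 25

  res <- torus_translation_test(fx$stems, fx$map, "spA", alpha = 0.1,
                                include_reflections = FALSE)
  expect_equal(attr(res, "n_translations"), 25)
  row <- res[res$habitat == "stripe", ]
  expect_equal(row$density, 0.8)
  expect_equal(row$quantile, hand_quantile)
  expect_equal(row$quantile, 0.92)
  expect_equal(row$verdict, "positive")  # at alpha = 0.1
})

test_that("torus shifts preserve habitat composition", {
  env <- make_env(5, 6)
  map <- classify_habitats(env, 3)
  null <- nichesignal:::torus_null_stats(
    matrix(1, nichesignal:::n_quadrats(env), 1), map,
    include_reflections = TRUE
  )
  # a species occupying every quadrat once: statistic = n_h/n_h-normalized
  # count, equal across shifts iff per-habitat quadrat counts are preserved
  for (h in seq_len(map$k)) {
    expect_equal(var(null[1, h, ]), 0)
  }
})

test_that("verdicts are covariant under joint translation", {
  set.seed(21)
  env <- make_env(5, 6)
  map <- classify_habitats(env, 3)
  n <- 40
  rows <- sample(0:4, n, replace = TRUE)
  cols <- sample(0:5, n, replace = TRUE)
  sm <- stems_at(rows, cols, extent = c(120, 100))
  base <- torus_association(sm, map, "spA", include_reflections = FALSE)
  for (shift in list(c(2, 1), c(4, 3))) {
    map2 <- habitat_map(
      map$labels[((0:4 - shift[1]) %% 5) + 1, ((0:5 - shift[2]) %% 6) + 1],
      map$names
    )
    sm2 <- stems_at((rows + shift[1]) %% 5, (cols + shift[2]) %% 6,
                    extent = c(120, 100))
    moved <- torus_association(sm2, map2, "spA", include_reflections = FALSE)
    expect_equal(moved$quantile, base$quantile)
    expect_equal(moved$verdict, base$verdict)
  }
})

test_that("torus verdicts under a random null hit the nominal rate", {
  # uniformly placed stems on the stripe map: positive rate ~ alpha per tail
  fx <- stripe_fixture()
  set.seed(31)
  n_rep <- 400
  verdicts <- character(n_rep)
  for (i in seq_len(n_rep)) {
    sm <- stems_at(sample(0:4, 12, replace = TRUE),
                   sample(0:4, 12, replace = TRUE), extent = c(100, 100))
    res <- torus_association(sm, fx$map, "spA", alpha = 0.1,
                             include_reflections = FALSE)
    verdicts[i] <- res$verdict[res$habitat == "stripe"]
  }
  expect_equal(mean(verdicts == "positive"), 0.1, tolerance = 0.6)
  expect_lt(mean(verdicts == "positive"), 0.25)
})

test_that("torus test rejects zero-stem species and bad alpha", {
  fx <- stripe_fixture()
  expect_error(torus_association(fx$stems, fx$map, "nobody"), "0 stems")
  expect_error(torus_association(fx$stems, fx$map, "spA", alpha = 0.6),
               "alpha")
})
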