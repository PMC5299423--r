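# Fixtures built in code: small reference trees and constructed grids.

# Balanced 4-tip tree used throughout the hand-worked examples:
# diag(V) = 2, V[A,B] = 1, V[A,C] = 0; all 6 pairwise distances {2,2,4,4,4,4}.
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# Balanced ultrametric tree with 2^m tips and unit branch lengths.
balanced_tree <- function(n_tips) {
  tr <- ape::stree(n_tips, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# Random rooted binary tree with strictly positive branch lengths.
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# Minimal complete environment grid with prescribed per-quadrat elevation
# (row-major). Other variables default to inert values unless supplied.
make_env <- function(n_rows, n_cols, elevation = NULL, quadrat_size = 20,
                     ...) {
  n <- n_rows * n_cols
  grid <- expand.grid(col = 0:(n_cols - 1), row = 0:(n_rows - 1))
  dat <- data.frame(row = grid$row, col = grid$col)
  set.seed(99)
  defaults <- list(
    aspect = seq(0, 359, length.out = n),
    convexity = rnorm(n), elevation = elevation %||% rnorm(n),
    slope = rnorm(n)
  )
  soil <- setNames(as.data.frame(matrix(rnorm(n * 9), n, 9)),
                   nichesignal:::SOIL_VARS)
  dat <- cbind(dat, defaults, soil)
  extra <- list(...)
  for (nm in names(extra)) dat[[nm]] <- extra[[nm]]
  environment_grid(dat, quadrat_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A stem map with one stem per given quadrat (row, col), single species.
stems_at <- function(rows, cols, species = "spA", stage = "adult",
                     quadrat_size = 20, extent) {
  n <- length(rows)
  stem_map(data.frame(
    tag = sprintf("t%04d", seq_len(n)), species = species,
    x = (cols + 0.5) * quadrat_size, y = (rows + 0.5) * quadrat_size,
    stage = stage
  ), extent = extent, quadrat_size = quadrat_size)
}

# 5x5 grid with a 2-column habitat stripe (columns 0 and 1 are "stripe").
stripe_fixture <- function() {
  labels <- matrix(2L, 5, 5)
  labels[, 1:2] <- 1L
  map <- habitat_map(labels, c("stripe", "matrix"))
  stems <- stems_at(rows = c(0, 1, 2, 3, 4, 0, 1, 2),
                    cols = c(0, 0, 0, 1, 1, 1, 1, 0),
                    extent = c(100, 100))
  list(map = map, stems = stems)
}
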