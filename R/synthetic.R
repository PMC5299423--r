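# Synthetic forest-plot generator: pure-birth phylogeny, Brownian-motion
# niche optima with a conservatism knob, spatially autocorrelated environment
# fields, and Gaussian niche-response stem placement. Everything is seeded so
# downstream stages can be tested against known ground truth.

#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic world. Defaults describe
#' a plot of 50 x 20 quadrats of 20 m (the scale at which the environment
#' and occupancy are tabulated), 64 species, unit-rate Brownian niche
#' evolution on a depth-1 tree, and a moderate Gaussian niche breadth.
#'
#' @param n_species Number of tips / species (>= 2).
#' @param grid_width,grid_height Quadrat counts (columns, rows).
#' @param quadrat_size Quadrat side, meters.
#' @param autocorr_range Correlation length (meters) of the exponential
#'   spatial covariance of the environment fields.
#' @param bm_sigma2 Brownian rate: trait variance per unit branch length.
#' @param conservatism_lambda In `[0, 1]`: internal-branch scaling. 1 keeps
#'   the full Brownian covariance (conserved niches); 0 collapses the tree
#'   to a star (fully labile niches).
#' @param niche_breadth Standard deviation (environment units) of the
#'   Gaussian occurrence response.
#' @param mean_abundance Expected stems per species for the adult stage.
#' @param seedling_abundance Expected stems per species for the seedling
#'   stage.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 64, grid_width = 50,
                              grid_height = 20, quadrat_size = 20,
                              autocorr_range = 40, bm_sigma2 = 1,
                              conservatism_lambda = 1, niche_breadth = 0.5,
                              mean_abundance = 150, seedling_abundance = 60,
                              seed = 1) {
  assert_scalar_number(n_species, "n_species", 2)
  assert_scalar_number(grid_width, "grid_width", 1)
  assert_scalar_number(grid_height, "grid_height", 1)
  assert_scalar_number(quadrat_size, "quadrat_size", 0, strict_min = TRUE)
  assert_scalar_number(autocorr_range, "autocorr_range", 0, strict_min = TRUE)
  assert_scalar_number(bm_sigma2, "bm_sigma2", 0)
  assert_scalar_number(conservatism_lambda, "conservatism_lambda", 0)
  if (conservatism_lambda > 1) stop_ns("`conservatism_lambda` must be in [0, 1]")
  assert_scalar_number(niche_breadth, "niche_breadth", 0, strict_min = TRUE)
  assert_scalar_number(mean_abundance, "mean_abundance", 0)
  assert_scalar_number(seedling_abundance, "seedling_abundance", 0)
  assert_scalar_number(seed, "seed", 1)
  structure(list(
    n_species = as.integer(n_species), grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height), quadrat_size = quadrat_size,
    autocorr_range = autocorr_range, bm_sigma2 = bm_sigma2,
    conservatism_lambda = conservatism_lambda, niche_breadth = niche_breadth,
    mean_abundance = mean_abundance, seedling_abundance = seedling_abundance,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Yule tree with unit birth rate, rescaled to root-to-tip depth 1 and
#' relabeled `sp0001`, `sp0002`, ... The tree is rooted, binary and
#' ultrametric; identical `(n_species, seed)` give identical trees.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` tree.
#' @export
#' @examples
#' tr <- simulate_tree(8, seed = 1)
simulate_tree <- function(n_species, seed = 1) {
  assert_scalar_number(n_species, "n_species", 2)
  n_species <- as.integer(n_species)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%04d", seq_len(n_species))
  tree
}

# Pagel-style lambda transform: internal branches scaled by lambda, tip
# branches stretched so every root-to-tip depth is preserved.
lambda_transform <- function(tree, lambda) {
  if (lambda < 0 || lambda > 1) stop_ns("`lambda` must be in [0, 1]")
  if (lambda == 1) return(tree)
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  is_tip <- tree$edge[, 2] <= n_tip
  out <- tree
  out$edge.length[!is_tip] <- tree$edge.length[!is_tip] * lambda
  parent_depth <- depth[tree$edge[is_tip, 1]]
  tip_depth <- depth[tree$edge[is_tip, 2]]
  out$edge.length[is_tip] <- tip_depth - lambda * parent_depth
  out
}

#' Evolve niche optima along a phylogeny
#'
#' Brownian-motion trait simulation on a lambda-transformed tree: Gaussian
#' increments with variance `bm_sigma2 * branch length` accumulate from the
#' root. `conservatism_lambda = 1` is plain Brownian motion;
#' `conservatism_lambda = 0` yields independent tip values (star phylogeny),
#' i.e. fully labile niches.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param bm_sigma2 Brownian rate (variance per unit branch length, >= 0).
#' @param conservatism_lambda Internal-branch scaling in `[0, 1]`.
#' @param root_value Trait value at the root.
#' @param seed Integer seed (or `NULL` to use the ambient RNG stream).
#' @return Named numeric vector of tip trait values (names = tip labels).
#' @export
evolve_niche_optima <- function(tree, bm_sigma2 = 1, conservatism_lambda = 1,
                                root_value = 0, seed = NULL) {
  tree <- validate_tree(tree)
  assert_scalar_number(bm_sigma2, "bm_sigma2", 0)
  if (conservatism_lambda < 0 || conservatism_lambda > 1) {
    stop_ns("`conservatism_lambda` must be in [0, 1]")
  }
  tr <- lambda_transform(tree, conservatism_lambda)
  with_seed(seed, bm_tips(tr, bm_sigma2, root_value))
}

# One BM realization on an already-transformed tree; consumes the ambient
# RNG stream.
bm_tips <- function(tree, sigma2, root_value) {
  n_tip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  vals <- rep(NA_real_, n_node)
  vals[n_tip + 1L] <- root_value
  inc <- stats::rnorm(nrow(ord$edge), 0, sqrt(sigma2 * ord$edge.length))
  # preorder = reversed postorder: parents are filled before children
  for (e in rev(seq_len(nrow(ord$edge)))) {
    vals[ord$edge[e, 2]] <- vals[ord$edge[e, 1]] + inc[e]
  }
  stats::setNames(vals[seq_len(n_tip)], tree$tip.label)
}

# Gaussian random field with exponential covariance exp(-d / range) on the
# quadrat centers, via dense Cholesky. `n_fields` independent fields share
# one factorization.
grf_fields <- function(n_rows, n_cols, quadrat_size, range, n_fields) {
  xy <- expand.grid(
    col = (seq_len(n_cols) - 1) * quadrat_size + quadrat_size / 2,
    row = (seq_len(n_rows) - 1) * quadrat_size + quadrat_size / 2
  )
  d <- as.matrix(stats::dist(xy[, c("col", "row")]))
  C <- exp(-d / range)
  L <- chol(C + diag(1e-8, nrow(C)))
  z <- matrix(stats::rnorm(nrow(C) * n_fields), nrow(C), n_fields)
  crossprod(L, z)
}

#' Generate a synthetic environment grid
#'
#' Each of the 12 linear variables (convexity, elevation, slope and nine
#' soil nutrients) is a stationary Gaussian random field with exponential
#' spatial correlation `exp(-d / autocorr_range)`, standardized to zero mean
#' and unit variance over the grid. Aspect is a spatially autocorrelated
#' circular field in `[0, 360)` degrees, built as the angle of two auxiliary
#' Gaussian fields; downstream analyses consume it as northness
#' `cos(aspect * pi / 180)`.
#'
#' @inheritParams simulation_config
#' @param seed Integer seed.
#' @return An `environment_grid`.
#' @export
generate_environment <- function(grid_width = 50, grid_height = 20,
                                 quadrat_size = 20, autocorr_range = 40,
                                 seed = 1) {
  assert_scalar_number(grid_width, "grid_width", 1)
  assert_scalar_number(grid_height, "grid_height", 1)
  assert_scalar_number(quadrat_size, "quadrat_size", 0, strict_min = TRUE)
  assert_scalar_number(autocorr_range, "autocorr_range", 0, strict_min = TRUE)
  n_rows <- as.integer(grid_height)
  n_cols <- as.integer(grid_width)
  vars <- c("convexity", "elevation", "slope", SOIL_VARS)
  fields <- with_seed(seed, grf_fields(n_rows, n_cols, quadrat_size,
                                       autocorr_range, length(vars) + 2L))
  lin <- fields[, seq_along(vars), drop = FALSE]
  lin <- scale(lin)  # zero mean, unit variance per column
  aspect <- (atan2(fields[, length(vars) + 1L],
                   fields[, length(vars) + 2L]) * 180 / pi) %% 360
  grid <- expand.grid(col = 0:(n_cols - 1L), row = 0:(n_rows - 1L))
  # expand.grid varies col fastest -> row-major order matching quadrat_index
  data <- data.frame(row = grid$row, col = grid$col, aspect = aspect)
  data[vars] <- as.data.frame(lin)
  environment_grid(data[c("row", "col", TOPO_VARS, SOIL_VARS)], quadrat_size)
}

#' Place stems by a Gaussian niche response
#'
#' For each species, per-quadrat Poisson intensities are proportional to
#' `exp(-(x_q - optimum)^2 / (2 * niche_breadth^2))` where `x_q` is the
#' quadrat's value on `axis`, scaled so the expected total equals
#' `mean_abundance`; stem positions are uniform within their quadrat.
#'
#' @param optima Named numeric vector of niche optima (names = species).
#' @param env An `environment_grid`.
#' @param axis Grid variable carrying the niche signal (default
#'   `"elevation"`; `"northness"` is derived from aspect).
#' @param niche_breadth Gaussian response s.d. (> 0).
#' @param mean_abundance Expected stems per species (>= 0).
#' @param stage Life stage recorded for every stem.
#' @param seed Integer seed.
#' @param tag_prefix Prefix for the generated stem tags.
#' @return A `stem_map`.
#' @export
place_individuals <- function(optima, env, axis = "elevation",
                              niche_breadth = 0.5, mean_abundance = 150,
                              stage = "adult", seed = 1, tag_prefix = stage) {
  assert_scalar_number(niche_breadth, "niche_breadth", 0, strict_min = TRUE)
  assert_scalar_number(mean_abundance, "mean_abundance", 0)
  if (is.null(names(optima)) || anyNA(names(optima))) {
    stop_ns("`optima` must be a named vector (names = species)")
  }
  x <- axis_values(env, axis)
  qs <- env$quadrat_size
  with_seed(seed, {
    recs <- lapply(names(optima), function(sp) {
      w <- exp(-(x - optima[[sp]])^2 / (2 * niche_breadth^2))
      if (sum(w) == 0 || mean_abundance == 0) {
        lam <- rep(0, length(x))
      } else {
        lam <- w / sum(w) * mean_abundance
      }
      counts <- stats::rpois(length(lam), lam)
      idx <- rep(seq_along(counts), counts)
      if (!length(idx)) return(NULL)
      data.frame(
        species = sp,
        x = (env$data$col[idx] + stats::runif(length(idx))) * qs,
        y = (env$data$row[idx] + stats::runif(length(idx))) * qs,
        stringsAsFactors = FALSE
      )
    })
    recs <- do.call(rbind, recs)
    if (is.null(recs)) {
      recs <- data.frame(species = character(0), x = numeric(0),
                         y = numeric(0))
    }
    recs$tag <- if (nrow(recs)) {
      sprintf("%s%06d", tag_prefix, seq_len(nrow(recs)))
    } else character(0)
    recs$stage <- rep(stage, nrow(recs))
    stem_map(recs, extent = c(env$n_cols, env$n_rows) * qs,
             quadrat_size = qs)
  })
}

#' Simulate a complete forest plot
#'
#' Runs the four generator stages under sub-seeds derived from the master
#' seed: phylogeny, niche optima (shared across life stages, so stages agree
#' on the truth), environment, and independent adult/seedling placements on
#' the elevation axis.
#'
#' @param config A [simulation_config()].
#' @return List with `tree`, `env`, `stems` (both stages pooled in one
#'   `stem_map`), `truth` (species, optimum, expected abundances) and
#'   `config`.
#' @export
simulate_forest <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- split_seed(config$seed, 4L)
  tree <- simulate_tree(config$n_species, seed = seeds[1])
  optima <- evolve_niche_optima(tree, config$bm_sigma2,
                                config$conservatism_lambda,
                                root_value = 0, seed = seeds[2])
  env <- generate_environment(config$grid_width, config$grid_height,
                              config$quadrat_size, config$autocorr_range,
                              seed = seeds[3])
  pseeds <- split_seed(seeds[4], 2L)
  adults <- place_individuals(optima, env, "elevation", config$niche_breadth,
                              config$mean_abundance, stage = "adult",
                              seed = pseeds[1], tag_prefix = "a")
  seedlings <- place_individuals(optima, env, "elevation",
                                 config$niche_breadth,
                                 config$seedling_abundance,
                                 stage = "seedling", seed = pseeds[2],
                                 tag_prefix = "s")
  stems <- stem_map(rbind(adults$stems[c("tag", "species", "x", "y", "stage")],
                          seedlings$stems[c("tag", "species", "x", "y", "stage")]),
                    extent = adults$extent, quadrat_size = config$quadrat_size)
  truth <- data.frame(
    species = names(optima), optimum = as.numeric(optima),
    adult_abundance = config$mean_abundance,
    seedling_abundance = config$seedling_abundance,
    stringsAsFactors = FALSE
  )
  list(tree = tree, env = env, stems = stems, truth = truth, config = config)
}

#' Write a simulated plot to disk
#'
#' Emits `tree.nwk`, `stems.csv`, `environment.csv`, `truth.csv` and
#' `config.txt` (flat key=value) under `dir`.
#'
#' @param sim Result of [simulate_forest()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(write_newick(sim$tree), file.path(dir, "tree.nwk"))
  write_plot_tables(sim$stems, sim$env, file.path(dir, "stems.csv"),
                    file.path(dir, "environment.csv"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  write_config(unclass(sim$config), file.path(dir, "config.txt"))
  invisible(dir)
}
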