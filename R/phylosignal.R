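# Phylogenetic-signal statistics and their permutation nulls: Blomberg's K
# for continuous niche values, Sankoff parsimony for categorical habitat
# associations, and NRI/NTI (standardized effect sizes of MPD/MNTD) for
# habitat-preference groups.

#' Phylogenetic covariance matrix
#'
#' `V[i, j]` is the shared branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip depths.
#' Built by a single postorder traversal (no calls into tree libraries), so
#' tests can check it against an independent construction.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric positive-semidefinite matrix with tip labels as
#'   dimnames, tips in `tree$tip.label` order.
#' @export
phylo_covariance <- function(tree) {
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  # node depths via preorder (reversed postorder)
  depth <- rep(NA_real_, n_node)
  depth[n_tip + 1L] <- 0
  for (e in rev(seq_len(nrow(ord$edge)))) {
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  }
  V <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(n_tip)]
  # tip-descendant sets accumulate bottom-up; when a child block joins a
  # node, its tips share depth[node] with all tips already gathered there
  tipsets <- vector("list", n_node)
  tipsets[seq_len(n_tip)] <- as.list(seq_len(n_tip))
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]
    child_tips <- tipsets[[ord$edge[e, 2]]]
    prev <- tipsets[[parent]]
    if (!is.null(prev) && length(prev)) {
      V[prev, child_tips] <- depth[parent]
      V[child_tips, prev] <- depth[parent]
    }
    tipsets[[parent]] <- c(prev, child_tips)
  }
  V
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between each pair of tips, derived
#' from the phylogenetic covariance: `d_ij = depth_i + depth_j - 2 V_ij`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric distance matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  V <- phylo_covariance(tree)
  d <- diag(V)
  outer(d, d, "+") - 2 * V
}

# Reusable pieces of the K computation for one tree: V^{-1} (via Cholesky),
# its row sums, and the Brownian-expectation denominator.
k_precompute <- function(tree) {
  V <- phylo_covariance(tree)
  n <- nrow(V)
  if (n < 3) stop_ns("Blomberg's K needs >= 3 tips")
  Vi <- chol2inv(chol(V))
  s <- sum(Vi)
  list(
    tips = rownames(V), n = n, Vi = Vi, Vi1 = rowSums(Vi), s = s,
    expected_ratio = (sum(diag(V)) - n / s) / (n - 1)
  )
}

# Vectorized K over the columns of a trait matrix (rows in pre$tips order).
blomberg_k_many <- function(pre, X) {
  X <- as.matrix(X)
  a_hat <- colSums(pre$Vi1 * X) / pre$s
  Xc <- sweep(X, 2, a_hat, "-")
  mse0 <- colSums(Xc^2)
  mse <- colSums(Xc * (pre$Vi %*% Xc))
  (mse0 / mse) / pre$expected_ratio
}

check_trait <- function(trait, tips) {
  if (is.null(names(trait))) stop_ns("`trait` must be named by tip label")
  miss <- setdiff(tips, names(trait))
  extra <- setdiff(names(trait), tips)
  if (length(miss) || length(extra)) {
    stop_ns("trait/tip label mismatch",
            if (length(miss)) paste0("; missing: ",
                                     paste(utils::head(miss, 5), collapse = ", ")),
            if (length(extra)) paste0("; unknown: ",
                                      paste(utils::head(extra, 5), collapse = ", ")))
  }
  trait <- trait[tips]
  if (anyNA(trait)) stop_ns("trait contains NA")
  if (stats::sd(trait) == 0) stop_ns("trait is constant; K is undefined")
  trait
}

#' Blomberg's K statistic
#'
#' Ratio of the observed to the Brownian-expected mean-squared-error ratio:
#' with GLS root estimate `a = (1' V^-1 X) / (1' V^-1 1)`,
#' `MSE0 = (X - a)'(X - a) / (n - 1)`,
#' `MSE = (X - a)' V^-1 (X - a) / (n - 1)`, and
#' `K = (MSE0 / MSE) / ((tr V - n / (1' V^-1 1)) / (n - 1))`.
#' `K = 1` matches Brownian motion on the tree; `K > 1` means close
#' relatives are more similar than the Brownian expectation, `K < 1` less.
#' K is invariant to affine trait transforms and to rescaling all branch
#' lengths by a common factor.
#'
#' @param tree A `phylo` tree with branch lengths (>= 3 tips).
#' @param trait Named numeric vector of tip values (non-constant).
#' @return K, a positive scalar.
#' @export
blomberg_k <- function(tree, trait) {
  pre <- k_precompute(tree)
  as.numeric(blomberg_k_many(pre, matrix(check_trait(trait, pre$tips))))
}

#' Permutation test for Blomberg's K
#'
#' Trait values are shuffled across the tips `n_perm` times; the p-value is
#' the add-one upper tail `p = (1 + #\{K_perm >= K_obs\}) / (1 + n_perm)`
#' (one-tailed: large K indicates more signal than the label-shuffled null,
#' so p can never fall below `1 / (n_perm + 1)`).
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (or `NULL`).
#' @return A `signal_result`: statistic `"K"`, `observed`, `n_perm`,
#'   `p_value`, `seed`, and the `null` K values.
#' @export
k_permutation_test <- function(tree, trait, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop_ns("`n_perm` must be >= 1")
  pre <- k_precompute(tree)
  x <- check_trait(trait, pre$tips)
  k_obs <- as.numeric(blomberg_k_many(pre, matrix(x)))
  perms <- with_seed(seed, vapply(seq_len(n_perm),
                                  function(i) sample(x), numeric(pre$n)))
  k_null <- blomberg_k_many(pre, perms)
  new_signal_result("K", k_obs, n_perm,
                    (1 + sum(k_null >= k_obs)) / (1 + n_perm), seed, k_null)
}

new_signal_result <- function(statistic, observed, n_perm, p_value, seed,
                              null) {
  structure(list(statistic = statistic, observed = observed, n_perm = n_perm,
                 p_value = p_value, seed = seed, null = null),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("<signal_result> %s = %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$observed, x$p_value, x$n_perm))
  invisible(x)
}

check_states <- function(states, tips, cost_matrix) {
  if (is.null(names(states))) stop_ns("`tip_states` must be named by tip label")
  miss <- setdiff(tips, names(states))
  if (length(miss)) stop_ns("tip(s) without a state: ",
                            paste(utils::head(miss, 5), collapse = ", "))
  states <- as.character(states[tips])
  if (anyNA(states)) stop_ns("tip state is NA")
  alphabet <- sort(unique(states))
  if (is.null(cost_matrix)) {
    k <- length(alphabet)
    cost_matrix <- matrix(1, k, k, dimnames = list(alphabet, alphabet))
    diag(cost_matrix) <- 0
  } else {
    if (!is.matrix(cost_matrix) || nrow(cost_matrix) != ncol(cost_matrix) ||
        is.null(rownames(cost_matrix)) ||
        !identical(rownames(cost_matrix), colnames(cost_matrix))) {
      stop_ns("`cost_matrix` must be square with matching row/col state names")
    }
    if (any(diag(cost_matrix) != 0) || any(cost_matrix < 0)) {
      stop_ns("`cost_matrix` must have zero diagonal and non-negative costs")
    }
    bad <- setdiff(alphabet, rownames(cost_matrix))
    if (length(bad)) stop_ns("state(s) absent from cost matrix: ",
                             paste(bad, collapse = ", "))
  }
  list(states = states, cost = cost_matrix)
}

# Sankoff DP vectorized over columns of a state-index matrix (tips x P).
# Returns the minimum total cost per column. Handles multifurcations.
sankoff_many <- function(tree, state_idx, cost) {
  n_tip <- length(tree$tip.label)
  k <- nrow(cost)
  P <- ncol(state_idx)
  ord <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  # costs[[node]] is a k x P matrix of minimal subtree costs per root state
  costs <- vector("list", n_node)
  big <- .Machine$double.xmax / 4
  for (tip in seq_len(n_tip)) {
    m <- matrix(big, k, P)
    m[cbind(state_idx[tip, ], seq_len(P))] <- 0
    costs[[tip]] <- m
  }
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]
    child <- costs[[ord$edge[e, 2]]]
    # contribution to parent state s: min_t cost[s, t] + child[t, ]
    contrib <- matrix(NA_real_, k, P)
    for (s in seq_len(k)) {
      cand <- child + cost[s, ]  # column recycling adds cost[s, t] to row t
      contrib[s, ] <- do.call(pmin, lapply(seq_len(k),
                                           function(t) cand[t, ]))
    }
    costs[[parent]] <- if (is.null(costs[[parent]])) contrib else
      costs[[parent]] + contrib
  }
  root <- costs[[n_tip + 1L]]
  do.call(pmin, lapply(seq_len(k), function(s) root[s, ]))
}

#' Sankoff parsimony score
#'
#' Minimum total transition cost of a categorical character over all
#' internal-state assignments, computed by leaf-to-root dynamic programming.
#' With the default unit cost matrix ("equal transition probabilities"
#' between states) this is the minimum number of state changes.
#'
#' @param tree A `phylo` tree.
#' @param tip_states Named character vector of tip states.
#' @param cost_matrix Optional square step-cost matrix with state names as
#'   dimnames (zero diagonal, non-negative); default unit costs over the
#'   observed states.
#' @return The parsimony score (numeric scalar; integer-valued under unit
#'   costs).
#' @export
sankoff_score <- function(tree, tip_states, cost_matrix = NULL) {
  tree <- validate_tree(tree, strict = FALSE)
  chk <- check_states(tip_states, tree$tip.label, cost_matrix)
  idx <- matrix(match(chk$states, rownames(chk$cost)), ncol = 1)
  sankoff_many(tree, idx, chk$cost)
}

#' Permutation test for the Sankoff parsimony score
#'
#' States are shuffled across tips `n_perm` times; conserved characters have
#' *low* scores, so the p-value is the add-one lower tail
#' `p = (1 + #\{S_perm <= S_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams sankoff_score
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (or `NULL`).
#' @return A `signal_result` with statistic `"sankoff"`.
#' @export
sankoff_permutation_test <- function(tree, tip_states, cost_matrix = NULL,
                                     n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop_ns("`n_perm` must be >= 1")
  tree <- validate_tree(tree, strict = FALSE)
  chk <- check_states(tip_states, tree$tip.label, cost_matrix)
  idx0 <- match(chk$states, rownames(chk$cost))
  s_obs <- sankoff_many(tree, matrix(idx0, ncol = 1), chk$cost)
  perm_idx <- with_seed(seed, vapply(seq_len(n_perm),
                                     function(i) sample(idx0),
                                     integer(length(idx0))))
  s_null <- sankoff_many(tree, perm_idx, chk$cost)
  new_signal_result("sankoff", s_obs, n_perm,
                    (1 + sum(s_null <= s_obs)) / (1 + n_perm), seed, s_null)
}

#' Mean pairwise and nearest-taxon phylogenetic distances
#'
#' `MPD` is the mean patristic distance over unordered pairs of group
#' members; `MNTD` the mean, over members, of the distance to the nearest
#' other member. `MNTD <= MPD` always.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param group Character vector of >= 2 tip labels.
#' @param dist_matrix Optional precomputed [patristic_distances()] matrix.
#' @return Named numeric vector `c(mpd = , mntd = )`.
#' @export
pairwise_dispersion <- function(tree, group, dist_matrix = NULL) {
  if (is.null(dist_matrix)) dist_matrix <- patristic_distances(tree)
  group <- unique(as.character(group))
  bad <- setdiff(group, rownames(dist_matrix))
  if (length(bad)) stop_ns("group member(s) not on the tree: ",
                           paste(bad, collapse = ", "))
  if (length(group) < 2) stop_ns("`group` needs >= 2 species")
  D <- dist_matrix[group, group]
  c(mpd = mean(D[upper.tri(D)]),
    mntd = mean(apply(D + diag(Inf, nrow(D)), 1, min)))
}

#' Standardized effect sizes of MPD and MNTD (NRI / NTI)
#'
#' The observed MPD/MNTD of a habitat-preference group is compared to
#' `n_null` random draws of the same number of species from the pool
#' ("phylogeny pool" null). `NRI = -(MPD_obs - mean(MPD_null)) /
#' sd(MPD_null)` and NTI analogously with MNTD, so positive values indicate
#' phylogenetic clustering and negative values overdispersion. The p-value
#' per metric is the add-one lower (clustering) tail
#' `(1 + #\{null <= observed\}) / (1 + n_null)`; the opposite tail is
#' `1 - p + 1/(n_null + 1)`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param group Character vector of group members (2 <= size < pool size).
#' @param pool Species pool to draw from (default: all tips); must strictly
#'   contain `group`.
#' @param n_null Number of null draws (default 999).
#' @param seed Integer seed (or `NULL`).
#' @param dist_matrix Optional precomputed distance matrix.
#' @return A `dispersion_result`: group size, observed `mpd`/`mntd`, null
#'   means and s.d.s, `nri`, `nti`, and clustering-tail p-values `p_mpd`,
#'   `p_mntd`.
#' @export
ses_dispersion <- function(tree, group, pool = NULL, n_null = 999,
                           seed = NULL, dist_matrix = NULL) {
  if (is.null(dist_matrix)) dist_matrix <- patristic_distances(tree)
  pool <- unique(as.character(pool %||% rownames(dist_matrix)))
  group <- unique(as.character(group))
  bad <- setdiff(pool, rownames(dist_matrix))
  if (length(bad)) stop_ns("pool member(s) not on the tree: ",
                           paste(bad, collapse = ", "))
  if (!all(group %in% pool)) stop_ns("`group` must be a subset of `pool`")
  if (length(group) < 2) stop_ns("`group` needs >= 2 species")
  if (length(group) >= length(pool)) {
    stop_ns("`group` must be a strict subset of `pool` (degenerate null)")
  }
  if (n_null < 2) stop_ns("`n_null` must be >= 2")
  obs <- pairwise_dispersion(tree, group, dist_matrix)
  null <- with_seed(seed, vapply(seq_len(n_null), function(i) {
    pairwise_dispersion(tree, sample(pool, length(group)), dist_matrix)
  }, numeric(2)))
  mu <- rowMeans(null)
  sdv <- apply(null, 1, stats::sd)
  if (any(sdv == 0)) stop_ns("null distribution has zero variance")
  structure(list(
    group_size = length(group),
    mpd = obs[["mpd"]], mntd = obs[["mntd"]],
    mpd_null_mean = mu[["mpd"]], mpd_null_sd = sdv[["mpd"]],
    mntd_null_mean = mu[["mntd"]], mntd_null_sd = sdv[["mntd"]],
    nri = -(obs[["mpd"]] - mu[["mpd"]]) / sdv[["mpd"]],
    nti = -(obs[["mntd"]] - mu[["mntd"]]) / sdv[["mntd"]],
    p_mpd = (1 + sum(null["mpd", ] <= obs[["mpd"]])) / (1 + n_null),
    p_mntd = (1 + sum(null["mntd", ] <= obs[["mntd"]])) / (1 + n_null),
    n_null = n_null, seed = seed
  ), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf(
    "<dispersion_result> n = %d: NRI = %.3f (p = %.3g), NTI = %.3f (p = %.3g)\n",
    x$group_size, x$nri, x$p_mpd, x$nti, x$p_mntd
  ))
  invisible(x)
}
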