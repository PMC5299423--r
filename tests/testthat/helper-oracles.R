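# Independent oracles. These deliberately avoid the package's computational
# paths: explicit dense matrix inversion for K, exhaustive enumeration of
# internal-state assignments for the parsimony score, and ape's own
# covariance / cophenetic constructions for tree geometry.

oracle_blomberg_k <- function(tree, trait) {
  V <- ape::vcv(tree)
  x <- trait[rownames(V)]
  n <- length(x)
  Vi <- solve(V)
  one <- rep(1, n)
  denom <- as.numeric(t(one) %*% Vi %*% one)
  a <- as.numeric(t(one) %*% Vi %*% x) / denom
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Vi %*% (x - a)) / (n - 1)
  (mse0 / mse) / ((sum(diag(V)) - n / denom) / (n - 1))
}

# Minimum total transition cost over every assignment of states to internal
# nodes (brute force; feasible for <= 8 tips, <= 3 states).
oracle_sankoff <- function(tree, states, cost) {
  n_tip <- length(tree$tip.label)
  k <- nrow(cost)
  tip_idx <- match(states[tree$tip.label], rownames(cost))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign <- c(tip_idx, grid[r, ])
    s <- sum(cost[cbind(assign[tree$edge[, 1]], assign[tree$edge[, 2]])])
    if (s < best) best <- s
  }
  best
}

unit_cost <- function(states) {
  k <- length(states)
  m <- matrix(1, k, k, dimnames = list(states, states))
  diag(m) <- 0
  m
}
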