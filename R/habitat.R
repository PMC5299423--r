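# Habitat classification from topography and torus-translation tests of
# species-habitat association.

#' Classify quadrats into habitat types
#'
#' Ward-linkage hierarchical clustering of quadrats on the standardized
#' topographic variables (northness, convexity, elevation, slope), cut into
#' `k` classes. The procedure is fully deterministic. With `k = 3` the
#' classes are named after the conventional topographic habitats: lowest
#' mean elevation -> `valley`; of the remainder, higher mean convexity ->
#' `ridge`, the other -> `slope`. For other `k`, classes are `habitat_1` ...
#' `habitat_k` ordered by mean elevation.
#'
#' @param env An `environment_grid`.
#' @param k Number of habitat classes (1 <= k <= number of quadrats).
#' @return An object of class `habitat_map`: integer label matrix
#'   (`n_rows` x `n_cols`), habitat `names`, and `k`.
#' @export
classify_habitats <- function(env, k = 3) {
  stopifnot(inherits(env, "environment_grid"))
  assert_scalar_number(k, "k", 1)
  k <- as.integer(k)
  nq <- n_quadrats(env)
  if (k > nq) stop_ns("`k` (", k, ") exceeds the number of quadrats (", nq, ")")
  feats <- cbind(
    northness = northness(env$data$aspect),
    convexity = env$data$convexity,
    elevation = env$data$elevation,
    slope = env$data$slope
  )
  sds <- apply(feats, 2, stats::sd)
  feats <- sweep(feats, 2, colMeans(feats), "-")
  feats <- sweep(feats, 2, ifelse(sds > 0, sds, 1), "/")
  cl <- if (k == 1L) {
    rep(1L, nq)
  } else {
    stats::cutree(stats::hclust(stats::dist(feats), method = "ward.D2"), k)
  }
  mean_elev <- tapply(env$data$elevation, cl, mean)
  ord <- order(mean_elev)  # cluster ids from lowest to highest elevation
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels_vec <- relabel[cl]
  if (k == 3L) {
    hab_names <- c("valley", NA, NA)
    mean_conv <- tapply(env$data$convexity, labels_vec, mean)
    upper <- c(2L, 3L)
    ridge <- upper[which.max(mean_conv[as.character(upper)])]
    hab_names[ridge] <- "ridge"
    hab_names[setdiff(upper, ridge)] <- "slope"
  } else {
    hab_names <- paste0("habitat_", seq_len(k))
  }
  lab_mat <- matrix(labels_vec, nrow = env$n_rows, ncol = env$n_cols,
                    byrow = TRUE)  # env$data is row-major
  structure(list(labels = lab_mat, names = hab_names, k = k),
            class = "habitat_map")
}

#' Construct a habitat map directly
#'
#' @param labels Integer matrix (`n_rows` x `n_cols`) of habitat indices in
#'   `1..k`; rows index y, columns x.
#' @param names Character vector of habitat names (length `k`).
#' @return A `habitat_map`.
#' @export
habitat_map <- function(labels, names) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  k <- length(names)
  if (anyNA(labels) || any(labels < 1L) || any(labels > k)) {
    stop_ns("`labels` must be integers in 1..", k)
  }
  if (any(tabulate(labels, k) == 0L)) {
    stop_ns("every habitat must label >= 1 quadrat")
  }
  structure(list(labels = labels, names = as.character(names), k = k),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  counts <- tabulate(x$labels, nbins = x$k)
  cat(sprintf("<habitat_map> %d x %d quadrats; %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s: %d", x$names, counts), collapse = ", ")))
  invisible(x)
}

#' Write a habitat map as a grid CSV
#'
#' One row per grid row (row 0 first), cells are habitat names.
#' @param map A `habitat_map`.
#' @param path Output path.
#' @export
write_habitat_map <- function(map, path) {
  grid <- matrix(map$names[map$labels], nrow(map$labels), ncol(map$labels))
  utils::write.table(grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-quadrat stem counts for the given species (columns), in row-major
# quadrat order. `species = NULL` -> all species present.
quadrat_counts <- function(stems, map, species = NULL, stage = NULL) {
  tab <- stems$stems
  if (!is.null(stage)) tab <- tab[tab$stage == stage, , drop = FALSE]
  if (is.null(species)) species <- sort(unique(tab$species))
  n_rows <- nrow(map$labels)
  n_cols <- ncol(map$labels)
  out <- matrix(0L, n_rows * n_cols, length(species),
                dimnames = list(NULL, species))
  tab <- tab[tab$species %in% species, , drop = FALSE]
  if (nrow(tab)) {
    if (any(tab$row >= n_rows | tab$col >= n_cols)) {
      stop_ns("stem map extends beyond the habitat map grid")
    }
    q <- quadrat_index(tab$row, tab$col, n_cols)
    cnt <- table(factor(tab$species, levels = species),
                 factor(q, levels = seq_len(n_rows * n_cols)))
    out[] <- t(unclass(cnt))
  }
  out
}

#' Relative density of a species in a habitat
#'
#' Stems of the species in quadrats of the habitat, divided by the number of
#' quadrats of that habitat — the torus-translation test statistic.
#'
#' @param stems A `stem_map`.
#' @param map A `habitat_map`.
#' @param species Species name (must have >= 1 stem).
#' @param habitat Habitat name (must exist in the map).
#' @param stage Optional life stage restriction.
#' @return Non-negative scalar.
#' @export
habitat_relative_density <- function(stems, map, species, habitat,
                                     stage = NULL) {
  h <- match(habitat, map$names)
  if (is.na(h)) stop_ns("unknown habitat: ", habitat)
  counts <- quadrat_counts(stems, map, species, stage)
  if (sum(counts) == 0) {
    stop_ns("species '", species, "' has no stems; association undefined")
  }
  in_hab <- as.vector(t(map$labels)) == h  # row-major
  sum(counts[in_hab, 1]) / sum(in_hab)
}

# The four map variants used by the canonical torus design: the original,
# its 180-degree rotation, and the two mirror images.
habitat_variants <- function(map, include_reflections) {
  m <- map$labels
  if (!include_reflections) return(list(m))
  list(
    m,
    m[nrow(m):1, ncol(m):1, drop = FALSE],  # 180-degree rotation
    m[, ncol(m):1, drop = FALSE],           # mirror about vertical axis
    m[nrow(m):1, , drop = FALSE]            # mirror about horizontal axis
  )
}

# All torus shifts of all variants, as per-habitat stem totals divided by
# the (shift-invariant) habitat quadrat counts. Totals are accumulated as
# integers so that equal null values compare exactly equal — the mean-rank
# tie handling depends on it.
torus_null_stats <- function(counts, map, include_reflections) {
  H <- nrow(map$labels)
  W <- ncol(map$labels)
  k <- map$k
  n_h <- tabulate(map$labels, nbins = k)
  if (any(n_h == 0)) stop_ns("every habitat must occupy >= 1 quadrat")
  variants <- habitat_variants(map, include_reflections)
  n_shift <- H * W
  null <- array(NA_real_, c(ncol(counts), k, length(variants) * n_shift))
  i <- 0L
  for (v in variants) {
    for (dr in 0:(H - 1)) {
      rows <- ((seq_len(H) - 1 - dr) %% H) + 1
      for (dc in 0:(W - 1)) {
        cols <- ((seq_len(W) - 1 - dc) %% W) + 1
        lab <- as.vector(t(v[rows, cols, drop = FALSE]))  # row-major
        oh <- matrix(0, length(lab), k)
        oh[cbind(seq_along(lab), lab)] <- 1
        i <- i + 1L
        # integer-valued sums, exact in doubles; then one exact division
        null[, , i] <- sweep(crossprod(counts, oh), 2, n_h, "/")
      }
    }
  }
  null
}

#' Torus-translation tests of species-habitat association
#'
#' The observed relative density of each species in each habitat is compared
#' to the null distribution obtained by recomputing it for every toroidal
#' translation of the habitat map by whole quadrats (identity included) and,
#' by default, of the map's 180-degree rotation and two mirror images. The
#' null quantile is the observed value's mean rank among all null values
#' divided by their count; a species is scored `positive` for a habitat when
#' the quantile exceeds `1 - alpha`, `negative` below `alpha`, otherwise
#' `neutral`.
#'
#' @param stems A `stem_map`.
#' @param map A `habitat_map`.
#' @param species Character vector of species to test (default: all species
#'   present, each of which must have >= 1 stem).
#' @param alpha Tail probability per side, in `(0, 0.5)`; default 0.025.
#' @param include_reflections Include the rotated/mirrored maps (default
#'   `TRUE`, the canonical 4-variant design).
#' @param stage Optional life stage restriction.
#' @return `data.frame` with one row per species x habitat: `species`,
#'   `habitat`, `density`, `quantile`, `verdict`, plus attributes `alpha`
#'   and `n_translations`.
#' @export
torus_association <- function(stems, map, species = NULL, alpha = 0.025,
                              include_reflections = TRUE, stage = NULL) {
  if (alpha <= 0 || alpha >= 0.5) stop_ns("`alpha` must be in (0, 0.5)")
  counts <- quadrat_counts(stems, map, species, stage)
  empty <- colnames(counts)[colSums(counts) == 0]
  if (length(empty)) {
    stop_ns("species with 0 stems (association undefined): ",
            paste(empty, collapse = ", "))
  }
  null <- torus_null_stats(counts, map, include_reflections)
  n_null <- dim(null)[3]
  obs <- null[, , 1, drop = FALSE][, , 1]  # identity shift of original map
  obs <- matrix(obs, ncol = map$k)
  res <- expand.grid(habitat = map$names, species = colnames(counts),
                     stringsAsFactors = FALSE)[, 2:1]
  res$density <- NA_real_
  res$quantile <- NA_real_
  r <- 0L
  for (s in seq_len(ncol(counts))) {
    for (h in seq_len(map$k)) {
      r <- r + 1L
      vals <- null[s, h, ]
      o <- obs[s, h]
      res$density[r] <- o
      res$quantile[r] <- (sum(vals < o) + (sum(vals == o) + 1) / 2) / n_null
    }
  }
  res$verdict <- ifelse(res$quantile > 1 - alpha, "positive",
                        ifelse(res$quantile < alpha, "negative", "neutral"))
  attr(res, "alpha") <- alpha
  attr(res, "n_translations") <- n_null
  res
}

#' @rdname torus_association
#' @details `torus_translation_test()` is the single-species form; it
#'   returns the same columns restricted to one species.
#' @export
torus_translation_test <- function(stems, map, species, alpha = 0.025,
                                   include_reflections = TRUE, stage = NULL) {
  stopifnot(length(species) == 1L)
  torus_association(stems, map, species, alpha, include_reflections, stage)
}
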