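# Niche estimation: soil PCA and the conditional occurrence probability
# p(E|x), whose argmax over an environmental axis is the species' niche
# value — the continuous trait fed to the phylogenetic-signal statistics.

#' Northness of an aspect
#'
#' Aspect is circular (degrees clockwise from north) and cannot feed linear
#' niche estimation directly; it is consumed everywhere downstream as
#' `northness = cos(aspect * pi / 180)`, +1 facing due north, -1 due south.
#'
#' @param aspect_deg Aspect in degrees.
#' @return Numeric in `[-1, 1]`.
#' @export
northness <- function(aspect_deg) cos(aspect_deg * pi / 180)

# The seven analysis axes: four topographic (aspect as northness) plus the
# three leading soil-PCA axes once soil_pca() has been applied.
NICHE_AXES <- c("northness", "convexity", "elevation", "slope",
                "soil_pc1", "soil_pc2", "soil_pc3")

# Per-quadrat values of a named axis, in row-major quadrat order.
axis_values <- function(env, axis) {
  if (axis %in% c("northness", "aspect")) return(northness(env$data$aspect))
  if (!axis %in% names(env$data)) {
    stop_ns("axis '", axis, "' is not a variable of the environment grid",
            if (grepl("^soil_pc", axis)) " (run soil_pca() first)" else "")
  }
  env$data[[axis]]
}

#' Principal component analysis of the soil variables
#'
#' PCA on the standardized (zero-mean, unit-variance) nine soil variables.
#' Each loading vector is oriented so that its largest-magnitude element is
#' positive, making signs reproducible. Scores for the leading `n_axes`
#' components are appended to the grid as `soil_pc1`, `soil_pc2`, ...
#'
#' @param env An `environment_grid`.
#' @param n_axes Number of score columns to retain (1..9).
#' @return An object of class `soil_pca`: `grid` (the augmented
#'   `environment_grid`), `scores`, `loadings`, `var_explained` (fractions
#'   of total soil variance, all 9 components).
#' @export
soil_pca <- function(env, n_axes = 3) {
  stopifnot(inherits(env, "environment_grid"))
  if (n_axes < 1 || n_axes > length(SOIL_VARS)) {
    stop_ns("`n_axes` must be in 1..", length(SOIL_VARS))
  }
  X <- as.matrix(env$data[SOIL_VARS])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop_ns("constant soil column(s): ",
            paste(SOIL_VARS[sds == 0], collapse = ", "))
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pr$rotation <- sweep(pr$rotation, 2, flip, "*")
  pr$x <- sweep(pr$x, 2, flip, "*")
  scores <- pr$x[, seq_len(n_axes), drop = FALSE]
  colnames(scores) <- paste0("soil_pc", seq_len(n_axes))
  grid <- env
  grid$data[colnames(scores)] <- as.data.frame(scores)
  structure(list(
    grid = grid,
    scores = scores,
    loadings = pr$rotation,
    var_explained = pr$sdev^2 / sum(pr$sdev^2)
  ), class = "soil_pca")
}

#' @export
print.soil_pca <- function(x, ...) {
  n <- ncol(x$scores)
  cat(sprintf(
    "<soil_pca> %d retained axes explaining %.1f%% of soil variance\n",
    n, 100 * sum(x$var_explained[seq_len(n)])
  ))
  invisible(x)
}

#' Conditional-probability niche of a species on one axis
#'
#' The axis range over the quadrats is split into `n_bins` equal-width bins;
#' within each bin, `p(E|x) = occupied quadrats / quadrats` estimates the
#' probability that the species occurs at a point whose environment is x.
#' Bins holding fewer than `min_bin_quadrats` quadrats are excluded from the
#' argmax. The niche value is the midpoint of the maximizing bin; ties are
#' broken toward the bin with more occupied quadrats, then toward smaller x.
#' The estimate depends only on quadrat occupancy, never on stem counts.
#'
#' @param stems A `stem_map`.
#' @param env An `environment_grid` (with soil-PCA columns if a `soil_pc*`
#'   axis is requested).
#' @param species Species name; must occupy >= 1 quadrat.
#' @param axis One of the niche axes (e.g. `"northness"`, `"elevation"`,
#'   `"soil_pc1"`).
#' @param n_bins Number of equal-width bins (>= 2, default 20).
#' @param min_bin_quadrats Minimum quadrats for a bin to enter the argmax
#'   (default 5).
#' @param stage Optional life stage restriction.
#' @param smooth_bw Optional Gaussian kernel bandwidth (axis units) applied
#'   to the binned curve before the argmax; `NULL` (default) disables
#'   smoothing.
#' @return An object of class `niche_estimate`: `species`, `axis`, `breaks`,
#'   `mids`, `p` (the curve), `n_quadrats`/`n_occupied` per bin,
#'   `niche_value`, and `support` (total occupied quadrats).
#' @export
conditional_probability_niche <- function(stems, env, species, axis,
                                          n_bins = 20, min_bin_quadrats = 5,
                                          stage = NULL, smooth_bw = NULL) {
  stopifnot(inherits(stems, "stem_map"), inherits(env, "environment_grid"))
  if (n_bins < 2) stop_ns("`n_bins` must be >= 2")
  x <- axis_values(env, axis)
  tab <- stems$stems
  if (!is.null(stage)) tab <- tab[tab$stage == stage, , drop = FALSE]
  tab <- tab[tab$species == species, , drop = FALSE]
  if (!nrow(tab)) {
    stop_ns("species '", species, "' occupies no quadrat",
            if (!is.null(stage)) paste0(" at stage '", stage, "'") else "")
  }
  occ <- rep(FALSE, n_quadrats(env))
  occ[unique(quadrat_index(tab$row, tab$col, env$n_cols))] <- TRUE
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  if (breaks[1] == breaks[n_bins + 1L]) {
    stop_ns("axis '", axis, "' is constant over the grid")
  }
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  n_q <- tabulate(bin, nbins = n_bins)
  n_occ <- tabulate(bin[occ], nbins = n_bins)
  p <- ifelse(n_q > 0, n_occ / pmax(n_q, 1L), NA_real_)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  p_for_argmax <- p
  if (!is.null(smooth_bw)) {
    assert_scalar_number(smooth_bw, "smooth_bw", 0, strict_min = TRUE)
    w <- outer(mids, mids, function(a, b) exp(-(a - b)^2 / (2 * smooth_bw^2)))
    ok <- !is.na(p)
    p_for_argmax <- as.vector(w[, ok, drop = FALSE] %*% p[ok]) /
      rowSums(w[, ok, drop = FALSE])
  }
  eligible <- which(n_q >= min_bin_quadrats)
  if (!length(eligible)) {
    stop_ns("all bins hold fewer than min_bin_quadrats = ", min_bin_quadrats,
            " quadrats")
  }
  # argmax with deterministic tie-breaks: higher p, then more occupied
  # quadrats, then smaller x (bins are in increasing-x order already)
  ord <- eligible[order(-p_for_argmax[eligible], -n_occ[eligible],
                        eligible)]
  best <- ord[1]
  structure(list(
    species = species, axis = axis, breaks = breaks, mids = mids, p = p,
    n_quadrats = n_q, n_occupied = n_occ,
    niche_value = mids[best], support = sum(occ)
  ), class = "niche_estimate")
}

#' @export
print.niche_estimate <- function(x, ...) {
  cat(sprintf(
    "<niche_estimate> %s on %s: niche value %.4g (support %d quadrats)\n",
    x$species, x$axis, x$niche_value, x$support
  ))
  invisible(x)
}

#' Niche table for many species and axes
#'
#' Applies [conditional_probability_niche()] over all species x axis
#' combinations and returns a long-format table.
#'
#' @inheritParams conditional_probability_niche
#' @param species Character vector of species.
#' @param axes Character vector of axes (default the seven standard axes).
#' @return `data.frame` with columns species, stage, axis, niche_value,
#'   support.
#' @export
niche_table <- function(stems, env, species, axes = NICHE_AXES,
                        n_bins = 20, min_bin_quadrats = 5, stage = NULL,
                        smooth_bw = NULL) {
  rows <- lapply(species, function(sp) {
    do.call(rbind, lapply(axes, function(ax) {
      est <- conditional_probability_niche(stems, env, sp, ax, n_bins,
                                           min_bin_quadrats, stage, smooth_bw)
      data.frame(species = sp, stage = stage %||% "all", axis = ax,
                 niche_value = est$niche_value, support = est$support,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
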