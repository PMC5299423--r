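# End-to-end orchestration: stage filters -> habitats -> torus associations
# -> preference groups -> niches -> signal statistics -> dispersion, under
# one config with a single master seed and a run manifest.

#' Stage filter
#'
#' Species enter a stage's analysis when their stem count at that stage
#' reaches `min_abundance` (inclusive): the conventional thresholds are 20
#' for seedlings and 100 for adults. Species named in `exclude` (e.g.
#' non-tree growth forms) are dropped regardless of abundance.
#'
#' @param stage `"seedling"` or `"adult"`.
#' @param min_abundance Minimum stem count (default 20 / 100 by stage).
#' @param exclude Character vector of species to exclude.
#' @return A list of class `stage_filter`.
#' @export
stage_filter <- function(stage,
                         min_abundance = if (stage == "seedling") 20 else 100,
                         exclude = character(0)) {
  stage <- match.arg(stage, c("seedling", "adult"))
  assert_scalar_number(min_abundance, "min_abundance", 1)
  structure(list(stage = stage, min_abundance = min_abundance,
                 exclude = as.character(exclude)),
            class = "stage_filter")
}

#' Filter species for one life stage
#'
#' Species of the filter's stage with abundance at or above the threshold,
#' present on the tree (absent species are dropped with a warning, mirroring
#' the removal of taxa missing from the molecular phylogeny), minus the
#' exclusion list; sorted and deduplicated.
#'
#' @param stems A `stem_map`.
#' @param filter A [stage_filter()].
#' @param tree Optional `phylo` tree to intersect with.
#' @return Sorted character vector of species; errors if empty.
#' @export
filter_species <- function(stems, filter, tree = NULL) {
  stopifnot(inherits(stems, "stem_map"), inherits(filter, "stage_filter"))
  tab <- stems$stems[stems$stems$stage == filter$stage, , drop = FALSE]
  counts <- table(tab$species)
  keep <- names(counts)[counts >= filter$min_abundance]
  if (!is.null(tree)) {
    off_tree <- setdiff(keep, tree$tip.label)
    if (length(off_tree)) {
      warning("dropping species absent from the phylogeny: ",
              paste(off_tree, collapse = ", "), call. = FALSE)
      keep <- intersect(keep, tree$tip.label)
    }
  }
  keep <- sort(setdiff(keep, filter$exclude))
  if (!length(keep)) {
    stop_ns("no species pass the ", filter$stage, " filter (min_abundance = ",
            filter$min_abundance, "); nothing to analyze")
  }
  keep
}

#' Assign habitat-preference groups from association verdicts
#'
#' A species positively associated with exactly one habitat (and negatively
#' with none) joins that habitat's group; a species with no positive and no
#' negative verdicts is `neutral`. Species with any negative association,
#' or positive association with more than one habitat, are removed from the
#' dispersion analysis.
#'
#' @param assoc Association table from [torus_association()] (one row per
#'   species x habitat with a `verdict` column).
#' @return List with `groups` (named character vector: species -> group)
#'   and `removed` (character vector of removed species).
#' @export
assign_preference_groups <- function(assoc) {
  need <- c("species", "habitat", "verdict")
  if (!all(need %in% names(assoc))) {
    stop_ns("association table must have columns ",
            paste(need, collapse = ", "))
  }
  habitats <- unique(assoc$habitat)
  split_by_sp <- split(assoc, assoc$species)
  bad <- names(split_by_sp)[vapply(split_by_sp, nrow, 1L) != length(habitats)]
  if (length(bad)) stop_ns("missing verdicts for species: ",
                           paste(utils::head(bad, 5), collapse = ", "))
  groups <- character(0)
  removed <- character(0)
  for (sp in names(split_by_sp)) {
    rows <- split_by_sp[[sp]]
    pos <- rows$habitat[rows$verdict == "positive"]
    neg <- rows$habitat[rows$verdict == "negative"]
    if (length(neg) > 0 || length(pos) > 1) {
      removed <- c(removed, sp)
    } else if (length(pos) == 1) {
      groups[sp] <- pos
    } else {
      groups[sp] <- "neutral"
    }
  }
  list(groups = groups, removed = removed)
}

#' Read / write a flat key=value config file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are coerced to numeric or logical (`true`/`false`) when possible,
#' and comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop_ns("bad config line (expected key = value): ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) {
      num
    } else if (all(tolower(vals) %in% c("true", "false"))) {
      tolower(vals) == "true"
    } else {
      vals
    }
  }
  out
}

#' @rdname read_config
#' @param config Named list to write.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    paste(vapply(v, function(x) {
      if (is.logical(x)) tolower(as.character(x)) else format(x, digits = 12)
    }, ""), collapse = ",")
  }, "")
  writeLines(paste(names(config), fmt, sep = " = "), path)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    simulate = TRUE,
    n_species = 64, grid_width = 50, grid_height = 20, quadrat_size = 20,
    autocorr_range = 40, bm_sigma2 = 1, conservatism_lambda = 1,
    niche_breadth = 0.5, mean_abundance = 150, seedling_abundance = 60,
    k_habitats = 3, alpha = 0.025, include_reflections = TRUE,
    n_bins = 20, min_bin_quadrats = 5,
    n_perm = 999, n_null = 999,
    min_seedlings = 20, min_adults = 100,
    exclude = character(0),
    seed = 1,
    tree_path = "", stem_path = "", env_path = ""
  )
}

resolve_config <- function(config) {
  base <- default_pipeline_config()
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stop_ns("unknown config key(s): ",
                               paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}

analyze_stage <- function(stage, stems, env7, tree, map, cfg, seeds) {
  filt <- stage_filter(stage,
                       if (stage == "seedling") cfg$min_seedlings else cfg$min_adults,
                       cfg$exclude)
  species <- filter_species(stems, filt, tree)
  assoc <- torus_association(stems, map, species, cfg$alpha,
                             cfg$include_reflections, stage)
  grp <- assign_preference_groups(assoc)
  niches <- niche_table(stems, env7, species, NICHE_AXES, cfg$n_bins,
                        cfg$min_bin_quadrats, stage)
  sig_seeds <- split_seed(seeds, length(NICHE_AXES) + 2L)
  k_tab <- do.call(rbind, lapply(seq_along(NICHE_AXES), function(i) {
    ax <- NICHE_AXES[i]
    trait <- stats::setNames(niches$niche_value[niches$axis == ax],
                             niches$species[niches$axis == ax])
    sub <- ape::keep.tip(tree, species)
    res <- k_permutation_test(sub, trait, cfg$n_perm, sig_seeds[i])
    data.frame(stage = stage, axis = ax, K = res$observed,
               p = res$p_value, n_species = length(species))
  }))
  retained <- names(grp$groups)
  sub_r <- ape::keep.tip(tree, retained)
  sank <- sankoff_permutation_test(sub_r, grp$groups, NULL, cfg$n_perm,
                                   sig_seeds[length(NICHE_AXES) + 1L])
  sankoff_tab <- data.frame(stage = stage, score = sank$observed,
                            p = sank$p_value, n_species = length(retained))
  disp_seeds <- split_seed(sig_seeds[length(NICHE_AXES) + 2L], cfg$k_habitats + 1L)
  group_names <- c("neutral", map$names)
  disp_rows <- lapply(seq_along(group_names), function(i) {
    g <- group_names[i]
    members <- names(grp$groups)[grp$groups == g]
    if (length(members) < 2 || length(members) >= length(species)) {
      return(data.frame(stage = stage, group = g, n = length(members),
                        NRI = NA_real_, p_NRI = NA_real_,
                        NTI = NA_real_, p_NTI = NA_real_))
    }
    d <- ses_dispersion(tree, members, pool = species, n_null = cfg$n_null,
                        seed = disp_seeds[i])
    data.frame(stage = stage, group = g, n = d$group_size,
               NRI = d$nri, p_NRI = d$p_mpd, NTI = d$nti, p_NTI = d$p_mntd)
  })
  list(
    species = species, assoc = assoc, groups = grp, niches = niches,
    k_table = k_tab, sankoff = sankoff_tab,
    dispersion = do.call(rbind, disp_rows)
  )
}

#' Run the full analysis pipeline
#'
#' Builds (or reads) the plot data, classifies habitats, runs the
#' torus-translation association tests, estimates niches on the seven axes,
#' and computes Blomberg's K, the Sankoff permutation test and NRI/NTI per
#' life stage, plus a cross-stage K table restricted to the species common
#' to both stages. All result tables and a run manifest are written to
#' `out_dir` when it is non-`NULL`.
#'
#' @param config Named list or path to a key=value config file; unspecified
#'   keys take the documented defaults. With `simulate = TRUE` the synthetic
#'   generator supplies the inputs; otherwise `tree_path`, `stem_path` and
#'   `env_path` are read.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Optional master-seed override.
#' @return List with per-stage results (`seedling`, `adult`), `cross_k`
#'   (cross-stage K table), `habitats`, `soil`, and `manifest`; invisibly
#'   when `out_dir` is given.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  cfg <- resolve_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  seeds <- split_seed(cfg$seed, 4L)
  if (isTRUE(cfg$simulate)) {
    sim <- simulate_forest(simulation_config(
      n_species = cfg$n_species, grid_width = cfg$grid_width,
      grid_height = cfg$grid_height, quadrat_size = cfg$quadrat_size,
      autocorr_range = cfg$autocorr_range, bm_sigma2 = cfg$bm_sigma2,
      conservatism_lambda = cfg$conservatism_lambda,
      niche_breadth = cfg$niche_breadth,
      mean_abundance = cfg$mean_abundance,
      seedling_abundance = cfg$seedling_abundance, seed = seeds[1]
    ))
    tree <- sim$tree; stems <- sim$stems; env <- sim$env
  } else {
    if (!nzchar(cfg$tree_path) || !nzchar(cfg$stem_path) ||
        !nzchar(cfg$env_path)) {
      stop_ns("simulate = false requires tree_path, stem_path and env_path")
    }
    tree <- read_newick(cfg$tree_path)
    tabs <- read_plot_tables(cfg$stem_path, cfg$env_path, cfg$quadrat_size)
    stems <- tabs$stems; env <- tabs$env
  }
  soil <- soil_pca(env, 3)
  env7 <- soil$grid
  map <- classify_habitats(env, cfg$k_habitats)
  stages <- list()
  for (st in c("seedling", "adult")) {
    stages[[st]] <- tryCatch(
      analyze_stage(st, stems, env7, tree, map, cfg,
                    if (st == "seedling") seeds[2] else seeds[3]),
      error = function(e) stop_ns("stage '", st, "' failed: ",
                                  conditionMessage(e))
    )
  }
  common <- intersect(stages$seedling$species, stages$adult$species)
  cross_seeds <- split_seed(seeds[4], 2L * length(NICHE_AXES))
  cross_k <- NULL
  if (length(common) >= 3) {
    sub <- ape::keep.tip(tree, common)
    cross_k <- do.call(rbind, lapply(seq_along(NICHE_AXES), function(i) {
      ax <- NICHE_AXES[i]
      do.call(rbind, lapply(c("seedling", "adult"), function(st) {
        ni <- stages[[st]]$niches
        sel <- ni$axis == ax & ni$species %in% common
        trait <- stats::setNames(ni$niche_value[sel], ni$species[sel])
        res <- k_permutation_test(
          sub, trait, cfg$n_perm,
          cross_seeds[2 * (i - 1) + match(st, c("seedling", "adult"))]
        )
        data.frame(stage = st, axis = ax, K = res$observed, p = res$p_value,
                   n_species = length(common))
      }))
    }))
  }
  manifest <- list(
    package = "nichesignal",
    version = as.character(utils::packageVersion("nichesignal")),
    config = cfg[order(names(cfg))],
    master_seed = cfg$seed,
    stage_seeds = stats::setNames(as.list(seeds),
                                  c("simulate", "seedling", "adult", "cross")),
    n_species = lapply(stages, function(s) length(s$species)),
    n_common = length(common),
    habitat_counts = stats::setNames(
      as.list(tabulate(map$labels, map$k)), map$names)
  )
  result <- list(seedling = stages$seedling, adult = stages$adult,
                 cross_k = cross_k, habitats = map, soil = soil,
                 tree = tree, stems = stems, env = env7, manifest = manifest)
  if (!is.null(out_dir)) {
    write_pipeline_results(result, out_dir)
    return(invisible(result))
  }
  result
}

write_pipeline_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  for (st in c("seedling", "adult")) {
    s <- result[[st]]
    wr(s$assoc, paste0("associations_", st, ".csv"))
    wr(data.frame(species = names(s$groups$groups),
                  group = unname(s$groups$groups)),
       paste0("groups_", st, ".csv"))
    wr(data.frame(species = s$groups$removed),
       paste0("removed_", st, ".csv"))
    wr(s$niches, paste0("niches_", st, ".csv"))
    wr(s$k_table, paste0("k_table_", st, ".csv"))
    wr(s$sankoff, paste0("sankoff_", st, ".csv"))
    wr(s$dispersion, paste0("dispersion_", st, ".csv"))
  }
  if (!is.null(result$cross_k)) wr(result$cross_k, "k_table_cross.csv")
  write_habitat_map(result$habitats, file.path(out_dir, "habitat_map.csv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
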