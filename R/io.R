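# Readers/writers for the formats the pipeline touches: Newick trees,
# delimited stem tables, delimited quadrat-environment tables. Validation is
# strict: these are the contracts every downstream stage relies on.

TOPO_VARS <- c("aspect", "convexity", "elevation", "slope")
SOIL_VARS <- c(
  "total_N", "total_P", "total_K", "available_N", "available_P",
  "available_K", "organic_C", "pH", "bulk_density"
)

#' Parse a Newick string into a phylogenetic tree
#'
#' Wraps [ape::read.tree()] with the validation the downstream statistics
#' need: unique tip labels, a single root, and (in strict mode) a branch
#' length on every edge. In lenient mode missing lengths are imputed as 0
#' with a warning.
#'
#' @param text A Newick string (must end in `;`).
#' @param strict Require branch lengths on every edge (default `TRUE`).
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("(A:1,B:2);")
#' tr$tip.label
parse_newick <- function(text, strict = TRUE) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop_ns("Newick input must be a single non-empty string")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop_ns(sprintf(
      "Newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
      n_open, n_close
    ))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop_ns("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop_ns("Newick parse error: unreadable tree string")
  validate_tree(tree, strict = strict)
}

validate_tree <- function(tree, strict = TRUE) {
  if (!inherits(tree, "phylo")) stop_ns("not a `phylo` tree")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop_ns("Newick parse error: duplicate tip label(s): ",
            paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    if (strict) stop_ns("Newick parse error: tree has no branch lengths")
    warning("tree has no branch lengths; imputing 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  bad <- which(is.na(tree$edge.length))
  if (length(bad)) {
    if (strict) {
      stop_ns("Newick parse error: missing branch length on edge(s) ",
              paste(bad, collapse = ", "))
    }
    warning("imputing 0 for missing branch lengths", call. = FALSE)
    tree$edge.length[bad] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop_ns("Newick parse error: negative branch length")
  }
  tree
}

#' Write a tree as a canonical Newick string
#'
#' Children of every node are ordered by the smallest tip label in their
#' subtree, so the output is identical across runs and tree-construction
#' orders.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 15) {
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(x) format(x, digits = digits, trim = TRUE,
                                scientific = FALSE)
  rec <- function(node) {
    if (node <= n_tip) {
      return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    }
    kid_edges <- children[[as.character(node)]]
    parts <- lapply(kid_edges, function(e) {
      sub <- rec(tree$edge[e, 2])
      sub$str <- paste0(sub$str, ":", fmt_len(tree$edge.length[e]))
      sub
    })
    ord <- order(vapply(parts, `[[`, "", "min"))
    parts <- parts[ord]
    list(
      str = paste0("(", paste(vapply(parts, `[[`, "", "str"),
                              collapse = ","), ")"),
      min = parts[[1]]$min
    )
  }
  root <- n_tip + 1L
  paste0(rec(root)$str, ";")
}

#' @rdname parse_newick
#' @param path Path to a Newick file.
#' @export
read_newick <- function(path, strict = TRUE) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""), strict)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Construct a stem map
#'
#' A stem map is the individual-level occurrence data: one row per mapped
#' stem with tag, species, coordinates in meters and life stage. Coordinates
#' live on `[0, extent)` (half-open); quadrat membership is
#' `floor(coordinate / quadrat_size)`.
#'
#' @param stems `data.frame` with columns tag, species, x, y, stage.
#' @param extent Numeric length-2 plot extent `(x, y)` in meters.
#' @param quadrat_size Quadrat side length in meters.
#' @return An object of class `stem_map`.
#' @export
stem_map <- function(stems, extent, quadrat_size) {
  need <- c("tag", "species", "x", "y", "stage")
  miss <- setdiff(need, names(stems))
  if (length(miss)) stop_ns("stem table missing column(s): ",
                            paste(miss, collapse = ", "))
  assert_scalar_number(quadrat_size, "quadrat_size", 0, strict_min = TRUE)
  if (length(extent) != 2L || any(extent <= 0)) {
    stop_ns("`extent` must be two positive numbers (x, y)")
  }
  stems <- as.data.frame(stems)[need]
  stems$tag <- as.character(stems$tag)
  stems$species <- as.character(stems$species)
  stems$stage <- as.character(stems$stage)
  if (nrow(stems)) {
    bad_stage <- setdiff(unique(stems$stage), c("seedling", "adult"))
    if (length(bad_stage)) stop_ns("unknown life stage(s): ",
                                   paste(bad_stage, collapse = ", "))
    dup <- stems$tag[duplicated(stems$tag)]
    if (length(dup)) stop_ns("duplicate stem tag(s): ",
                             paste(unique(dup), collapse = ", "))
    oob <- which(stems$x < 0 | stems$x >= extent[1] |
                   stems$y < 0 | stems$y >= extent[2])
    if (length(oob)) {
      stop_ns("stem(s) outside the half-open plot extent [0, ",
              extent[1], ") x [0, ", extent[2], "): rows ",
              paste(utils::head(oob, 10), collapse = ", "))
    }
    # 0-based quadrat indices; (row, col) from (y, x)
    stems$col <- as.integer(floor(stems$x / quadrat_size))
    stems$row <- as.integer(floor(stems$y / quadrat_size))
  } else {
    stems$col <- integer(0)
    stems$row <- integer(0)
  }
  structure(
    list(stems = stems, extent = as.numeric(extent),
         quadrat_size = quadrat_size),
    class = "stem_map"
  )
}

#' @export
print.stem_map <- function(x, ...) {
  cat(sprintf(
    "<stem_map> %d stems, %d species, extent %g x %g m (quadrat %g m)\n",
    nrow(x$stems), length(unique(x$stems$species)),
    x$extent[1], x$extent[2], x$quadrat_size
  ))
  invisible(x)
}

#' Construct an environment grid
#'
#' A complete rectangular lattice of quadrats carrying the four topographic
#' variables (aspect in degrees, convexity, elevation, slope) and nine soil
#' variables. Rows index y, columns index x, both 0-based.
#'
#' @param data `data.frame` with columns row, col, the four topographic and
#'   nine soil variables (see `nichesignal:::SOIL_VARS`).
#' @param quadrat_size Quadrat side length in meters.
#' @return An object of class `environment_grid`.
#' @export
environment_grid <- function(data, quadrat_size) {
  assert_scalar_number(quadrat_size, "quadrat_size", 0, strict_min = TRUE)
  need <- c("row", "col", TOPO_VARS, SOIL_VARS)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_ns("environment table missing column(s): ",
                            paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  n_rows <- max(data$row) + 1L
  n_cols <- max(data$col) + 1L
  if (nrow(data) != n_rows * n_cols ||
      anyDuplicated(data[c("row", "col")]) ||
      min(data$row) != 0L || min(data$col) != 0L) {
    stop_ns("environment grid is not a complete 0-based rectangle (",
            n_rows, " x ", n_cols, " quadrats expected, got ",
            nrow(data), " rows)")
  }
  data <- data[order(data$row, data$col), , drop = FALSE]
  rownames(data) <- NULL
  structure(
    list(data = data, n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         quadrat_size = quadrat_size),
    class = "environment_grid"
  )
}

#' @export
print.environment_grid <- function(x, ...) {
  cat(sprintf(
    "<environment_grid> %d x %d quadrats of %g m; variables: %s\n",
    x$n_rows, x$n_cols, x$quadrat_size,
    paste(setdiff(names(x$data), c("row", "col")), collapse = ", ")
  ))
  invisible(x)
}

n_quadrats <- function(env) env$n_rows * env$n_cols

# Linear quadrat index (1-based, row-major: row*n_cols + col + 1).
quadrat_index <- function(row, col, n_cols) row * n_cols + col + 1L

#' Read stem and environment tables from disk
#'
#' Delimiter (comma or tab) is auto-detected from the header line. Stems are
#' validated against the plot extent implied by the environment grid;
#' quadrat membership uses half-open intervals, so a stem at exactly the
#' plot extent is rejected.
#'
#' @param stem_path Path to the stem table (tag, species, x, y, stage).
#' @param env_path Path to the environment table (row, col, variables).
#' @param quadrat_size Quadrat side length in meters.
#' @return List with elements `stems` (a `stem_map`) and `env` (an
#'   `environment_grid`).
#' @export
read_plot_tables <- function(stem_path, env_path, quadrat_size = 20) {
  env_tab <- utils::read.table(env_path, header = TRUE,
                               sep = detect_delim(env_path),
                               stringsAsFactors = FALSE)
  env <- environment_grid(env_tab, quadrat_size)
  stem_tab <- utils::read.table(stem_path, header = TRUE,
                                sep = detect_delim(stem_path),
                                stringsAsFactors = FALSE,
                                colClasses = c(tag = "character"))
  extent <- c(env$n_cols, env$n_rows) * quadrat_size
  list(stems = stem_map(stem_tab, extent, quadrat_size), env = env)
}

#' Write stem and environment tables
#'
#' @param stems A `stem_map`.
#' @param env An `environment_grid`.
#' @param stem_path,env_path Output paths (comma-delimited).
#' @return Invisibly, the paths written.
#' @export
write_plot_tables <- function(stems, env, stem_path, env_path) {
  utils::write.csv(stems$stems[c("tag", "species", "x", "y", "stage")],
                   stem_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(env$data, env_path, row.names = FALSE, quote = FALSE)
  invisible(c(stem_path, env_path))
}
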