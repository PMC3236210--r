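# Delimited-text readers and writers. Presence matrices, overlap tables
# and trait tables travel as comma-separated text with a header row and the
# species id in the first column; biome columns are canonicalized to the
# order I, II, II/III, III, IV, V, VI, VII, VIII, IX. Trees travel as
# Newick with branch lengths at full precision.

#' Read / write a presence matrix as CSV
#'
#' @param path File path.
#' @param presence A presence tibble.
#' @return `read_presence()` returns a validated presence tibble with biome
#'   columns in canonical order; `write_presence()` returns `path`
#'   invisibly.
#' @export
read_presence <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stop_on_parse_problems(df, path)
  if (anyDuplicated(df$species)) {
    abort(paste0("Duplicate species ids in ", path, ": ",
                 paste(unique(df$species[duplicated(df$species)]), collapse = ", ")))
  }
  extra <- setdiff(names(df), c("species", .BIOME_LEVELS))
  cols <- presence_cols(df)
  if (length(cols) < length(.BIOME_LEVELS)) {
    abort(paste0(path, " is missing biome column(s): ",
                 paste(setdiff(.BIOME_LEVELS, cols), collapse = ", ")))
  }
  validate_presence(df[, c("species", .BIOME_LEVELS, extra)])
}

#' @rdname read_presence
#' @export
write_presence <- function(presence, path) {
  presence <- validate_presence(presence)
  extra <- setdiff(names(presence), c("species", .BIOME_LEVELS))
  readr::write_csv(presence[, c("species", presence_cols(presence), extra)], path)
  invisible(path)
}

stop_on_parse_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    abort(paste0("Malformed row(s) in ", path, " at line(s): ",
                 paste(unique(pr$row), collapse = ", ")))
  }
  invisible(df)
}

#' Read / write an overlap table as CSV
#'
#' Columns: `species`, `dominion`, `range_fraction`, `dominion_fraction`,
#' optionally `montane`.
#'
#' @param path File path.
#' @param overlaps An overlap tibble.
#' @return A validated overlap tibble; the writer returns `path` invisibly.
#' @export
read_overlaps <- function(path) {
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      species = readr::col_character(),
      dominion = readr::col_character(),
      range_fraction = readr::col_double(),
      dominion_fraction = readr::col_double(),
      .default = readr::col_guess()
    ),
    show_col_types = FALSE, progress = FALSE
  ))
  stop_on_parse_problems(df, path)
  validate_overlaps(df)
}

#' @rdname read_overlaps
#' @export
write_overlaps <- function(overlaps, path) {
  readr::write_csv(validate_overlaps(overlaps), path)
  invisible(path)
}

#' Read / write trees in Newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that insist
#' on branch lengths and preserve them at full precision.
#'
#' @param path File path.
#' @param tree An `ape::phylo`.
#' @return `read_tree()` returns a `phylo`; `write_tree()` returns `path`
#'   invisibly.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("Could not parse a Newick tree from ", path, "."))
  if (is.null(tree$edge.length)) abort(paste0("Tree in ", path, " lacks branch lengths."))
  tree
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a tip-trait table
#'
#' Two-column CSV (`species`, `bsi` or `x`). When a tree is supplied the
#' table must cover its tips exactly.
#'
#' @param path File path.
#' @param tree Optional `phylo` to validate against.
#' @return A tibble `species`, `x`.
#' @export
read_traits <- function(path, tree = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stop_on_parse_problems(df, path)
  xcol <- if ("x" %in% names(df)) "x" else if ("bsi" %in% names(df)) "bsi"
    else abort(paste0(path, " needs a column named `x` or `bsi`."))
  out <- tibble::tibble(species = as.character(df$species), x = as.numeric(df[[xcol]]))
  if (anyDuplicated(out$species)) abort(paste0("Duplicate species ids in ", path, "."))
  if (!is.null(tree)) {
    missing_tips <- setdiff(tree$tip.label, out$species)
    if (length(missing_tips) > 0) {
      abort(paste0("Trait table lacks tree tip(s): ",
                   paste(head(missing_tips, 5), collapse = ", ")))
    }
    extra <- setdiff(out$species, tree$tip.label)
    if (length(extra) > 0) {
      abort(paste0("Trait table has species missing from the tree: ",
                   paste(head(extra, 5), collapse = ", ")))
    }
  }
  out
}

#' @rdname read_traits
#' @export
write_traits <- function(traits, path) {
  stopifnot(all(c("species", "x") %in% names(traits)) ||
              all(c("species", "bsi") %in% names(traits)))
  readr::write_csv(tibble::as_tibble(traits), path)
  invisible(path)
}
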