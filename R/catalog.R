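# Biome catalog: maps climatic dominions (the unit at which species-range
# overlap is measured) onto the ten biome classes. Montane dominions carry
# the biome of the analogous lowland vegetation belt and a montane flag, so
# that mountain-dwelling species can be coded into analog biomes and later
# excluded for the high-latitude reanalysis.

#' Build a biome catalog
#'
#' A biome catalog maps every climatic dominion to exactly one of the ten
#' biome classes (see [biome_levels()]). Montane dominions represent
#' altitudinal vegetation belts: they are assigned the biome they are
#' analogous to and flagged `montane = TRUE`.
#'
#' @param dominions A data frame with columns `dominion` (unique id),
#'   `biome` (one of [biome_levels()]) and optionally `montane` (logical,
#'   default `FALSE`).
#' @return A tibble of class `biome_catalog` with columns `dominion`,
#'   `biome`, `montane`.
#' @export
#' @examples
#' biome_catalog(data.frame(
#'   dominion = c("II.a", "II.b", "alp.IX"),
#'   biome = c("II", "II", "IX"),
#'   montane = c(FALSE, FALSE, TRUE)
#' ))
biome_catalog <- function(dominions) {
  dominions <- tibble::as_tibble(dominions)
  if (!all(c("dominion", "biome") %in% names(dominions))) {
    abort("`dominions` must have columns `dominion` and `biome`.")
  }
  if (!"montane" %in% names(dominions)) dominions$montane <- FALSE
  dominions$dominion <- as.character(dominions$dominion)
  dominions$biome <- as.character(dominions$biome)
  dominions$montane <- as.logical(dominions$montane)
  bad <- setdiff(unique(dominions$biome), .BIOME_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("Unknown biome label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(dominions$dominion)) {
    dup <- unique(dominions$dominion[duplicated(dominions$dominion)])
    abort(paste0("Duplicated dominion id(s): ", paste(dup, collapse = ", ")))
  }
  out <- dominions[, c("dominion", "biome", "montane")]
  class(out) <- c("biome_catalog", class(out))
  out
}

#' Read / write a biome catalog as a YAML config file
#'
#' The file format is a mapping with a `dominions` block, each entry
#' `id: {biome: <label>, montane: <true/false>}`.
#'
#' @param path File path.
#' @param catalog A `biome_catalog`.
#' @return `read_biome_catalog()` returns a `biome_catalog`;
#'   `write_biome_catalog()` returns `path` invisibly.
#' @export
read_biome_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$dominions)) abort("Catalog file has no `dominions` block.")
  recs <- purrr::imap_dfr(raw$dominions, function(rec, id) {
    tibble::tibble(
      dominion = id,
      biome = rec$biome %||% NA_character_,
      montane = isTRUE(rec$montane)
    )
  })
  biome_catalog(recs)
}

#' @rdname read_biome_catalog
#' @export
write_biome_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "biome_catalog"))
  doms <- purrr::set_names(
    purrr::map2(catalog$biome, catalog$montane, ~ list(biome = .x, montane = .y)),
    catalog$dominion
  )
  yaml::write_yaml(list(biomes = .BIOME_LEVELS, dominions = doms), path)
  invisible(path)
}

#' Synthetic biome catalog
#'
#' Builds a catalog with a configurable number of regular dominions per biome
#' (ids like `II.1`, `II.2`) plus one montane-analog dominion per biome
#' (ids like `mont.IX`), used by the synthetic-data generators.
#'
#' @param dominions_per_biome Regular (lowland) dominions per biome.
#' @param montane_biomes Biomes that receive a montane-analog dominion.
#' @return A `biome_catalog`.
#' @export
synthetic_catalog <- function(dominions_per_biome = 2,
                              montane_biomes = .BIOME_LEVELS) {
  stopifnot(dominions_per_biome >= 1)
  regular <- tidyr::expand_grid(
    biome = .BIOME_LEVELS,
    k = seq_len(dominions_per_biome)
  )
  regular$dominion <- paste0(regular$biome, ".", regular$k)
  regular$montane <- FALSE
  montane <- tibble::tibble(
    biome = montane_biomes,
    dominion = paste0("mont.", montane_biomes),
    montane = TRUE
  )
  biome_catalog(dplyr::bind_rows(regular[, c("dominion", "biome", "montane")],
                                 montane[, c("dominion", "biome", "montane")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
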