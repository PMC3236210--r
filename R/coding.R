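# Biome coding: from range-dominion overlap fractions to a species x biome
# presence matrix and the biomic specialization index (BSI).
#
# A species is coded present in a biome when at least 15% of its geographic
# range falls in that biome (summing dominions of the same biome), or when it
# covers at least 50% of any single climatic dominion of the biome. Both
# comparisons are inclusive. Montane dominions contribute to their analog
# biome; a species whose presence in some biome comes exclusively through
# montane dominions is flagged a montane dweller.

presence_cols <- function(df) intersect(.BIOME_LEVELS, names(df))

validate_presence <- function(presence, arg = "presence") {
  presence <- tibble::as_tibble(presence)
  if (!"species" %in% names(presence)) {
    abort(sprintf("`%s` must have a `species` column.", arg))
  }
  cols <- presence_cols(presence)
  if (length(cols) == 0) {
    abort(sprintf("`%s` has no biome columns (expected labels %s).",
                  arg, paste(.BIOME_LEVELS, collapse = ", ")))
  }
  if (anyDuplicated(presence$species)) {
    abort(sprintf("`%s` has duplicated species ids.", arg))
  }
  m <- as.matrix(presence[cols])
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    abort(sprintf("Biome columns of `%s` must be 0/1 with no missing values.", arg))
  }
  presence[cols] <- lapply(presence[cols], as.integer)
  presence
}

validate_overlaps <- function(overlaps, tol = 1e-6) {
  overlaps <- tibble::as_tibble(overlaps)
  need <- c("species", "dominion", "range_fraction", "dominion_fraction")
  miss <- setdiff(need, names(overlaps))
  if (length(miss) > 0) {
    abort(paste0("Overlap table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  fr <- c(overlaps$range_fraction, overlaps$dominion_fraction)
  if (anyNA(fr) || any(fr < 0) || any(fr > 1)) {
    abort("Overlap fractions must lie in [0, 1] with no missing values.")
  }
  sums <- tapply(overlaps$range_fraction, overlaps$species, sum)
  if (any(sums > 1 + tol)) {
    bad <- names(sums)[sums > 1 + tol]
    abort(paste0("Per-species range fractions exceed 1 for: ",
                 paste(bad, collapse = ", ")))
  }
  overlaps
}

#' Aggregate range-dominion overlaps to the biome level
#'
#' Sums a species' range fractions over dominions of the same biome and
#' retains the largest single-dominion coverage per biome. Montane dominions
#' contribute to their analog biome; fractions excluding montane dominions
#' are carried alongside so that [code_presence()] can flag montane dwellers.
#'
#' @param overlaps A data frame with columns `species`, `dominion`,
#'   `range_fraction` (fraction of the species' range inside the dominion)
#'   and `dominion_fraction` (fraction of the dominion covered by the
#'   species), all fractions in `[0, 1]`.
#' @param catalog A [biome_catalog()] covering every dominion in `overlaps`.
#' @return A tibble with one row per species-biome combination that has any
#'   overlap: `species`, `biome`, `range_fraction` (summed),
#'   `max_dominion_fraction`, and the same two quantities restricted to
#'   non-montane dominions (`nm_range_fraction`, `nm_max_dominion_fraction`).
#' @export
aggregate_overlaps <- function(overlaps, catalog) {
  stopifnot(inherits(catalog, "biome_catalog"))
  overlaps <- validate_overlaps(overlaps)
  unknown <- setdiff(unique(overlaps$dominion), catalog$dominion)
  if (length(unknown) > 0) {
    abort(paste0("Unknown dominion id(s) in overlap table: ",
                 paste(unknown, collapse = ", ")))
  }
  overlaps$montane <- NULL  # the catalog's montane flag is authoritative
  joined <- dplyr::left_join(overlaps, catalog, by = "dominion")
  joined |>
    dplyr::group_by(.data$species, .data$biome) |>
    dplyr::summarise(
      range_fraction = sum(.data$range_fraction),
      max_dominion_fraction = max(.data$dominion_fraction),
      nm_range_fraction = sum(.data$range_fraction[!.data$montane], 0),
      nm_max_dominion_fraction = max(c(.data$dominion_fraction[!.data$montane], 0)),
      .groups = "drop"
    )
}

#' Code species-biome presence from aggregated overlap fractions
#'
#' Applies the inclusive double rule: a species is present in a biome when
#' its summed range fraction there is at least `range_threshold`, or when it
#' covers at least `dominion_threshold` of any single dominion of that biome.
#' Species that qualify for no biome are dropped with a warning; their ids
#' are kept in the `"excluded"` attribute of the result.
#'
#' @param aggregated Output of [aggregate_overlaps()].
#' @param range_threshold Minimum fraction of the species range in a biome
#'   (default 0.15; the comparison is `>=`).
#' @param dominion_threshold Minimum coverage of a single dominion
#'   (default 0.50; the comparison is `>=`).
#' @return A presence tibble: `species`, one 0/1 column per biome in
#'   canonical order, and a logical `montane` column flagging species with at
#'   least one presence that derives only from montane dominions.
#' @export
code_presence <- function(aggregated, range_threshold = 0.15,
                          dominion_threshold = 0.50) {
  stopifnot(range_threshold > 0, range_threshold <= 1,
            dominion_threshold > 0, dominion_threshold <= 1)
  agg <- tibble::as_tibble(aggregated)
  agg$present <- as.integer(agg$range_fraction >= range_threshold |
                              agg$max_dominion_fraction >= dominion_threshold)
  agg$present_nm <- as.integer(agg$nm_range_fraction >= range_threshold |
                                 agg$nm_max_dominion_fraction >= dominion_threshold)
  agg$montane_only <- agg$present == 1L & agg$present_nm == 0L
  wide <- agg |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(montane = any(.data$montane_only), .groups = "drop")
  pm <- tidyr::pivot_wider(agg[, c("species", "biome", "present")],
                           names_from = "biome", values_from = "present",
                           values_fill = 0L)
  for (b in setdiff(.BIOME_LEVELS, names(pm))) pm[[b]] <- 0L
  pm <- pm[, c("species", .BIOME_LEVELS)]
  pm <- dplyr::left_join(pm, wide, by = "species")
  bsi <- rowSums(pm[.BIOME_LEVELS])
  excluded <- pm$species[bsi == 0]
  if (length(excluded) > 0) {
    warn(paste0(length(excluded), " species coded into zero biomes were excluded: ",
                paste(head(excluded, 10), collapse = ", "),
                if (length(excluded) > 10) ", ..." else ""))
    pm <- pm[bsi > 0, ]
  }
  out <- validate_presence(pm)
  attr(out, "excluded") <- as.character(excluded)
  out
}

#' Biomic specialization index (BSI)
#'
#' The BSI of a species is the number of biomes it inhabits: the row sum of
#' the presence matrix. Species are classed as stenobiomic (BSI = 1),
#' semi-eurybiomic (1 < BSI < 5) or extreme eurybiomic (BSI >= 5).
#'
#' @param presence A presence tibble (`species` plus 0/1 biome columns).
#' @return A tibble with columns `species`, `bsi`, `category`.
#' @export
#' @examples
#' pm <- tibble::tibble(species = c("a", "b"), I = c(1L, 1L), II = c(0L, 1L))
#' compute_bsi(pm)
compute_bsi <- function(presence) {
  presence <- validate_presence(presence)
  bsi <- as.integer(rowSums(presence[presence_cols(presence)]))
  if (any(bsi == 0)) {
    abort("Presence matrix has species occupying zero biomes; exclude them first.")
  }
  tibble::tibble(
    species = presence$species,
    bsi = bsi,
    category = classify_specialization(bsi)
  )
}

#' Specialization category from a BSI value
#'
#' @param bsi Integer vector of BSI values, between 1 and the number of
#'   biome classes (10).
#' @return A character vector: `"stenobiomic"` (BSI = 1), `"semi-eurybiomic"`
#'   (1 < BSI < 5) or `"extreme eurybiomic"` (BSI >= 5).
#' @export
classify_specialization <- function(bsi) {
  if (any(is.na(bsi)) || any(bsi < 1) || any(bsi > length(.BIOME_LEVELS))) {
    abort("BSI values must lie between 1 and the number of biomes (10).")
  }
  dplyr::case_when(
    bsi == 1 ~ "stenobiomic",
    bsi < 5 ~ "semi-eurybiomic",
    TRUE ~ "extreme eurybiomic"
  )
}

#' Drop montane-dwelling species from a presence matrix
#'
#' Restricts the matrix to species not flagged as montane dwellers, the
#' reanalysis used to probe specialization of true high-latitude (e.g.
#' tundra) faunas without their mountain analogs.
#'
#' @param presence A presence tibble with a logical `montane` column, or an
#'   explicit `flags` vector.
#' @param flags Optional logical vector parallel to `presence$species`
#'   (overrides the `montane` column).
#' @return The presence tibble restricted to non-montane species.
#' @export
filter_montane <- function(presence, flags = NULL) {
  presence <- validate_presence(presence)
  if (is.null(flags)) {
    if (!"montane" %in% names(presence)) {
      abort("No `montane` column and no `flags` supplied.")
    }
    flags <- presence$montane
  }
  if (length(flags) != nrow(presence) || anyNA(flags)) {
    abort("`flags` must be a complete logical vector covering all species.")
  }
  out <- presence[!flags, ]
  if (nrow(out) == 0) warn("All species are montane dwellers; result is empty.")
  out
}

#' Per-biome species richness of a presence matrix
#'
#' @param presence A presence tibble.
#' @return A named integer vector of column sums in canonical biome order.
#' @export
biome_richness <- function(presence) {
  presence <- validate_presence(presence)
  cols <- presence_cols(presence)
  out <- setNames(integer(length(.BIOME_LEVELS)), .BIOME_LEVELS)
  out[cols] <- as.integer(colSums(presence[cols]))
  out
}
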