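# Reference richness structures for a ruminant-like global assemblage:
# per-biome species richness and per-biome specialist counts for the whole
# assemblage (197 species) and its two species-rich families. These are the
# published marginal summaries the synthetic generator emulates; the
# underlying species-by-biome matrix is not redistributable.

#' Ruminant-like per-biome richness marginals
#'
#' Named integer vectors over [biome_levels()]: species richness per biome
#' for a 197-species ruminant-like assemblage (`ruminant_richness()`), its
#' 47-species deer subset (`cervid_richness()`) and 137-species bovid subset
#' (`bovid_richness()`), and the per-biome counts of biome specialists
#' (BSI = 1) in the full assemblage (`ruminant_specialist_counts()`).
#'
#' @return A named integer vector of length 10.
#' @export
#' @examples
#' sum(ruminant_richness()) / 197 # mean BSI
ruminant_richness <- function() {
  setNames(c(44L, 93L, 48L, 35L, 26L, 44L, 29L, 45L, 40L, 10L), .BIOME_LEVELS)
}

#' @rdname ruminant_richness
#' @export
cervid_richness <- function() {
  setNames(c(15L, 25L, 7L, 2L, 5L, 18L, 11L, 10L, 12L, 1L), .BIOME_LEVELS)
}

#' @rdname ruminant_richness
#' @export
bovid_richness <- function() {
  setNames(c(25L, 65L, 38L, 32L, 21L, 25L, 13L, 29L, 23L, 9L), .BIOME_LEVELS)
}

#' @rdname ruminant_richness
#' @export
ruminant_specialist_counts <- function() {
  setNames(c(12L, 29L, 5L, 11L, 6L, 3L, 2L, 9L, 1L, 1L), .BIOME_LEVELS)
}
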