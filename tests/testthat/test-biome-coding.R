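test_that("aggregation sums dominions within a biome and routes montane analogs", {
  cat <- toy_catalog()
  ov <- tibble::tibble(
    species = c("a", "b", "b", "c"),
    dominion = c("II.a", "II.a", "II.b", "mont.IX"),
    range_fraction = c(0.20, 0.10, 0.08, 0.16),
    dominion_fraction = c(0.3, 0.2, 0.4, 0.6)
  )
  agg <- aggregate_overlaps(ov, cat)
  expect_equal(agg$range_fraction[agg$species == "a" & agg$biome == "II"], 0.20)
  b2 <- agg[agg$species == "b" & agg$biome == "II", ]
  expect_equal(b2$range_fraction, 0.18)
  expect_equal(b2$max_dominion_fraction, 0.4)
  # montane dominion contributes to its analog biome, and is excluded from
  # the non-montane fractions used to flag montane dwellers
  c9 <- agg[agg$species == "c" & agg$biome == "IX", ]
  expect_equal(c9$range_fraction, 0.16)
  expect_equal(c9$nm_range_fraction, 0)
})

test_that("aggregation rejects unknown dominions and bad fractions", {
  cat <- toy_catalog()
  bad_dom <- tibble::tibble(species = "a", dominion = "nope",
                            range_fraction = 0.2, dominion_fraction = 0.1)
  expect_error(aggregate_overlaps(bad_dom, cat), "nope")
  bad_frac <- tibble::tibble(species = "a", dominion = "I.a",
                             range_fraction = 1.2, dominion_fraction = 0.1)
  expect_error(aggregate_overlaps(bad_frac, cat), "\\[0, 1\\]")
  over_budget <- tibble::tibble(species = "a", dominion = c("I.a", "II.a"),
                                range_fraction = c(0.7, 0.6),
                                dominion_fraction = c(0.1, 0.1))
  expect_error(aggregate_overlaps(over_budget, cat), "exceed 1")
})

test_that("presence coding applies both inclusive thresholds", {
  cat <- toy_catalog()
  ov <- tibble::tibble(
    species = c("at_range", "via_dominion", "neither"),
    dominion = c("II.a", "II.a", "II.a"),
    range_fraction = c(0.15, 0.149, 0.149),
    dominion_fraction = c(0.10, 0.50, 0.49)
  )
  pm <- suppressWarnings(code_presence(aggregate_overlaps(ov, cat)))
  expect_equal(pm$II[pm$species == "at_range"], 1L)
  expect_equal(pm$II[pm$species == "via_dominion"], 1L)
  expect_false("neither" %in% pm$species)
  expect_equal(attr(pm, "excluded"), "neither")
  expect_warning(
    code_presence(aggregate_overlaps(ov, cat)),
    "zero biomes"
  )
})

test_that("coding is monotone in the fractions and invariant to row order", {
  cat <- synthetic_catalog()
  set.seed(71)
  for (rep in 1:5) {
    pm0 <- generate_presence_matrix(20, c(I = 8, II = 12, III = 6, V = 9))
    ov <- generate_overlap_table(pm0, cat)
    base <- code_presence(aggregate_overlaps(ov, cat))
    shuffled <- ov[sample.int(nrow(ov)), ]
    again <- code_presence(aggregate_overlaps(shuffled, cat))
    expect_equal(dplyr::arrange(base, species), dplyr::arrange(again, species),
                 ignore_attr = TRUE)
    # raise one record's fractions: no presence may disappear
    i <- sample.int(nrow(ov), 1)
    bumped <- ov
    bumped$range_fraction[i] <- min(1, bumped$range_fraction[i] + 0.1)
    tot <- tapply(bumped$range_fraction, bumped$species, sum)
    if (all(tot <= 1)) {
      more <- code_presence(aggregate_overlaps(bumped, cat))
      a <- as.matrix(dplyr::arrange(base, species)[biome_levels()])
      b <- as.matrix(dplyr::arrange(more, species)[biome_levels()])
      expect_true(all(b >= a))
    }
  }
})

test_that("BSI equals the row sum and the mean-BSI identity holds", {
  m <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  colnames(m) <- c("I", "II", "III")
  pm <- presence_from_matrix(m)
  bsi <- compute_bsi(pm)
  expect_equal(bsi$bsi, c(1L, 2L, 3L))
  expect_equal(bsi$bsi, unname(rowSums(pm[biome_levels()])))

  # a full-size matrix with the reference marginals: mean BSI is exactly
  # the summed richness over the species count, 414/197 = 2.10
  pm197 <- generate_presence_matrix(197, ruminant_richness(), seed = 5)
  bsi197 <- compute_bsi(pm197)
  expect_equal(mean(bsi197$bsi), sum(ruminant_richness()) / 197)
  expect_equal(round(mean(bsi197$bsi), 2), 2.10)

  zero_row <- presence_from_matrix(rbind(c(1, 0), c(0, 0)) |>
                                     `colnames<-`(c("I", "II")))
  expect_error(compute_bsi(zero_row), "zero biomes")
})

test_that("specialization categories use the exact BSI boundaries", {
  expect_equal(classify_specialization(1), "stenobiomic")
  expect_equal(classify_specialization(c(2, 3, 4)),
               rep("semi-eurybiomic", 3))
  expect_equal(classify_specialization(c(5, 10)),
               rep("extreme eurybiomic", 2))
  expect_error(classify_specialization(0), "between 1")
  expect_error(classify_specialization(11), "between 1")
})

test_that("montane filtering drops flagged species and recounts richness", {
  set.seed(9)
  pm <- generate_presence_matrix(40, c(I = 15, II = 25, VIII = 10, IX = 8),
                                 montane_fraction = 0.3)
  kept <- filter_montane(pm)
  expect_equal(kept$species, pm$species[!pm$montane])
  # brute-force recount oracle
  manual <- colSums(pm[!pm$montane, biome_levels()])
  expect_equal(biome_richness(kept), setNames(as.integer(manual), biome_levels()))
  # degenerate cases
  expect_equal(filter_montane(pm, flags = rep(FALSE, 40)), pm, ignore_attr = TRUE)
  expect_warning(empty <- filter_montane(pm, flags = rep(TRUE, 40)), "empty")
  expect_equal(nrow(empty), 0)
})
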