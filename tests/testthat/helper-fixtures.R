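# Small fixtures built in code.

toy_catalog <- function() {
  biome_catalog(data.frame(
    dominion = c("I.a", "II.a", "II.b", "III.a", "mont.IX"),
    biome = c("I", "II", "II", "III", "IX"),
    montane = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  ))
}

# presence tibble from a plain 0/1 matrix whose columns are biome labels
presence_from_matrix <- function(m, species = sprintf("sp%02d", seq_len(nrow(m))),
                                 ...) {
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- colnames(m)
  for (b in setdiff(biome_levels(), names(out))) out[[b]] <- 0L
  res <- dplyr::bind_cols(tibble::tibble(species = species), out[, biome_levels()])
  extras <- list(...)
  for (nm in names(extras)) res[[nm]] <- extras[[nm]]
  res
}

# a small ultrametric tree with traits, grown under a constant-rate model
quick_dataset <- function(n_tips = 30, lambda = 0.3, mu = 0.05, sigma2 = 0.05,
                          x0 = 2, seed = 3) {
  m <- speciation_model("constant", lambda0 = lambda, mu = mu, sigma2 = sigma2)
  generate_phylo_dataset(m, x0 = x0, max_tips = n_tips, seed = seed)
}
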