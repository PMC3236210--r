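# biomespec

Macroevolutionary analysis of **biomic specialization**: does confinement
to a single biome come with a higher speciation rate?

The resource-use hypothesis predicts that biome specialists — species whose
range sits inside one major vegetation/climate zone — experience more
vicariance during climatic cycles and therefore speciate (and die out)
faster than generalists. `biomespec` implements the full analytical
pipeline for testing this on a modern assemblage:

* **Biome coding.** Convert per-species range–dominion overlap fractions
  into a species × biome presence matrix under the inclusive double rule
  (present if ≥ 15% of the range lies in the biome, or ≥ 50% of any single
  climatic dominion is covered), with montane dominions mapped to their
  analog biomes. The **biomic specialization index** (BSI) of a species is
  its number of occupied biomes; BSI = 1 is stenobiomic, 1 < BSI < 5
  semi-eurybiomic, BSI ≥ 5 extreme eurybiomic.
* **Richness-constrained null model.** Monte Carlo randomizations that
  place `sp_b` distinct species in each biome *b* uniformly at random
  (fixed per-biome richness, independent biomes), with empirical two-tail
  p-values and an exact Poisson-binomial oracle: per species,
  `P(occupy b) = sp_b / N`, so BSI is Poisson-binomial and the probability
  that an occupant of biome *b* is a specialist is
  `prod_{j != b} (1 - sp_j / N)`.
* **Trait-dependent speciation (QuaSSE-style).** A grid likelihood for
  models where the speciation rate λ(x) is a constant, linear, sigmoidal
  or modal function of BSI (extinction constant, trait evolving by
  Brownian motion with optional directional drift), a forward simulator,
  random depth-conserving polytomy resolution, ML fitting and AIC
  comparison across a distribution of trees.
* **Synthetic data.** Generators that emulate a 197-species, 10-biome
  ruminant-like assemblage (exact per-biome richness marginals, calibrated
  specialist excess, montane routing) and trees grown under any of the
  speciation models — so the whole pipeline is testable without any
  external dataset.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` displays.

## Worked example

Generate a ruminant-like matrix (197 species; richness marginals
44, 93, 48, 35, 26, 44, 29, 45, 40, 10 across the ten biomes I…IX; 79
specialists placed as observed) and test it against the null:

```r
library(biomespec)

pm <- generate_presence_matrix(197, ruminant_richness(),
        specialist_counts = ruminant_specialist_counts(), seed = 42)
res <- run_null_analysis(pm, n_reps = 10000, seed = 42)
res
#> Richness-constrained null analysis
#> 197 species, 10000 replicates (seed 42)
#>
#> BSI frequency distribution (%):
#>  bsi observed_pct null_mean null_sd p_display direction
#>    1        40.10     27.49    2.65    <0.001     upper
#>    2        26.40     34.13    3.50     0.012     lower
#>    3        18.78     23.99    3.00     0.037     lower
#>    4        12.69     10.62    2.05     0.161     upper
#>    ...
#>
#> Per-biome specialist proportions (%):
#>   biome sp n_specialists observed_pct null_mean null_sd p_display
#>       I 44            12        27.27     11.04    4.54     0.002
#>      II 93            29        31.18     16.25    3.47    <0.001
#>  II/III 48             5        10.42     11.35    4.33     0.529
#>     III 35            11        31.43     10.40    5.03    <0.001
#>    ...
#>    VIII 40             1         2.50     10.75    4.76     0.056
```

Reading it: 40.1% of species are specialists against a null expectation of
27.5% (upper-tail p < 0.001) — a strong specialist excess. Per biome, the
rainforest (I), tropical deciduous woodland (II) and sub-tropical desert
(III) hold significantly more specialists than chance, while the taiga
(VIII) holds fewer (2.5% vs 10.8%). Mean BSI is `sum(richness)/197 = 2.10`.
The same object plots with `autoplot(res)` and
`plot_biome_specialists(res)`, and `tidy(res)` returns the table above.

On the phylogenetic side:

```r
sig <- speciation_model("sigmoid", lambda0 = 0.17, lambda1 = 0.018,
                        xmid = 4.61, r = 1.5, mu = 0.01, sigma2 = 0.15)
ds  <- generate_phylo_dataset(sig, x0 = 3, max_tips = 100, seed = 1)
fc  <- fit_speciation_model(ds, "constant", n_starts = 1)
fs  <- fit_speciation_model(ds, "sigmoid",  n_starts = 1,
                            init = fc$model$pars)
compare_speciation_models(list(fc, fs))
```

fits a decreasing-sigmoid scenario (speciation ~tenfold higher in
specialists than in extreme generalists, inflection near BSI 4.6) and asks
whether AIC recovers the non-constant shape. `run_pipeline()` chains
coding, null tests (assemblage, per clade, montane-excluded), polytomy
resolution, fitting and comparison, and writes seed-stamped CSV summaries.

## Package layout

| file | contents |
|---|---|
| `R/coding.R` | overlap aggregation, presence coding, BSI, montane filter |
| `R/null-model.R` | Monte Carlo null, Poisson-binomial oracle, p-values |
| `R/quasse.R`, `R/fit.R` | grid likelihood, ML fitting, AIC comparison |
| `R/simulate-tree.R`, `R/polytomy.R` | forward simulator, polytomy resolution |
| `R/synthetic.R`, `R/presets.R` | synthetic-data generators, reference marginals |
| `R/io.R`, `R/pipeline.R` | delimited-text / Newick / YAML I/O, orchestration |
| `vignettes/biomespec-methods.Rmd` | models, numerics and design decisions |
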