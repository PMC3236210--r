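---
title: "Biomic specialization: models, null distributions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomic specialization: models, null distributions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomespec)
```

## The scientific problem

The resource-use hypothesis predicts that biome specialists — species whose
geographic range is confined to a single major vegetation/climate zone —
speciate (and go extinct) faster than generalists, because contraction and
fragmentation of their biome during climatic cycles exposes them to
vicariance. `biomespec` implements the two complementary ways this
prediction is usually tested on a modern assemblage:

1. **Non-phylogenetic**: compare the observed frequency distribution of the
   biomic specialization index (BSI — the number of biomes a species
   inhabits) against a randomization null that preserves each biome's
   species richness.
2. **Phylogenetic**: fit trait-dependent speciation models (QuaSSE-style)
   in which the speciation rate is a function of BSI, and compare rate
   shapes by AIC over a distribution of dichotomized trees.

Both analyses operate on tabular data (a species-by-biome 0/1 matrix, a
tip-trait table) plus a Newick tree, and every stochastic step takes an
explicit seed.

## Coding presence from range–dominion overlaps

The unit of measurement is the *climatic dominion*, a sub-biome climatic
region. The input is, per species and dominion, the fraction of the
species' range inside the dominion and the fraction of the dominion the
species covers. A species is coded present in a biome when

* at least **15%** of its range lies in the biome (summing the dominions of
  that biome), **or**
* it covers at least **50%** of any single dominion of the biome.

Both comparisons are inclusive (`>=`), and both defaults are exposed as
arguments (`range_threshold`, `dominion_threshold`). The second rule exists
because some dominions are small enough that a wide-ranging species could
never reach 15% of its range inside them. Two readings of the rules are
possible where the source conventions are ambiguous; we fix them as
follows and treat them as part of the method's definition:

* the 15% rule is evaluated **per biome after aggregation** over that
  biome's dominions (a "climate zone" is taken to be the biome);
* the 50% rule is evaluated **per single dominion**, never on dominions
  pooled within a biome.

Montane dominions are catalogued with the biome of the analogous lowland
vegetation belt (e.g. an alpine belt as tundra) and a montane flag. A
species whose presence in some biome derives *only* from montane dominions
is flagged a montane dweller; `filter_montane()` reruns any analysis
without those species, which is how the high-latitude (tundra) question is
probed separately from its mountain analogs. Species coded into zero biomes
are excluded with a warning and reported in the `"excluded"` attribute
rather than failing the run; per-species range fractions are *not*
renormalized to sum to one, since ranges may straddle uncatalogued area.

The savannah (II/III) is a first-class biome category among the ten labels,
not a union of biomes II and III.

BSI is the row sum of the presence matrix; species are stenobiomic
(BSI = 1), semi-eurybiomic (1 < BSI < 5) or extreme eurybiomic (BSI >= 5).

## The richness-constrained null model

Biomes differ enormously in species richness, so a meaningful null must
hold each biome's richness fixed while shuffling which species occupy it.
One replicate draws, for each biome $b$ independently, $sp_b$ distinct
species uniformly without replacement from the $N$ species. BSI frequencies
are expressed as percentages of the species occupying at least one biome in
that replicate (species left with zero biomes are excluded from the
denominator, exactly as zero-biome species are excluded from an observed
matrix). With 10000 replicates (the default) the run takes a few seconds.

Why this convention matters: under the replicate law a species occupies
biome $b$ with probability $p_b = sp_b/N$ independently across biomes, so
its BSI is Poisson-binomial. For the ruminant-like marginals the
*unconditional* probability of BSI = 1 is about 25.1%, while conditioning
on occupancy gives 27.5% — and only the conditional version matches the
Monte Carlo percentages, because the replicate denominator is the occupied
count. `analytic_null_bsi()` implements this Poisson-binomial oracle
exactly (direct convolution), including the per-biome specialist
probability $P(\mathrm{BSI}=1 \mid \text{present in } b) =
\prod_{j \neq b} (1 - p_j)$, which is exact for every system size because
it is a per-species (linear) statistic. The oracle is used to verify the
simulator in the test suite; in tiny systems the *replicate-mean percentage*
differs from the per-species law (a mean of ratios is not a ratio of
means), and there the simulator is checked against exhaustive enumeration
instead.

Empirical p-values use inclusive counting in both tails
(`# replicates >= observed` for the upper tail), with no pseudo-count; both
tails are always stored, the reported tail is chosen by the side of the
null mean the observation falls on, and values below $10^{-3}$ display as
`"<0.001"` while the exact fraction is kept. No multiple-testing correction
is applied across BSI values or biomes, mirroring standard practice for
these tables; the stored two-tail fractions make any correction easy to
apply downstream. Clade-restricted analyses recompute marginals and $N$
on the filtered matrix — the clade null is *not* the assemblage null.

## Trait-dependent speciation

BSI is integer-valued but is treated as a continuous trait $x$ evolving by
Brownian motion with diffusion rate $\sigma^2$ (BSI$^2$/Myr) and optional
directional drift $\varphi$ (BSI/Myr; positive pushes toward generalism).
Lineages speciate at rate $\lambda(x)$ and go extinct at a constant,
trait-independent rate $\mu$ — extinction-rate inference from extant-only
trees is deliberately out of scope. Four shapes are supported, with free
parameter counts including $\mu$ and $\sigma^2$:

| shape | $\lambda(x)$ | free parameters |
|---|---|---|
| constant | $\lambda_0$ | 3 |
| linear | $\max(0,\ \lambda_0 + s x)$ (clamp reported by `lambda_at()`) | 4 |
| sigmoid | $\lambda_1 + (\lambda_0-\lambda_1)/(1+e^{r(x-x_{mid})})$ | 6 |
| modal | $\lambda_1 + (\lambda_0-\lambda_1)\,e^{-(x-x_{mid})^2/2w^2}$ | 6 |

Drift adds one parameter. The sigmoid/modal functional forms are the
conventional four-parameter logistic and Gaussian bump; these choices are
pinned by the parameter counts above and the qualitative shapes they must
take (a decreasing sigmoid runs from a high rate in specialists to a low
rate in extreme generalists).

### Likelihood

`quasse_loglik()` propagates the standard pair of quantities along each
branch on a regular trait grid: $E(x,t)$, the probability that a lineage in
state $x$ leaves no sampled descendants, and $D(x,t)$, the likelihood
density of the observed subtree. Numerics, in the order they matter:

* **Operator splitting (Strang).** Each time step applies a half reaction
  step, a diffusion step, and another half reaction step, giving
  second-order accuracy in the step size.
* **Exact reaction step.** With $\lambda(x)$ frozen at each grid point, the
  birth–death ODEs have a closed-form solution over a step, including the
  $\lambda = \mu$ degeneracy and the pure-death limit; no inner ODE solver
  is needed and $E$ cannot leave $[0,1]$.
* **Spectral diffusion.** Brownian motion with drift over a step is an
  exact Gaussian multiplier in Fourier space, applied by FFT on the
  periodic grid. This avoids discretizing a narrow kernel: accuracy does
  not degrade when $\sqrt{\sigma^2 \Delta t}$ is smaller than the grid
  spacing.
* **Tips.** Each tip is initialized as a Gaussian kernel of sd `tip_sd`
  (default 0.25 BSI) around its observed value — a numerically stable
  stand-in for a delta that doubles as a measurement-error model. The
  kernel is automatically floored at one grid cell so it can never
  degenerate into sampling noise on coarse grids.
* **Nodes and root.** At internal nodes $D \leftarrow D_L D_R \lambda(x)$
  (the root included). The root returns the log of a weighted average of
  $D$: weights proportional to $D$ itself by default, or flat
  (`root = "flat"`) for sensitivity analyses and for closed-form checks.
  No survival conditioning is applied; all models share the convention, so
  AIC comparisons are unaffected.
* **Guard rails.** $D$ is renormalized per branch with the log factor
  accumulated (no underflow), and if more than $10^{-4}$ of the mass sits
  in the outer grid cells the call errors with advice to widen the bounds
  rather than silently wrapping around the periodic domain.

When bounds are not given they are resolved from the tip range plus
padding for the diffusive spread over the tree depth. `fit_speciation_model()`
freezes the bounds once per dataset — independent of shape and drift — so
every likelihood in a comparison integrates over the same domain.

Verification is two-route. For trait-independent rates the likelihood
factorizes into (constant-rate birth–death) × (Brownian trait likelihood);
the test suite computes the first factor by scalar ODE integration
(deSolve) and the second in closed form (GLS with a flat root prior and
tip-kernel measurement error) and requires agreement to $10^{-3}$.
Trait-dependent cases are checked by grid/step refinement (doubling points
and halving the step changes lnL by less than $10^{-2}$; a three-tip toy
agrees with a very fine reference run to $10^{-4}$).

### Fitting and model comparison

Rates are optimized on the log scale by Nelder–Mead from a documented
multistart table (a moment-based start, a constant-equivalent start, and a
perturbed start); an explicit `init` can seed the search from a nested
fit, which also guarantees the nested-model dominance property in tests. A
simplex search was preferred over a bounded quasi-Newton because the
objective is evaluated through an adaptive grid with hard error guards,
which makes finite-difference gradients fragile near the guard boundary;
positivity is enforced by the log transform instead of box constraints.
Fits that exhaust the iteration budget are flagged not converged and are
excluded from comparisons with a warning. `compare_speciation_models()`
computes $AIC = 2n - 2\,\mathrm{lnL}$, per-tree $\Delta AIC$, flags
differences of two units or less as indistinguishable, and summarizes
across a tree distribution (mean, sd, range, frequency best).

### Simulator

`simulate_tree()` is the forward counterpart: per small time step each
lineage first diffuses its trait, then speciates or dies with
probabilities $\lambda(x)\,dt$ and $\mu\,dt$. Stopping is by elapsed time
or by an exact extant-lineage count (simultaneous events beyond the target
are rolled back); extinct side branches are pruned by default, complete
extinction is flagged rather than raised. Because the run stops at an
event, trees stopped by tip count can carry zero-length terminal edges;
downstream code (contrast-based starting values, the likelihood) handles
these.

### Polytomy resolution

`resolve_polytomies()` breaks each polytomy by randomly joining two
children under a new node whose branch length is drawn uniformly on
$(0,\ \varepsilon_{max} \cdot \min(\text{child lengths})]$, shortening the
joined children by the same amount so that every root-to-tip depth is
conserved exactly ($\varepsilon_{max} = 0.5$ by default). This is a
deliberately simple randomization scheme — a stand-in for full Bayesian
polytomy resolution, which is out of scope — and it is adequate for
propagating topological uncertainty into the AIC comparison.

## The synthetic-data generator

No species-by-biome dataset ships with the package; the generator creates
matrices with the marginal structure the analyses assume, so that every
stage is testable from code alone. Presets provide the reference
marginals: per-biome richness (44, 93, 48, 35, 26, 44, 29, 45, 40, 10) for
197 species (sum 414, hence mean BSI 414/197 = 2.10), the cervid
(N = 47) and bovid (N = 137) subsets, and per-biome specialist counts
summing to 79 (40.1% observed specialists).

The mixture design: a configurable share of species are generated as pure
specialists (their biome drawn without replacement from an urn holding each
biome's richness, which caps per-biome specialist counts at the marginals),
and the remainder draw occupancy from independent Bernoulli($p_b$)
conditioned on at least one biome (at least two when the specialist count
is pinned exactly). Two constraints then have to be reconciled:

* **Exact column sums.** Residual mismatches are repaired by moving a
  presence from an over-full biome to an under-full biome *within the same
  species*, which changes no species' BSI. The final matrix matches the
  target marginals exactly.
* **Total presence count.** Full occupancy plus exact marginals can demand
  more (or fewer) total presences than the conditional null law produces
  on average — for the ruminant-like preset the gap is substantial, because
  the null law leaves ~9% of species with no biome while the real matrix
  has none. The occupancy probabilities are therefore exponentially tilted
  so the expected total matches the required total, and the block is
  redrawn until it matches exactly.

Consequence, stated openly: when zero occupancy is likely under the null
law, the generated per-species BSI law is a tilted version of the
conditional null, not the null itself. The generator is exactly
null-distributed (up to the total-count conditioning) only where full
occupancy is nearly automatic; the goodness-of-fit test in the suite
uses such a configuration. `calibrate_specialist_excess()` inverts the
mixture expectation so a target observed specialist percentage (e.g.
40.1%) can be hit on average.

`generate_overlap_table()` inverts presence coding for round-trip tests:
each presence triggers exactly one rule (range or dominion, chosen at
random within a per-species range budget kept below 1), absences get
sub-threshold decoys, and one presence of each montane-flagged species is
routed through a montane dominion so the coding step re-flags it.

What the generator does *not* emulate: phylogenetic autocorrelation of
biome occupancy (occupancies are exchangeable across species given the
mixture), spatial nestedness of real ranges, and any species-level
identity. Passing tests therefore certify the pipeline's arithmetic and
statistical calibration, not ecological realism of any particular matrix.

## Study conditions used by the heavier checks

The parameter-recovery experiments simulate under the decreasing sigmoid
scenario (λ0 = 0.17, λ1 = 0.018 lineages/Myr, inflection at BSI 4.61)
with steepness r = 1.5/BSI, so the rate drop plays out over roughly two
BSI units; σ² = 0.15 BSI²/Myr, which lets Brownian motion span the
observed 1–8 BSI range over a ruminant-like tree depth of ~35 Myr; a
small constant μ = 0.01/Myr; and a root state of BSI 3, between the
observed mean specialization (2.1) and the inflection point, so simulated
clades actually straddle the rate transition — a recovery experiment whose
trait variation never crosses the inflection cannot identify it. Trees are
grown to 100 tips; fits use a 64-point grid, a 1-Myr step, a relative
tolerance of 1e-4, and the constant fit's estimates as the starting point
of the richer shapes, whose fitted menu (constant, linear, sigmoid)
mirrors how a decreasing trend can be captured at different parameter
costs. The Monte Carlo suite uses 10000 replicates, matching the default
analysis.

## Known limitations

* The likelihood does not condition on survival of the two root lineages;
  absolute lnL values are therefore not comparable to implementations that
  do, though differences between models fitted here are.
* Extinction is constant by design; trait-dependent μ is out of scope.
* The tilted generator is a structural emulator, not a sampler of the
  exact null (see above).
* Polytomy resolution is uniform-random, not informed by branch-length
  priors.
* BSI-as-continuous is an approximation shared with the underlying method;
  the tip kernel sd is the knob controlling how literally integer BSI
  values are taken.
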