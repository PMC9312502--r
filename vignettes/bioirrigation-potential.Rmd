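---
title: "Methods: community bioirrigation potential, its mapping and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community bioirrigation potential, its mapping and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthirr)
```

## The index and its assumptions

Bioirrigation — the flushing of burrow water by sediment-dwelling
macrofauna — is a dominant pathway of solute exchange across the
sediment–water interface, but direct rate measurements are scarce. The
community bioirrigation potential condenses routinely monitored community
data into a single proxy. For taxa $i = 1..n$ with abundance $A_i$
(ind m$^{-2}$) and ash-free dry-weight biomass $B_i$ (g m$^{-2}$):

$$\mathrm{BIPc} = \sum_{i=1}^{n} \frac{B_i}{A_i} \cdot A_i \cdot FT_i
\cdot BT_i \cdot L_i$$

$FT_i$, $BT_i$, $L_i$ are ordinal expert scores for feeding type, burrow
type and burrowing depth. The formulation carries three assumptions worth
making explicit:

* **Multiplicative traits.** A zero in any factor (e.g. burrow type zero
  for epifauna) silences the taxon entirely; traits do not compensate for
  one another.
* **Potential, not rate.** The index is static: it ignores seasonality,
  activity rhythms and density-dependent behaviour, and therefore tracks
  the *latent capacity* of the community, not momentary fluxes.
* **System dependence.** Pore-water transport is diffusion-dominated in
  muddy to fine-sand sediments and advection-dominated in permeable medium
  and coarser sands, and the same organism affects solute exchange
  differently in the two regimes. Each taxon therefore carries two score
  sets, and the sample's sediment system decides which applies.

Algebraically the mean individual biomass $B_i/A_i$ and the abundance
weight cancel for $A_i > 0$, so the index is linear in biomass at fixed
scores; the engine still evaluates the stated form (guarding $A_i = 0$,
which contributes zero without evaluating $0/0$) and the test suite
asserts the cancellation to $10^{-12}$ relative. The reference
bioturbation potential $\mathrm{BPc} = \sum_i \sqrt{B_i/A_i}\, A_i M_i
R_i$ (mobility, reworking; one score set) is computed alongside because
the two indices are routinely compared.

Taxa absent from the score table are excluded, never imputed; the loss is
quantified by coverage diagnostics (the percentage of total abundance and
biomass carried by scored taxa), and scored plus unscored shares always
total 100.

## Sediment-system classification

The package assigns the system from the sample's median grain size:
advective at or above `advective_min_grain_um`, otherwise diffusive. The
default threshold is **177 µm** (2.5 φ), the conventional boundary between
fine and medium sand in the Wentworth/φ scheme — consistent with treating
very fine and fine sands as diffusion-dominated. The threshold is a
configuration parameter, not a constant. Expert knowledge enters through
per-station overrides (some fine-sand sites with high organic content
behave diffusively despite a borderline median), which always beat the
grain-size rule; a sample with neither grain size, nor override, nor an
explicit label is an error rather than a silent default. Classification is
monotone in grain size by construction.

## Depth-resolved indices

Two depth-aware variants serve validation against sliced sediment cores:

* `layer_index()` restricts the community to records whose measured depth
  of occurrence lies in $[\mathrm{top}, \mathrm{bottom})$ cm — closed
  lower, open upper bound, so adjacent layers partition the core.
* `depth_profile()` distributes each taxon's whole contribution into the
  slice containing its depth, either the *measured* mid-depth of the slice
  of occurrence or the *theoretical* literature burrow depth
  (`lit_depth_cm` in the score table). Slices are half-open with a closed
  final slice and are 0-based at the sediment–water interface; slice sums
  plus the contribution of taxa lacking a depth reproduce the whole-core
  value exactly. The theoretical depth is a point value anticipating the
  maximum penetration depth — no within-burrow distribution is modelled —
  so theoretical profiles place mass at or below the measured ones.

## Temporal comparisons

Interannual variability is summarised by five-number box statistics per
station and compared by one-way ANOVA with Tukey's HSD (Tukey–Kramer for
unequal group sizes, via `stats::TukeyHSD`). Because index values are
strongly right-skewed, the ANOVA runs on $\log_{10}(x+1)$ by default; the
scale is configurable and the contrast of system means is always reported
on the untransformed scale (ratio of arithmetic means). Compact letters
come from an insert-and-absorb algorithm with the usual guarantee:
significantly different groups never share a letter, non-significant pairs
share at least one. When every group has zero residual variance the
comparison degenerates; the implementation then separates unequal means
exactly and letters equal means together rather than producing NaN
p-values. Whether the system contrast should pool samples or use station
means is genuinely open; pooled samples are the default and a
`by_station` option exposes the alternative.

## Spatial modelling

Mapping proceeds in the idiom of species-distribution modelling:

1. **Collinearity screen.** Predictor pairs with $|r| > 0.90$ (Pearson,
   $p < 0.05$) are resolved by dropping the member with the lower
   univariate predictive power, operationalized as the smaller absolute
   Spearman correlation with the response — simple, deterministic, and
   documented as a choice (ties break alphabetically). Constant predictors
   are dropped first with a warning.
2. **Random forest.** $\log_{10}(\mathrm{BIPc}+1)$ is regressed on the
   retained predictors with 1000 trees; 1–5 variables per node are tried
   and the setting with the highest out-of-bag percent variance explained
   wins. The reference BPc surface uses the 500-tree, 3-variables-per-node
   protocol. Importance is %IncMSE — the out-of-bag increase in MSE under
   predictor permutation, 10 permutations per tree — via the
   `randomForest` package, the standard tool for this protocol.
3. **Validation.** Kendall's τ between out-of-bag predictions and observed
   transformed values (out-of-bag rather than resubstitution, the
   defensible choice when no external data exist), plus held-out τ in the
   synthetic parameter-recovery tests.
4. **Prediction.** Cell-wise prediction over the raster stack; missing
   cells propagate; the log-scale surface is the primary product and the
   back-transform $10^{\hat y} - 1$ is provided without bias correction.

Rasters are plain matrices with cell-center registration (row 1 =
northernmost) inside a `predictor_stack`; stations are extracted by the
nearest-cell rule without interpolation. Text I/O uses the ESRI ASCII grid
format, chosen because it is human-readable, self-describing and
diff-able; the package does not read or write GeoTIFF.

As a complementary, model-free summary, `variance_explained()` reports the
percent of variance a single predictor explains: for one
Euclidean-distance response variable a distance-based redundancy analysis
reduces exactly to OLS, so the quantity is $100 R^2$.

## Hotspot overlay

"Relative hotspot" has no canonical definition, so the overlay is an
explicit operationalization: each surface is reduced to within-raster
quantile ranks (midranks, scaled to $(0,1]$), and a cell is `a_higher` /
`b_higher` when the rank difference exceeds `delta_quantile` (default
0.10), `both_hot` when both ranks reach `hot_quantile` (default 0.75) and
the difference is within tolerance, otherwise `neither`. Rank-based
differencing makes the overlay invariant to any monotone rescaling of
either input, so comparing a log-scale and a linear-scale surface is
legitimate. Both thresholds are exposed; the defaults are interpretation,
not reproduction of any published rule.

## Validation statistics

Correlation suites use pairwise-complete observations and midranks for
ties. For Spearman and Kendall with $n \le 9$ untied observations the
p-value is exact — the full rank-permutation distribution, as computed by
`stats::cor.test` — and the test suite checks it against an exhaustive
permutation enumeration; larger or tied samples use the t / normal
approximation. Pairs with fewer than three complete observations or a
constant member are reported missing, never zero. Flux tables are matched
to index values per analyte, with optional mean or max aggregation of
repeated station visits; analytes with fewer than three matched stations
are skipped with a warning.

## The synthetic-data generator

The generator exists so that every stage has inputs with *declared* ground
truth. Defaults encode the study conditions the pipeline is designed for:
a 120-taxon score pool, eight monitoring stations (four per system)
sampled over 20 years, a five-fold expected advective/diffusive index
ratio, and 14 incubation cores.

* **Scores:** integer scores uniform on $1..3$; 10% of taxa are epifauna
  (burrow type zero in both systems); half of the remainder get advective
  scores whose product differs from the diffusive one.
* **Communities:** Bernoulli occupancy (p = 0.3), lognormal abundance
  (meanlog 4, sdlog 1) and individual mass (meanlog −3, sdlog 0.7) —
  right-skewed, as macrofauna data are, which is what motivates the
  $\log_{10}(x+1)$ transform downstream. The sample's true index is drawn
  lognormally around its system mean (CV 0.3) and biomasses are rescaled
  so the assembled community's index — computed by a literal per-taxon
  loop, independent of the vectorized engine — *equals* the draw. The
  declared truth is therefore exact, and the planted 5× contrast with CV
  0.3 at 20 samples per system gives the temporal stage a known effect
  size whose recovered ratio falls in [4, 6] with high probability.
* **Landscape:** standardized Gaussian-smoothed random fields (smoothing
  radius 4 cells on a 50 × 70 grid); the true log-index surface is a
  declared linear combination of 3 driver layers (coefficients 1, 0.8,
  0.6, rescaled to mean 1.5, sd 0.5) with 5 inert decoys; 200 stations
  observe the surface with lognormal-scale noise (sd 0.15, chosen as
  modest observation noise that leaves the mapping task non-trivial). A
  companion bioturbation surface uses the reversed coefficients, giving
  the overlay two related but distinct patterns.
* **Measurements:** irrigation $= a\,\mathrm{BIPc}^{b} e^{\varepsilon}$,
  $\varepsilon \sim N(0, 0.4)$ — a declared monotone power link whose
  expected rank correlation at $n = 14$ is comfortably detectable.

One master seed fans out into fixed per-generator sub-seeds, so adding a
generator never changes another's stream. What the generator does **not**
emulate: a real species pool or salinity gradient, absolute index
magnitudes, spatial autocorrelation of communities beyond the smooth
environmental fields, taxonomic misspellings, or zero-inflated
measurement error. Passing tests therefore demonstrate that the machinery
recovers planted structure under the stated statistical assumptions — not
that those assumptions hold in any particular sea.

## Numerical choices and degenerate inputs

* Score matching is exact after whitespace squeezing and case folding; no
  fuzzy matching (misspellings surface in the coverage diagnostics).
* Replicate grabs are pooled by mean after conversion to per-m² units,
  with the pooling mode always explicit in the reader, never inferred.
* $A_i = 0$ with $B_i = 0$ contributes zero before any division; $B_i > 0$
  with $A_i = 0$ is rejected at validation.
* Ranking ties (key-species shares) break alphabetically for determinism.
* Zero total biomass makes coverage undefined (`NA`), not 0; an entirely
  unscored, non-empty sample yields index 0 with a warning, not an error.
* Quantiles are linear-interpolation (type 7) throughout.
* All stochastic stages record their seed; refits and pipeline reruns with
  the same seed are bit-identical, which the tests assert on file digests.

## Problem sizes

The test and acceptance runs use the generator's default conditions where
they matter (200 mapping stations, 8 predictor layers, 1000 trees × 5
node settings; 20 station-years per system for the temporal contrast;
1000 random samples for the engine/oracle equivalence) and scaled-down
grids (≈ 18 × 22 cells, 100 trees) for the pipeline determinism checks,
sizes chosen to keep the full suite comfortably interactive on one core.

## Known limitations

* The index inherits the limits of expert scoring: no temporal dynamics,
  no density dependence, and scores constant within a taxon.
* The 177 µm default threshold is a convention; where a mapped sediment
  classification disagrees with station medians, overrides must carry the
  expert decision.
* %IncMSE importance is known to spread credit among correlated
  predictors; the collinearity screen mitigates but does not remove this.
* The back-transformed surface $10^{\hat y}-1$ is biased low for a
  log-scale model; the log surface is the primary product.
* dbRDA is supported only in its univariate reduction (OLS); full
  multivariate redundancy analysis is out of scope.
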