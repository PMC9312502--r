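# benthirr

Trait-based estimation of the **community bioirrigation potential (BIPc)**
of soft-sediment macrofauna, with the full analysis pipeline around it:
sediment-system classification, temporal comparisons, random-forest spatial
mapping, hotspot overlays against the community bioturbation potential
(BPc), and validation against tracer-irrigation and solute-flux
measurements.

## The problem and the index

Burrowing macrofauna flush water through their burrows ("bioirrigation"),
enhancing solute exchange across the sediment–water interface. Measuring
irrigation rates directly is costly, so large-scale assessments instead
score each taxon's relevant traits and weight them by how much of that
taxon is present. For a sample with taxa *i = 1..n*, abundance *Aᵢ*
(ind m⁻²) and ash-free dry-weight biomass *Bᵢ* (g m⁻²):

    BIPc = Σᵢ (Bᵢ/Aᵢ) · Aᵢ · FTᵢ · BTᵢ · Lᵢ

where *FTᵢ*, *BTᵢ* and *Lᵢ* score feeding type, burrow type and burrowing
depth. A trait irrelevant to solute exchange (e.g. epifauna) scores zero
and silences the taxon's contribution. The distinctive feature of BIPc is
that each taxon carries **two score sets** — one for diffusion-dominated
(muddy to fine-sand) and one for advection-dominated (medium sand and
coarser) sediments — because burrow ventilation interacts differently with
the two pore-water transport regimes. The package classifies each sample
from its median grain size (default cutoff 177 µm, the conventional
fine/medium-sand boundary, with expert overrides) and applies the matching
score column. The reference bioturbation index is computed alongside:

    BPc = Σᵢ √(Bᵢ/Aᵢ) · Aᵢ · Mᵢ · Rᵢ

with mobility and reworking scores and no system switching.

Downstream stages mirror a complete regional assessment: ANOVA + Tukey HSD
compact-letter displays of interannual variability per station;
collinearity-screened random-forest regression of log₁₀(BIPc + 1) on
environmental raster layers (1000 trees, 1–5 variables per node, %IncMSE
permutation importance, Kendall-τ validation); raster prediction and a
quantile-rank bivariate hotspot overlay of the BIPc and BPc surfaces; and
Spearman correlation suites against bromide-tracer irrigation and solute
fluxes. A seeded synthetic-data generator produces score tables,
communities, landscapes and measurements with declared ground truth, so
every stage is testable without field data.

## Worked example

```r
library(benthirr)

cfg    <- sim_config(seed = 1, n_stations = 4, years = 5)
scores <- gen_scores(cfg)                  # 120-taxon trait-score table
comm   <- gen_communities(cfg, scores)     # 20 station-year samples
rule   <- system_rule()                    # 177 um grain-size cutoff

res <- bipc(comm$samples[[1]], scores,
            classify_system(comm$samples[[1]], rule))
res
#> BIPc result: station ST01 on 2001-05-01 ( diffusive system )
#>   BIPc = 66.63   BPc = 151.9
#>   coverage: 100.0% of abundance, 100.0% of AFDW biomass
```

The index value (66.63, on the score·g·m⁻² scale the formula produces) is
the sum of the per-taxon contributions in `res$contributions`; the
coverage lines report how much of the sample's abundance and biomass the
score table accounts for. Comparing the two sediment systems across all 20
samples:

```r
vals <- vapply(comm$samples, function(s)
  bipc(s, scores, classify_system(s, rule))$bipc, 1)
sys  <- vapply(comm$samples, function(s) classify_system(s, rule), "")
system_contrast(vals, sys)
#> $ratio ......... 4.98        # advective/diffusive mean BIPc
#> $tukey_p ....... 2.58e-10

tukey_letters(vals, vapply(comm$samples, function(s) s$station_id, ""))
#> Tukey HSD compact letter display (alpha = 0.05 )
#>  group     mean letters
#>   ST01 1.981341       b
#>   ST02 1.933566       b
#>   ST03 2.652979       a
#>   ST04 2.639766       a
```

The generator planted a five-fold advective/diffusive contrast; the
estimate (4.98) recovers it, the contrast is significant, and the two
advective stations (ST03, ST04) share a letter distinct from the two
diffusive ones. `run_pipeline()` chains all stages (simulate → index →
temporal → map → overlay → validate) into an output directory with a
digest manifest; `vignettes/bioirrigation-potential.Rmd` documents the
methods and design choices.

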