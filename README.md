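# paleocatch

Quantitative tools for marine historical ecology built around
zooarchaeological fish remains. The package is aimed at
zooarchaeologists and fisheries ecologists who compile faunal data from
excavation reports (counts of identified specimens per taxon per site)
and want to (i) summarise those assemblages with defensible abundance
and richness metrics, (ii) diagnose how much of the observed pattern is
an artefact of recovery methods such as sieve mesh size, and (iii) ask
whether the species people caught in the past were a non-random,
trait-selective subset of the regional fish fauna — the core question
behind fisheries-baseline studies.

## What it computes

**Assemblage metrics.** Counts are NISP (number of identified
specimens) or, where only those are published, MNI (minimum number of
individuals), pooled into the same arithmetic. Relative abundance of a
taxon *i* is

```
RA_i = 100 * NISP_i / sum_j NISP_j ,
```

where the denominator excludes remains recorded only at class level
(Actinopterygii, Elasmobranchii) — those stay in the totals and in the
per-class identified fractions. Species richness follows the Minimal
Level of Taxonomic Identification (MLTI): a record is discarded when it
is an ancestor of another record present in the same assemblage
(`Genidens sp.` contributes nothing next to `Genidens barbus`), and
class-level records never count. The weighted average trophic level of
an assemblage is `WATL = sum_i w_i TL_i` with `w_i` the
class-excluded relative abundances renormalised over taxa whose trophic
level resolves; genus-, family- and order-level records receive the
mean TL of regional member species.

**Recovery-bias diagnostics.** NISP/m³ and SR/NISP are compared across
sieve mesh classes (2–3 mm pooled, 4 mm, 5 mm) with one-way ANOVA and
Tukey HSD (Tukey–Kramer for unbalanced groups), and the sample-size
effect is probed with Pearson correlations of SR against NISP/m³,
including an endmember-sensitivity re-fit that drops the point maximal
in both variables.

**Trait null model.** For each time period, the observed trophic
levels, maximum body sizes and maximum body masses of the period's
catch list (size and mass on the log scale) are compared against
richness-matched random assemblages: 1000 draws of *n* species sampled
without replacement from the total regional pool (union of all period
catches and the regional non-target species). The default test is a
two-sided Welch *t* of observed values against the pooled null values;
an empirical alternative ranks the observed mean among the null means.
Size classes (<7, 7–15.0, 15.1–30.0, 30.1–50.0, 50.1–80.0, >80 cm),
trophic groups, and their pairing into functional entities are
tabulated per period and compared with an exact two-tailed binomial
test (minimum-likelihood method).

**Synthetic assemblages.** A seeded generator produces a regional pool
with correlated log size/mass and trophic level, trait-selective period
catch lists, and site assemblages degraded by lognormal specimen
allocation, logistic mesh-dependent sieve retention, and class-level
identification loss — so every downstream statistic can be tested
against known ground truth.

## Worked example

```r
library(paleocatch)

cfg <- generator_config(seed = 11)   # 365-species pool, 3 periods, 12 sites
sim <- simulate_dataset(cfg)
ds  <- sim$dataset
ds
#> <catch_dataset>
#>   taxa:        463 records
#>   sites:       12
#>   counts:      488 rows in 12 assemblages (total NISP/MNI 45,283)
#>   traits:      365 species
#>   periods:     3 (190 presence rows)

pool <- build_total_pool(ds$periods, ds$traits$species, ds$traits)
pool
#> <species_pool> 365 species (152 targets + 213 non-targets, overlap 152)

# is the first period's catch larger-bodied than random draws from the pool?
trait_null_test(ds$periods$species[ds$periods$period_id == "P1"],
                pool, ds$traits, "max_body_size_cm",
                reps = 1000, period_id = "P1")
#> <null_model_result> max_body_size_cm, period P1: observed mean 4.206
#>   vs null 3.412, p = 3.379e-13 (pooled_t, 1000 reps)

asm <- ds$counts[ds$counts$site_id == "site01", ]
species_richness_mlti(asm, ds$taxa)   # MLTI richness of one assemblage
#> [1] 49
watl(asm, ds$taxa, ds$traits)         # abundance-weighted trophic level
#> [1] 3.313
```

The observed mean is the mean log maximum body size of the period's 62
species; the null mean is that of 1000 richness-matched random pools.
Here the generator's size-selective catch (its default for pre-modern
periods) is correctly flagged as far larger-bodied than random
(p ≈ 3e-13), while the simulated site assemblage resolves 49 species
at an average trophic level of 3.3.

`run_pipeline(run_config(...))` chains validation, simulation or
loading, abundance summaries, mesh diagnostics and the null model into
one run that writes CSV tables plus a JSON manifest with the seed,
configuration and per-file checksums.

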