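---
title: "Methods: fish-assemblage baselines from zooarchaeological records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fish-assemblage baselines from zooarchaeological records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocatch)
```

## The problem

Archaeological fish bones are one of the few records of what coastal
people caught before systematic fisheries statistics existed. Two
obstacles stand between the excavated counts and an ecological
statement. First, the record is filtered: fine bones fall through
coarse sieves, and most remains can only be identified to class
(Actinopterygii or Elasmobranchii), so raw counts confound past fishing
with recovery and identification practice. Second, "the past catch was
different" is only meaningful against an explicit expectation: a catch
of 62 species will differ from the regional fauna by chance alone, so
trait differences must be judged against random assemblages of equal
richness. This package implements both halves — the descriptive
metrics with their bias diagnostics, and the null-model inference —
plus a synthetic-data generator that provides ground truth for testing
every stage.

## Assemblage metrics

An assemblage is the set of per-taxon counts for one site and cultural
phase; counts published for separate excavation areas are summed first
(`aggregate_counts()`), which preserves total NISP exactly. MNI-based
sites are flagged via `quantification_basis` and enter the same
arithmetic, reflecting how compiled datasets pool the two measures; an
assemblage mixing both bases is refused.

`relative_abundance()` removes class-level records from the percentage
denominator because a specimen identified only as "bony fish" carries
no taxonomic signal; those specimens remain in the totals and in the
per-class identified fractions, which are themselves informative about
analytical intensity. Percentages are computed at full precision and
rounded to one decimal only for display.

MLTI richness (`species_richness_mlti()`) counts the leaves of the
presence forest induced by the assemblage's lineages: a record is
subsumed by any present descendant, and class-level records never
count. Two consequences are worth stating: adding an ancestor of a
present taxon never changes richness, and adding a genuinely new leaf
adds exactly one. Both are enforced as property tests.

Trophic-level attribution (`taxon_trophic_level()`) is exact for
species and an arithmetic mean for higher ranks, taken over regional
species inside the taxon, with an optional fallback checklist (e.g. a
national biodiversity listing) when no regional species resolves. The
provenance of every attributed value is attached to the result. WATL
weights these levels by class-excluded relative abundance renormalised
over resolvable taxa; it is invariant to rescaling all counts, and a
presence-weighted variant is available through `weighting =
"presence"` because compilations do not always state which weighting
produced a published assemblage-level trophic value.

Qualitative (source C) reports name taxa without usable counts. They
must participate in richness and occurrence but never in abundance, so
the validator admits presence markers (count = 1) at C sites and flags
anything larger. Occurrence is hierarchical — a family occurs wherever
any member occurs — because family-level occurrence in compiled data
legitimately exceeds that of any single member.

## Recovery-bias diagnostics

Mesh sizes collapse to three classes (2–3 mm pooled, 4 mm, 5 mm);
other values are refused rather than guessed. The mesh comparison uses
one-way ANOVA with Tukey HSD at 95% family-wise confidence;
`stats::TukeyHSD()` supplies the Tukey–Kramer harmonic-mean adjustment,
which matters because compiled mesh groups are heavily unbalanced. At
two groups the Tukey p-value collapses to the pooled-variance t-test
p-value, which the tests verify as an analytic anchor.

The sample-size effect is probed with a Pearson correlation of MLTI
richness against NISP/m³. Because compiled datasets are small, a
single site that is maximal in both variables can manufacture a
correlation; `endmember_sensitivity()` reports the fit with and
without that point. When no point is maximal in both coordinates, the
largest-Mahalanobis point is used and the result flagged, or an error
raised if the fallback is disabled — silent substitution of a
different definition seemed worse than either option.

## The trait null model

The total pool is the union of all period catch lists (targets) with
the regional species never recorded as targets. Null assemblages are
richness-matched: each of `reps` draws samples *n* species uniformly
without replacement, where *n* is the focal period's richness. This is
the standard community-ecology construction when the question is
"would a random catch of this many species look like this?"; sampling
without replacement matches the fact that a catch list is a species
set.

Two observed-vs-null tests are provided because the literature is
genuinely ambiguous about the construction:

* `pooled_t` (default): Welch two-sided t of the observed values
  against all null values pooled across draws. With draws from a
  finite pool this is slightly conservative — the t statistic ignores
  the without-replacement variance reduction of the observed mean, by
  the factor `1 - (n-1)/(N-1)` — so its realised type-I error sits
  below the nominal 5%.
* `null_means`: the observed mean is ranked among the per-draw null
  means with an add-one two-sided empirical p. Under uniform catches
  the observed mean is exchangeable with the null means, so this mode
  is calibrated by construction; the calibration property (5% ± 2%
  rejection over 1000 simulated uniform catches) is tested in this
  mode.

Maximum body size and mass are analysed on the natural-log scale
(their distributions span orders of magnitude and are strongly
right-skewed); trophic level is analysed raw. The same convention
applies to the across-period ANOVA. Every result object stores `reps`,
`seed` and the mode, so a reported p-value is replayable.

Size classes follow the printed one-decimal labels, which fixes the
boundary convention: breaks are upper-inclusive at 15.0, 30.0, 50.0
and 80.0, the `<7` class is open at 7, and 30.05 falls in
`30.1–50.0`. The exact two-tailed binomial test uses the
minimum-likelihood method — the p-value sums the probabilities of all
outcomes no more likely than the observed one — with a `1 + 1e-7`
relative tolerance absorbing floating-point ties, and is verified
exhaustively against enumeration for all n ≤ 20. When two periods'
proportions are compared, the comparison period's observed proportion
serves as the null `p0` with `k` and `n` from the focal period; the
roles can be swapped, and reporting both directions is recommended
because neither direction is canonical.

## The synthetic generator

`generator_config()` encodes the study conditions: a 365-species
regional pool; period catch lists of 62, 34 and 94 species; total
site NISP drawn log-uniformly from 10² to 10⁵; excavated volumes from
0.06 to 13.8 m³; identification beyond class succeeding for 17% of
bony and 56.7% of cartilaginous remains; and a squared size–mass
correlation target of 0.67. The two pre-modern periods default to a
size-selective catch (`beta_logl = 1.5`, the effect size at which the
null model's power property is defined) and the modern period to an
unselective one, mirroring the qualitative contrast the null model is
meant to detect.

Values the study conditions do not pin down were chosen once, as
field-plausible, and are not tuned: trophic level follows a scaled
Beta(2, 2) on [2.0, 4.9] (most species mid-trophic, few at either
extreme); log10 body size is Normal(1.5, 0.35), i.e. typical maxima
near 30 cm spanning roughly 3–300 cm; the mass allometry is
`log10 W = -2 + 3 log10 L` (the cube law for W in g, L in cm), with
noise variance solved from the correlation target as
`sd = |b| * sd_x * sqrt((1 - r2) / r2)`; species abundances within a
site follow a lognormal species-abundance distribution (σ = 1) with
multinomial specimen allocation; and sieve retention is logistic in
log body size with slope 4 and a mesh-proportional midpoint (4 cm at
2 mm mesh), which is smooth, monotone in mesh, and collapses to a hard
sieve cut-off at large slope. Trophic groups are drawn from
TL-conditional guild probabilities (low TL: herbivores/planktivores;
mid: omnivores and invertivores; high: macrocarnivores and
piscivores).

Every generated object draws from a sub-seed hashed from the master
seed and the object's identifier, so a single site can be regenerated
without replaying the whole simulation, and the same configuration is
byte-identical across runs.

What the generator does *not* emulate — bone fragmentation,
inter-site spatial structure, taphonomic loss correlated with skeletal
element, taxonomic mis-identification, temporal autocorrelation of
catches — bounds what passing tests show: they demonstrate that the
statistics recover known ground truth under the stated sampling model,
not that real compiled data satisfy that model.

## Numerical choices and degenerate inputs

* Internal arithmetic is full precision; display rounding (one decimal
  for percentages, nearest integer for occurrence) is applied only in
  `*_display` fields.
* Latitude is stored signed (southern hemisphere negative) so trend
  fits against latitude are unambiguous.
* An assemblage whose remains are all class-level yields an empty
  abundance table with a warning, not an error — it is a legitimate,
  if uninformative, observation. A site without excavated volume is
  excluded from density analyses with a message rather than failing
  the run.
* Degenerate statistical input errors early and by name: constant x in
  a trend fit, zero variance in a correlation, groups of size one in
  the ANOVA, a null sample larger than the pool, `p0` outside (0, 1).
* Infinite selectivity coefficients are honoured as the exact limit
  (the catch becomes the top-n species in the infinitely weighted
  trait, ties broken at random) because the limit case is part of the
  generator's contract.

## Problem sizes in the test suite

The suite favours fixed-seed simulations sized for tight feedback:
module tests run pools of 80 species and 6–12 sites; the calibration
property uses 1000 simulated uniform catches with 1000 null draws
each; the power property 200 selective catches at the full pool size
(n = 62 of 365); the finite-population check 10,000 draws; the
binomial enumeration is exhaustive to n = 20; coverage of the trend
fit's confidence band uses 400 replicate fits. These sizes are the
package's chosen trade-off between Monte-Carlo error and turnaround.

## Known limitations

Occurrence and richness treat the taxon table as authoritative:
synonymy and misspellings must be resolved upstream. The MLTI rule is
purely topological — it cannot recognise that `Genidens sp.` recorded
at one site and `Genidens barbus` at another might be the same
population. The null model treats species as exchangeable units and
ignores phylogenetic or habitat structure in the pool, and the
binomial comparisons treat species as independent trials. Radiocarbon
calibration is out of scope: `median_age_cal_bp` is consumed as given.
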