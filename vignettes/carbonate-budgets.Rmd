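---
title: "Census-based reef-flat carbonate budgets: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census-based reef-flat carbonate budgets: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefbudget)
```

## The budget model

A reef's carbonate budget balances biological accretion against
biological erosion, expressed throughout as
G = kg CaCO₃ per planar m² per year. The package implements the
census-based formulation used for reef-flat surveys: every quantity is
computed per 10 m survey line and then summarised upward, never the
other way around, because the line is the replication unit of the field
protocol.

**Gross production.** Each line carries 100 point-intercept
observations at 10 cm spacing (positions 10–1000 cm). For each
carbonate producer *i* on the line — a (taxon, morphology) group of
live coral, or crustose coralline algae (CCA) — gross production is

$$G_i = R \times \frac{X_i}{100} \times \frac{C_i \times 10\,000}{1000},$$

where $X_i$ is the producer's percent cover (its point count, since
there are exactly 100 points), $C_i$ its calcification rate in
g cm⁻² yr⁻¹, and $R$ the line's rugosity coefficient — the mean of
three 1 m chain sections, each the ratio of draped-chain (surface)
length to linear length. The conversion factor is 10⁴ cm² m⁻² divided
by 10³ g kg⁻¹ and reduces to exactly ×10; `gross_production_rate()`
asserts that reduction on every call so the implemented form can never
drift from the published one. The rugosity multiplier converts cover on
the planar tape to the true three-dimensional substrate area that
calcifies. One $R$ — the line's own — applies to all producers on that
line, and CCA is scaled by $R$ exactly like corals: the production
equation is applied uniformly to every producer, the simplest reading
of its generic form.

**Bioerosion** has three components, summed exactly:

- *Endolithic borers*: micro- and macro-borers erode all available
  substrate — the census categories live coral, reef framework, dead
  coral and rubble — at fixed published rates. With `f_avail` the
  fraction of points on available substrate,
  $E_{borer} = R \times f_{avail} \times (0.052 + 0.053)$. The printed
  single-rate form of this law shows the micro-borer constant only; the
  accompanying description applies both constants, so the package uses
  their sum with each independently configurable.
- *Parrotfish*: an imported belt-survey-derived grazing rate (default
  3.81 G) applied per planar m² of available substrate,
  $E_{fish} = 3.81 \times f_{avail}$. No rugosity multiplier is applied
  by default because fish-survey rates are normalised to planar area; a
  flag (`parrotfish_use_rugosity`) enables $R$-scaling for sensitivity
  analysis. Available substrate is taken to include live coral, as the
  borer definition lists it, although parrotfish graze mostly dead
  surfaces; the category sets make this assumption explicit and
  editable.
- *Echinoids*: per genus, the test-size power law
  $E = ((a \cdot X^{1.6624}) \cdot e \cdot 365/60)/1000$ with $X$ the
  mean test diameter (mm) and $e$ the density (individuals m⁻²,
  computed as count/area so belt geometry cancels for fixed density).
  The 365/60 factor belongs to the published daily-to-annual rate chain
  and is applied verbatim. The *Diadema* coefficient is $a = 0.0029$.
  The *Phyllocanthus* coefficient is commonly printed as $8 \times
  10^5$, which produces rates about eight orders of magnitude above the
  *Diadema* law for a similar-sized urchin — physically incoherent — so
  the package defaults to $8 \times 10^{-5}$ (the sign-of-exponent
  reading) and leaves the literal value injectable through
  `rate_table()` or an erosion config file.

Belt transects are coarser than survey lines, so the belt-scale
echinoid rate reaches a line through the closest available match: mean
of belts sharing the line's transect and zone, else the transect's
belts, else the reef-wide belt mean (belts are typically surveyed on
only a subset of transects). With no belts the term is zero, with a
warning.

**Net budget and aggregation.** Net G per line is exactly gross minus
total erosion. `aggregate_budget()` reports unweighted means and sample
(n−1) SDs at three scales: (transect × zone) groups of replicate lines,
transects, and the reef. The reef scope averages transect means —
the convention for a reef-wide figure built from radial transects —
with pooled-line averaging available as an option; the two differ
whenever transects carry unequal line counts. Because the mean is
linear, the accounting identities (net = gross − erosion; total =
component sum) survive aggregation exactly, and the test suite asserts
them at every scale. Sand-moat (zone 1) lines contain no carbonate
producers by construction and are excluded from all aggregates.

**Cover threshold.** `cover_threshold()` fits net G on live coral cover
by OLS and reports the x-intercept — the cover below which the
predicted budget turns negative. Its interval comes from inverting the
confidence band for the mean response: the bounds solve
$(b_0 + b_1 x)^2 = t^2(v_{00} + 2xv_{01} + x^2 v_{11})$, a Fieller-type
quadratic in the coefficient covariance. When the band never excludes a
flat line (the quadratic's leading term is non-positive) the interval
is reported as unbounded rather than silently truncated. A threshold is
only reported when the slope is positive and significant at 5%; flat or
decreasing relationships return the fit with a diagnostic reason
instead. Perfect (zero-residual) fits are handled specially: the
coefficient covariance is computed directly as $\sigma^2 (X^TX)^{-1}$,
and the slope's sign is judged against a scale-aware round-off
tolerance so that constant data never manufactures a threshold.

## The synthetic survey generator

No public dataset carries a full reef-flat census of this design, so the
package ships a generator whose output has the statistical structure the
analysis assumes, with the generating parameters recorded in a
machine-readable truth file (`truth.json`) so tests never reach into
generator internals.

A `zone_profile()` specifies one eco-geomorphic zone: a multinomial
distribution over the nine benthic categories, a (taxon, morphology)
mixture for live coral, a rugosity distribution (normal truncated at 1,
the physical floor), and an urchin community (density, genus mix, mean
test sizes). A `reef_scenario()` arranges profiles along radial
transects and fixes replication and the seed; the same seed regenerates
the dataset byte for byte.

`default_mahutigala_scenario()` emulates a small Maldivian lagoonal
reef platform surveyed shortly after a mass bleaching event:

- five zones — a producer-free sand moat (zone 1), a patch-reef zone
  over a sand/rubble plain (~70% sand+rubble, ~15% live coral), an
  inner reef flat (~30% dead coral, ~17.5% live), and two outer
  reef-flat zones (~40–45% dead framework under turf and CCA, ~18–20%
  live). Category probabilities sit at the midpoints of the cover
  ranges characteristic of each zone type, the only defensible choice
  when a range is all that is known; they are a synthetic stand-in,
  not the field data.
- a massive-dominated post-bleaching coral community: massive *Porites*
  66%, branching *Acropora* 13%, the calcifying octocoral *Heliopora*
  13% (treated as a carbonate producer alongside the scleractinians,
  recorded under its observed branching morphology), and 8% spread over
  encrusting, digitate, tabular and free-living forms;
- zone rugosity means 2.2–2.8 (SD 0.3), spanning the ~1.9–2.9 range
  typical of structurally intact reef flats;
- sparse urchins at 0.1 ind. m⁻², split evenly between *Diadema* (mean
  test 30 mm, truncated to the 21–40 mm class) and *Phyllocanthus*
  (90 mm, 81–100 mm class), with per-belt counts drawn as
  Poisson(density × area × genus share) over 30 m × 2 m belts, two
  replicates per zone crossing on four of the seven transects;
- seven radial transects, each crossing three productive zones with
  three replicate lines per crossing: 63 lines and 6300 census points.
  A transect does not cross every zone on a real platform, and the
  63-line total cannot be decomposed uniquely from published totals
  alone; assigning each transect three productive zones reproduces the
  protocol arithmetic exactly while keeping the design balanced, which
  in turn makes the transect-means and pooled-line reef averages
  coincide in expectation.

Census points are drawn independently along the line by default; real
benthos is patchy, so an optional first-order Markov persistence
parameter (`patchiness`) lets a point repeat its predecessor's category
with fixed probability while preserving the marginal composition. It is
off by default because the census protocol provides no autocorrelation
information to calibrate it.

**What passing tests do and do not show.** The generator reproduces the
*composition* structure of a reef-flat census: zone-specific cover
distributions, a coral mixture, truncated rugosity, sparse urchins. It
does not simulate spatial gradients within zones, observer error,
tide-dependent detectability, bleaching dynamics or temporal change.
Parameter-recovery tests therefore validate the *pipeline arithmetic*
(that the estimators recover known inputs at the expected Monte-Carlo
rate), not the ecological fidelity of any particular rate table.

## Rates and their defaults

`default_rate_table()` ships morphology-level calcification defaults of
realistic Indo-Pacific magnitude (massive 1.2, branching 2.5, tabular
2.0, digitate 1.5, encrusting 0.6, free-living 0.8, CCA 0.4
g cm⁻² yr⁻¹, plus genus rows for the taxa the generator emits). They
are deliberately labelled illustrative: published compilations are
study-specific, so any real analysis should inject its own table via
`read_rates()`. Lookup resolves genus rows first, then morphology-level
fallbacks; `strict = TRUE` turns fallback into an error for analyses
whose rate table is supposed to be complete. Erosion constants default
to the values quoted above and can be overridden per study from a plain
`key = value` config file (`read_erosion_config()`), which also accepts
the verbatim $8 \times 10^5$ *Phyllocanthus* coefficient for
exact-reproduction runs.

## Numerical choices and degenerate inputs

- Percent covers are exact point counts (integers over 100 points), so
  category covers sum to exactly 100 with no floating-point slack.
- Identities (net = gross − erosion, component sums, term sums) are
  exact arithmetic, tested with `expect_identical()` where possible.
- Chain ratios below 1, belts with non-positive area, test sizes
  outside 1–200 mm, incomplete lines, duplicate positions and unknown
  enum values are all rejected at validation with messages naming the
  offending line, row or value.
- Zero total production yields an empty morphology-share map (nothing
  to apportion); zero total erosion yields empty component shares.
- The truncated-normal rugosity sampler uses rejection (negligible cost
  at the default means); its closed-form mean
  (`truncated_normal_mean()`) feeds the truth record and the
  closed-form expectations (`expected_budget()`) used in recovery
  tests.

## Problem sizes used in the validation suite

The test suite runs entirely on generated data: oracle-equivalence
checks compare the pipeline against a brute-force recomputation on 120
small randomised reefs; parameter recovery uses a 504-line scaled-up
default scenario against closed-form expectations within three
Monte-Carlo standard errors; threshold coverage uses 200 simulated
regressions of 25 points each against the nominal 95% band. These sizes
give comfortable statistical resolution for every check while keeping
the full suite under half a minute on one CPU.

## Known limitations

- The parrotfish term is an imported constant, not a fish census; its
  (large) published uncertainty is not propagated into net-G SDs, which
  therefore reflect spatial variation only.
- Secondary producers other than CCA (foraminifera, molluscs) and
  abiotic cementation are not modelled; macroalgae contribute zero
  production by default, with an opt-in switch (`halimeda_ci` in
  `rate_table()`) that counts censused *Halimeda* as a calcifier when a
  study warrants it.
- Chemical dissolution and physical (non-biological) erosion are out of
  scope; "net" means net *biological* carbonate production.
- Zones are categorical labels; the package does no spatial or GIS
  handling of zone extents.
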