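---
title: "Harmonising floral resource traits: the floresdb workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising floral resource traits: the floresdb workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floresdb)
```

## The problem

Quantifying the food a habitat offers pollinators requires, per plant
taxon: when it flowers, how densely, and how much nectar sugar and pollen
each flowering unit provides per day. Literature values for these traits
come in heterogeneous units (µl vs ml, µg vs g, percent vs molar sugar
concentration, pollen as mass or grain volume) and, worse, refer to
different floral entities — a single flower for one source, a whole umbel
for another. `floresdb` standardises such records onto the *floral unit*
(FU), the set of flowers an insect can visit without flying, in canonical
physical units, and aggregates them into a per-taxon trait database from
which daily per-m² resource supply can be computed.

## The model and its assumptions

**Floral units.** Clustered flowering structures (raceme, panicle, corymb,
umbel, catkin) are treated as one floral unit. Densities counted as single
flowers per m² are divided by the number of open flowers per inflorescence,
`fu_A = f_A / f_I`; per-single-flower resources are multiplied by it,
`R_fu = R_f · f_i`. `f_I` and `f_i` are the same quantity — open flowers
per inflorescence, taken from a lookup table with an override slot for
species the survey missed. The two transformations jointly conserve the
per-area resource, `f_A · R_f = fu_A · R_fu`, which the test suite asserts
as an invariant. When a species is absent from the lookup table the single
flower *is* the floral unit; the record is flagged, not rejected, because
most non-clustered species legitimately never appear in such a table. The
multiplicative rule assumes flowers within an inflorescence provision
synchronously; no within-inflorescence opening sequence is modelled.

**Nectar chemistry.** Nectar sugar is treated as pure saccharose with
density ρ_z = 1570 mg ml⁻¹ and molar mass M_z = 342.3 g mol⁻¹. Sugar mass,
nectar volume and concentration interconvert as

* m_z \[mg\] = ρ_z · V_nec \[ml\] · c_perc/100
* m_z \[mg\] = V_nec \[ml\] · c_mol \[mol l⁻¹\] · M_z \[g mol⁻¹\]
* c_mol = (c_perc/100) · ρ_z / M_z, and inverses.

All conversions are written in dimension-checked form — ml, mg, mol l⁻¹
in, ml, mg, mol l⁻¹ out — so the percent and molar paths agree to
floating-point accuracy for every concentration; this consistency is a
non-negotiable invariant of the implementation and is enforced at relative
tolerance 1e-9 in the tests. The percent concentration is interpreted as
the volume fraction of saccharose, exactly as the mass equation above
forces; no weight/volume correction is attempted. Real nectar is a
glucose–fructose–saccharose mixture, so derived masses are approximations.

**Pollen.** Pollen reported as grain volume is converted to mass with a
mixture density: the protein fraction P_prot at protein density
(1300 mg ml⁻¹), the remainder split equally between starch (1440), fat
(900) and water (1000 mg ml⁻¹):
ρ_p = 1300·P + (1−P)/3·3340, a linear function rising from 1113.33 to
1300 mg ml⁻¹. All constants live in one overridable block,
`flores_constants()`.

## Source-level conventions

Three conventions resolve ambiguous zeros and gaps at the record level,
before any arithmetic:

* corolla depth 0 is a true zero — the species has an open flower;
* species whose records contain pollen but no nectar trait (nectar volume,
  nectar sugar content, or sugar concentration) get their corolla records
  removed: pollen-only sources say nothing about the flower tube;
* a nectar volume of 0 is dropped when another source reports positive
  nectar volume or sugar for the same species.

Removals are logged with a rule identifier; the record count after the
pass equals the input count minus the logged removals, and the pass is
idempotent. Unknown unit strings are quarantined into a rejection report
at read time rather than raising, so one bad literature row cannot abort a
batch run. Missing values are empty cells on disk and `NA` internally.

## Aggregation rules and imputation

Each record contributes one entry value with precedence **mean, else the
min/max midpoint, else the single reported bound** (sources report any
subset of the three; the midpoint is the natural point estimate when only
a range is given). Per species and trait, entries are combined by the
arithmetic mean — except floral-unit density, where the **maximum** is
used and read as the density at 100% cover of the species; this is what
lets cover percentages scale the supply later. Phenology start and end are
averaged like any other trait.

Missing traits are then derived in three passes: once per species profile
after aggregation, once per taxon after synonym/group aggregation, and
once more after the default concentration. Derivation only ever fills
missing slots — observed values are never overwritten, and concentration
is never inferred from volume and mass jointly (it is not among the
derivation rules; an inconsistent observed triple is preserved as
observed). A profile holding sugar mass but no concentration deliberately
waits: the 40% wildflower default for sugar concentration is applied only
at the final taxon stage, to every taxon still lacking a concentration,
and flagged `sugar_conc_default_40`. Applying it earlier would leak the
default into species-level means and silently dominate observed
concentrations of grouped taxa.

The raw records hold one trait per row, so cross-trait derivation is only
well-defined once entries are collapsed to one value per trait; the first
derivation pass therefore runs on the per-species profile rather than per
record.

Pollen protein missing for a taxon is imputed as the mean protein of
same-genus taxa with observations (protein is fairly conserved within a
genus), else the global mean of all observed values, each flagged. The
genus is the first whitespace token of the taxon name after stripping the
designators sp./spec./spp./agg. Imputation operates on taxon-level means:
only taxa with no observation anywhere are filled, so an observed value is
never diluted by an imputed one. A database with no protein observation at
all cannot support imputation; `impute_protein()` raises, and the pipeline
wrapper instead leaves protein missing everywhere (the affected taxa stay
incomplete), which degrades gracefully on tiny inputs.

Profiles with fewer than `min_resource_traits` (default 1) non-missing
traits among nectar volume, nectar sugar, sugar concentration and pollen
are deleted before taxon aggregation: phenology-only rows cannot
contribute resources, and the threshold is configurable because the
appropriate strictness depends on the downstream use.

The final partition produces three nested tables: all taxa (`raw`), taxa
with all nine trait slots (`complete_trait`), and taxa complete except
corolla depth (`no_corolla`) — the latter exists because corolla depth
only matters when filtering by pollinator proboscis length, and many
applications do not.

## Habitat assessment

Daily supply of sugar \[mg m⁻² d⁻¹\], nectar volume \[ml m⁻² d⁻¹\] and
pollen \[mg m⁻² d⁻¹\] is
`Σ_taxa cover/100 · flowers_m2 · R_fu · 1[start ≤ day ≤ end]`.
Cover scaling is multiplicative because `flowers_m2` is defined as the
density at 100% cover: half the cover means half the floral units, hence
half the resource — supply is linear in cover and additive over disjoint
compositions. Flowering windows are closed integer day-of-year intervals
with flat provisioning; the data carry no within-window phenology shape,
so the flat indicator is the only form they support. No wrap-around at the
year boundary and no leap days. Taxa missing a requested resource trait
are a hard error by default; `allow_incomplete = TRUE` makes them
contribute zero to that resource only. Provisioning gaps are maximal runs
of consecutive days strictly below a threshold.

## The synthetic fixture generator

`generate_fixture_bundle()` emulates a raw literature compilation: latent
per-species trait values are drawn log-uniformly over 1–1000 FU m⁻²,
10⁻⁴–10⁻¹ ml FU⁻¹ d⁻¹ nectar and 0.01–10 mg FU⁻¹ pollen (spanning the
three-plus orders of magnitude real floral traits cover), protein uniform
on 10–60%, sugar concentration 20–60%, corolla 0–15 mm with a 10% chance
of a true open flower, and flowering windows of 20–120 days starting
between day 60 and 240. Observations are then corrupted: randomized unit
dialects and reference units, min/max-only entries, duplicate sources,
full duplicate record sets under synonym names, per-trait missingness,
contradictory zero-nectar records and occasional unregistered units. All
draws flow from one seed; the same seed reproduces a bundle bit for bit.

Two design choices make the bundle analytically tractable: duplicate
entries are placed symmetrically about the latent truth (below it for
flower density, whose rule is the maximum), and synonym sets are full
duplicates — so with zero missingness the pipeline must recover the latent
truth exactly, a property the tests assert. Ground truth for corrupted
bundles comes from `oracle_standardize()`, a deliberately plain base-R
re-evaluation of every rule, record by record, sharing no code with the
pipeline; the suite demands pipeline–oracle agreement at relative
tolerance 1e-9 across 100 seeded bundles of 1–50 species.

What the generator does **not** emulate: the covariance structure of real
floral traits (latent values are independent), biased or heteroscedastic
measurement error, nomenclatural chaos beyond clean synonym pairs, and
per-area-only sources (`l/(m² d)`, `g/m²` records are registered dialects
but cannot be expressed per floral unit and are quarantined). Passing
tests therefore demonstrate that the *rules* are implemented correctly,
not that the rules recover truth from realistically biased literature
data.

## Numerical choices and degenerate inputs

* All tolerance-bearing comparisons use relative error with a floor at the
  smallest normalised double, so exact zeros compare cleanly.
* Zero sugar mass yields zero volume without requiring a concentration;
  positive mass at zero concentration is a domain error (infinite volume).
* Empty databases, empty compositions and all-filtered profile tables
  propagate as empty tables rather than errors.
* Aggregation is order-independent (means and maxima); ties need no
  breaking.
* Problem sizes throughout the suite — bundles of 1–50 species, 100 seeds,
  365-day profiles — keep the full test run under a minute while covering
  the degenerate (single-species, empty-table) and moderately large cases;
  the pipeline is vectorised and scales linearly in record count.

## Known limitations

Diurnal nectar secretion rhythms, humidity effects on concentration,
sugar-mixture chemistry, anther position and within-inflorescence opening
order are not modelled; corolla-based accessibility filtering per
pollinator species is left to downstream users; no phylogeny-aware
imputation or uncertainty propagation is attempted — imputed values carry
flags instead. The few-entries deletion rule is a configurable threshold
by design, as no single strictness suits all uses.
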