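---
title: "Energy availability for methanogenesis in serpentinized fluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy availability for methanogenesis in serpentinized fluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpenergy)
```

## The problem

Serpentinization — the reaction of water with ultramafic rock — produces
reduced, hyperalkaline (pH > 11), H2-rich fluids. These fluids can fuel
hydrogenotrophic methanogenesis, but above pH 11 almost no dissolved CO2
remains: the inorganic carbon pool sits as carbonate ion, and total DIC is
itself drawn down to tens of micromolal by carbonate precipitation. Formate
and acetate, produced abiotically under serpentinizing conditions, are
plausible alternative carbon substrates. This package quantifies, per fluid
sample, how much energy each of three methanogenic catabolisms can deliver:

| metabolism | reaction |
|---|---|
| hydrogenotrophic | 4 H2 + HCO3- + H+ -> CH4 + 3 H2O |
| formatotrophic | 4 HCOO- + H+ + H2O -> CH4 + 3 HCO3- |
| acetoclastic | CH3COO- + H2O -> CH4 + HCO3- |

Three complementary quantities are computed:

1. **Chemical affinity**, `A = R T ln(K/Q)`, in kJ per mole CH4 produced —
   the energy released per catabolic event.
2. **Energy supply**, `E = A * m_lim / v_lim`, in J per kg fluid — the
   energy obtainable from a closed kilogram of fluid if the reaction runs
   until its limiting reactant pool is exhausted.
3. **Potential flux**, `J = 4 pi D R (C_inf - C_R)`, in attomoles per day —
   the diffusion-limited delivery rate of each substrate to a cell-sized
   sphere, an upper bound on uptake.

## Speciation and the activity model

Field measurements are bulk totals: DIC, total formate, total acetate,
dissolved H2 (all molal). The reaction quotient needs individual species
activities, so each pool is partitioned by mass action at the sample's pH
and temperature:

* DIC into CO2(aq), HCO3-, CO3-2 via the two carbonic acid constants;
* formate and acetate into neutral acid and anion via their pKa;
* `a(H+) = 10^-pH`, OH- from the water constant, `a(H2O) = 1`;
* H2 and CH4 carried as neutral species at their measured molalities.

All equilibrium constants are derived from a shipped table of standard-state
formation properties (SUPCRT-lineage compilations; see
`inst/extdata/thermo_constants.yaml`, where every entry carries its source).
Deriving constants from formation properties rather than storing them per
reaction means every thermodynamic cycle closes exactly: the package tests
the Hess identity `ln K(formatotrophic) = ln K(hydrogenotrophic) + 4 ln
K(formate hydrolysis)` to 1e-6 and the corresponding affinity identity on
random fluids. Temperature dependence is van't Hoff from the 25 degC
anchors — the fluids span roughly 19–36 degC, where higher-order heat
capacity terms are below display precision.

Activity coefficients come from the Davies equation,
`log10(gamma) = -A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I)`, with the
Debye–Hückel A parameter interpolated in temperature. This is a deliberate
simplification relative to a full B-dot/ion-pairing speciation code: the
field tables do not carry the major-ion analyses such a code needs, the
fluids are dilute (default I = 0.01 mol/kg when major ions are absent), and
the quantities the package reproduces exactly — energy supplies and summary
statistics — depend on *pool totals*, not on database-fidelity activities.
The cost is visible where it should be: in Ca-rich pristine fluids a full
speciation soaks part of the carbonate pool into CaCO3(aq)/CaHCO3+ ion
pairs, so our free-ion activities (hence affinities and fluxes) can differ
from an EQ3/6 calculation by up to an order of magnitude in individual
species. Affinity and flux columns are therefore approximation targets
only; the structural properties (sign, ordering, Hess closure, equilibrium
round trips) are asserted instead.

Pools never interconvert during speciation: DIC, formate, acetate, H2 and
CH4 are treated as redox-decoupled reservoirs, matching the suppressed-redox
convention of geochemical speciation practice for low-temperature fluids.

## Limiting reactant and energy supply

For energy supply, the relevant reservoir is everything in equilibrium with
the consumed substrate: as HCO3- is consumed, the carbonate system
re-equilibrates and resupplies it until the whole DIC pool is gone. The
limiting pool of a reaction is therefore the *measured total* (DIC total,
formate total, acetate total, H2) minimizing `m_pool / |v|`; H+ and H2O are
never candidates (pH and solvent are buffered at the kg scale). Negative
affinities clamp the supply to exactly zero — the reaction cannot run — but
the affinity itself is always reported signed. A worked example at a
DIC-limited hyperalkaline seep:

```{r}
fluids <- samail_fluids()
pub <- samail_energy_published()
rxn <- methanogenesis_reactions()$hydrogenotrophic
z <- fluids[fluids$site_id == "140115Z", ]
lim <- limiting_reactant(rxn, z)
str(lim)
energy_supply(pub$affinity_hydrogenotrophic[pub$site_id == "140115Z"],
              lim$m_lim, lim$v_lim)
```

Only 34 micromolal of DIC stands against 230 micromolal H2 (which, divided
by its coefficient of 4, could support 57.5 micromoles of CH4): carbon, not
electron donor, limits hydrogenotrophic methanogenesis in pristine
serpentinized fluid.

## Potential flux to a cell

`flux_table()` evaluates `J = 4 pi D R (C_inf - C_R)` for six substrate
forms — CO2, formic acid, acetic acid and their anions — using tabulated
diffusion coefficients at 25 degC (used without temperature correction,
matching the convention of the tabulation they support) and a default cell
radius of 0.5 um. `C_inf` is the species activity treated numerically as
molarity (dilute fluids, no density correction). `C_R`, the concentration
at the cell surface, is bounded below by the *metabolic equilibrium*
concentration: a cell can at best draw its substrate down to the activity
at which its catabolism reaches `A = 0`. That bound is computed by
`equilibrium_substrate_activity()`, solving `a_eq = (K/Q_rest)^(1/v_s)`
holding all other activities fixed; the neutral conjugates (CO2, formic
acid, acetic acid) follow through the acid-dissociation equilibrium at the
fluid pH. Because the equilibrium bound needs a CH4 activity — not measured
in the shipped compilation — `flux_table(boundary = "zero")` provides the
pure upper bound `C_R = 0` for data without methane; with a strongly
favorable reaction the two differ by well under a percent.

Negative concentration differences (bulk below the boundary value) clamp to
zero flux with a warning: the construct is an upper bound on uptake, and
efflux is out of scope. No resupply kinetics are modeled — each form
diffuses independently, so in principle near-cell protonation of formate
and acetate could raise the neutral-acid fluxes above the values computed
here.

## Mixing, summaries and the ATP check

Si is a conservative tracer of the extent of serpentinization:
`pct_serpentinized()` places a sample linearly between an unreacted end
member (default Si = 8.5e-4 molal, the highest measured unreacted-fluid
value in the compilation) and a pristine end member (default 1.4e-6 molal,
the most serpentinized site). Both defaults are configurable because the
end member used in the original field studies comes from a geochemical
model rather than a printed value — reconstructed percentages agree with
the published ones to a few tenths of a percent, sub-percent everywhere.

`summarize_affinity()` reports mean, sample (n-1) standard deviation, min
and max per metabolism, over all sites or by fluid type (both sd
conventions round to the same integer here; sample sd is the reporting
norm). `rank_metabolisms()` orders the three metabolisms per site by
affinity or supply — the two rankings disagree instructively: formatotrophy
usually wins per mole of CH4 in pristine fluids (three moles of scarce
HCO3- appear as *products*), while hydrogenotrophy usually wins per kg of
fluid (the DIC pool, however small, typically exceeds the formate pool).
`atp_feasibility()` converts an affinity into a whole-ATP yield at a
configurable 45 kJ/mol phosphorylation cost, with the required ATP count
explicit (acetate activation by acetyl-CoA synthetase costs two), reporting
`floor(max(A, 0)/cost)` and leaving any interpretive rounding to the
caller:

```{r}
s <- summarize_affinity(pub, reaction_id = "acetoclastic")
s
atp_feasibility(s$mean_affinity, atp_cost = 45, n_required = 2)
```

## The synthetic generator

`generate_fluids()` emulates the field chemistry so every stage is testable
without field data. Its defaults are the study conditions: pristine
(type 2) fluids draw pH from a truncated normal (mean 11.4, sd 0.12, bounds
11.2–11.65), temperature uniform on 19–36 degC, and concentrations from
lognormals (medians/geometric sds: Si 3e-6/1.8, DIC 4e-5/2, H2 5e-5/10,
formate 1.5e-6/2, acetate 2e-6/1.6); unreacted (type 1) fluids are
circumneutral and carbon-rich (pH 7.9 +/- 0.3, Si 5e-4, DIC 3e-3, H2 3e-8).
CH4 distributions (type 2 median 1e-5 gsd 5; type 1 median 1e-8 gsd 3) are
the package's own choice of order-of-magnitude realistic values, needed
because affinities require a methane activity. Mixed fluids are
conservative blends of two end-member vectors at a uniform mixing fraction
with multiplicative lognormal noise (gsd 1.2), which reproduces the
positive Si–DIC covariance of real conservative mixing; their pH is
interpolated linearly between the end-member values — a declared
approximation, since true mixed-fluid pH would require titration modeling
of the carbonate/hydroxide systems.

What passing tests on synthetic fluids do *not* show: real fluids carry
ion-pairing major-ion matrices, degassing histories and microbial
consumption that the generator does not emulate, and its single type 1
parameterization leans on one well-characterized unreacted site. The
generator validates the arithmetic and the pipeline's invariants, not the
geochemistry of any particular field site.

## Numerical choices and degenerate inputs

* Missing measurements are `NA` from file to output: a blank cell suppresses
  exactly the result cells that need it, and nothing is imputed.
* Zero totals speciate to zero species; a zero or missing activity in a
  reaction makes its quotient unevaluable (`NA`), never infinite.
* Display rounding is round-half-even at 2 significant figures
  (`format_sci()`); full precision is kept internally.
* The Davies model refuses I > 0.5 mol/kg (its validity limit) and charges
  beyond +/-2; temperatures are bounded to the tabulated A-parameter range.
* Limiting-reactant ties break toward the carbon substrate (the package
  reports carbon limitation when the ratios are exactly equal).
* Equilibrium activities are computed in log space, exact in one step; the
  test suite cross-checks them against a bracketing root finder at 1e-10
  relative tolerance and verifies the `A(a_eq) = 0` round trip to 1e-8 kJ.

Problem sizes in the shipped tests: property loops use 10–25 random fluids,
the brute-force limiting-reactant oracle 1,000 random pool pairs, and the
generator checks n = 1000 per-type draws — the full suite runs in well
under a minute on one CPU.

## Known limitations

* No Pitzer/B-dot activity model, no mineral saturation, no gas–solution
  equilibria, and no Ca/Mg carbonate ion pairs: free-ion activities in
  Ca-rich hyperalkaline fluids are upper-bound estimates, and affinity/flux
  values should be read at order-of-magnitude precision there.
* No Monod or uptake kinetics: fluxes are physical upper bounds, and energy
  supplies assume reactions run to substrate exhaustion.
* The shipped field compilation carries no CH4 measurements, so affinities
  on those samples require externally supplied CH4 data (the published
  reference table ships for exactly that reason).
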