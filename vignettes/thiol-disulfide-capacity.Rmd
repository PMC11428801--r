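---
title: "Species-specific modelling of thiol-disulfide antioxidant systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-specific modelling of thiol-disulfide antioxidant systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxspec)
```

## The problem

Thiols protect cells against oxidative stress in two coupled steps:
deprotonation of the thiol (-SH) to the thiolate, and two-electron oxidation
of two thiolates to a disulfide. Both steps are governed by the electron
density on the sulfur atom, so a thiolate's basicity (its microscopic
log *k* protonation constant) and its oxidizability are tightly correlated.
Apparent pKa and redox potentials of a polyprotic thiol are pH-dependent
mixtures over its protonation *microstates* — the specific patterns of which
basic sites carry protons — and only the species-specific (microscopic)
constants characterize the chemistry at the submolecular level. This
package implements that species-specific framework end to end:
microspeciation, basicity-to-potential prediction, apparent redox potential
pH profiles, and an antioxidant-capacity score with a design surface.

## Microspeciation

A ligand with `n` basic sites has `2^n` microstates connected by
`n * 2^(n-1)` microscopic constants `k(site | context)` — one per site per
protonation context of the other sites. Thermodynamic consistency requires
*cycle closure*: the summed log constants along any protonation path between
two microstates must be path-invariant. `microstate_system()` validates
completeness and closure (tolerance `1e-9` on the log scale) on
construction and *rejects* violating inputs rather than averaging them:
silent averaging would hide data errors.

Internally every microstate is assigned a cumulative log10 path product
("free energy") relative to the fully deprotonated species. All speciation
arithmetic happens on the log10 scale with max-shifted log-sum-exp
evaluation of the binding polynomial, because cumulative constants of even
a triprotic amino acid reach ~`1e21` and the pH grid may extend to ±30
in limit checks. Mole fractions from `mole_fractions()` therefore sum to 1
to ~`1e-15` at any finite pH, and the `log10_chi` component stays finite
even where `chi` underflows — the redox machinery consumes that.

Microstates are ordered canonically: by proton count, then by site-order
bitmask. For 3- and 4-site ligands the customary one-letter tags
(`a`..`h`, `a'`..`p'`) are attached as metadata in that order; with sites
ordered amino (N), thiolate (S), carboxylate (O) this reproduces the
conventional lettering (`b` = N-protonated, `f` = N,O-protonated, and for
the dimer `f'` = both amines, `k'` = both carboxylates). The lettering is
figure-style documentation, not part of the algorithm. `n` is capped at 12
sites (4096 microstates), far above any real thiol, which keeps brute-force
path-enumeration tests feasible.

`generate_consistent_microconstants()` builds systems from an additive
model — intrinsic per-site basicities plus symmetric pairwise interaction
terms — and is therefore cycle-closed by construction. It is the canonical
source of synthetic fixtures; `random_microstate_system()` draws the
parameters from uniform ranges (defaults: site log *k* in [2, 11],
interactions in [-1, 0], the realistic sign: protonating a neighbour lowers
a site's basicity) under a caller-supplied seed.

## From basicity to standard redox potential

`basicity_redox_model()` stores the calibrated linear map

E° = slope · log *k* + intercept,

with default coefficients slope = -0.0605 V/log-unit (se 0.0011) and
intercept = 0.1683 V (se 0.0083), from a published 31-point calibration
over species-specific thiolate data. We do not refit it — the underlying
calibration set is not distributed — so the printed coefficients are
treated as versioned constants (`model_version = "printed-v1"`),
overridable through the constructor. The published fit's adjusted R² and
F-statistic are likewise not reproducible here and are not claimed.

Uncertainty is propagated by the delta method:
se(Ê°)² = logk²·se_slope² + se_intercept² + 2·logk·cov. The
slope-intercept covariance of the calibration was never published; the
default `cov = 0` yields *conservative* (wider) intervals. A published
prediction interval at one abscissa pins the covariance down:
`calibrate_covariance()` back-solves it from the delta-method variance
equation. Applied to the remaining rows of the embedded protein table the
agreement is close (within a few mV) but deliberately not claimed as exact
reproduction — whether the published intervals were confidence or
prediction intervals is itself unknown. Tabulated output from
`annotate_table()` is rounded half-away-from-zero to 3 decimals, the
convention that matches tabulated potentials; comparisons in the test suite
use ±0.001 V, the rounding granularity of such tables. Under the printed
4-decimal coefficients a handful of table rows land one unit off in the
third decimal, implying the original table used unrounded coefficients;
the package reports what the printed coefficients give.

Selenolates follow a parallel line offset by roughly a quarter volt. This
is modelled as a single additive intercept offset, default -0.250 V
(selenolates are the stronger reductants, hence more negative), applied
when the model's chalcogen is `"Se"` and flagged as approximate: the
literature gives the offset only to "approximately 250 mV" precision.
Because of this offset, thiolate- and selenolate-derived capacity scores
are not on a common scale; capacity profiles carry a chalcogen attribute
and should never be ranked across chalcogens.

`e0_from_exchange()` implements the complementary experimental route: a
species-specific standard potential from the apparent exchange equilibrium
constant against a reference couple (canonically glutathione GSSG/GSH),
with the microspecies mole fractions converting apparent to
species-specific concentrations and z = 2 electrons. Constants are
R = 8.314 J mol⁻¹ K⁻¹, F = 96485 C mol⁻¹, T = 298.15 K by default
(temperature is configurable; the published work does not state one).

## Apparent redox potential pH profiles

For a thiol/disulfide couple, each thiolate-bearing monomer microstate
pairs with the dimer microstate formed by joining two such monomers, and
each pair `i` has its own Nernst potential

E_i = E°_i − RT/(2F) · ln( (c_red · χ_red,i)² / (c_ox · χ_ox,i) ).

`apparent_potential()` combines the pairs at each pH by weighting each with
the product of its reduced and oxidized mole fractions,
w_i = χ_red,i · χ_ox,i, the relative abundance of that redox pair, and
reports the weighted mean and weighted standard deviation. Three numerical
and modelling choices matter:

* **This weighted mean is a heuristic average**, not a simultaneous
  common-potential equilibrium solve; a true coupled-equilibrium solver is
  out of scope, and the divergence is documented rather than hidden. The
  monomer and dimer mole fractions enter as independent products, which is
  what the weighted form implies.
* **Everything runs in log space.** Mole fractions at pH far from a site's
  pK underflow double precision; potentials use `log10_chi` directly and
  weights are normalized by max-shifted log-sum-exp, so profiles have no
  gaps or division failures even where every raw abundance product
  underflows.
* **Totals default to 1 mol/L for both forms**, the conventional
  standardization for such profiles; different totals give different curves
  (the `s`-fold reduced / `s²`-fold oxidized scaling is the invariant one).

`build_pairs_from_basicity()` closes the loop with the regression: each
pair's E° is predicted from the thiolate microconstant in that pair's
protonation context, and the delta-method standard error of the prediction
propagates into an approximate confidence band on the profile (treating the
χ weights as exact — the band construction used for published curves of
this kind is unstated, so ours is labelled approximate). No smoothing is
applied to profiles; small non-monotonic stretches are genuine consequences
of microspecies with different E° exchanging dominance.

## The capacity score Y and the design surface

The antioxidant-capacity score is the abundance-weighted **sum** of
thiolate-specific basicities over the thiolate-bearing microstates
(`2^(n-1)` of them for an n-site ligand):

Y(pH) = Σ_i χ_i(pH) · log k^S(context_i).

A weighted sum, not a mean: at low pH the reactive thiolate-bearing species
vanish and Y correctly falls to zero, while a weighted mean would not. Y is
concentration-independent (it is defined for the reduced form alone) but
chalcogen-specific. When per-context uncertainties of the thiolate
microconstants are supplied, `capacity_profile()` propagates them as
se_Y² = Σ (χ_i · se_i)² — delta method with the χ weights treated as exact
and errors independent. A full-gradient treatment through the weights is
not well-posed on the raw microconstant parametrization (perturbing a
single microconstant in isolation breaks cycle closure), and with
0.1-log-unit input errors the simple form already reproduces the expected
order of magnitude (se_Y ≲ 0.1, since Σχ_i ≤ 1).

For design, the monoprotic idealization — a thiolate interacting with no
other site — collapses Y to the closed form
`Y = logk / (1 + 10^(logk - pH))`. `design_surface()` evaluates it on a
(logk, pH) grid (defaults 0–14 at 0.01 × 0.1 steps), reports the per-pH
argmax at grid resolution (no interpolation), and refines it against the
closed-form stationarity condition 1 + u − logk·ln(10)·u = 0 with
u = 10^(logk−pH), solved by bisection. The ridge trades reducing strength
(higher basicity) against availability (the thiolate must be deprotonated
to act):

```{r design}
ds <- design_surface(pH = c(5, 6, 7, 8, 9))
ds$argmax
```

At pH 7 the optimum sits at log *k* ≈ 5.9 — "around 6" — which is why
typical high-basicity thiols (log k^S ≥ 8) only develop their full capacity
at alkaline pH.

## What the synthetic fixtures do and do not show

The experimentally determined microconstants of cysteine/cystine and
friends live in the primary literature and are not redistributed here; the
shipped 3-site aminothiol and 4-site disulfide systems
(`example_aminothiol_system()`, `example_disulfide_system()`) are
**synthetic**: plausible intrinsic basicities (N 10.5, S 8.5, O 2.2) with
small negative pairwise couplings, cycle-closed by construction. They
exercise every code path — 8 and 16 microstates, the four matched redox
pairs, regression-derived pair potentials — so passing tests demonstrate
the correctness of the machinery (speciation sums, path independence,
longhand-oracle equality, Nernst stoichiometry) on thermodynamically
consistent inputs. They do not demonstrate agreement with measured curves
of any real compound; real-data features the generator does not emulate
include measurement error in microconstants, ionic-strength and
temperature effects (activity coefficients are ignored throughout; pH is
−log10[H⁺]), and strongly non-additive three-site interactions. The
embedded 19-row protein thiolate table is real published data and anchors
the regression module against printed values.

## Problem sizes and numerical conventions

Property tests run 100 seeded random systems with up to 4 sites at 50
random pH points each, with brute-force permutation oracles for path
independence — small enough to be exhaustive, large enough to hit every
microstate topology the chemistry uses. Profile and capacity oracles use
100 random pH points on the synthetic fixtures. Cycle-closure tolerance is
1e-9 (log scale), speciation identities are asserted at 1e-10 to 1e-12,
and TSV output uses `.` decimals, UTF-8 and ASCII hyphens. All randomness
flows through explicit seeds.
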