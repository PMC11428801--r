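# redoxspec

Species-specific acid–base and redox modelling of thiol (and selenol)
antioxidant systems, for chemists and drug designers who need to reason
about thiolate reactivity at the submolecular level.

Thiols defend cells against reactive oxygen species in two coupled steps:
deprotonation to the thiolate, then two-electron oxidation of two thiolates
to a disulfide. Both steps depend on the electron density at the sulfur, so
a thiolate's microscopic basicity log *k* and its standard redox potential
E° are tightly correlated. `redoxspec` implements the species-specific
framework built on that correlation:

* **Microspeciation** — all 2^n protonation microstates of a polyprotic
  ligand, validated microscopic constants *k*(site | context) with
  thermodynamic cycle-closure checking, macroscopic β and K_p constants,
  and pH-dependent mole fractions χ computed overflow-safely in log space.
* **Basicity → potential** — the calibrated linear model
  E° = −0.0605·log *k* + 0.1683 V (coefficient standard errors 0.0011 and
  0.0083) with delta-method confidence intervals, a ~−0.25 V parallel
  offset for selenolates, and the exchange-equilibrium route
  E° = E°_ref + RT/2F · ln(K_C · χ_red²·χ_ox,ref / (χ_ox·χ_red,ref²))
  against a reference couple such as glutathione.
* **Apparent potential pH profiles** — per-microspecies Nernst potentials
  E_i = E°_i − RT/2F · ln((c_red χ_red)²/(c_ox χ_ox)), averaged with
  abundance weights w_i = χ_red,i·χ_ox,i.
* **Antioxidant capacity** — the score
  Y(pH) = Σ_i χ_i(pH)·log k^S(context_i) over thiolate-bearing
  microstates, and the monoprotic (log k, pH) design surface whose ridge
  locates the basicity that maximizes capacity at each pH.

## Worked example

Predict standard potentials for experimentally characterized protein
thiolates (19 embedded records from the PKAD pKa database):

```r
library(redoxspec)
m <- basicity_redox_model()
tab <- annotate_table(m, protein_thiol_table())
head(tab, 4)
#>               protein_name pdb_id res_id logk e0_volts ci_low ci_high
#>        Alpha-1-antitrypsin   1QLP    232 6.86   -0.247 -0.269  -0.225
#>  Hydroperoxide reductase c   4MA9     46 5.94   -0.191 -0.212  -0.170
#>                 Human DJ-1   1P5F    106 5.40   -0.158 -0.178  -0.138
#>            Creatine kinase   1I0E    283 5.60   -0.170 -0.191  -0.150
```

`e0_volts` is the species-specific standard potential of the
thiolate→disulfide couple in V (more negative = stronger reductant); the
intervals use the conservative zero-covariance delta method (see
`?calibrate_covariance`).

Build a synthetic three-site aminothiol (amino N, thiolate S,
carboxylate O), pair it with its disulfide dimer, and compute the apparent
potential profile and capacity score:

```r
mono  <- example_aminothiol_system()
dimer <- example_disulfide_system()
enumerate_microstates(mono)       # 8 microstates a..h; b = "N", f = "NO"

couple <- build_pairs_from_basicity(mono, dimer, m, aminothiol_pairing())
prof <- apparent_potential(couple, pH = c(3, 5, 7, 9, 11))
prof[, c("pH", "E_app", "band_low", "band_high")]
#>  pH   E_app band_low band_high
#>   3 -0.0198  -0.0433    0.0038
#>   5 -0.1381  -0.1616   -0.1145
#>   7 -0.2537  -0.2773   -0.2302
#>   9 -0.3262  -0.3491   -0.3034
#>  11 -0.3392  -0.3637   -0.3147

capacity_profile(mono, pH = c(3, 5, 7, 9, 11))[, c("pH", "Y")]
#>  pH      Y
#>   3 0.0001
#>   5 0.0099
#>   7 0.8826
#>   9 7.2867
#>  11 8.3342
```

The apparent potential drops (stronger reducing power) as pH rises and the
thiolate-bearing microspecies take over; Y rises from ~0 (no thiolate
available) toward the basicity of the dominant thiolate context. Finally,
the design question — which thiolate basicity maximizes capacity at a
given pH:

```r
design_surface(pH = 7)$argmax
#>  pH logk_opt logk_opt_refined Y_opt
#>   7      5.9              5.9 5.466
```

At physiological pH the optimum is around log *k* 6: more basic thiolates
are stronger reductants but barely deprotonated, less basic ones are
available but weak.

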