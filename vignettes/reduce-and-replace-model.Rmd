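---
title: "The reduce-and-replace release model: structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The reduce-and-replace release model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrsim)
```

## The strategy being modelled

Genetic pest management programmes for *Aedes aegypti* have pursued two
routes: *reduction* (releasing strains whose female offspring die, shrinking
the population) and *replacement* (spreading an anti-pathogen transgene so
the surviving mosquitoes cannot transmit virus). A reduce-and-replace (R&R)
programme releases a strain homozygous for both transgenes (`KKAA`): the
female-killing (FK) component suppresses the population while the
anti-pathogen (AP) component converts what remains into refractory insects.
The quantity of interest is therefore not total female density but the
density of *competent vectors* — females carrying no AP allele.

`rrsim` implements this as a deterministic, genotype-structured ODE system:
nine two-locus genotypes × three stages (juvenile `J`, adult male `M`,
adult female `F`), 27 state variables.

## Model structure and assumptions

* **Inheritance.** The loci are autosomal, unlinked, and segregate
  Mendelianly. The inheritance tensor `Pr(i|m,n)` is assembled once from
  per-locus gamete counts in integer arithmetic (every entry is a multiple
  of 1/16) and only then converted to floating point; the most heavily
  reused object in the model carries no rounding error, and parental-role
  symmetry and normalisation hold exactly.
* **Mating.** Random mating with female-limited reproduction: each female
  produces larvae at rate `λ`, fathered according to the *frequencies*
  `M_n / ΣM` of the male pool. Male abundance does not limit female mating
  except in the degenerate all-male-extinct case, where the birth rate is
  defined as zero. This is the standard reading of random mating in
  continuous-population release models; it also keeps the zero-male limit
  well behaved.
* **Fitness.** Costs act on egg-to-larva survival: `w_i` multiplies the
  birth rate of offspring genotype *i*. Costs are additive within a locus
  (heterozygotes pay half) and multiplicative across loci. Costs outside
  [0, 1] are rejected, not clamped — silent clamping hides configuration
  errors.
* **Density dependence.** Per-capita juvenile mortality is
  `μ_J + α J^(β−1)` with `J` the *total* juvenile density: larval
  competition is genotype-blind. `β` controls how fast the population
  rebounds after perturbation.
* **FK lethality** acts at adult emergence: female emergence is multiplied
  by `γ_i ∈ {0, 1}` (`0` for every K-carrying genotype). Released females
  are tetracycline-reared adults and enter `F` directly, so "released"
  versus "native" females are distinguishable purely by genotype — no
  extra bookkeeping — because `γ = 0` genotypes can never arise in `F`
  through emergence.
* **Releases** are continuous at rate `r·M̂/7` per day (split evenly across
  sexes in bi-sex mode) over `[start, start + T)`: the same number of
  individuals every week regardless of what the resident population does.
  `M̂` is the *analytic* male equilibrium, never a simulated steady state,
  so forcing magnitudes are exactly reproducible and independent of solver
  settings.
* **Immigration**, when enabled, adds wild-type juveniles at `ι·J*` per day
  into the `kkaa` juvenile compartment, where they face the same density
  dependence as residents.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `mu_J` | density-independent juvenile mortality | 0.03 | day⁻¹ |
| `mu_M` | adult male mortality | 0.28 | day⁻¹ |
| `mu_F` | adult female mortality | 0.10 | day⁻¹ |
| `lambda` | larval production per female | 8 | day⁻¹ |
| `nu` | emergence rate | 0.14 | day⁻¹ |
| `alpha` | density-dependence scale | 2×10⁻⁴ | — |
| `beta` | density-dependence exponent | 3.4 | — |
| `c_K`, `c_A` | egg-viability costs | 0 | — |

These are standard field- and laboratory-derived rates for *Ae. aegypti*;
`β = 3.4` represents strong larval regulation, under which suppression
alone cannot eliminate the population — exactly the situation in which an
R&R programme is more attractive than FK alone. Density units are abstract:
every reported density is relative to the pre-release equilibrium total
female density `F*`, and release sizes are relative to `M̂`, so no absolute
scale is needed.

With the defaults the closed form gives

```{r}
wildtype_equilibrium(rr_params())
```

## Outcome metrics and their conventions

* **Competence.** Refractoriness is treated as **dominant**: one AP allele
  makes a female incompetent. The biology of the accounting demands it —
  heterozygous `kkAa` females persist long after releases while competent
  vectors all but vanish, which is only coherent if heterozygotes are
  refractory. This is the single largest interpretive choice in the
  package; `competent_density(..., refractoriness = "recessive")` is
  provided as a sensitivity switch, and every metric that consumes it
  accepts the same switch.
* **Recovery.** "The population has returned to its pre-release density" is
  asymptotic in an ODE model, so recovery is declared at 99% of baseline
  (`tol = 0.01`), measured on *native* females. `competent_at_recovery()`
  reports the horizon-end value, flagged `recovered = FALSE`, when the
  population never gets there (near-extinction scenarios).
* **Allele extinction.** Deterministic densities never hit zero; an allele
  is declared lost on the first post-release day its juvenile frequency
  drops below 10⁻⁶ *and stays below it* for the rest of the trajectory
  (transient dips do not count).
* **Juvenile frequencies.** Allele frequencies are reported in the juvenile
  pool, not the adult pool, because during releases the adult pool is
  dominated by the released individuals themselves; the juvenile pool shows
  what the population is actually inheriting.
* **Linkage disequilibrium.** The model tracks genotypes, not gamete
  phase, so gametic `D` is not identifiable from the state;
  `composite_ld()` implements Burrows' composite Δ, which needs only
  genotype counts and reduces to `D` under random union of gametes.

## Numerical choices

* **Integrator:** `deSolve::ode` with `lsoda` (automatic stiff/non-stiff
  switching), `rtol = 1e-8`, `atol = 1e-10`. The tight tolerances are not
  cosmetic: trajectories are compared on log scales across six or more
  orders of magnitude, and the FK-versus-R&R total-density equivalence is
  asserted to within 10⁻⁶ relative.
* **Forcing discontinuities:** integration restarts at the release onset
  and release end, so the piecewise-constant forcing never sits inside one
  adaptive step. Breakpoints that fall within 10⁻⁸ of an output time are
  snapped onto it to avoid degenerate, near-duplicate mesh points (this
  moves a release end by at most ~10⁻¹⁴ days).
* **Degenerate inputs:** total juvenile density is clamped at zero before
  the non-integer power `β − 1 = 2.4`; female/male pools are clamped at
  zero inside the mating sum; a state component below −10⁻⁹ at an output
  time triggers a warning. An all-male or all-female population produces no
  births rather than an error. With `α = 0` no equilibrium exists; runs are
  then allowed only with an explicit initial state, no releases and no
  immigration (that configuration is what the emergence-bookkeeping tests
  use, since it has a linear closed form).
* **Ties:** the day of minimum native female density resolves ties to the
  earliest day.

## Scenario designs and open choices

The bundled catalogue (`rr_catalogue()`, backed by a human-readable YAML
file) covers: four release ratios for a year of male-only releases of both
strains; duration variation at `r = 2`; the fixed-budget sweep; sex-mode
comparisons at `r = 1`; AP fitness costs; female-only durations near the
extinction boundary; and wild-type immigration at
`ι ∈ {0, 0.001, 0.01, 0.05}·J*` per day.

Fixed-budget sweeps are parameterised in **ratio-days** (`r·T`), which is
proportional to the head count released under constant-rate forcing and
independent of the arbitrary density units; the canonical budget of 80
ratio-days spans `r = 4` for 20 days to `r = 0.16` for 500 days. The
intermediate grid — 15 log-spaced durations — is this package's choice; the
design is defined by its endpoints and budget, not by any particular
intermediate spacing. The female-only duration study is catalogued as
**female-only** releases (bi-sex and female-only releases at `r = 1`
sustain suppression towards extinction when extended past ~120 days, which
male-only releases at that ratio do not). Density-dependence variants are
supported as user-supplied `(α, β)` overrides; when comparing `β` values it
is usually right to re-solve `α` so the equilibrium stays fixed, as the
package's tests do.

## Problem sizes used by the tests

The reference release scenarios are integrated to day 2 500 (enough for
full demographic recovery and FK-allele loss under the defaults), the
fitness-cost scenarios to day 9 000 (AP-allele loss at `c_A = 0.1` takes
roughly 2 800 days), and the lowest immigration scenario
(`ι = 0.001 J*`/day) to day 45 000, because the competent-vector rebound
under weak immigration is genuinely that slow — immigrants contribute of
order 10⁻⁴ of daily recruitment. These horizons are properties of the
dynamics being measured, and the integrator covers them in seconds.

## What this model does and does not capture

The model is a deliberately general strategic tool. It omits demographic
stochasticity (relevant exactly where R&R matters most, at very low
competent-vector densities), spatial structure, seasonality, an explicit
egg stage (egg production is implicit in `λ`), mating-competitiveness
differences between transgenic and wild males, and any pathogen or human
epidemiology. Passing tests therefore demonstrate the internal consistency
and the comparative statics of the deterministic system — orderings across
release designs, equivalences, conservation laws — not field predictions.
Released females are assumed to reproduce at the same rate `λ` as wild
females (they are viable, tetracycline-reared adults; absent fitness costs
there is no mechanism in the model to distinguish them).
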