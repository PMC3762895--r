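# rrsim

Deterministic simulation of **Reduce-and-Replace (R&R)** releases of
transgenic *Aedes aegypti*: continuous releases of a strain carrying both a
female-killing (FK) transgene and an anti-pathogen (AP) transgene into a
wild-type population regulated by density-dependent larval mortality. The
package is for quantitative vector-control researchers who want to compare
release strategies — R&R versus FK-only, male-only versus bi-sex versus
female-only, short intense versus long dilute releases at a fixed budget —
by their effect on the density of *competent vectors*: adult females able to
transmit the pathogen (here, females carrying no AP allele).

## The model

Two independently segregating autosomal loci (alleles K/k and A/a) give nine
genotypes, indexed `KKAA … kkaa`. Each genotype *i* has juvenile, adult male
and adult female compartments *J_i*, *M_i*, *F_i*:

```
dJ_i/dt = B_i − (μ_J + α J^(β−1) + ν) J_i        J = Σ_k J_k
dM_i/dt = (ν/2) J_i − μ_M M_i + R_M,i(t)
dF_i/dt = γ_i (ν/2) J_i − μ_F F_i + R_F,i(t)
```

with random mating and Mendelian inheritance:

```
B_i = w_i λ Σ_m Σ_n F_m (M_n / Σ_k M_k) Pr(i | m, n)
```

`Pr(i|m,n)` is the Mendelian inheritance tensor (built exactly, in integer
arithmetic over sixteenths), `w_i` the egg-to-larva fitness (costs `c_K`,
`c_A` additive within a locus, multiplicative across loci), and `γ_i` the
female viability coefficient: FK lethality strikes females at adult
emergence (`γ = 0` for every K-carrying genotype). Released
tetracycline-reared females are viable adults and enter *F* directly.
Releases are a constant forcing `R = r M̂ / 7` per day over a window, where
`r` is the weekly release ratio relative to the analytic wild-type male
equilibrium `M̂`. The wild-type equilibrium has the closed form

```
J* = [(λν/(2μ_F) − μ_J − ν)/α]^(1/(β−1)),  M* = νJ*/(2μ_M),  F* = νJ*/(2μ_F)
```

Default rates (day⁻¹): `μ_J = 0.03`, `μ_M = 0.28`, `μ_F = 0.10`, `λ = 8`,
`ν = 0.14`, with `α = 2×10⁻⁴`, `β = 3.4` and cost-free transgenes.

## Worked example

A year-long male-only release of the R&R strain at a 2:1 weekly ratio:

```r
library(rrsim)
sched <- release_schedule("KKAA", "male-only", r = 2, duration = 365)
sim   <- simulate_release(rr_params(), sched, t_final = 2500)
glance(sim)
#>   strain     sexes r duration min_native_female min_native_day competent_at_recovery
#> 1   KKAA male-only 2      365            0.0869            395              3.35e-05
#>   recovery_day recovered extinction_day_K extinction_day_A
#> 1          478      TRUE              493               NA
```

Reading the row: during releases the native female population falls to 8.7%
of its pre-release equilibrium, reaching its minimum on the last release day
(395). The total population recovers to within 1% of baseline by day 478,
but at that point competent vectors stand at only 3.4×10⁻⁵ of baseline — the
AP allele has replaced the wild allele (it persists indefinitely,
`extinction_day_A = NA`), while the self-limiting FK allele disappears by
day 493. `metric_series(sim)` gives the full daily series,
`autoplot(sim)` and `plot_allele_frequencies(sim)` the standard log-scale
panels, and `tidy(sim)` the long per-genotype trajectory.

Scenario batches: `rr_catalogue()` bundles the standard designs;
`run_sweep(budget = 80)` runs the fixed-budget ratio–duration sweep;
`rr_run_config()`, `rr_run_sweep()` and `rr_make_figures()` (or the thin CLI
in `inst/cli/rrsim-cli.R`) write tidy CSV/JSON outputs and figures.

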