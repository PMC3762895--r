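# Bundled release-scenario designs. Each entry expands to a grid of release
# scenarios (one row per combination). Omitted fields take their defaults:
# start = 30, c_K = c_A = 0, immigration = 0, strain = KKAA, sexes = male-only.
# A budget entry replaces explicit ratios: r = budget / duration, so every
# combination releases the same total number of individuals (budget in
# ratio-days). durations: default uses the package's log-spaced 20..500-day
# grid.

fig1:
  description: Year-long male-only releases of the R&R (KKAA) and FK (KKaa)
    strains at four weekly release ratios.
  strain: [KKAA, KKaa]
  sexes: [male-only]
  r: [1, 2, 3, 4]
  duration: [365]

fig2:
  description: Male-only R&R releases at r = 2 for three durations.
  strain: [KKAA]
  sexes: [male-only]
  r: [2]
  duration: [120, 240, 360]

fig3:
  description: Fixed-budget (80 ratio-day) ratio-duration sweep for each sex
    mode; every combination releases the same total number of mosquitoes.
  strain: [KKAA]
  sexes: [male-only, bi-sex, female-only]
  budget: 80
  duration: default

fig4:
  description: Male-only, bi-sex and female-only R&R releases at r = 1 for
    100 days.
  strain: [KKAA]
  sexes: [male-only, bi-sex, female-only]
  r: [1]
  duration: [100]

fig5:
  description: Year-long male-only R&R releases at r = 2 under anti-pathogen
    fitness costs.
  strain: [KKAA]
  sexes: [male-only]
  r: [2]
  duration: [365]
  c_A: [0, 0.1, 0.2]

figS3:
  description: Female-only R&R releases at r = 1 for durations straddling the
    extinction boundary.
  strain: [KKAA]
  sexes: [female-only]
  r: [1]
  duration: [100, 110, 120]

figS4:
  description: Male-only R&R releases at r = 2 for 100 days with wild-type
    juvenile immigration (fractions of the equilibrium juvenile density per
    day).
  strain: [KKAA]
  sexes: [male-only]
  r: [2]
  duration: [100]
  immigration: [0, 0.001, 0.01, 0.05]
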