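# Shared fixtures: an independent Mendelian oracle, a cache so expensive
# simulations are computed once per test run, and a synthetic-trajectory
# builder for metric unit tests.

# Independent brute-force oracle for offspring genotype probabilities:
# enumerate the 16 equiprobable maternal x paternal gamete pairings directly
# from the genotype label strings. Returns integer counts out of 16.
oracle_offspring_counts <- function(mother, father) {
  gametes <- function(label) {
    l1 <- c(substr(label, 1, 1), substr(label, 2, 2))  # K locus alleles
    l2 <- c(substr(label, 3, 3), substr(label, 4, 4))  # A locus alleles
    out <- character(0)
    for (a in l1) for (b in l2) out <- c(out, paste0(a, b))
    out  # 4 gametes, equiprobable
  }
  normalize <- function(g1, g2) {
    # locale-independent: transgenic allele (uppercase) written first
    ord <- function(x) x[order(match(x, c("K", "k", "A", "a")))]
    k <- ord(c(substr(g1, 1, 1), substr(g2, 1, 1)))
    a <- ord(c(substr(g1, 2, 2), substr(g2, 2, 2)))
    paste0(paste(k, collapse = ""), paste(a, collapse = ""))
  }
  counts <- setNames(integer(9), genotypes()$label)
  for (gm in gametes(mother)) {
    for (gf in gametes(father)) {
      off <- normalize(gm, gf)
      counts[off] <- counts[off] + 1L
    }
  }
  counts
}

# Cache for simulations shared between test files (one R process per run).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# Hand-built rr_sim object with a prescribed native (kkaa) female series;
# every other compartment zero except small wild-type juveniles/males so
# frequencies stay defined. Baseline taken from the analytic equilibrium.
synthetic_sim <- function(times, rel_native, schedule = NULL,
                          J9 = 1, M9 = 1) {
  eq <- wildtype_equilibrium(rr_params())
  states <- matrix(0, nrow = length(times), ncol = 27)
  colnames(states) <- paste0(rep(c("J_", "M_", "F_"), each = 9),
                             rep(genotypes()$label, 3))
  states[, 9] <- J9
  states[, 18] <- M9
  states[, 27] <- rel_native * eq$F_star
  structure(
    list(times = times, states = states, params = rr_params(),
         schedule = schedule,
         rates = release_rates(schedule, rr_params()),
         immigration = 0, equilibrium = eq, baseline = eq$F_star,
         solver = list(method = "synthetic", rtol = NA, atol = NA)),
    class = "rr_sim"
  )
}
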