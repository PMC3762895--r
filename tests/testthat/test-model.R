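eq <- wildtype_equilibrium(rr_params())

test_that("birth rates implement the random-mating sum", {
  only <- function(i, v = 1) replace(numeric(9), i, v)
  p <- rr_params()
  # single genotype breeds true
  B <- birth_rates(only(9, eq$F_star), only(9, eq$M_star))
  expect_equal(unname(B), replace(numeric(9), 9, p$lambda * eq$F_star))
  # forced cross: kkaa females x KKAA males -> all offspring KkAa
  B <- birth_rates(only(9, 3), only(1, 10))
  expect_equal(unname(B), replace(numeric(9), 5, p$lambda * 3))
  # male pool half KKAA half kkaa: offspring split evenly by male frequency
  B <- birth_rates(only(9, 3), only(1, 5) + only(9, 5))
  expect_equal(unname(B[5]), p$lambda * 3 / 2)
  expect_equal(unname(B[9]), p$lambda * 3 / 2)
  expect_equal(sum(B), p$lambda * 3)
  # no males -> no mating
  expect_equal(unname(birth_rates(only(9, 3), numeric(9))), numeric(9))
  # fitness multiplies the offspring genotype's birth rate
  w <- fitness_vector(c_K = 0.5, c_A = 0)
  B <- birth_rates(only(9, 1), only(1, 1), w = w)
  expect_equal(unname(B[5]), p$lambda * unname(w["KkAa"]))
})

test_that("derivatives honour forcing, viability and immigration bookkeeping", {
  p <- rr_params()
  sched <- release_schedule("KKAA", "male-only", r = 2, duration = 365,
                            start = 30)
  # empty population, release active: only forcing remains
  d <- rr_derivatives(100, numeric(27), p, sched)
  expect_equal(unname(d["M_KKAA"]), 2 * eq$M_star / 7)
  expect_equal(max(abs(d[setdiff(names(d), "M_KKAA")])), 0)
  # outside the window the forcing is off
  d0 <- rr_derivatives(10, numeric(27), p, sched)
  expect_equal(max(abs(d0)), 0)
  d1 <- rr_derivatives(395, numeric(27), p, sched)
  expect_equal(max(abs(d1)), 0)
  # a pure gamma = 0 juvenile cohort adds males but never females
  state <- numeric(27); state[7] <- 12  # J_KKaa
  d <- rr_derivatives(0, state, p)
  expect_equal(unname(d["M_KKaa"]), p$nu / 2 * 12)
  expect_equal(max(abs(d[19:27])), 0)
  # immigration feeds the wild-type juvenile compartment only
  d <- rr_derivatives(0, numeric(27), p, immigration = 0.01)
  expect_equal(unname(d["J_kkaa"]), 0.01 * eq$J_star)
  expect_equal(max(abs(d[setdiff(names(d), "J_kkaa")])), 0)
  expect_error(rr_derivatives(0, c(NaN, numeric(26)), p), "non-finite")
})

test_that("no-release control stays at equilibrium", {
  sim <- cached_sim("control_1000", simulate_release(rr_params(),
                                                     t_final = 1000))
  ms <- metric_series(sim)
  expect_lt(max(abs(ms$rel_total_female - 1)), 1e-3)
  expect_lt(max(abs(ms$rel_native_female - 1)), 1e-3)
  expect_gt(min(sim$states), -1e-9)
})

test_that("the AP allele alone is a neutral marker for total dynamics", {
  p <- rr_params()  # c_A = 0, no K anywhere
  base <- numeric(27)
  base[9] <- eq$J_star; base[18] <- eq$M_star; base[27] <- eq$F_star
  mix <- numeric(27)
  hw <- c(0.25, 0.5, 0.25)  # kkAA, kkAa, kkaa
  mix[c(3, 6, 9)] <- eq$J_star * hw
  mix[c(12, 15, 18)] <- eq$M_star * hw
  mix[c(21, 24, 27)] <- eq$F_star * hw
  # perturb both identically so there are real dynamics to compare
  sim_wt <- simulate_release(p, t_final = 300, init = 0.5 * base)
  sim_ap <- simulate_release(p, t_final = 300, init = 0.5 * mix)
  tot <- function(s) rowSums(s$states[, 19:27])
  expect_equal(tot(sim_ap), tot(sim_wt), tolerance = 1e-8)
  juv <- function(s) rowSums(s$states[, 1:9])
  expect_equal(juv(sim_ap), juv(sim_wt), tolerance = 1e-8)
})

test_that("larger release ratios suppress total females pointwise harder", {
  p <- rr_params()
  sims <- lapply(c(1, 3), function(r)
    simulate_release(p, release_schedule("KKAA", "male-only", r = r,
                                         duration = 165), t_final = 195))
  m1 <- metric_series(sims[[1]]); m3 <- metric_series(sims[[2]])
  w <- m1$time >= 40 & m1$time <= 190
  expect_true(all(m3$total_female[w] < m1$total_female[w]))
})

test_that("stronger density dependence recovers faster from the same perturbation", {
  p1 <- rr_params()
  # re-solve alpha so the equilibrium stays fixed while beta weakens
  beta2 <- 2.5
  net <- p1$lambda * p1$nu / (2 * p1$mu_F) - p1$mu_J - p1$nu
  p2 <- rr_params(beta = beta2, alpha = net / eq$J_star^(beta2 - 1))
  expect_equal(wildtype_equilibrium(p2)$J_star, eq$J_star, tolerance = 1e-12)
  base <- numeric(27)
  base[9] <- eq$J_star; base[18] <- eq$M_star; base[27] <- eq$F_star
  recovery_day <- function(p) {
    sim <- simulate_release(p, t_final = 600, init = 0.5 * base)
    ms <- metric_series(sim)
    ms$time[which(ms$rel_total_female >= 0.99)[1]]
  }
  expect_lt(recovery_day(p1), recovery_day(p2))
})

test_that("simulate rejects malformed inputs with useful messages", {
  expect_error(simulate_release(t_final = -5), "t_final")
  expect_error(simulate_release(immigration = -1), "immigration")
  expect_error(simulate_release(init = numeric(5)), "27")
  expect_error(simulate_release(t_final = 100, times = c(-5, 50)), "times")
  expect_error(rr_params(beta = 0.9), "beta")
  expect_error(rr_params(mu_F = -1), "mu_F")
})
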