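# Genotype-structured ODE right-hand side and the stiff integrator wrapper.
#
# State layout (27 values): J_1..J_9, M_1..M_9, F_1..F_9 in genotype order.
# dJ_i/dt = B_i - (mu_J + alpha * J_tot^(beta-1) + nu) * J_i  (+ iota*J* for kkaa)
# dM_i/dt = (nu/2) J_i - mu_M M_i + R_M,i(t)
# dF_i/dt = gamma_i (nu/2) J_i - mu_F F_i + R_F,i(t)
# with B_i = w_i * lambda * sum_{m,n} F_m (M_n / sum M) Pr[i|m,n].

# 81 x 9 matrix view of the inheritance tensor: row (m,n) column-major,
# column i. Built once per session.
the <- new.env(parent = emptyenv())

tensor_matrix <- function() {
  if (is.null(the$Tmat)) the$Tmat <- t(matrix(inheritance_tensor(), nrow = 9L))
  the$Tmat
}

#' Per-genotype larval production rates
#'
#' Under random mating, each female mates according to the genotype
#' frequencies of the male pool (female-limited reproduction), so the rate at
#' which viable larvae of genotype `i` are produced is
#' `B_i = w_i * lambda * sum_{m,n} F_m * (M_n / sum(M)) * Pr[i|m,n]`.
#' If no males are present mating is impossible and all rates are zero.
#'
#' @param F,M Female and male densities by genotype (length 9).
#' @param w Fitness vector from [fitness_vector()].
#' @param lambda Per-capita larval production rate (day^-1).
#' @return Named numeric vector of production rates, length 9.
#' @examples
#' eq <- wildtype_equilibrium()
#' F <- M <- numeric(9); F[9] <- eq$F_star; M[9] <- eq$M_star
#' birth_rates(F, M)  # wild type breeds true: B_9 = lambda * F*
#' @export
birth_rates <- function(F, M, w = fitness_vector(), lambda = 8) {
  stopifnot(length(F) == 9L, length(M) == 9L, length(w) == 9L)
  B <- birth_rates_core(pmax(F, 0), pmax(M, 0), tensor_matrix(), w, lambda)
  names(B) <- GENOTYPE_LABELS
  B
}

birth_rates_core <- function(F, M, Tmat, w, lambda) {
  Mtot <- sum(M)
  if (Mtot <= 0) return(numeric(9L))
  cross <- as.vector(outer(F, M / Mtot))
  w * (lambda * as.vector(crossprod(Tmat, cross)))
}

# Shared derivative core; relM/relF are the (constant) forcing vectors in
# effect at the evaluated time.
derivs_core <- function(y, p, Tmat, w, gam, iota, J_star, relM, relF) {
  J <- y[1:9]; M <- y[10:18]; F <- y[19:27]
  B <- birth_rates_core(pmax(F, 0), pmax(M, 0), Tmat, w, p$lambda)
  J_tot <- max(sum(J), 0)
  loss <- p$mu_J + p$alpha * J_tot^(p$beta - 1) + p$nu
  dJ <- B - loss * J
  dJ[9L] <- dJ[9L] + iota * J_star
  dM <- 0.5 * p$nu * J - p$mu_M * M + relM
  dF <- gam * (0.5 * p$nu * J) - p$mu_F * F + relF
  c(dJ, dM, dF)
}

# Forcing vectors (length 9 each for M and F) for a schedule, given resolved
# rates; active = TRUE inside the release window.
forcing_vectors <- function(schedule, rates, active) {
  relM <- numeric(9L); relF <- numeric(9L)
  if (!is.null(schedule) && active) {
    si <- genotype_index(schedule$strain)
    relM[si] <- rates$male_rate
    relF[si] <- rates$female_rate
  }
  list(relM = relM, relF = relF)
}

#' Time derivative of the full model state
#'
#' Evaluates the right-hand side of the genotype-structured system at one
#' time point, including release forcing (if `t` falls inside the schedule's
#' window) and wild-type juvenile immigration. Mainly useful for fixed-point
#' and bookkeeping checks; [simulate_release()] integrates the same core.
#'
#' @param t Time in days.
#' @param state Numeric state vector of length 27 (`J` then `M` then `F`,
#'   genotype order).
#' @param params An [rr_params()] parameter set.
#' @param schedule An [release_schedule()] or `NULL`.
#' @param immigration Wild-type juvenile immigration rate, as a fraction of
#'   the equilibrium juvenile density `J*` per day.
#' @return Named derivative vector of length 27.
#' @export
rr_derivatives <- function(t, state, params = rr_params(), schedule = NULL,
                           immigration = 0) {
  p <- as_rr_params(params)
  stopifnot(length(state) == 27L)
  if (any(!is.finite(state))) {
    stop("non-finite state component at t = ", t, call. = FALSE)
  }
  eq <- wildtype_equilibrium(p)
  rates <- release_rates(schedule, p)
  active <- !is.null(schedule) && t >= schedule$start && t < schedule$end
  f <- forcing_vectors(schedule, rates, active)
  d <- derivs_core(as.numeric(state), p, tensor_matrix(),
                   fitness_vector(p$c_K, p$c_A), viability_vector(),
                   immigration, eq$J_star, f$relM, f$relF)
  names(d) <- state_names()
  d
}

#' Simulate the population under a release schedule
#'
#' Integrates the genotype-structured system with the adaptive stiff solver
#' (`deSolve::ode`, `lsoda`), restarting the integration at the release onset
#' and release end so the discontinuous forcing never falls inside a solver
#' step. The initial condition defaults to the wild-type equilibrium.
#'
#' @param params An [rr_params()] parameter set.
#' @param schedule An [release_schedule()], or `NULL` for a no-release control.
#' @param immigration Wild-type juvenile immigration rate as a fraction of
#'   the equilibrium juvenile density per day (default 0).
#' @param t_final Final day of the simulation.
#' @param times Output grid in days (default daily from 0 to `t_final`).
#' @param init Optional initial state (length 27); overrides the equilibrium
#'   start.
#' @param rtol,atol Solver relative/absolute tolerances. Trajectories span
#'   many orders of magnitude, hence the tight defaults.
#' @return An object of class `rr_sim`: a list with the output `times`, the
#'   state matrix `states` (rows = times, 27 named columns), the attached
#'   `params`, `schedule`, resolved release `rates`, `immigration`,
#'   analytic `equilibrium`, the pre-release `baseline` total female density,
#'   and `solver` settings. Use [tidy()][generics::tidy] for a long tibble or
#'   [metric_series()] for derived outcome series.
#' @examples
#' sim <- simulate_release(rr_params(),
#'                         release_schedule("KKAA", "male-only", r = 2,
#'                                          duration = 365),
#'                         t_final = 600)
#' glance(sim)
#' @export
simulate_release <- function(params = rr_params(), schedule = NULL,
                             immigration = 0, t_final = 1000,
                             times = NULL, init = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  p <- as_rr_params(params)
  if (!is.numeric(immigration) || length(immigration) != 1L ||
      is.na(immigration) || immigration < 0) {
    stop("`immigration` must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(t_final) || length(t_final) != 1L || t_final <= 0) {
    stop("`t_final` must be a single positive number of days", call. = FALSE)
  }
  # the analytic equilibrium anchors release rates, the immigration source
  # and the default start; runs that need none of these (explicit init, no
  # schedule, no immigration) may use parameters with no equilibrium
  eq <- tryCatch(wildtype_equilibrium(p), error = function(e) e)
  if (inherits(eq, "error")) {
    if (is.null(init) || !is.null(schedule) || immigration > 0) stop(eq)
    eq <- NULL
  }
  if (is.null(times)) times <- seq(0, t_final, by = 1)
  times <- sort(unique(as.numeric(times)))
  if (min(times) < 0 || max(times) > t_final) {
    stop("`times` must lie within [0, t_final]", call. = FALSE)
  }
  y0 <- if (is.null(init)) equilibrium_state(eq) else {
    stopifnot(length(init) == 27L)
    stats::setNames(as.numeric(init), state_names())
  }

  rates <- release_rates(schedule, p)
  t0 <- min(times)
  breaks <- c(t0, t_final)
  if (!is.null(schedule)) breaks <- c(breaks, schedule$start, schedule$end)
  # snap breakpoints onto output times they all but coincide with, so the
  # per-segment time vectors never contain near-duplicate entries
  breaks <- vapply(breaks, function(b) {
    j <- which.min(abs(times - b))
    if (abs(times[j] - b) < 1e-8 * max(1, abs(b))) times[j] else b
  }, numeric(1))
  breaks <- sort(unique(breaks[breaks >= t0 & breaks <= t_final]))
  breaks <- breaks[c(TRUE, diff(breaks) > 1e-10)]

  Tmat <- tensor_matrix()
  w <- fitness_vector(p$c_K, p$c_A)
  gam <- viability_vector()

  out_times <- numeric(0)
  out_states <- NULL
  y <- y0
  for (k in seq_len(length(breaks) - 1L)) {
    a <- breaks[k]; b <- breaks[k + 1L]
    mid <- (a + b) / 2  # robust to snapped breakpoints
    active <- !is.null(schedule) && mid >= schedule$start && mid < schedule$end
    f <- forcing_vectors(schedule, rates, active)
    rhs <- function(t, y, parms) {
      if (any(!is.finite(y))) {
        stop("solver produced a non-finite state at t = ", t, call. = FALSE)
      }
      list(derivs_core(y, p, Tmat, w, gam, immigration,
                       if (is.null(eq)) 0 else eq$J_star, f$relM, f$relF))
    }
    seg_req <- times[times >= a & times <= b]
    seg_times <- sort(unique(c(a, seg_req, b)))
    sol <- deSolve::ode(y = y, times = seg_times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (attr(sol, "istate")[1L] < 0) {
      stop("stiff integration failed in segment [", a, ", ", b, "]; ",
           "last time reached ", max(sol[, 1L]), call. = FALSE)
    }
    y <- sol[nrow(sol), -1L]
    keep <- sol[, 1L] %in% seg_req & !(sol[, 1L] %in% out_times)
    out_times <- c(out_times, sol[keep, 1L])
    out_states <- rbind(out_states, sol[keep, -1L, drop = FALSE])
  }
  colnames(out_states) <- state_names()
  rownames(out_states) <- NULL

  worst <- min(out_states)
  if (worst < -1e-9) {
    warning("state components fell below -1e-9 (min = ", signif(worst, 3),
            "); solver tolerances may be too loose", call. = FALSE)
  }

  structure(
    list(times = out_times, states = out_states, params = p,
         schedule = schedule, rates = rates, immigration = immigration,
         equilibrium = eq,
         baseline = if (is.null(eq)) sum(y0[f_cols()]) else eq$F_star,
         solver = list(method = "lsoda", rtol = rtol, atol = atol)),
    class = "rr_sim"
  )
}

#' @export
print.rr_sim <- function(x, ...) {
  cat("<rr_sim> ", length(x$times), " time points over [",
      min(x$times), ", ", max(x$times), "] days\n", sep = "")
  if (is.null(x$schedule)) cat("  no-release control\n") else print(x$schedule)
  if (x$immigration > 0) cat("  immigration:", x$immigration, "J*/day\n")
  invisible(x)
}

# Column index helpers into the 27-column state matrix
j_cols <- function() 1:9
m_cols <- function() 10:18
f_cols <- function() 19:27
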