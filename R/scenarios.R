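# Release-scenario designs: the bundled catalogue, fixed-budget sweeps, and
# batch runners that attach outcome metrics to each design row.

#' Log-spaced duration grid for fixed-budget sweeps
#'
#' @param n Number of durations.
#' @param from,to Range in days.
#' @return Numeric vector of durations, log-spaced from `from` to `to`.
#' @export
sweep_durations <- function(n = 15, from = 20, to = 500) {
  v <- exp(seq(log(from), log(to), length.out = n))
  v[1] <- from          # pin the endpoints exactly
  v[n] <- to
  v
}

#' Ratio-duration combinations at a fixed release budget
#'
#' Holds the total release effort fixed at `budget` ratio-days (`r * T`),
#' which is proportional to the total number of individuals released under
#' constant-rate forcing, and varies the split between weekly ratio and
#' duration: each duration `T` gets `r = budget / T`. The default 80
#' ratio-day budget spans `r = 4` for 20 days to `r = 0.16` for 500 days.
#'
#' @param budget Total effort in ratio-days (> 0).
#' @param durations Durations in days (default the log-spaced 20-500 grid).
#' @param sexes Sex mode(s); one schedule per duration and mode.
#' @param strain Released genotype, `"KKAA"` or `"KKaa"`.
#' @param start Release start day.
#' @return A design tibble with columns `strain`, `sexes`, `r`, `duration`,
#'   `start`, `c_K`, `c_A`, `immigration`; `r * duration == budget` in every
#'   row.
#' @examples
#' fixed_budget_sweep(80, durations = c(20, 100, 500))
#' @export
fixed_budget_sweep <- function(budget = 80, durations = sweep_durations(),
                               sexes = "male-only", strain = "KKAA",
                               start = 30) {
  stopifnot(is.numeric(budget), length(budget) == 1L, budget > 0,
            all(durations > 0))
  tidyr::expand_grid(strain = strain, sexes = sexes, duration = durations) |>
    dplyr::mutate(r = budget / .data$duration, start = start,
                  c_K = 0, c_A = 0, immigration = 0) |>
    dplyr::select("strain", "sexes", "r", "duration", "start",
                  "c_K", "c_A", "immigration")
}

#' The bundled catalogue of release-scenario designs
#'
#' Reads the package's scenario configuration file and expands each entry to
#' a design tibble (one row per released-strain / sex-mode / ratio / duration
#' / fitness-cost / immigration combination). The designs cover the standard
#' experiments: four-ratio year-long male-only releases of both strains;
#' duration variation at `r = 2`; the 80 ratio-day fixed-budget sweep for all
#' three sex modes; single- versus bi-sex releases at `r = 1`; anti-pathogen
#' fitness costs; female-only durations near the extinction boundary; and
#' wild-type juvenile immigration.
#'
#' @param file Path to a scenario YAML file (defaults to the bundled one).
#' @return A named list of design tibbles (see [fixed_budget_sweep()] for the
#'   columns); each carries its prose description as attribute
#'   `"description"`.
#' @examples
#' names(rr_catalogue())
#' rr_catalogue()$fig2
#' @export
rr_catalogue <- function(file = system.file("extdata", "scenarios.yaml",
                                            package = "rrsim")) {
  raw <- yaml::read_yaml(file)
  purrr::imap(raw, function(entry, id) {
    if (!is.null(entry$budget)) {
      durations <- entry$duration
      if (is.null(durations) || identical(durations, "default")) {
        durations <- sweep_durations()
      }
      design <- fixed_budget_sweep(entry$budget, durations = durations,
                                   sexes = unlist(entry$sexes),
                                   strain = unlist(entry$strain),
                                   start = entry$start %||% 30)
    } else {
      design <- tidyr::expand_grid(
        strain = unlist(entry$strain) %||% "KKAA",
        sexes = unlist(entry$sexes) %||% "male-only",
        r = as.numeric(unlist(entry$r)),
        duration = as.numeric(unlist(entry$duration)),
        c_K = as.numeric(unlist(entry$c_K) %||% 0),
        c_A = as.numeric(unlist(entry$c_A) %||% 0),
        immigration = as.numeric(unlist(entry$immigration) %||% 0)
      )
      design$start <- entry$start %||% 30
      design <- dplyr::select(design, "strain", "sexes", "r", "duration",
                              "start", "c_K", "c_A", "immigration")
    }
    attr(design, "description") <- entry$description
    design
  })
}

#' Run every scenario of a design and attach outcome metrics
#'
#' Simulates each row of a design tibble (as produced by [rr_catalogue()] or
#' [fixed_budget_sweep()]) and returns the design with the one-row
#' [glance()][glance.rr_sim] summary of each run bound to it.
#'
#' @param design Design tibble with columns `strain`, `sexes`, `r`,
#'   `duration`, `start` and optionally `c_K`, `c_A`, `immigration`.
#' @param params Base parameter set; per-row `c_K`/`c_A` override its costs.
#' @param t_final Simulation horizon in days (default: 2000 days past the
#'   latest release end, enough for post-release recovery under the default
#'   density dependence).
#' @param ... Passed to [simulate_release()] (e.g. solver tolerances).
#' @return A tibble: the design columns plus `min_native_female`,
#'   `min_native_day`, `competent_at_recovery`, `recovery_day`, `recovered`,
#'   `extinction_day_K`, `extinction_day_A`.
#' @export
run_design <- function(design, params = rr_params(), t_final = NULL, ...) {
  stopifnot(all(c("strain", "sexes", "r", "duration", "start") %in%
                  names(design)))
  if (is.null(t_final)) {
    t_final <- max(design$start + design$duration) + 2000
  }
  metrics <- purrr::pmap(design, function(strain, sexes, r, duration, start,
                                          c_K = NULL, c_A = NULL,
                                          immigration = 0, ...) {
    p <- params
    if (!is.null(c_K) || !is.null(c_A)) {
      p <- as_rr_params(utils::modifyList(
        unclass(params), list(c_K = c_K %||% params$c_K,
                              c_A = c_A %||% params$c_A)))
    }
    sched <- release_schedule(strain, sexes, r = r, duration = duration,
                              start = start)
    sim <- simulate_release(p, sched, immigration = immigration,
                            t_final = t_final, ...)
    g <- glance(sim)
    g[, setdiff(names(g), c("strain", "sexes", "r", "duration"))]
  })
  dplyr::bind_cols(design, dplyr::bind_rows(metrics))
}

#' Run a fixed-budget ratio-duration sweep
#'
#' Convenience wrapper: builds the [fixed_budget_sweep()] design and runs it
#' with [run_design()].
#'
#' @inheritParams fixed_budget_sweep
#' @inheritParams run_design
#' @return The metrics tibble from [run_design()], one row per
#'   (duration, sex mode).
#' @export
run_sweep <- function(budget = 80, durations = sweep_durations(),
                      sexes = "male-only", strain = "KKAA",
                      params = rr_params(), t_final = NULL, ...) {
  run_design(fixed_budget_sweep(budget, durations, sexes, strain),
             params = params, t_final = t_final, ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
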