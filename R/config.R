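# Run configuration handling and end-to-end commands: one-scenario runs
# (trajectory CSV + metrics/metadata JSON), sweeps (tidy CSV), and
# regeneration of the catalogue experiments as plots. The deterministic core
# plus fixed solver settings make every command byte-reproducible.

#' Read a run configuration
#'
#' A run configuration is a YAML file with optional blocks `params`
#' (overrides of the [rr_params()] defaults), `schedule` (`strain`, `sexes`,
#' `r`, `duration`, `start`), `immigration`, `solver` (`rtol`, `atol`),
#' `t_final`, and `seed` (recorded in the metadata for provenance; the core
#' model is deterministic and does not consume it). Omitted fields fall back
#' to the package defaults. All invalid fields are reported together.
#'
#' @param file Path to a YAML configuration.
#' @return An object of class `rr_config` (a validated list).
#' @export
rr_read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  rr_config(raw)
}

#' @rdname rr_read_config
#' @param x A named list with the fields described above.
#' @export
rr_config <- function(x = list()) {
  known <- c("params", "schedule", "immigration", "solver", "t_final", "seed")
  problems <- character()
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown field(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  params <- tryCatch(do.call(rr_params, x$params %||% list()),
                     error = function(e) {
                       problems <<- c(problems, conditionMessage(e))
                       NULL
                     })
  schedule <- NULL
  if (!is.null(x$schedule)) {
    schedule <- tryCatch(do.call(release_schedule, x$schedule),
                         error = function(e) {
                           problems <<- c(problems, paste0(
                             "schedule: ", conditionMessage(e)))
                           NULL
                         })
  }
  solver <- x$solver %||% list()
  rtol <- solver$rtol %||% 1e-8
  atol <- solver$atol %||% 1e-10
  if (!is.numeric(rtol) || rtol <= 0 || !is.numeric(atol) || atol <= 0) {
    problems <- c(problems, "solver: rtol and atol must be positive numbers")
  }
  immigration <- x$immigration %||% 0
  if (!is.numeric(immigration) || length(immigration) != 1L || immigration < 0) {
    problems <- c(problems, "immigration: must be a single nonnegative number")
  }
  t_final <- x$t_final %||% 1000
  if (!is.numeric(t_final) || length(t_final) != 1L || t_final <= 0) {
    problems <- c(problems, "t_final: must be a single positive number of days")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(params = params, schedule = schedule,
                 immigration = as.numeric(immigration),
                 solver = list(rtol = as.numeric(rtol), atol = as.numeric(atol)),
                 t_final = as.numeric(t_final), seed = x$seed),
            class = "rr_config")
}

#' Write a run configuration back to YAML
#'
#' Configurations round-trip losslessly: `rr_read_config(rr_write_config(cfg,
#' f))` reproduces `cfg`.
#'
#' @param config An `rr_config` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
rr_write_config <- function(config, file) {
  stopifnot(inherits(config, "rr_config"))
  out <- list(params = unclass(config$params),
              immigration = config$immigration,
              solver = config$solver, t_final = config$t_final)
  if (!is.null(config$schedule)) {
    s <- config$schedule
    out$schedule <- list(strain = s$strain, sexes = s$sexes, r = s$r,
                         duration = s$duration, start = s$start)
  }
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, file)
  invisible(file)
}

#' Run one configured scenario end-to-end
#'
#' Simulates the configured scenario and writes `trajectory.csv` (tidy
#' columns `time`, `stage`, `genotype`, `density`), `metrics.json` (the
#' [glance()][glance.rr_sim] summary plus the outcome series), and
#' `metadata.json` (parameters, schedule, resolved release rates, solver
#' settings, analytic equilibrium, seed) into `out_dir`.
#'
#' @param config An `rr_config` object or a path to a YAML configuration.
#' @param out_dir Output directory (created if missing).
#' @return The `rr_sim` object, invisibly.
#' @export
rr_run_config <- function(config, out_dir) {
  if (is.character(config)) config <- rr_read_config(config)
  stopifnot(inherits(config, "rr_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_release(config$params, config$schedule,
                          immigration = config$immigration,
                          t_final = config$t_final,
                          rtol = config$solver$rtol, atol = config$solver$atol)
  utils::write.csv(tidy(sim), file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = glance(sim), series = metric_series(sim)),
    file.path(out_dir, "metrics.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(
    list(params = unclass(sim$params),
         schedule = if (is.null(sim$schedule)) NULL else unclass(sim$schedule),
         release_rates = sim$rates[, c("male_rate", "female_rate")],
         immigration = sim$immigration,
         solver = sim$solver,
         equilibrium = unclass(sim$equilibrium),
         seed = config$seed),
    file.path(out_dir, "metadata.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(sim)
}

#' Run a sweep and write it as one tidy CSV
#'
#' @param design Design tibble (e.g. from [fixed_budget_sweep()] or an
#'   [rr_catalogue()] entry), run with [run_design()].
#' @param file Output CSV path.
#' @param ... Passed to [run_design()].
#' @return The metrics tibble, invisibly.
#' @export
rr_run_sweep <- function(design, file, ...) {
  res <- run_design(design, ...)
  res <- dplyr::mutate(res, scenario = dplyr::row_number(), .before = 1)
  utils::write.csv(res, file, row.names = FALSE)
  invisible(res)
}

#' Regenerate catalogue figure experiments
#'
#' Re-runs the named catalogue designs and renders, for each, the log-scale
#' relative-density panel (and, for single-scenario designs, the
#' allele-frequency panel) with release-window markers, saving one image per
#' panel into `out_dir`. Unknown names are rejected with the list of valid
#' ones.
#'
#' @param names Catalogue entries to regenerate (see [rr_catalogue()]).
#' @param out_dir Output directory (created if missing).
#' @param t_final Simulation horizon in days.
#' @param params Base parameter set.
#' @param device Image format passed to [ggplot2::ggsave()] (default
#'   `"png"`).
#' @return Tibble of written files with their scenario rows, invisibly.
#' @export
rr_make_figures <- function(names, out_dir, t_final = 1500,
                            params = rr_params(), device = "png") {
  cat <- rr_catalogue()
  bad <- setdiff(names, base::names(cat))
  if (length(bad)) {
    stop("unknown figure name(s): ", paste(bad, collapse = ", "),
         "; valid names are ", paste(base::names(cat), collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names) {
    design <- cat[[nm]]
    series <- purrr::pmap(design, function(strain, sexes, r, duration, start,
                                           c_K = 0, c_A = 0,
                                           immigration = 0, ...) {
      p <- as_rr_params(utils::modifyList(unclass(params),
                                          list(c_K = c_K, c_A = c_A)))
      sim <- simulate_release(
        p, release_schedule(strain, sexes, r = r, duration = duration,
                            start = start),
        immigration = immigration, t_final = t_final)
      dplyr::mutate(metric_series(sim),
                    strain = strain, sexes = sexes, r = r,
                    duration = duration, c_A = c_A,
                    immigration = immigration)
    })
    df <- dplyr::bind_rows(series, .id = "scenario")
    long <- tidyr::pivot_longer(
      df[, c("scenario", "time", "rel_total_female", "rel_competent")],
      c("rel_total_female", "rel_competent"),
      names_to = "series", values_to = "density")
    pl <- ggplot2::ggplot(long,
                          ggplot2::aes(x = .data$time, y = .data$density,
                                       colour = .data$scenario,
                                       linetype = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::geom_vline(xintercept = design$start[1], linetype = "dashed",
                          colour = "grey50") +
      ggplot2::geom_vline(xintercept = design$start + design$duration,
                          linetype = "dashed", colour = "grey70") +
      ggplot2::labs(title = nm, x = "day", y = "relative female density")
    f <- file.path(out_dir, paste0(nm, "_density.", device))
    ggplot2::ggsave(f, pl, width = 7, height = 4.5, dpi = 150)
    written <- c(written, f)
    freq <- tidyr::pivot_longer(
      df[, c("scenario", "time", "freq_K_juv", "freq_A_juv")],
      c("freq_K_juv", "freq_A_juv"), names_to = "allele",
      values_to = "frequency")
    pf <- ggplot2::ggplot(freq,
                          ggplot2::aes(x = .data$time, y = .data$frequency,
                                       colour = .data$scenario,
                                       linetype = .data$allele)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = nm, x = "day", y = "juvenile allele frequency")
    f2 <- file.path(out_dir, paste0(nm, "_frequencies.", device))
    ggplot2::ggsave(f2, pf, width = 7, height = 4.5, dpi = 150)
    written <- c(written, f2)
  }
  invisible(written)
}
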