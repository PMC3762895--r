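#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated trajectory
#'
#' @param x An [simulate_release()] result.
#' @param ... Unused.
#' @return A long tibble with columns `time`, `stage` (`"J"`, `"M"`, `"F"`),
#'   `genotype` (label) and `density`, one row per time/stage/genotype.
#' @export
tidy.rr_sim <- function(x, ...) {
  wide <- tibble::as_tibble(x$states)
  wide$time <- x$times
  out <- tidyr::pivot_longer(wide, -"time",
                             names_to = c("stage", "genotype"),
                             names_sep = "_", values_to = "density")
  out$stage <- factor(out$stage, levels = c("J", "M", "F"))
  out$genotype <- factor(out$genotype, levels = GENOTYPE_LABELS)
  dplyr::arrange(out, .data$time, .data$stage, .data$genotype)
}

#' One-row summary of a simulated release
#'
#' @param x An [simulate_release()] result.
#' @param ... Unused.
#' @return A one-row tibble: the schedule (`strain`, `sexes`, `r`,
#'   `duration`), the minimum relative native female density and its day, the
#'   relative competent density at recovery (with recovery day and status),
#'   and the K- and A-allele extinction days (`NA` while the allele
#'   persists).
#' @export
glance.rr_sim <- function(x, ...) {
  mn <- min_native_female(x)
  cr <- competent_at_recovery(x)
  sched <- if (is.null(x$schedule)) {
    tibble::tibble(strain = NA_character_, sexes = NA_character_,
                   r = 0, duration = 0)
  } else {
    tibble::tibble(strain = x$schedule$strain, sexes = x$schedule$sexes,
                   r = x$schedule$r, duration = x$schedule$duration)
  }
  dplyr::bind_cols(
    sched,
    tibble::tibble(
      min_native_female = mn$value, min_native_day = mn$day,
      competent_at_recovery = cr$value, recovery_day = cr$day,
      recovered = cr$recovered,
      extinction_day_K = allele_extinction_day(x, "K"),
      extinction_day_A = allele_extinction_day(x, "A")
    )
  )
}
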