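#' Release schedule for continuous transgenic releases
#'
#' Releases are modelled as a constant daily rate over a window
#' `[start, start + duration)`. The weekly release ratio `r` is the number of
#' transgenic adults released per week divided by the pre-release equilibrium
#' wild-type male density `M*`; dividing by 7 converts it to a daily rate, so
#' the same number of individuals is released each week regardless of how the
#' resident population changes. Two strains can be released: the
#' reduce-and-replace strain `KKAA` (female-killing plus anti-pathogen) and
#' the female-killing-only strain `KKaa`.
#'
#' Sex modes: `"male-only"` releases males at `r * M* / 7` per day;
#' `"female-only"` is symmetric; `"bi-sex"` splits the same total evenly, each
#' sex at `r * M* / 14` per day. Released females are viable adults
#' (tetracycline-reared), placed directly in the adult female compartment of
#' the released genotype.
#'
#' @param strain Released genotype: `"KKAA"` (R&R) or `"KKaa"` (FK).
#' @param sexes One of `"male-only"`, `"bi-sex"`, `"female-only"`.
#' @param r Weekly release ratio (dimensionless, >= 0).
#' @param duration Length of the release window in days (> 0).
#' @param start First day of release (default 30).
#' @return An object of class `rr_schedule`.
#' @examples
#' release_schedule("KKAA", "male-only", r = 2, duration = 365)
#' @export
release_schedule <- function(strain = c("KKAA", "KKaa"),
                             sexes = c("male-only", "bi-sex", "female-only"),
                             r, duration, start = 30) {
  strain <- match.arg(strain)
  sexes <- match.arg(sexes)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0) {
    stop("`r` must be a single nonnegative number", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number of days", call. = FALSE)
  }
  if (!is.numeric(start) || length(start) != 1L || is.na(start) || start < 0) {
    stop("`start` must be a single nonnegative day", call. = FALSE)
  }
  structure(
    list(strain = strain, sexes = sexes, r = as.numeric(r),
         duration = as.numeric(duration), start = as.numeric(start),
         end = as.numeric(start) + as.numeric(duration)),
    class = "rr_schedule"
  )
}

#' @export
print.rr_schedule <- function(x, ...) {
  cat(sprintf("<rr_schedule> %s %s  r=%g  days [%g, %g)\n",
              x$strain, x$sexes, x$r, x$start, x$end))
  invisible(x)
}

#' Resolved daily release rates of a schedule
#'
#' Anchors the schedule's weekly ratio to the analytic wild-type male
#' equilibrium `M*` for the given parameters.
#'
#' @param schedule An [release_schedule()] object (or `NULL` for no release).
#' @param params An [rr_params()] parameter set.
#' @return A one-row tibble with columns `strain`, `sexes`, `r`, `duration`,
#'   `start`, `end`, `male_rate`, `female_rate` (individuals per day).
#' @export
release_rates <- function(schedule, params = rr_params()) {
  if (is.null(schedule)) {
    return(tibble::tibble(strain = NA_character_, sexes = NA_character_,
                          r = 0, duration = 0, start = 0, end = 0,
                          male_rate = 0, female_rate = 0))
  }
  stopifnot(inherits(schedule, "rr_schedule"))
  M_hat <- wildtype_equilibrium(as_rr_params(params))$M_star
  weekly <- schedule$r * M_hat / 7
  rates <- switch(schedule$sexes,
    "male-only"   = c(weekly, 0),
    "female-only" = c(0, weekly),
    "bi-sex"      = c(weekly / 2, weekly / 2)
  )
  tibble::tibble(strain = schedule$strain, sexes = schedule$sexes,
                 r = schedule$r, duration = schedule$duration,
                 start = schedule$start, end = schedule$end,
                 male_rate = rates[1], female_rate = rates[2])
}
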