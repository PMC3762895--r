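# Derived outcomes: relative densities, competent-vector density, minima,
# recovery readouts, juvenile allele frequencies, allele extinction times.

#' Competent-vector density of a female pool
#'
#' A competent vector is an adult female able to transmit the pathogen. The
#' anti-pathogen transgene is treated as dominant by default: a single A
#' allele renders a female refractory, so only females with zero A alleles
#' (genotypes `KKaa`, `Kkaa`, `kkaa`) are competent. With
#' `refractoriness = "recessive"` only `AA` females are refractory.
#'
#' @param F Female densities by genotype (length 9, genotype order).
#' @param refractoriness `"dominant"` (default) or `"recessive"`.
#' @return Total competent female density (a single number).
#' @examples
#' competent_density(c(0, 0, 0, 0, 0, 5, 0, 0, 3))  # kkAa refractory -> 3
#' @export
competent_density <- function(F, refractoriness = c("dominant", "recessive")) {
  refractoriness <- match.arg(refractoriness)
  stopifnot(length(F) == 9L)
  competent <- if (refractoriness == "dominant") GENOTYPE_NA == 0L
               else GENOTYPE_NA < 2L
  sum(F[competent])
}

#' Outcome time series of a simulation
#'
#' Computes, on the simulation's output grid, the densities and allele
#' frequencies the release designs are judged by. "Native" females are those
#' of viable (`gamma = 1`) genotypes; released females carry at least one K
#' allele and can never arise through emergence, so released and native
#' females are distinguished purely by genotype. Relative densities are
#' scaled by the pre-release equilibrium total female density.
#'
#' @param sim An [simulate_release()] result.
#' @param refractoriness Passed to [competent_density()].
#' @return A tibble with one row per output time and columns `time`,
#'   `total_female`, `native_female`, `competent` (absolute densities),
#'   `rel_total_female`, `rel_native_female`, `rel_competent`, and the
#'   juvenile allele frequencies `freq_K_juv`, `freq_A_juv`.
#' @export
metric_series <- function(sim, refractoriness = c("dominant", "recessive")) {
  stopifnot(inherits(sim, "rr_sim"))
  refractoriness <- match.arg(refractoriness)
  S <- pmax(sim$states, 0)
  Fm <- S[, f_cols(), drop = FALSE]
  Jm <- S[, j_cols(), drop = FALSE]
  native_idx <- which(GENOTYPE_NK == 0L)
  competent_idx <- if (refractoriness == "dominant") which(GENOTYPE_NA == 0L)
                   else which(GENOTYPE_NA < 2L)
  total_female <- rowSums(Fm)
  native_female <- rowSums(Fm[, native_idx, drop = FALSE])
  competent <- rowSums(Fm[, competent_idx, drop = FALSE])
  J_tot <- rowSums(Jm)
  freq_K <- ifelse(J_tot > 0, as.vector(Jm %*% GENOTYPE_NK) / (2 * J_tot), NA_real_)
  freq_A <- ifelse(J_tot > 0, as.vector(Jm %*% GENOTYPE_NA) / (2 * J_tot), NA_real_)
  b <- sim$baseline
  tibble::tibble(
    time = sim$times,
    total_female = total_female,
    native_female = native_female,
    competent = competent,
    rel_total_female = total_female / b,
    rel_native_female = native_female / b,
    rel_competent = competent / b,
    freq_K_juv = freq_K,
    freq_A_juv = freq_A
  )
}

release_window <- function(sim) {
  if (is.null(sim$schedule)) c(start = 0, end = 0)
  else c(start = sim$schedule$start, end = sim$schedule$end)
}

#' Minimum native female density after release onset
#'
#' The minimum, over all output times at or after the release start, of the
#' total adult female density *excluding released-genotype females*, relative
#' to the pre-release baseline, together with the day on which it occurs
#' (ties broken to the earliest day). For a no-release control the window
#' starts at day 0.
#'
#' @param sim An [simulate_release()] result whose horizon covers the release
#'   window.
#' @return A one-row tibble with columns `value` (relative density) and `day`.
#' @export
min_native_female <- function(sim) {
  ms <- metric_series(sim)
  win <- release_window(sim)
  if (max(ms$time) < win["end"]) {
    stop("trajectory (ends day ", max(ms$time),
         ") is shorter than the release window (ends day ", win["end"], ")",
         call. = FALSE)
  }
  ms <- ms[ms$time >= win["start"], ]
  k <- which.min(ms$rel_native_female)  # which.min takes the first minimum
  tibble::tibble(value = ms$rel_native_female[k], day = ms$time[k])
}

#' Competent-vector density at population recovery
#'
#' Evaluates the relative competent-vector density at the first output time
#' after the release window in which the native total female density has
#' returned to within `tol` of the pre-release baseline. The approach to
#' baseline is asymptotic, so an exact return never happens; the default
#' tolerance is 1%. If the population has not recovered by the end of the
#' trajectory (e.g. near-extinction scenarios), `recovered` is `FALSE` and
#' the horizon-end value is reported.
#'
#' @param sim An [simulate_release()] result extending past the release end.
#' @param tol Recovery tolerance as a fraction of baseline (default 0.01).
#' @return A one-row tibble with columns `value` (relative competent
#'   density), `day`, and `recovered` (logical).
#' @export
competent_at_recovery <- function(sim, tol = 0.01) {
  ms <- metric_series(sim)
  win <- release_window(sim)
  if (max(ms$time) < win["end"]) {
    stop("trajectory ends (day ", max(ms$time),
         ") before the release window does (day ", win["end"], ")",
         call. = FALSE)
  }
  post <- ms[ms$time >= win["end"], ]
  k <- which(post$rel_native_female >= 1 - tol)
  if (length(k)) {
    tibble::tibble(value = post$rel_competent[k[1L]], day = post$time[k[1L]],
                   recovered = TRUE)
  } else {
    n <- nrow(post)
    tibble::tibble(value = post$rel_competent[n], day = post$time[n],
                   recovered = FALSE)
  }
}

#' Day on which a transgenic allele is effectively lost
#'
#' Deterministic densities never reach exact zero, so extinction is declared
#' at the first day after the release end on which the juvenile frequency of
#' the allele falls below `eps` and stays below it for the remainder of the
#' trajectory.
#'
#' @param sim An [simulate_release()] result.
#' @param allele `"K"` (female-killing) or `"A"` (anti-pathogen).
#' @param eps Extinction threshold on the frequency (default 1e-6).
#' @return The day (numeric), or `NA` if the allele persists to the horizon.
#' @export
allele_extinction_day <- function(sim, allele = c("K", "A"), eps = 1e-6) {
  allele <- match.arg(allele)
  ms <- metric_series(sim)
  freq <- if (allele == "K") ms$freq_K_juv else ms$freq_A_juv
  win <- release_window(sim)
  post <- which(ms$time > win["end"])
  if (!length(post)) return(NA_real_)
  below <- !is.na(freq[post]) & freq[post] < eps
  # first index from which everything is below eps
  run <- rev(cumprod(rev(below)))
  k <- which(run == 1)
  if (!length(k)) return(NA_real_)
  ms$time[post[k[1L]]]
}
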