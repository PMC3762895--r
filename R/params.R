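#' Demographic and genetic parameter set
#'
#' Constructs the parameter record used throughout the model. Defaults are the
#' standard values for a strongly density-regulated *Aedes aegypti*
#' population; density units are abstract (all reported outputs are relative
#' to the pre-release baseline), times are in days and rates per day.
#'
#' @param mu_J Density-independent juvenile mortality rate (day^-1).
#' @param mu_M Adult male mortality rate (day^-1).
#' @param mu_F Adult female mortality rate (day^-1).
#' @param lambda Per-capita rate at which females produce larvae (day^-1).
#' @param nu Per-capita emergence rate from juvenile to adult (day^-1).
#' @param alpha Density-dependence scale: the density-dependent component of
#'   per-capita juvenile mortality is `alpha * J_tot^(beta - 1)`.
#' @param beta Density-dependence exponent (> 1); larger values mean stronger
#'   regulation and faster recovery after perturbation.
#' @param c_K,c_A Fitness costs of homozygosity for the female-killing and
#'   anti-pathogen alleles (egg-to-larva survival), each in \[0, 1\].
#' @return An object of class `rr_params` (a named list).
#' @examples
#' rr_params()
#' rr_params(c_A = 0.1)
#' @export
rr_params <- function(mu_J = 0.03, mu_M = 0.28, mu_F = 0.10,
                      lambda = 8, nu = 0.14,
                      alpha = 2e-4, beta = 3.4,
                      c_K = 0, c_A = 0) {
  p <- list(mu_J = mu_J, mu_M = mu_M, mu_F = mu_F, lambda = lambda, nu = nu,
            alpha = alpha, beta = beta, c_K = c_K, c_A = c_A)
  problems <- character()
  for (nm in c("mu_J", "mu_M", "mu_F", "lambda", "nu", "alpha")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      problems <- c(problems, paste0("`", nm, "` must be a single nonnegative number"))
    }
  }
  if (!is.numeric(p$beta) || length(p$beta) != 1L || is.na(p$beta) || p$beta <= 1) {
    problems <- c(problems, "`beta` must be a single number > 1")
  }
  for (nm in c("c_K", "c_A")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      problems <- c(problems, paste0("`", nm, "` must be a single number in [0, 1]"))
    }
  }
  if (length(problems)) {
    stop("invalid parameter set:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  p <- lapply(p, as.numeric)
  structure(p, class = "rr_params")
}

#' @export
print.rr_params <- function(x, ...) {
  cat("<rr_params>\n")
  cat(sprintf("  mortality: mu_J=%g  mu_M=%g  mu_F=%g (day^-1)\n",
              x$mu_J, x$mu_M, x$mu_F))
  cat(sprintf("  reproduction: lambda=%g  nu=%g (day^-1)\n", x$lambda, x$nu))
  cat(sprintf("  density dependence: alpha=%g  beta=%g\n", x$alpha, x$beta))
  cat(sprintf("  fitness costs: c_K=%g  c_A=%g\n", x$c_K, x$c_A))
  invisible(x)
}

as_rr_params <- function(x) {
  if (inherits(x, "rr_params")) return(x)
  if (is.list(x)) return(do.call(rr_params, x))
  stop("`params` must be an `rr_params` object or a named list", call. = FALSE)
}
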