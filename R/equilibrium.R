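#' Closed-form wild-type equilibrium
#'
#' In an all-wild-type population the model collapses to one juvenile and two
#' adult compartments. Setting the derivatives to zero gives the juvenile
#' balance `lambda * nu / (2 mu_F) = mu_J + nu + alpha * J^(beta - 1)`, whose
#' unique positive root is
#' `J* = ((lambda nu / (2 mu_F) - mu_J - nu) / alpha)^(1 / (beta - 1))`, with
#' adults `M* = nu J* / (2 mu_M)` and `F* = nu J* / (2 mu_F)`. A positive
#' equilibrium exists iff net reproduction exceeds the density-independent
#' losses, `lambda nu / (2 mu_F) > mu_J + nu`.
#'
#' The analytic form (never a simulated steady state) anchors release
#' magnitudes, so release forcing is exactly reproducible and independent of
#' solver settings.
#'
#' @param params An [rr_params()] parameter set.
#' @return An object of class `rr_equilibrium`: a list with `J_star`,
#'   `M_star`, `F_star`.
#' @examples
#' wildtype_equilibrium(rr_params())
#' @export
wildtype_equilibrium <- function(params = rr_params()) {
  p <- as_rr_params(params)
  if (p$alpha <= 0) {
    stop("no positive equilibrium: alpha = 0 removes density regulation, ",
         "so a self-sustaining population grows without bound", call. = FALSE)
  }
  net <- p$lambda * p$nu / (2 * p$mu_F) - p$mu_J - p$nu
  if (net <= 0) {
    stop("no positive equilibrium: lambda*nu/(2*mu_F) = ",
         signif(p$lambda * p$nu / (2 * p$mu_F), 6),
         " does not exceed mu_J + nu = ", signif(p$mu_J + p$nu, 6),
         " (population not self-sustaining)", call. = FALSE)
  }
  J <- (net / p$alpha)^(1 / (p$beta - 1))
  structure(
    list(J_star = J,
         M_star = p$nu * J / (2 * p$mu_M),
         F_star = p$nu * J / (2 * p$mu_F)),
    class = "rr_equilibrium"
  )
}

#' @export
print.rr_equilibrium <- function(x, ...) {
  cat("<rr_equilibrium>  J* =", format(x$J_star, digits = 6),
      " M* =", format(x$M_star, digits = 6),
      " F* =", format(x$F_star, digits = 6), "\n")
  invisible(x)
}

# Full 27-dimensional state (J[1..9], M[1..9], F[1..9]) with all density in
# the wild-type (kkaa, index 9) compartments.
equilibrium_state <- function(eq) {
  y <- numeric(27L)
  names(y) <- state_names()
  y[9L] <- eq$J_star
  y[18L] <- eq$M_star
  y[27L] <- eq$F_star
  y
}

state_names <- function() {
  c(paste0("J_", GENOTYPE_LABELS),
    paste0("M_", GENOTYPE_LABELS),
    paste0("F_", GENOTYPE_LABELS))
}
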