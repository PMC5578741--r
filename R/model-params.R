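#' Global parameters of the receptor free-energy and adaptation model
#'
#' Bundles the parameters shared by the receptor-team activity model and the
#' methylation adaptation kinetics. Defaults reproduce the wild-type
#' simulation conditions: an adapted activity of 1/3, a saturation parameter
#' `N0 = 2`, reference temperature 24 degC, free-energy temperature slope
#' `f1 = 1.2` kT/degC and a methylation coefficient `g(T) = g0 + (T - T0) g1`
#' with `g0 = 0`, `g1 = 0.2` kT per methyl group per degC.
#'
#' @param f1 Free-energy slope with temperature (kT per degC).
#' @param g0 Methylation free-energy coefficient at the reference temperature
#'   (kT per methyl group).
#' @param g1 Temperature slope of the methylation coefficient
#'   (kT per methyl group per degC).
#' @param T0 Reference temperature (degC).
#' @param mtot Maximum methylation level per receptor dimer (positive integer).
#' @param N0 Methylation-saturation parameter (dimensionless, >= 0). `N0 = 0`
#'   corresponds to perfect adaptation (no slowing of methylation near the
#'   saturated limits).
#' @param A0 Adapted kinase activity in the absence of saturation
#'   (fraction, strictly between 0 and 1).
#' @param dT_step Stimulus temperature step used for response curves (degC).
#' @param f0_sat Free-energy offset representing ligand saturation (kT), used
#'   to normalize thermal-response curves.
#'
#' @return An object of class `thermo_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$A0
#' @export
model_params <- function(f1 = 1.2, g0 = 0, g1 = 0.2, T0 = 24, mtot = 8,
                         N0 = 2, A0 = 1 / 3, dT_step = 3, f0_sat = 15) {
  stopifnot(
    is.numeric(f1), length(f1) == 1L, is.finite(f1),
    is.numeric(g0), length(g0) == 1L, is.finite(g0),
    is.numeric(g1), length(g1) == 1L, is.finite(g1),
    is.numeric(T0), length(T0) == 1L, is.finite(T0)
  )
  if (!(is.numeric(mtot) && length(mtot) == 1L && mtot >= 1 &&
        mtot == round(mtot))) {
    stop("`mtot` must be a positive integer", call. = FALSE)
  }
  if (!(is.numeric(N0) && length(N0) == 1L && is.finite(N0) && N0 >= 0)) {
    stop("`N0` must be a non-negative number", call. = FALSE)
  }
  if (!(is.numeric(A0) && length(A0) == 1L && A0 > 0 && A0 < 1)) {
    stop("`A0` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(is.numeric(dT_step) && length(dT_step) == 1L && dT_step > 0)) {
    stop("`dT_step` must be positive", call. = FALSE)
  }
  stopifnot(is.numeric(f0_sat), length(f0_sat) == 1L, is.finite(f0_sat))
  structure(
    list(f1 = f1, g0 = g0, g1 = g1, T0 = T0, mtot = as.numeric(mtot),
         N0 = N0, A0 = A0, dT_step = dT_step, f0_sat = f0_sat),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Receptor model parameters\n")
  cat(sprintf("  f1 = %g kT/degC, g(T) = %g + (T - %g) * %g kT/methyl\n",
              x$f1, x$g0, x$T0, x$g1))
  cat(sprintf("  mtot = %g, N0 = %g, A0 = %.4g\n", x$mtot, x$N0, x$A0))
  cat(sprintf("  dT_step = %g degC, f0_sat = %g kT\n", x$dT_step, x$f0_sat))
  invisible(x)
}

#' Methylation/demethylation rate constants
#'
#' Rate constants of the CheR (methylation) and CheB (demethylation) arms of
#' the adaptation kinetics. Model time is in arbitrary units; by default
#' `gamma_B = 1` and `gamma_R = A0 / (1 - A0)` so that the perfect-adaptation
#' fixed point reproduces the adapted activity `A0`.
#'
#' @param gamma_R Methylation rate constant (> 0, per unit model time).
#' @param gamma_B Demethylation rate constant (> 0, per unit model time).
#' @param params A [model_params()] object used only to compute the default
#'   `gamma_R`.
#' @return An object of class `thermo_kinetics`.
#' @examples
#' kinetics_params()          # gamma_R = 0.5, gamma_B = 1 for A0 = 1/3
#' @export
kinetics_params <- function(gamma_R = NULL, gamma_B = 1,
                            params = model_params()) {
  if (is.null(gamma_R)) gamma_R <- params$A0 / (1 - params$A0)
  if (!(is.numeric(gamma_R) && length(gamma_R) == 1L && gamma_R > 0)) {
    stop("`gamma_R` must be positive", call. = FALSE)
  }
  if (!(is.numeric(gamma_B) && length(gamma_B) == 1L && gamma_B > 0)) {
    stop("`gamma_B` must be positive", call. = FALSE)
  }
  structure(list(gamma_R = gamma_R, gamma_B = gamma_B),
            class = "thermo_kinetics")
}

#' Two-state ligand-binding model for the receptor free-energy offset
#'
#' Describes how a chemoeffector shifts the free-energy difference between the
#' active and inactive receptor conformations. `Kon` and `Koff` are the
#' dissociation constants in the active and inactive state respectively; for a
#' chemoattractant `Koff < Kon` (the inactive state binds more tightly), so
#' increasing ligand raises the offset and lowers activity.
#'
#' @param f0_zero Free-energy difference with no ligand (kT).
#' @param Kon Dissociation constant in the active state (> 0, concentration).
#' @param Koff Dissociation constant in the inactive state (> 0, same units).
#' @param L Ligand concentration (>= 0, same units as the constants).
#' @return An object of class `ligand_model`.
#' @seealso [ligand_free_energy()]
#' @examples
#' lig <- ligand_model(f0_zero = 0, Kon = 1000, Koff = 10, L = 100)
#' ligand_free_energy(lig)    # log(10)
#' @export
ligand_model <- function(f0_zero = 0, Kon, Koff, L = 0) {
  if (!(is.numeric(Kon) && length(Kon) == 1L && Kon > 0) ||
      !(is.numeric(Koff) && length(Koff) == 1L && Koff > 0)) {
    stop("`Kon` and `Koff` must be positive", call. = FALSE)
  }
  stopifnot(is.numeric(f0_zero), length(f0_zero) == 1L, is.finite(f0_zero),
            is.numeric(L), length(L) == 1L, L >= 0)
  structure(list(f0_zero = f0_zero, Kon = Kon, Koff = Koff, L = L),
            class = "ligand_model")
}
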