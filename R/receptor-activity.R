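#' Ligand-dependent free-energy offset
#'
#' Effective free-energy offset of a receptor in the two-state binding model,
#' `f0(L) = f0(0) + log[(1 + L/Koff) / (1 + L/Kon)]` (kT). For an attractant
#' (`Koff < Kon`) the offset increases monotonically with ligand and saturates
#' at `f0(0) + log(Kon/Koff)`.
#'
#' @param lig A [ligand_model()] object.
#' @return Free-energy offset in kT (scalar).
#' @export
ligand_free_energy <- function(lig) {
  if (!inherits(lig, "ligand_model")) {
    stop("`lig` must be a `ligand_model` object", call. = FALSE)
  }
  lig$f0_zero + log((1 + lig$L / lig$Koff) / (1 + lig$L / lig$Kon))
}

#' Free-energy difference of a single receptor dimer
#'
#' Active-minus-inactive free-energy difference, expanded to first order in
#' temperature about the reference `T0` and linear in the methylation level:
#' `f = f0 + (T - T0) f1 - [g0 + (T - T0) g1] m` (kT). Methylation lowers the
#' free energy (favours the active state); its coefficient grows with
#' temperature, which is what makes the thermal response methylation-dependent.
#'
#' @param f0 Ligand-dependent free-energy offset (kT), e.g. from
#'   [ligand_free_energy()]. Vectorized.
#' @param T_c Temperature (degC). Vectorized.
#' @param m Methylation level per dimer, in `[0, mtot]`. Vectorized.
#' @param params A [model_params()] object.
#' @return Free-energy difference(s) in kT.
#' @examples
#' receptor_free_energy(0, T_c = 30, m = 6)   # 0: m = f1/g1 is T-insensitive
#' @export
receptor_free_energy <- function(f0, T_c, m, params = model_params()) {
  if (any(!is.finite(f0))) stop("`f0` must be finite", call. = FALSE)
  if (any(m < 0 | m > params$mtot)) {
    stop(sprintf("`m` must lie in [0, %g]", params$mtot), call. = FALSE)
  }
  dT <- T_c - params$T0
  f0 + dT * params$f1 - (params$g0 + dT * params$g1) * m
}

#' Activity of a receptor team (trimer of dimers)
#'
#' Probability that an allosterically coupled team of three receptor dimers is
#' active: `A = 1 / (1 + exp(F))` with `F` the sum of the member free
#' energies. All dimers share one methylation level `m`; a team holds `n_tar`
#' Tar and `3 - n_tar` Tsr dimers which may carry different ligand offsets.
#' The logistic is evaluated in a numerically safe form for large `|F|`.
#'
#' @param n_tar Number of Tar dimers in the team (0..3).
#' @param f0_tar,f0_tsr Ligand-dependent free-energy offsets (kT) of Tar and
#'   Tsr dimers.
#' @param T_c Temperature (degC).
#' @param m Shared methylation level per dimer, in `[0, mtot]`.
#' @param params A [model_params()] object.
#' @return Activity in (0, 1). Vectorized over `T_c` and `m`.
#' @examples
#' trimer_activity(3, 0, 0, T_c = 24, m = 0)  # F = 0 -> 0.5
#' @export
trimer_activity <- function(n_tar, f0_tar, f0_tsr, T_c, m,
                            params = model_params()) {
  if (!(n_tar %in% 0:3)) stop("`n_tar` must be 0, 1, 2 or 3", call. = FALSE)
  F_tot <- n_tar * receptor_free_energy(f0_tar, T_c, m, params) +
    (3 - n_tar) * receptor_free_energy(f0_tsr, T_c, m, params)
  stats::plogis(-F_tot)
}

## Team free energy without the [0, mtot] domain check on m; used internally
## where the perfect-adaptation (unbounded methylation) variant is allowed.
trimer_free_energy_unchecked <- function(n_tar, f0_tar, f0_tsr, T_c, m,
                                         params) {
  dT <- T_c - params$T0
  g <- params$g0 + dT * params$g1
  n_tar * f0_tar + (3 - n_tar) * f0_tsr + 3 * (dT * params$f1 - g * m)
}

trimer_activity_unchecked <- function(n_tar, f0_tar, f0_tsr, T_c, m, params) {
  stats::plogis(-trimer_free_energy_unchecked(n_tar, f0_tar, f0_tsr, T_c, m,
                                              params))
}

#' Binomial mixing distribution over trimer compositions
#'
#' With Tar and Tsr inserted at random into teams of three, the number of Tar
#' dimers per team is Binomial(3, `p_tar`). `p_tar = 0.5` corresponds to the
#' wild-type 1:1 expression ratio.
#'
#' @param p_tar Probability that a given dimer is Tar (fraction in `[0, 1]`).
#' @return A data frame with columns `n_tar` (3, 2, 1, 0) and `weight`
#'   (summing to 1).
#' @examples
#' trimer_mixing(0.5)   # weights 1/8, 3/8, 3/8, 1/8
#' @export
trimer_mixing <- function(p_tar) {
  if (!(is.numeric(p_tar) && length(p_tar) == 1L && p_tar >= 0 && p_tar <= 1)) {
    stop("`p_tar` must lie in [0, 1]", call. = FALSE)
  }
  n <- 3:0
  data.frame(n_tar = n, weight = stats::dbinom(n, size = 3, prob = p_tar))
}
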