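## Saturating occupancy factor x / (x + N0), with the N0 = 0 limit taken as an
## indicator of x > 0 (the factor is 1 in the interior and 0 at the boundary).
occupancy <- function(x, N0) {
  ifelse(x <= 0, 0, x / (x + N0))
}

#' Methylation kinetics rate
#'
#' Net methylation rate of a receptor dimer,
#' `dm/dt = gamma_R (mtot - m)/(mtot - m + N0) (1 - A)
#'        - gamma_B m/(m + N0) A`.
#' The occupancy factors slow methylation (demethylation) as `m` approaches
#' `mtot` (0); how abruptly is set by `N0`. With `N0 = 0` they equal 1 in the
#' interior and the kinetics implement perfect adaptation towards
#' `A = gamma_R / (gamma_R + gamma_B)`.
#'
#' @param m Methylation level(s), in `[0, mtot]`.
#' @param A Team activity(ies), in `[0, 1]`.
#' @param kinetics A [kinetics_params()] object.
#' @param params A [model_params()] object.
#' @return `dm/dt` in methyl groups per unit model time. The flux signs make
#'   the box `[0, mtot]` invariant: the rate is >= 0 at `m = 0` and <= 0 at
#'   `m = mtot`.
#' @export
methylation_rate <- function(m, A, kinetics = kinetics_params(),
                             params = model_params()) {
  stopifnot(all(m >= 0 & m <= params$mtot), all(A >= 0 & A <= 1))
  kinetics$gamma_R * occupancy(params$mtot - m, params$N0) * (1 - A) -
    kinetics$gamma_B * occupancy(m, params$N0) * A
}

#' Integrate the methylation kinetics in time
#'
#' Numerically integrates `dm/dt` with the activity re-evaluated at every
#' step, via [deSolve::ode()]. Intended for inspecting the approach to the
#' adapted state; the algebraic fixed point is available directly from
#' [solve_steady_state()].
#'
#' @param m0 Initial methylation level, in `[0, mtot]`.
#' @param activity_fn Function `(m, T_c) -> activity fraction`, e.g. a closure
#'   over [trimer_activity()].
#' @param T_c Temperature (degC), passed to `activity_fn`.
#' @param kinetics A [kinetics_params()] object.
#' @param params A [model_params()] object.
#' @param t_end Final model time (arbitrary units).
#' @param n_steps Number of output time points.
#' @return A data frame with columns `time` and `m` (clipped to `[0, mtot]`).
#' @examples
#' act <- function(m, T_c) trimer_activity(3, 0, 0, T_c, m)
#' traj <- integrate_methylation(0, act, T_c = 30, t_end = 100)
#' tail(traj, 1)
#' @export
integrate_methylation <- function(m0, activity_fn, T_c,
                                  kinetics = kinetics_params(),
                                  params = model_params(),
                                  t_end = 100, n_steps = 200L) {
  if (!(is.numeric(m0) && length(m0) == 1L && m0 >= 0 && m0 <= params$mtot)) {
    stop(sprintf("`m0` must lie in [0, %g]", params$mtot), call. = FALSE)
  }
  stopifnot(is.function(activity_fn), t_end > 0)
  rhs <- function(t, state, parms) {
    m <- min(max(state[[1L]], 0), params$mtot)
    A <- activity_fn(m, T_c)
    if (!is.finite(A)) stop("activity function returned a non-finite value",
                            call. = FALSE)
    list(methylation_rate(m, A, kinetics, params))
  }
  times <- seq(0, t_end, length.out = n_steps + 1L)
  sol <- deSolve::ode(y = c(m = m0), times = times, func = rhs, parms = NULL)
  data.frame(time = sol[, "time"],
             m = pmin(pmax(sol[, "m"], 0), params$mtot))
}

## Residual of the adapted-state balance at methylation m for one trimer:
## h(m) = (mtot-m)/(mtot-m+N0) (1-A)/(1-A0) - m/(m+N0) A/A0.
## h(0) >= 0 and h(mtot) <= 0, so a root is always bracketed on [0, mtot].
steady_state_residual <- function(m, n_tar, f0_tar, f0_tsr, T_c, params) {
  A <- trimer_activity_unchecked(n_tar, f0_tar, f0_tsr, T_c, m, params)
  occupancy(params$mtot - m, params$N0) * (1 - A) / (1 - params$A0) -
    occupancy(m, params$N0) * A / params$A0
}

#' Adapted steady-state methylation of one trimer composition
#'
#' Solves the steady-state balance of the methylation kinetics for the shared
#' methylation level `m_ss` of a team with `n_tar` Tar dimers, at temperature
#' `T_c` and given ligand offsets. The root of the residual
#' `h(m) = (mtot-m)/(mtot-m+N0)*(1-A)/(1-A0) - m/(m+N0)*A/A0`
#' is bracketed on `[0, mtot]` and located by bisection (interval tolerance
#' 1e-12, 200 iterations; exact ties resolve to the lower `m`).
#'
#' With `N0 = 0` the balance reduces to perfect adaptation `A(m_ss) = A0`,
#' solved in closed form. `unbounded_m = TRUE` (only meaningful with
#' `N0 = 0`) removes the `[0, mtot]` box so adaptation is exact at any free
#' energy; otherwise the closed-form root is clipped to the box and flagged as
#' a boundary solution. When the methylation coefficient
#' `g = g0 + (T - T0) g1` is not positive, activity does not decrease with
#' `m`: the saturating solver still has a unique root (the occupancy factors
#' are monotone) but the unbounded perfect-adaptation state does not exist and
#' a degenerate `NA` state is returned with a warning.
#'
#' @param n_tar Number of Tar dimers in the team (0..3).
#' @param f0_tar,f0_tsr Ligand free-energy offsets (kT).
#' @param T_c Temperature (degC).
#' @param params A [model_params()] object.
#' @param unbounded_m Allow `m_ss` outside `[0, mtot]` (perfect-adaptation
#'   variant, requires `N0 = 0`).
#' @return An object of class `adapted_state`: a list with `m_ss`, `A`
#'   (activity at `m_ss`), `boundary` (logical: root clipped or degenerate),
#'   `residual` (value of `h` at `m_ss`), and the inputs.
#' @examples
#' st <- solve_steady_state(3, 0, 0, T_c = 30)
#' st$m_ss; st$A
#' @export
solve_steady_state <- function(n_tar, f0_tar, f0_tsr, T_c,
                               params = model_params(),
                               unbounded_m = FALSE) {
  if (!(n_tar %in% 0:3)) stop("`n_tar` must be 0, 1, 2 or 3", call. = FALSE)
  if (unbounded_m && params$N0 != 0) {
    stop("`unbounded_m = TRUE` requires `N0 = 0`", call. = FALSE)
  }
  g <- params$g0 + (T_c - params$T0) * params$g1
  out <- list(n_tar = n_tar, f0_tar = f0_tar, f0_tsr = f0_tsr, T_c = T_c,
              params = params, unbounded_m = unbounded_m)

  if (params$N0 == 0) {
    # Perfect adaptation: A(m_ss) = A0, i.e. F(m_ss) = log((1 - A0)/A0).
    if (g <= 0) {
      if (unbounded_m) {
        warning(sprintf(
          "methylation coefficient g = %g <= 0 at T = %g degC: no adapted state exists in the unbounded perfect-adaptation variant",
          g, T_c))
        out$m_ss <- NA_real_
        out$A <- NA_real_
        out$boundary <- TRUE
        out$residual <- NA_real_
        class(out) <- "adapted_state"
        return(out)
      }
      # Bounded N0 = 0 with g <= 0: activity cannot be tuned by m; report the
      # boundary favoured by the flux sign at the midpoint.
      A_mid <- trimer_activity_unchecked(n_tar, f0_tar, f0_tsr, T_c,
                                         params$mtot / 2, params)
      m_root <- if (A_mid > params$A0) 0 else params$mtot
      out$m_ss <- m_root
      out$A <- trimer_activity_unchecked(n_tar, f0_tar, f0_tsr, T_c, m_root,
                                         params)
      out$boundary <- TRUE
      out$residual <- NA_real_
      class(out) <- "adapted_state"
      return(out)
    }
    F0 <- trimer_free_energy_unchecked(n_tar, f0_tar, f0_tsr, T_c, 0, params)
    m_root <- (F0 - log((1 - params$A0) / params$A0)) / (3 * g)
    boundary <- FALSE
    if (!unbounded_m) {
      clipped <- min(max(m_root, 0), params$mtot)
      boundary <- clipped != m_root
      m_root <- clipped
    }
    out$m_ss <- m_root
    out$A <- trimer_activity_unchecked(n_tar, f0_tar, f0_tsr, T_c, m_root,
                                       params)
    out$boundary <- boundary
    out$residual <- if (boundary) NA_real_ else
      (1 - out$A) / (1 - params$A0) - out$A / params$A0
    class(out) <- "adapted_state"
    return(out)
  }

  h <- function(m) steady_state_residual(m, n_tar, f0_tar, f0_tsr, T_c, params)
  lo <- 0
  hi <- params$mtot
  h_lo <- h(lo)
  h_hi <- h(hi)
  if (h_lo <= 0) {        # h(0) = occ(mtot)(1-A(0))/(1-A0) >= 0 always; = 0
    out$m_ss <- 0         # only if A(0) = 1 exactly (unreachable for finite F)
    out$boundary <- TRUE
  } else if (h_hi >= 0) {
    out$m_ss <- params$mtot
    out$boundary <- TRUE
  } else {
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      h_mid <- h(mid)
      if (h_mid == 0) { lo <- hi <- mid; break }  # exact tie -> keep lower end
      if (h_mid > 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-12) break
    }
    out$m_ss <- lo
    out$boundary <- FALSE
  }
  out$A <- trimer_activity_unchecked(n_tar, f0_tar, f0_tsr, T_c, out$m_ss,
                                     params)
  out$residual <- h(out$m_ss)
  class(out) <- "adapted_state"
  out
}

#' @export
print.adapted_state <- function(x, ...) {
  cat(sprintf(
    "Adapted trimer state (n_tar = %d, T = %g degC): m_ss = %.6g, A = %.6g%s\n",
    x$n_tar, x$T_c, x$m_ss, x$A,
    if (isTRUE(x$boundary)) " [boundary]" else ""))
  invisible(x)
}

#' Adapted activity of a mixed-receptor trimer ensemble
#'
#' Adapts each of the four trimer compositions (0-3 Tar dimers) independently
#' at temperature `T_c` — every dimer within a team shares one methylation
#' level — and averages their activities with binomial mixing weights.
#'
#' @param p_tar Fraction of Tar among receptor dimers (1:1 expression gives
#'   0.5).
#' @param f0_tar,f0_tsr Ligand free-energy offsets (kT) for Tar and Tsr.
#' @param T_c Temperature (degC).
#' @param params A [model_params()] object.
#' @param unbounded_m Passed to [solve_steady_state()].
#' @return A list with `A_bar` (weighted mean activity) and `states`, a data
#'   frame with one row per composition: `n_tar`, `weight`, `m_ss`, `A`,
#'   `boundary`.
#' @examples
#' ens <- ensemble_adapted_activity(0.5, f0_tar = 15, f0_tsr = 0, T_c = 30)
#' ens$A_bar
#' ens$states
#' @export
ensemble_adapted_activity <- function(p_tar, f0_tar, f0_tsr, T_c,
                                      params = model_params(),
                                      unbounded_m = FALSE) {
  mix <- trimer_mixing(p_tar)
  states <- lapply(mix$n_tar, function(n) {
    solve_steady_state(n, f0_tar, f0_tsr, T_c, params, unbounded_m)
  })
  df <- data.frame(
    n_tar = mix$n_tar,
    weight = mix$weight,
    m_ss = vapply(states, `[[`, numeric(1), "m_ss"),
    A = vapply(states, `[[`, numeric(1), "A"),
    boundary = vapply(states, `[[`, logical(1), "boundary")
  )
  list(A_bar = sum(df$weight * df$A), states = df)
}
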