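#' Normalized thermal-response curve of a receptor ensemble
#'
#' For every temperature `T` on the grid, adapts the trimer ensemble at `T`
#' and computes the normalized response to a step of `dT_step`:
#' `R(T) = [A_bar(T + dT) - A_bar(T)] / dA_norm`.
#'
#' In the default `mode = "transient"`, `A_bar(T + dT)` is evaluated with each
#' trimer's methylation frozen at its `T`-adapted value — the initial response
#' amplitude a kinase-activity (FRET-type) readout measures before adaptation
#' catches up. `mode = "re_adapted"` instead re-adapts at `T + dT`, which is
#' identically zero under perfect adaptation.
#'
#' The normalization `dA_norm` is the activity drop at the lowest grid
#' temperature when the cognate receptor (default Tar) is driven to ligand
#' saturation: the ensemble is adapted there with no ligand, then the
#' saturating offset `f0_sat` is applied with methylation frozen, and
#' `dA_norm` is the difference between the two ensemble activities.
#'
#' Negative `R` means kinase activity falls on warming — an attractant-like,
#' thermophilic response; positive `R` is cryophilic.
#'
#' @param p_tar Fraction of Tar dimers (0.5 for 1:1 Tar:Tsr).
#' @param f0_tar,f0_tsr Ligand free-energy offsets (kT).
#' @param T_grid Ascending temperature grid (degC). Default 24 to 39 in 3 degC
#'   steps.
#' @param params A [model_params()] object.
#' @param mode `"transient"` (default) or `"re_adapted"`, see Details.
#' @param unbounded_m Use the unbounded perfect-adaptation solver (requires
#'   `N0 = 0`).
#' @param sat_receptor Receptor driven to saturation for the normalization,
#'   `"Tar"` or `"Tsr"`. Defaults to `"Tar"`, or `"Tsr"` for a Tar-free
#'   ensemble (`p_tar = 0`), so the saturating stimulus always engages a
#'   receptor that is present.
#' @param tol Classification tolerance: points with `|R| <= tol` are labelled
#'   `"none"`.
#' @return An object of class `thermal_response`: list with `curve` (data
#'   frame `T_c`, `A_bar`, `A_post`, `R`, `class`), `delta_A_norm`, `T_inv`
#'   (linear-interpolated inversion temperature or `NA`), and the call
#'   settings.
#' @examples
#' tr <- thermal_response_curve(p_tar = 1, f0_tar = 0, f0_tsr = 0)
#' tr$curve$R        # all negative: thermophilic at low methylation
#' @export
thermal_response_curve <- function(p_tar, f0_tar, f0_tsr,
                                   T_grid = seq(24, 39, by = 3),
                                   params = model_params(),
                                   mode = c("transient", "re_adapted"),
                                   unbounded_m = FALSE,
                                   sat_receptor = NULL,
                                   tol = 1e-6) {
  mode <- match.arg(mode)
  if (is.null(sat_receptor)) sat_receptor <- if (p_tar > 0) "Tar" else "Tsr"
  sat_receptor <- match.arg(sat_receptor, c("Tar", "Tsr"))
  if (is.unsorted(T_grid, strictly = TRUE)) {
    stop("`T_grid` must be strictly ascending", call. = FALSE)
  }
  dT <- params$dT_step

  frozen_A_bar <- function(states, f_tar, f_tsr, T_eval) {
    A <- mapply(function(n, m) {
      if (is.na(m)) return(NA_real_)
      trimer_activity_unchecked(n, f_tar, f_tsr, T_eval, m, params)
    }, states$n_tar, states$m_ss)
    sum(states$weight * A)
  }

  # Normalization: saturate the cognate receptor at the lowest grid
  # temperature, methylation frozen at the no-ligand adapted state. If the
  # adapted state is degenerate there (unbounded perfect adaptation at
  # g <= 0), use the lowest grid temperature where it exists.
  ens0 <- NULL
  T_min <- NA_real_
  for (T_try in T_grid) {
    ens_try <- suppressWarnings(
      ensemble_adapted_activity(p_tar, 0, 0, T_try, params, unbounded_m))
    if (!anyNA(ens_try$states$m_ss)) {
      ens0 <- ens_try
      T_min <- T_try
      break
    }
  }
  if (is.null(ens0)) {
    stop("no grid temperature admits an adapted state for the normalization",
         call. = FALSE)
  }
  A_sat <- if (sat_receptor == "Tar") {
    frozen_A_bar(ens0$states, params$f0_sat, 0, T_min)
  } else {
    frozen_A_bar(ens0$states, 0, params$f0_sat, T_min)
  }
  delta_A_norm <- ens0$A_bar - A_sat
  if (!is.finite(delta_A_norm) || delta_A_norm <= 0) {
    stop("normalization failed: saturating the cognate receptor did not lower ensemble activity",
         call. = FALSE)
  }

  rows <- lapply(T_grid, function(T_c) {
    ens <- ensemble_adapted_activity(p_tar, f0_tar, f0_tsr, T_c, params,
                                     unbounded_m)
    A_post <- if (mode == "transient") {
      frozen_A_bar(ens$states, f0_tar, f0_tsr, T_c + dT)
    } else {
      ensemble_adapted_activity(p_tar, f0_tar, f0_tsr, T_c + dT, params,
                                unbounded_m)$A_bar
    }
    c(A_bar = ens$A_bar, A_post = A_post)
  })
  A_bar <- vapply(rows, `[[`, numeric(1), "A_bar")
  A_post <- vapply(rows, `[[`, numeric(1), "A_post")
  R <- (A_post - A_bar) / delta_A_norm
  cls <- ifelse(is.na(R), NA_character_,
                ifelse(R < -tol, "thermophilic",
                       ifelse(R > tol, "cryophilic", "none")))
  curve <- data.frame(T_c = T_grid, A_bar = A_bar, A_post = A_post, R = R,
                      class = cls)
  out <- structure(
    list(curve = curve, delta_A_norm = delta_A_norm, T_inv = NA_real_,
         p_tar = p_tar, f0_tar = f0_tar, f0_tsr = f0_tsr, mode = mode,
         unbounded_m = unbounded_m, params = params, tol = tol),
    class = "thermal_response")
  out$T_inv <- find_inversion_temperature(out)
  out
}

#' Inversion temperature of a thermal-response curve
#'
#' Scans the grid for the first adjacent pair with a strict sign change in the
#' response and returns the linearly interpolated zero crossing. Pairs
#' containing `NA` responses are skipped. Returns `NA` when the response never
#' changes sign — e.g. for a single receptor type, or a mixed ensemble under
#' perfect adaptation.
#'
#' @param x A `thermal_response` object from [thermal_response_curve()].
#' @return Inversion temperature (degC) or `NA_real_`.
#' @export
find_inversion_temperature <- function(x) {
  if (!inherits(x, "thermal_response")) {
    stop("`x` must be a `thermal_response` object", call. = FALSE)
  }
  Tg <- x$curve$T_c
  R <- x$curve$R
  for (i in seq_len(length(R) - 1L)) {
    r1 <- R[[i]]
    r2 <- R[[i + 1L]]
    if (is.na(r1) || is.na(r2)) next
    if (r1 * r2 < 0) {
      return(Tg[[i]] + (Tg[[i + 1L]] - Tg[[i]]) * r1 / (r1 - r2))
    }
  }
  NA_real_
}

#' @export
print.thermal_response <- function(x, ...) {
  cat(sprintf(
    "Thermal response curve (p_tar = %g, f0_Tar = %g, f0_Tsr = %g, mode = %s)\n",
    x$p_tar, x$f0_tar, x$f0_tsr, x$mode))
  cat(sprintf("  normalization dA = %.6g\n", x$delta_A_norm))
  if (is.na(x$T_inv)) {
    cat("  no inversion temperature on the grid\n")
  } else {
    cat(sprintf("  inversion temperature: %.3f degC\n", x$T_inv))
  }
  print(x$curve[, c("T_c", "R", "class")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.thermal_response <- function(x, ...) {
  cols <- c(thermophilic = "firebrick", cryophilic = "steelblue",
            none = "grey60")
  graphics::plot(x$curve$T_c, x$curve$R, type = "b", pch = 19,
                 col = cols[x$curve$class],
                 xlab = "Temperature (degC)", ylab = "Normalized response R",
                 ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  if (!is.na(x$T_inv)) graphics::abline(v = x$T_inv, lty = 3)
  invisible(x)
}
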