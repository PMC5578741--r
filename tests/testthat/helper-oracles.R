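# Independent oracles used across test files. These re-derive quantities from
# first principles (dense scans, direct arithmetic) and never call the code
# paths they are used to check.

# Residual of the adapted-state balance, written out from the model equations.
oracle_residual <- function(m, n_tar, f0_tar, f0_tsr, T_c, p) {
  g <- p$g0 + (T_c - p$T0) * p$g1
  f_tar <- f0_tar + (T_c - p$T0) * p$f1 - g * m
  f_tsr <- f0_tsr + (T_c - p$T0) * p$f1 - g * m
  A <- 1 / (1 + exp(n_tar * f_tar + (3 - n_tar) * f_tsr))
  occ <- function(x) ifelse(x <= 0, 0, x / (x + p$N0))
  occ(p$mtot - m) * (1 - A) / (1 - p$A0) - occ(m) * A / p$A0
}

# Dense-grid root of the balance residual (bracket midpoint; half-spacing
# accuracy). Falls back to the boundary dictated by the residual sign.
oracle_steady_state <- function(n_tar, f0_tar, f0_tsr, T_c, p,
                                n_grid = 1e5) {
  m <- seq(0, p$mtot, length.out = n_grid)
  h <- oracle_residual(m, n_tar, f0_tar, f0_tsr, T_c, p)
  j <- which(h[-length(h)] > 0 & h[-1] <= 0)[1]
  if (is.na(j)) {
    if (h[1] <= 0) 0 else p$mtot
  } else {
    (m[j] + m[j + 1]) / 2
  }
}

# Direct arithmetic re-evaluation of the thermal migration coefficient.
oracle_tmc <- function(x, x_min, x_max) {
  -2 * ((mean(x) - x_min) / (x_max - x_min) - 0.5)
}
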