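test_that("ligand free-energy offset follows the two-state binding form", {
  # no ligand leaves the offset unchanged
  expect_equal(ligand_free_energy(ligand_model(0, Kon = 1000, Koff = 10,
                                               L = 0)), 0)
  # direct arithmetic: log((1 + 100/10) / (1 + 100/1000)) = log(10)
  expect_equal(ligand_free_energy(ligand_model(0, Kon = 1000, Koff = 10,
                                               L = 100)), log(10))
  # saturation limit log(Kon/Koff)
  expect_equal(ligand_free_energy(ligand_model(0, Kon = 1000, Koff = 10,
                                               L = 1e12)), log(100),
               tolerance = 1e-8)
  # attractant: offset increases with ligand and exceeds f0_zero
  f_lo <- ligand_free_energy(ligand_model(0.3, Kon = 1000, Koff = 10, L = 1))
  f_hi <- ligand_free_energy(ligand_model(0.3, Kon = 1000, Koff = 10, L = 50))
  expect_gt(f_lo, 0.3)
  expect_gt(f_hi, f_lo)
  expect_error(ligand_model(0, Kon = -1, Koff = 10), "positive")
})

test_that("receptor free energy is linear in temperature and methylation", {
  p <- model_params()
  expect_equal(receptor_free_energy(0, 24, 4, p), 0)   # T = T0, g0 = 0
  # m = f1/g1 = 6 is the temperature-insensitive methylation level
  expect_equal(receptor_free_energy(0, 30, 6, p), 7.2 - 1.2 * 6)
  expect_equal(receptor_free_energy(1.5, 27, 2, p), 1.5 + 3.6 - 1.2)
  expect_error(receptor_free_energy(0, 30, 9, p), "\\[0, 8\\]")
  expect_error(receptor_free_energy(0, 30, -0.1, p), "\\[0, 8\\]")
})

test_that("team activity is the logistic of the summed free energies", {
  p <- model_params()
  expect_equal(trimer_activity(3, 0, 0, 24, 0, p), 0.5)  # F = 0
  # F = log 2 -> A = 1/3: choose f0 so that 3 * f0 = log(2) at T = T0
  expect_equal(trimer_activity(3, log(2) / 3, 0, 24, 0, p), 1 / 3)
  # saturation without overflow
  expect_equal(trimer_activity(3, 500, 500, 24, 0, p), 0)
  expect_equal(trimer_activity(3, -500, -500, 24, 0, p), 1)
  # bounds hold wherever the team free energy stays within double precision
  for (f0 in c(-8, -5, 0, 5, 8)) {
    A <- trimer_activity(2, f0, 0, 35, 4, p)
    expect_true(A > 0 && A < 1)
  }
  expect_error(trimer_activity(4, 0, 0, 24, 0, p), "n_tar")
})

test_that("trimer mixing weights are Binomial(3, p_tar)", {
  expect_equal(trimer_mixing(1)$weight, c(1, 0, 0, 0))
  expect_equal(trimer_mixing(0.5)$weight, c(1, 3, 3, 1) / 8)
  expect_equal(trimer_mixing(0.25)$weight, c(1, 9, 27, 27) / 64)
  expect_equal(sum(trimer_mixing(0.37)$weight), 1, tolerance = 1e-12)
  expect_error(trimer_mixing(1.2), "\\[0, 1\\]")
})

test_that("methylation rate has the saturating two-arm form", {
  p0 <- model_params(N0 = 0)
  kin <- kinetics_params(gamma_R = 0.4, gamma_B = 0.8)
  # pure demethylation at full activity, N0 = 0, interior m
  expect_equal(methylation_rate(3, 1, kin, p0), -0.8)
  # the gamma_R/(gamma_R + gamma_B) fixed point has zero net rate
  expect_equal(methylation_rate(3, 0.4 / 1.2, kin, p0), 0, tolerance = 1e-15)
  # boundary fluxes keep [0, mtot] invariant
  p <- model_params()
  expect_gte(methylation_rate(0, 0.7, kin, p), 0)
  expect_lte(methylation_rate(p$mtot, 0.2, kin, p), 0)
})

test_that("steady-state solver matches closed forms at default parameters", {
  # perfect adaptation (N0 = 0): activity at the root is exactly A0
  p0 <- model_params(N0 = 0)
  st <- solve_steady_state(3, 0, 0, 30, p0, unbounded_m = TRUE)
  expect_equal(st$A, 1 / 3, tolerance = 1e-10)
  # analytic root: 3 * (7.2 - 1.2 m) = log((1 - A0)/A0)
  expect_equal(st$m_ss, (7.2 - log(2) / 3) / 1.2, tolerance = 1e-10)
  # saturating solver at defaults: residual vanishes at the root
  p <- model_params()
  st2 <- solve_steady_state(3, 0, 0, 30, p)
  expect_lt(abs(st2$residual), 1e-10)
  expect_false(st2$boundary)
  # asymptotic methylation approaches f1/g1 = 6
  expect_equal(solve_steady_state(3, 0, 0, 24 + 1000, p)$m_ss, 6,
               tolerance = 0.05)
  expect_error(solve_steady_state(3, 0, 0, 30, p, unbounded_m = TRUE),
               "N0")
})

test_that("bisection root matches a dense-scan oracle on random draws", {
  set.seed(42)
  for (i in 1:200) {
    N0 <- runif(1, 0, 5)
    f0 <- runif(1, 0, 15)
    T_c <- 24 + runif(1, 1e-3, 20)
    n_tar <- sample(0:3, 1)
    p <- model_params(N0 = N0)
    st <- solve_steady_state(n_tar, f0, 0, T_c, p)
    expect_lt(abs(st$m_ss - oracle_steady_state(n_tar, f0, 0, T_c, p)), 1e-4)
    # the kinetics are stationary at the root when gamma_R/gamma_B = A0/(1-A0)
    rate <- methylation_rate(st$m_ss, st$A, kinetics_params(params = p), p)
    expect_lt(abs(rate), 1e-8)
  }
})

test_that("adapted methylation rises with temperature and with ligand", {
  p <- model_params()
  # monotone approach to f1/g1 from below for a single receptor type
  m_T <- vapply(24 + c(6, 30, 100, 1000), function(T_c) {
    solve_steady_state(3, 0, 0, T_c, p)$m_ss
  }, numeric(1))
  expect_true(all(diff(m_T) > 0))
  expect_true(all(m_T < 6))
  # non-decreasing in the ligand offset at fixed temperature
  m_f <- vapply(c(0, 0.5, 1.5, 2.5, 5, 15), function(f0) {
    solve_steady_state(3, f0, f0, 32, p)$m_ss
  }, numeric(1))
  expect_true(all(diff(m_f) >= 0))
})

test_that("ODE integration converges to the algebraic fixed point", {
  set.seed(7)
  for (i in 1:10) {
    N0 <- runif(1, 0, 5)
    f0 <- runif(1, 0, 15)
    T_c <- 24 + runif(1, 0.5, 20)
    n_tar <- sample(0:3, 1)
    p <- model_params(N0 = N0)
    st <- solve_steady_state(n_tar, f0, 0, T_c, p)
    act <- function(m, T_now) trimer_activity(n_tar, f0, 0, T_now, m, p)
    traj <- integrate_methylation(4, act, T_c, kinetics_params(params = p),
                                  p, t_end = 3000)
    expect_lt(abs(traj$m[nrow(traj)] - st$m_ss), 1e-4)
  }
  # starting at the fixed point stays there
  p <- model_params()
  st <- solve_steady_state(3, 0, 0, 30, p)
  act <- function(m, T_now) trimer_activity(3, 0, 0, T_now, m, p)
  traj <- integrate_methylation(st$m_ss, act, 30, kinetics_params(params = p),
                                p, t_end = 50)
  expect_equal(max(abs(traj$m - st$m_ss)), 0, tolerance = 1e-6)
})

test_that("forced full activity with N0 = 0 demethylates linearly to zero", {
  p0 <- model_params(N0 = 0)
  kin <- kinetics_params(gamma_R = 0.5, gamma_B = 1)
  traj <- integrate_methylation(2, function(m, T_c) 1, 30, kin, p0,
                                t_end = 4, n_steps = 400)
  expect_equal(traj$m[traj$time <= 1.9],
               2 - traj$time[traj$time <= 1.9], tolerance = 1e-4)
  expect_equal(traj$m[traj$time >= 2.2],
               rep(0, sum(traj$time >= 2.2)), tolerance = 1e-4)
})

test_that("ensemble averaging respects symmetry and saturation ordering", {
  p <- model_params()
  # identical offsets make all compositions identical
  ens <- ensemble_adapted_activity(0.5, 1.2, 1.2, 31, p)
  expect_equal(diff(range(ens$states$A)), 0, tolerance = 1e-12)
  expect_equal(ens$A_bar, ens$states$A[1], tolerance = 1e-12)
  # perfect adaptation: ensemble activity is A0 regardless of composition
  p0 <- model_params(N0 = 0)
  ens0 <- ensemble_adapted_activity(0.5, 4, 1, 33, p0, unbounded_m = TRUE)
  expect_equal(ens0$A_bar, 1 / 3, tolerance = 1e-10)
  # Tar-saturating ligand: methylation increases with Tar content
  ens_mix <- ensemble_adapted_activity(0.5, 15, 0, 30, p)
  ord <- order(ens_mix$states$n_tar)
  expect_true(all(diff(ens_mix$states$m_ss[ord]) > 0))
})
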