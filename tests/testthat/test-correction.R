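test_that("scaling factors restore the charge rule exactly", {
  ## already satisfied: f = 1 and charges untouched
  q_N <- c(-2, -3)  # sums to -Q_N with Q_N = 5
  q_e <- c(4, 4)    # sums to -Q_e with Q_e = -8
  r <- correct_scale(q_N, q_e, 5, -8)
  expect_equal(r$f_N, 1)
  expect_equal(r$f_e, 1)
  expect_equal(r$q_N, q_N)
  ## Q_e = -8 e but the electronic sum is only 7.92 e: f_e = 8/7.92
  q_e2 <- c(4, 3.92)
  r2 <- correct_scale(q_N, q_e2, 5, -8)
  expect_equal(r2$f_e, 8 / 7.92, tolerance = 1e-12)
  expect_equal(sum(r2$q_e), 8, tolerance = 1e-12)
  expect_lt(abs(r2$defect_after), 1e-12)
  ## zero-charge component with zero sum passes through; otherwise error
  r3 <- correct_scale(q_N, numeric(0), 5, 0)
  expect_equal(r3$f_e, 1)
  expect_error(correct_scale(numeric(0), q_e, 5, -8), "nuclear")
})

test_that("Lagrangian correction solves the constrained minimization", {
  set.seed(21)
  B <- matrix(rnorm(25), 5)
  A <- crossprod(B) + diag(5)
  phi <- rnorm(5)
  Q <- 0.7
  r <- correct_lagrangian(A, phi, Q)
  expect_equal(sum(r$q), -Q, tolerance = 1e-12)
  ## independent oracle: minimize the functional over the feasible set
  ## parameterized as q = q0 + N z, N a null-space basis of 1^T
  q0 <- rep(-Q / 5, 5)
  N <- qr.Q(qr(cbind(rep(1, 5))), complete = TRUE)[, 2:5]
  fun <- function(z) {
    q <- q0 + N %*% z
    0.5 * crossprod(q, A %*% q) + sum(phi * q)
  }
  opt <- optim(rep(0, 4), fun, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  q_oracle <- q0 + drop(N %*% opt$par)
  expect_equal(r$q, q_oracle, tolerance = 1e-6)
  ## optimality: feasible perturbations only increase the functional
  f_star <- drop(0.5 * crossprod(r$q, A %*% r$q)) + sum(phi * r$q)
  for (i in 1:20) {
    dz <- rnorm(4, sd = 0.1)
    q_pert <- r$q + drop(N %*% dz)
    f_pert <- drop(0.5 * crossprod(q_pert, A %*% q_pert)) + sum(phi * q_pert)
    expect_gt(f_pert, f_star)
  }
  ## if the unconstrained solution already satisfies the constraint,
  ## lambda = 0 and q' is the plain conductor solution
  q_uncon <- drop(-solve(A, phi))
  r0 <- correct_lagrangian(A, phi, -sum(q_uncon))
  expect_equal(r0$lambda, 0, tolerance = 1e-12)
  expect_equal(r0$q, q_uncon, tolerance = 1e-10)
})

test_that("corrected potentials follow Phi' = -A q' with the nuclear part removed", {
  set.seed(3)
  B <- matrix(rnorm(16), 4)
  A <- crossprod(B) + diag(4)
  phi_N <- rnorm(4); phi_e <- rnorm(4)
  phi <- phi_N + phi_e
  q <- solve_screening(A, phi = phi)$q
  ## no correction: the boundary condition gives back the input potential
  cp <- corrected_potential(A, q, phi_N)
  expect_equal(cp$phi, phi, tolerance = 1e-10)
  expect_equal(cp$phi_e, phi_e, tolerance = 1e-10)
  ## zero charges: zero potential, electronic part is minus the nuclear
  cp0 <- corrected_potential(A, rep(0, 4), phi_N)
  expect_equal(cp0$phi, rep(0, 4))
  expect_equal(cp0$phi_e, -phi_N)
})

test_that("dielectric energy identities hold", {
  expect_equal(dielectric_energy(c(1, 2), c(0, 0))$hartree, 0)
  e <- dielectric_energy(c(0.5, -0.5), c(-0.1, 0.2))
  expect_equal(e$kcal, e$hartree * HARTREE_KCAL)
  ## Born ion through the KS pipeline, within 0.5% of -q^2/2R
  E <- born_energy("fine", R_ang = 2, method = "ks")
  expect_equal(E, born_exact(1, 2), tolerance = 5e-3)
  expect_lt(E, 0)
})

test_that("charge_defect is the signed Gauss-law residual", {
  q <- rep(-2 / 60, 60)  # uniform charges summing to -Q
  expect_equal(charge_defect(q, 2), 0)
  expect_equal(charge_defect(c(0.1, 0.2), -0.5), -0.2)
})

test_that("corrections move the potential and the energy on an outlying-charge case", {
  res_corr <- run_cosmo(cosmo_config(fixture = "born_anion", method = "ks",
                                     charge_correction = "scale"))
  res_leg <- run_cosmo(cosmo_config(fixture = "born_anion", method = "ks",
                                    charge_correction = "scale",
                                    potcorr = TRUE))
  ## potential correction is a real change...
  expect_gt(max(abs(res_corr$potentials$phi_used - res_corr$potentials$phi)), 0)
  ## ...and shifts the energy relative to the legacy path
  expect_gt(abs(res_corr$energy$E_diel_kcal - res_leg$energy$E_diel_kcal),
            1e-3)
  ## the legacy flag gates only the energy expression, not the charges
  expect_equal(res_leg$charges$q, res_corr$charges$q, tolerance = 1e-12)
  ## uncorrected defect is real but substantially smaller than the
  ## outlying charge itself (the conductor picture already absorbs most
  ## of the tail)
  res_off <- run_cosmo(cosmo_config(fixture = "born_anion", method = "ks",
                                    charge_correction = "off"))
  fx <- make_fixture("born_anion")
  out <- abs(charge_outside_cavity(fx$solute, fx$spheres))
  expect_gt(abs(res_off$log$defect_after), 1e-4)
  expect_lt(abs(res_off$log$defect_after), out)
})

test_that("with no outlying charge, corrections leave the energy unchanged", {
  ## born_ion has no clouds: the only defect is discretization noise
  E_off <- run_cosmo(cosmo_config(fixture = "born_ion", method = "ks",
                                  charge_correction = "off"))$energy$E_diel
  E_lag <- run_cosmo(cosmo_config(fixture = "born_ion", method = "ks",
                                  charge_correction = "lagrangian"))$energy$E_diel
  E_scl <- run_cosmo(cosmo_config(fixture = "born_ion", method = "ks",
                                  charge_correction = "scale"))$energy$E_diel
  expect_equal(E_lag, E_off, tolerance = 1e-3)
  expect_equal(E_scl, E_off, tolerance = 1e-3)
})
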