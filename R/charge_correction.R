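## Outlying-charge corrections. Discretization error and solute electron
## density outside the cavity leave the screening charges violating the
## charge rule -Q = 1^T q. Two global fixes are provided: per-component
## scaling factors (f = -Q / 1^T q, applied separately to the nuclear and
## electronic parts) and a Lagrange-multiplier constrained minimization of
## the conductor energy functional. In either case the surface potential is
## rebuilt from the corrected charges, Phi' = -A q', so that all energies
## use mutually consistent charges and potentials; the legacy behaviour
## (charges corrected, potential left alone) remains available as `potcorr`.

#' Scaling-factor outlying charge correction
#'
#' Enforces the charge rule `-Q_N = 1^T q_N`, `-Q_e = 1^T q_e` by
#' per-component scaling: `f = -Q / (1^T q)`, `q' = f q`. With this sign
#' convention the corrected sums satisfy the rule exactly and the factors
#' are near +1 for well-discretized cavities (the nuclear factor would be
#' exactly 1 for perfect discretization, as all nuclear charge is inside
#' the cavity). A component with zero total charge and zero charge sum is
#' left untouched (`f = 1`).
#'
#' @param q_N,q_e Nuclear and electronic screening charge vectors (e).
#' @param Q_N,Q_e Total nuclear and electronic solute charges (e).
#' @return List with `q_N`, `q_e`, `q = q_N + q_e`, `f_N`, `f_e`,
#'   `defect_before`, `defect_after`.
#' @export
correct_scale <- function(q_N, q_e, Q_N, Q_e) {
  factor_for <- function(qsum, Q, label) {
    if (abs(qsum) < 1e-300) {
      if (abs(Q) < 1e-12) return(1)
      stop("cannot scale ", label, " charges: zero charge sum with Q = ", Q)
    }
    -Q / qsum
  }
  f_N <- factor_for(sum(q_N), Q_N, "nuclear")
  f_e <- factor_for(sum(q_e), Q_e, "electronic")
  defect_before <- sum(q_N) + sum(q_e) + Q_N + Q_e
  q_Np <- f_N * q_N
  q_ep <- f_e * q_e
  list(q_N = q_Np, q_e = q_ep, q = q_Np + q_ep, f_N = f_N, f_e = f_e,
       defect_before = defect_before,
       defect_after = sum(q_Np) + sum(q_ep) + Q_N + Q_e)
}

#' Lagrange-multiplier outlying charge correction
#'
#' Minimizes the conductor energy functional `1/2 q^T A q + Phi^T q`
#' subject to Gauss's law `1^T q = -Q_total`. The solution is the linear
#' system `q' = -A^{-1}(Phi + lambda 1)` with
#' `lambda = (Q_total - 1^T A^{-1} Phi) / (1^T A^{-1} 1)`.
#'
#' @param A A `coulomb_matrix` or plain SPD matrix.
#' @param phi Total solute potential on segments (a.u.).
#' @param Q_total Total solute charge `Q_N + Q_e` (e).
#' @param method Linear solver passed to the SPD solve.
#' @return List with `q` (corrected charges), `lambda`, `defect_before`,
#'   `defect_after`.
#' @export
correct_lagrangian <- function(A, phi, Q_total,
                               method = c("auto", "dense", "iterative")) {
  method <- match.arg(method)
  M <- if (inherits(A, "coulomb_matrix")) A$A else A
  x <- solve_spd(M, cbind(phi, rep(1, length(phi))), method)
  Ainv_phi <- x[, 1]
  Ainv_one <- x[, 2]
  lambda <- (Q_total - sum(Ainv_phi)) / sum(Ainv_one)
  q <- -(Ainv_phi + lambda * Ainv_one)
  list(q = q, lambda = lambda,
       defect_before = -sum(Ainv_phi) + Q_total,
       defect_after = sum(q) + Q_total)
}

#' Corrected surface potentials
#'
#' Rebuilds the total potential implied by the corrected charges,
#' `Phi' = -A q'`, so the conductor boundary condition holds for the
#' charges actually used; the corrected electronic potential removes the
#' (unaffected) nuclear part, `Phi_e' = Phi' - Phi_N`.
#'
#' @param A A `coulomb_matrix` or plain matrix.
#' @param q_prime Corrected charges (e).
#' @param phi_N Nuclear potential on segments (a.u.).
#' @return List with `phi` (the corrected total `Phi'`) and `phi_e`.
#' @export
corrected_potential <- function(A, q_prime, phi_N) {
  M <- if (inherits(A, "coulomb_matrix")) A$A else A
  phi <- -drop(M %*% q_prime)
  list(phi = phi, phi_e = phi - phi_N)
}

#' Dielectric (solute-continuum) interaction energy
#'
#' `E_diel = 1/2 Phi^T q` in Hartree, with the factor 1/2 accounting for
#' the back-polarization cost. Pass a consistent pair: either the
#' uncorrected potential with uncorrected charges, or the corrected
#' `Phi'`/`q'` pair.
#'
#' @param phi Surface potential (a.u.).
#' @param q Screening charges (e).
#' @return List with `hartree` and `kcal` (1 Hartree = 627.509 kcal/mol).
#' @export
dielectric_energy <- function(phi, q) {
  E <- 0.5 * sum(phi * q)
  list(hartree = E, kcal = E * .HARTREE_KCAL)
}

#' Total charge defect
#'
#' `1^T q + Q_total`: the signed residual violation of Gauss's law by the
#' screening charges (zero for a perfect conductor with all solute charge
#' enclosed).
#'
#' @param q Screening charges (e).
#' @param Q_total Total solute charge (e).
#' @return Signed defect in e.
#' @export
charge_defect <- function(q, Q_total) sum(q) + Q_total
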