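## Conductor surface-charge solver. The boundary condition of vanishing
## total potential on the cavity surface, 0 = Phi + A q, is discretized over
## segments in either the Klamt-Schuurmann point-charge form (KS) or the
## York-Karplus smeared-Gaussian form (YK), solved dense (Cholesky) or by
## Jacobi-preconditioned conjugate gradients, and scaled for a finite
## dielectric. All matrix entries are atomic units.

#' KS (point-charge) Coulomb matrix
#'
#' Off-diagonal `A_ij = 1/|r_i - r_j|` (Bohr); diagonal self-interaction
#' `A_ii = 1.07 * sqrt(4 pi / s_i)` with `s_i` in Bohr^2 (the
#' Klamt-Schuurmann convention for a homogeneous charge patch).
#'
#' @param segments A `cosmo_segments` object (post-merge: all centers must
#'   be distinct).
#' @param diag_const Self-interaction constant (default 1.07).
#' @return List of class `coulomb_matrix`: `A` (m x m, a.u.), `variant`.
#' @export
build_A_ks <- function(segments, diag_const = 1.07) {
  centers <- ang2bohr(segments$centers)
  s <- ang2bohr(ang2bohr(segments$areas))
  r <- as.matrix(stats::dist(centers))
  if (any(r[upper.tri(r)] < 1e-10))
    stop("coincident segment centers: enable segment merging (mfactor > 0)")
  A <- 1 / r
  diag(A) <- diag_const * sqrt(4 * pi / s)
  structure(list(A = A, variant = "ks"), class = "coulomb_matrix")
}

#' YK (smeared-Gaussian) Coulomb matrix
#'
#' Surface elements are spherical Gaussians with exponents `zeta_i`
#' (Bohr^-1 scale): off-diagonal
#' `A_ij = erf(zeta_ij r_ij) / r_ij` with
#' `zeta_ij = zeta_i zeta_j / sqrt(zeta_i^2 + zeta_j^2)`, diagonal
#' `A_ii = zeta_i sqrt(2/pi)`. Finite for coincident centers, so no
#' merging is required.
#'
#' @param segments A `cosmo_segments` object.
#' @param zeta Positive exponent per segment (see [yk_exponents()]).
#' @return A `coulomb_matrix` list.
#' @export
build_A_yk <- function(segments, zeta) {
  m <- n_segments(segments)
  zeta <- rep_len(zeta, m)
  if (any(zeta <= 0)) stop("YK exponents must be positive")
  centers <- ang2bohr(segments$centers)
  r <- as.matrix(stats::dist(centers))
  zij <- outer(zeta, zeta) / sqrt(outer(zeta^2, zeta^2, "+"))
  A <- ifelse(r < 1e-14, zij * 2 / sqrt(pi), erf(zij * r) / r)
  diag(A) <- zeta * sqrt(2 / pi)
  structure(list(A = A, variant = "yk"), class = "coulomb_matrix")
}

## ---- YK calibration --------------------------------------------------------

.yk_cache <- new.env(parent = emptyenv())

#' Calibrate the YK exponent rule
#'
#' Finds the per-level scalar `zbar` such that, with the uniformity rule
#' `zeta_i = zbar / sqrt(s_i)` (`s_i` in Bohr^2; equal-area segments get
#' equal exponents), the discretized conductor energy of a unit Born
#' sphere equals the exact `-q^2/(2R)`. The rule is scale-invariant in the
#' sphere radius by construction, so one calibration per tessellation
#' level suffices; results are cached.
#'
#' @param level Tessellation level, see [tess_level()].
#' @return The calibrated scalar `zbar` (dimensionless).
#' @export
calibrate_yk <- function(level) {
  level <- tess_level(level)
  key <- level$label
  if (!is.null(.yk_cache[[key]])) return(.yk_cache[[key]])
  ## unit sphere (1 Bohr) at this level, uniform segments, central unit charge
  segs <- tessellate_sphere(c(0, 0, 0), .BOHR, level)  # radius 1 Bohr
  phi <- rep(1, n_segments(segs))                      # q/R = 1 a.u.
  born_err <- function(zbar) {
    Ayk <- build_A_yk(segs, zbar / sqrt(ang2bohr(ang2bohr(segs$areas))))
    q <- solve_spd(Ayk$A, -phi, "dense")
    0.5 * sum(phi * q) + 0.5                           # E_diel - (-1/2)
  }
  sol <- tryCatch(
    stats::uniroot(born_err, c(0.5, 50), tol = 1e-13),
    error = function(e) stop("YK calibration failed to bracket a root in ",
                             "[0.5, 50]: ", conditionMessage(e)))
  .yk_cache[[key]] <- sol$root
  sol$root
}

#' Per-segment YK exponents
#'
#' Applies the calibrated uniformity rule `zeta_i = zbar / sqrt(s_i)`
#' (`s_i` in Bohr^2).
#'
#' @param segments A `cosmo_segments` object.
#' @param level Tessellation level the cavity was built at.
#' @return Numeric vector of exponents.
#' @export
yk_exponents <- function(segments, level) {
  calibrate_yk(level) / sqrt(ang2bohr(ang2bohr(segments$areas)))
}

## ---- linear solvers --------------------------------------------------------

#' Default linear-solver choice by problem size
#'
#' The dense (Cholesky) solver is used up to m = 7500 segments; above that
#' the default switches to the iterative (conjugate-gradient) method.
#'
#' @param m Number of segments.
#' @return `"dense"` or `"iterative"`.
#' @export
lineq_method <- function(m) if (m > 7500) "iterative" else "dense"

## SPD solve; b may be a matrix of right-hand sides
solve_spd <- function(A, b, method = c("dense", "iterative", "auto")) {
  method <- match.arg(method)
  b <- as.matrix(b)
  if (method == "auto") method <- lineq_method(nrow(A))
  if (method == "dense") {
    ch <- tryCatch(chol(A), error = function(e)
      stop("Coulomb matrix is not positive definite: ", conditionMessage(e)))
    x <- backsolve(ch, forwardsolve(t(ch), b))
  } else {
    x <- apply(b, 2, function(bb) cg_solve(A, bb))
  }
  if (ncol(b) == 1) drop(x) else x
}

## Jacobi-preconditioned conjugate gradients
cg_solve <- function(A, b, tol = 1e-10, maxit = 10 * length(b)) {
  d <- diag(A)
  x <- b / d
  r <- b - drop(A %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(numeric(length(b)))
  for (it in seq_len(maxit)) {
    Ap <- drop(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bnorm) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf(
    "conjugate gradients did not converge in %d iterations (relative residual %.3e)",
    maxit, sqrt(sum(r^2)) / bnorm))
}

#' Solve the conductor screening equations
#'
#' Solves `A q = -Phi` (the vanishing-total-potential condition
#' `0 = Phi + A q`). When the split potentials are supplied, the nuclear
#' and electronic systems are solved with the same matrix and
#' `q = q_N + q_e`.
#'
#' @param A A `coulomb_matrix` or plain SPD matrix.
#' @param phi Total solute potential on segments (a.u.). Ignored when
#'   `phi_N`/`phi_e` are given.
#' @param phi_N,phi_e Optional split potentials (both required together).
#' @param method `"dense"`, `"iterative"` or `"auto"` (dense up to 7500
#'   segments).
#' @return A `screening_charges` list: `q`, `q_N`, `q_e` (e), `f_eps`
#'   (scaling already applied, initially 1), `method`.
#' @export
solve_screening <- function(A, phi = NULL, phi_N = NULL, phi_e = NULL,
                            method = c("auto", "dense", "iterative")) {
  method <- match.arg(method)
  M <- if (inherits(A, "coulomb_matrix")) A$A else A
  split <- !is.null(phi_N)
  if (split) {
    if (is.null(phi_e)) phi_e <- numeric(length(phi_N))
    qs <- solve_spd(M, cbind(-phi_N, -phi_e), method)
    q_N <- qs[, 1]; q_e <- qs[, 2]
    q <- q_N + q_e
  } else {
    if (is.null(phi)) stop("supply either phi or phi_N/phi_e")
    q <- solve_spd(M, -phi, method)
    q_N <- q; q_e <- numeric(length(q)) * NA_real_
  }
  structure(list(q = q, q_N = q_N, q_e = q_e, f_eps = 1,
                 method = if (method == "auto") lineq_method(nrow(M)) else method),
            class = "screening_charges")
}

## ---- dielectric scaling ----------------------------------------------------

#' Dielectric scaling factor
#'
#' `screen = "ideal"` treats the solvent as a perfect conductor
#' (`f = 1`, the dielectric constant is irrelevant); `"ks"` applies the
#' original Klamt-Schuurmann scaling `f = (eps - 1)/(eps + 0.5)`; `"st"`
#' the Stefanovich-Truong scaling `f = (eps - 1)/eps`.
#'
#' @param screen One of `"ideal"`, `"ks"`, `"st"`.
#' @param eps Relative permittivity (> 1; required for `"ks"`/`"st"`).
#' @return The scaling factor `f_eps` in (0, 1].
#' @export
scale_factor <- function(screen = c("ideal", "ks", "st"), eps = NULL) {
  screen <- match.arg(screen)
  if (screen == "ideal") return(1)
  if (is.null(eps)) stop("eps must be supplied for screen = '", screen, "'")
  if (eps <= 1) stop("eps must be > 1 for screen = '", screen, "'")
  if (!is.finite(eps)) return(1)  # conductor limit
  switch(screen, ks = (eps - 1) / (eps + 0.5), st = (eps - 1) / eps)
}

#' Apply dielectric scaling to screening charges
#'
#' Multiplies all charge components (`q`, `q_N`, `q_e`) by `f_eps`.
#'
#' @param charges A `screening_charges` (or correction result carrying
#'   `q`, `q_N`, `q_e`).
#' @param f_eps Scaling factor in (0, 1].
#' @return The scaled object, with its `f_eps` field updated.
#' @export
apply_scaling <- function(charges, f_eps) {
  if (f_eps <= 0 || f_eps > 1) stop("f_eps must be in (0, 1]")
  charges$q <- charges$q * f_eps
  charges$q_N <- charges$q_N * f_eps
  charges$q_e <- charges$q_e * f_eps
  charges$f_eps <- if (is.null(charges$f_eps)) f_eps else charges$f_eps * f_eps
  charges
}
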