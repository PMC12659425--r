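## shared helpers: analytic oracles and small geometry utilities

BOHR <- cosmo_constants()$bohr_angstrom
HARTREE_KCAL <- cosmo_constants()$hartree_kcal

## exact conductor (Born) solvation energy for charge q centered in a
## spherical cavity of radius R_ang Angstrom, in Hartree
born_exact <- function(q, R_ang) -q^2 / (2 * (R_ang / BOHR))

## rotation matrix about a unit axis
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## point-in-spherical-triangle: p and vertices are unit vectors; uses the
## sign of the scalar triple products for an outward-oriented triangle
in_spherical_triangle <- function(p, v1, v2, v3, tol = -1e-12) {
  tp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  sum(p * tp(v1, v2)) >= tol && sum(p * tp(v2, v3)) >= tol &&
    sum(p * tp(v3, v1)) >= tol
}

## dense Born-ion pipeline energy for a given matrix builder, used by
## solver-level tests without going through run_cosmo()
born_energy <- function(level, R_ang = 2, method = c("ks", "yk")) {
  method <- match.arg(method)
  segs <- tessellate_sphere(c(0, 0, 0), R_ang, level)
  phi <- rep(1 / (R_ang / BOHR), n_segments(segs))
  A <- if (method == "ks") build_A_ks(segs)
    else build_A_yk(segs, yk_exponents(segs, level))
  q <- solve_screening(A, phi = phi)$q
  dielectric_energy(phi, q)$hartree
}
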