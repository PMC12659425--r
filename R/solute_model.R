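## Classical solute charge models: point nuclei plus spherical Gaussian
## electron clouds. These generate the split nuclear/electronic potentials
## the screening solver consumes and, through the Gaussian tails, a
## controllable amount of outlying charge -- the feature the correction
## schemes exist to handle. Geometry is stored in Angstrom; potentials are
## evaluated in atomic units.

#' Classical solute charge model
#'
#' @param nuclei Data frame with columns `x`, `y`, `z` (Angstrom) and `Z`
#'   (nuclear charge, e). May have zero rows.
#' @param clouds Data frame with columns `x`, `y`, `z` (Angstrom), `q`
#'   (total cloud charge, e, normally negative) and `alpha` (Gaussian
#'   exponent, Bohr^-2, > 0). May be `NULL` / zero rows.
#' @return A `solute_model` with total charges `Q_N = sum(Z)` and
#'   `Q_e = sum(q)`.
#' @export
solute_model <- function(nuclei, clouds = NULL) {
  if (is.null(clouds)) clouds <- data.frame(x = numeric(0), y = numeric(0),
                                            z = numeric(0), q = numeric(0),
                                            alpha = numeric(0))
  stopifnot(all(c("x", "y", "z", "Z") %in% names(nuclei)),
            all(c("x", "y", "z", "q", "alpha") %in% names(clouds)))
  if (nrow(clouds) && any(clouds$alpha <= 0))
    stop("cloud exponents alpha must be positive")
  if (sum(nuclei$Z) < 0) stop("total nuclear charge must be >= 0")
  structure(list(nuclei = nuclei, clouds = clouds,
                 Q_N = sum(nuclei$Z), Q_e = sum(clouds$q)),
            class = "solute_model")
}

#' @export
print.solute_model <- function(x, ...) {
  cat(sprintf("<solute_model> %d nuclei (Q_N = %+g e), %d clouds (Q_e = %+g e)\n",
              nrow(x$nuclei), x$Q_N, nrow(x$clouds), x$Q_e))
  invisible(x)
}

as_points <- function(points) matrix(as.numeric(points), ncol = 3)

#' Nuclear electrostatic potential
#'
#' Coulomb potential of the point nuclei, `Phi_N(r) = sum_k Z_k / |r - R_k|`
#' in atomic units (coordinates are converted from Angstrom to Bohr
#' internally).
#'
#' @param solute A [solute_model()].
#' @param points n x 3 matrix of evaluation points, Angstrom.
#' @return Numeric vector of potentials, Hartree/e.
#' @export
nuclear_potential <- function(solute, points) {
  points <- as_points(points)
  phi <- numeric(nrow(points))
  for (k in seq_len(nrow(solute$nuclei))) {
    r <- sqrt((points[, 1] - solute$nuclei$x[k])^2 +
                (points[, 2] - solute$nuclei$y[k])^2 +
                (points[, 3] - solute$nuclei$z[k])^2)
    r <- ang2bohr(r)
    if (any(r < 1e-10)) {
      bad <- which(r < 1e-10)[1]
      stop(sprintf("evaluation point %d coincides with nucleus %d", bad, k))
    }
    phi <- phi + solute$nuclei$Z[k] / r
  }
  phi
}

#' Electron-cloud electrostatic potential
#'
#' Potential of the spherical Gaussian clouds. A cloud of total charge `n`
#' and exponent `alpha` contributes `n * erf(sqrt(alpha) r) / r` at
#' distance `r` (Bohr), with the finite limit `n * 2 sqrt(alpha/pi)` at
#' `r = 0`.
#'
#' @inheritParams nuclear_potential
#' @return Numeric vector of potentials, Hartree/e.
#' @export
cloud_potential <- function(solute, points) {
  points <- as_points(points)
  phi <- numeric(nrow(points))
  for (k in seq_len(nrow(solute$clouds))) {
    r <- ang2bohr(sqrt((points[, 1] - solute$clouds$x[k])^2 +
                         (points[, 2] - solute$clouds$y[k])^2 +
                         (points[, 3] - solute$clouds$z[k])^2))
    a <- solute$clouds$alpha[k]
    q <- solute$clouds$q[k]
    v <- ifelse(r < 1e-12, q * 2 * sqrt(a / pi), q * erf(sqrt(a) * r) / r)
    phi <- phi + v
  }
  phi
}

#' Split solute potential on a set of points
#'
#' @inheritParams nuclear_potential
#' @return List with `phi_N`, `phi_e` and `phi = phi_N + phi_e` (a.u.).
#' @export
solute_potential <- function(solute, points) {
  phi_N <- nuclear_potential(solute, points)
  phi_e <- cloud_potential(solute, points)
  list(phi_N = phi_N, phi_e = phi_e, phi = phi_N + phi_e)
}

#' Cloud charge enclosed within a radius
#'
#' Closed form for a single spherical Gaussian cloud: the charge within
#' radius `R` (Bohr) of the cloud center is
#' `q * (erf(sqrt(alpha) R) - 2 sqrt(alpha/pi) R exp(-alpha R^2))`.
#'
#' @param q Total cloud charge, e.
#' @param alpha Gaussian exponent, Bohr^-2.
#' @param R Radius in Bohr.
#' @return Enclosed charge, e.
#' @export
cloud_charge_within <- function(q, alpha, R) {
  u <- sqrt(alpha) * R
  q * (erf(u) - 2 / sqrt(pi) * u * exp(-u^2))
}

#' Solute charge outside the cavity
#'
#' Estimates how much of the electron-cloud charge lies outside the union
#' of the cavity spheres. Each cloud is sampled from its own (Gaussian)
#' density by Monte Carlo; for a cavity consisting of a single sphere the
#' closed form [cloud_charge_within()] is used instead (offset clouds in a
#' single-sphere cavity still fall back to Monte Carlo).
#'
#' @param solute A [solute_model()].
#' @param cavity A `cosmo_cavity` (or a sphere data frame).
#' @param n_samples Monte Carlo sample count per cloud.
#' @param seed Integer seed for the sampler.
#' @return Outside charge (e) with attributes `se` (Monte Carlo standard
#'   error, 0 for the closed form) and `fraction` (outside / total cloud
#'   charge; `NA` when there are no clouds).
#' @export
charge_outside_cavity <- function(solute, cavity, n_samples = 2e5,
                                  seed = 1L) {
  spheres <- if (inherits(cavity, "cosmo_cavity")) cavity$spheres else cavity
  if (nrow(solute$clouds) == 0)
    return(structure(0, se = 0, fraction = NA_real_))
  outside <- 0
  var_sum <- 0
  set.seed(seed)
  for (k in seq_len(nrow(solute$clouds))) {
    q <- solute$clouds$q[k]; a <- solute$clouds$alpha[k]
    c0 <- c(solute$clouds$x[k], solute$clouds$y[k], solute$clouds$z[k])
    centered <- nrow(spheres) == 1 &&
      sqrt(sum((c0 - c(spheres$x, spheres$y, spheres$z))^2)) < 1e-12
    if (centered) {
      qin <- cloud_charge_within(q, a, ang2bohr(spheres$radius[1]))
      outside <- outside + (q - qin)
    } else {
      ## sample the normalized density (alpha/pi)^{3/2} exp(-alpha r^2):
      ## per-axis sd = 1/sqrt(2 alpha) Bohr
      sd_ang <- bohr2ang(1 / sqrt(2 * a))
      pts <- matrix(stats::rnorm(3 * n_samples, sd = sd_ang), ncol = 3)
      pts <- sweep(pts, 2, c0, "+")
      inside <- rep(FALSE, n_samples)
      for (s in seq_len(nrow(spheres))) {
        d2 <- (pts[, 1] - spheres$x[s])^2 + (pts[, 2] - spheres$y[s])^2 +
          (pts[, 3] - spheres$z[s])^2
        inside <- inside | d2 < spheres$radius[s]^2
      }
      p_out <- mean(!inside)
      outside <- outside + q * p_out
      var_sum <- var_sum + q^2 * p_out * (1 - p_out) / n_samples
    }
  }
  structure(outside, se = sqrt(var_sum),
            fraction = if (abs(solute$Q_e) > 0) abs(outside / solute$Q_e) else NA_real_)
}

## ---- fixture catalogue -----------------------------------------------------

## exponent giving an outside-charge fraction `frac` for a centered cloud in
## a sphere of radius R_ang (Angstrom)
alpha_for_outside_fraction <- function(R_ang, frac) {
  Rb <- ang2bohr(R_ang)
  f <- function(a) 1 - (cloud_charge_within(1, a, Rb)) - frac
  stats::uniroot(f, c(1e-3, 1e3), tol = 1e-12)$root
}

#' Built-in solute/cavity fixtures
#'
#' Deterministic desk-scale stand-ins for quantum-mechanical solutes, used
#' throughout the test-suite and addressable from the command line:
#'
#' * `born_ion`: one sphere (R = 2 Angstrom) with a central +1 point
#'   charge and no clouds -- the analytic Born oracle.
#' * `born_anion`: one sphere, nucleus Z = 8, one centered cloud of charge
#'   -9 with its exponent solved so ~1% of the cloud charge lies outside
#'   the cavity.
#' * `diatomic`: two overlapping spheres, neutral two-center model.
#' * `water_like`: three centers in a bent geometry, neutral.
#' * `chain9`: nine colinear overlapping spheres emulating an n-nonane-like
#'   shape (for SES-vs-vdW area comparisons), neutral.
#'
#' @param name Fixture name.
#' @param seed Integer seed (fixtures are deterministic given the seed;
#'   the current catalogue does not use randomness).
#' @return List with elements `solute` ([solute_model()]) and `spheres`
#'   ([make_spheres()]).
#' @export
#' @examples
#' fx <- make_fixture("born_ion")
#' fx$solute$Q_N + fx$solute$Q_e  # +1
make_fixture <- function(name = c("born_ion", "born_anion", "diatomic",
                                  "water_like", "chain9"), seed = 1L) {
  name <- match.arg(name)
  set.seed(seed)
  nuc <- function(pos, Z) data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                     Z = Z)
  cld <- function(pos, q, alpha) data.frame(x = pos[, 1], y = pos[, 2],
                                            z = pos[, 3], q = q, alpha = alpha)
  origin <- matrix(0, 1, 3)
  switch(name,
    born_ion = list(
      solute = solute_model(nuc(origin, 1)),
      spheres = make_spheres(origin, 2.0)),
    born_anion = {
      a <- alpha_for_outside_fraction(2.0, 0.01)
      list(solute = solute_model(nuc(origin, 8), cld(origin, -9, a)),
           spheres = make_spheres(origin, 2.0))
    },
    diatomic = {
      pos <- rbind(c(0, 0, 0), c(1.5, 0, 0))
      ## tight clouds: most charge inside, small outlying tail
      list(solute = solute_model(nuc(pos, c(6, 8)),
                                 cld(pos, c(-6, -8), c(1.2, 1.6))),
           spheres = make_spheres(pos, c(2.0, 1.8)))
    },
    water_like = {
      pos <- rbind(c(0, 0, 0), c(0.76, 0.59, 0), c(-0.76, 0.59, 0))
      list(solute = solute_model(nuc(pos, c(8, 1, 1)),
                                 cld(pos, c(-8, -1, -1), c(1.6, 0.9, 0.9))),
           spheres = make_spheres(pos, c(1.79, 1.30, 1.30)))
    },
    chain9 = {
      pos <- cbind((0:8) * 1.5, 0, 0)
      list(solute = solute_model(nuc(pos, rep(1, 9)),
                                 cld(pos, rep(-1, 9), rep(0.9, 9))),
           spheres = make_spheres(pos, 2.0))
    })
}
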