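test_that("nuclear potential is the Coulomb sum in atomic units", {
  ## Z = 1 at the origin, point at 2 Bohr -> 0.5 a.u.
  s <- solute_model(data.frame(x = 0, y = 0, z = 0, Z = 1))
  p <- matrix(c(2 * BOHR, 0, 0), 1)
  expect_equal(nuclear_potential(s, p), 0.5, tolerance = 1e-14)
  ## brute-force term-by-term oracle, several nuclei and points
  set.seed(7)
  nuc <- data.frame(x = rnorm(5), y = rnorm(5), z = rnorm(5),
                    Z = sample(1:8, 5, TRUE))
  pts <- matrix(rnorm(21, sd = 5), ncol = 3)
  s2 <- solute_model(nuc)
  expected <- vapply(seq_len(7), function(i) {
    sum(vapply(seq_len(5), function(k) {
      r <- sqrt(sum((pts[i, ] - c(nuc$x[k], nuc$y[k], nuc$z[k]))^2)) / BOHR
      nuc$Z[k] / r
    }, numeric(1)))
  }, numeric(1))
  expect_equal(nuclear_potential(s2, pts), expected, tolerance = 1e-14)
  ## singular evaluation point names the offending nucleus
  expect_error(nuclear_potential(s, matrix(0, 1, 3)), "nucleus 1")
})

test_that("cloud potential has the erf form with the correct limits", {
  ## huge exponent recovers the point-charge law
  s <- solute_model(data.frame(x = numeric(0), y = numeric(0),
                               z = numeric(0), Z = numeric(0)),
                    data.frame(x = 0, y = 0, z = 0, q = -1, alpha = 1e6))
  p <- matrix(c(2 * BOHR, 0, 0), 1)
  expect_equal(cloud_potential(s, p), -0.5, tolerance = 1e-10)
  ## r = 0, q = -2, alpha = 1 -> -4/sqrt(pi)
  s2 <- solute_model(data.frame(x = numeric(0), y = numeric(0),
                                z = numeric(0), Z = numeric(0)),
                     data.frame(x = 0, y = 0, z = 0, q = -2, alpha = 1))
  expect_equal(cloud_potential(s2, matrix(0, 1, 3)), -4 / sqrt(pi),
               tolerance = 1e-14)
})

test_that("enclosed cloud charge matches numerical radial quadrature", {
  q <- -3; alpha <- 0.7
  for (R in c(0.5, 2, 4)) {
    numeric_q <- stats::integrate(function(r)
      q * (alpha / pi)^1.5 * exp(-alpha * r^2) * 4 * pi * r^2,
      0, R, rel.tol = 1e-12)$value
    expect_equal(cloud_charge_within(q, alpha, R), numeric_q,
                 tolerance = 1e-10)
  }
})

test_that("potentials superpose and obey the far-field and unit-scaling laws", {
  nuc <- data.frame(x = c(0, 1), y = c(0, -0.5), z = c(0, 0.2), Z = c(3, 5))
  cl <- data.frame(x = c(0.2, -0.4), y = c(0, 0.3), z = c(0.1, 0),
                   q = c(-4, -3), alpha = c(1.1, 0.6))
  full <- solute_model(nuc, cl)
  pts <- matrix(rnorm(15, sd = 6), ncol = 3)
  ## superposition over particles
  phi_sum <- Reduce(`+`, lapply(1:2, function(k)
    nuclear_potential(solute_model(nuc[k, ]), pts))) +
    Reduce(`+`, lapply(1:2, function(k)
      cloud_potential(solute_model(nuc[0, ], cl[k, ]), pts)))
  got <- solute_potential(full, pts)
  expect_equal(got$phi, phi_sum, tolerance = 1e-14)
  ## far field: total charge over distance (monopole dominates once the
  ## dipole term p/(Q r) drops below the tolerance)
  far <- matrix(c(5e6, 3e6, -2e6), 1)
  r_far <- sqrt(sum(far^2)) / BOHR
  expect_equal(solute_potential(full, far)$phi,
               (full$Q_N + full$Q_e) / r_far, tolerance = 1e-6)
  ## doubling all coordinates (solute and points) halves the nuclear potential
  nuc2 <- transform(nuc, x = 2 * x, y = 2 * y, z = 2 * z)
  expect_equal(nuclear_potential(solute_model(nuc2), 2 * pts),
               nuclear_potential(solute_model(nuc), pts) / 2,
               tolerance = 1e-12)
})

test_that("charge outside the cavity matches the closed-form complement", {
  ## tight cloud at the sphere center: nothing outside
  tight <- solute_model(data.frame(x = 0, y = 0, z = 0, Z = 1),
                        data.frame(x = 0, y = 0, z = 0, q = -1, alpha = 1e4))
  sp <- make_spheres(c(0, 0, 0), 2.0)
  out <- charge_outside_cavity(tight, sp)
  expect_lt(abs(out), 1e-8)
  ## Monte Carlo path (union of two spheres forming one effective sphere)
  ## against the single-sphere closed form
  fx <- make_fixture("born_anion")
  sp2 <- rbind(fx$spheres,
               make_spheres(c(0, 0, 0), 1.0, atom = NA)[1, ])  # engulfed
  out_mc <- charge_outside_cavity(fx$solute, sp2, n_samples = 2e5, seed = 3)
  cl <- fx$solute$clouds
  closed <- cl$q - cloud_charge_within(cl$q, cl$alpha, 2.0 / BOHR)
  se <- attr(out_mc, "se")
  expect_gt(se, 0)
  expect_lt(abs(out_mc - closed), 3 * se)
})

test_that("the fixture catalogue is deterministic and correctly charged", {
  a <- make_fixture("born_anion", seed = 11)
  b <- make_fixture("born_anion", seed = 11)
  expect_identical(a, b)
  ion <- make_fixture("born_ion")
  expect_equal(ion$solute$Q_N + ion$solute$Q_e, 1)
  expect_equal(nrow(ion$spheres), 1L)
  expect_equal(nrow(ion$solute$clouds), 0L)
  ## born_anion: ~1% of the cloud charge outside the cavity
  out <- charge_outside_cavity(a$solute, a$spheres)
  expect_equal(as.numeric(abs(out)), 0.01 * abs(a$solute$Q_e),
               tolerance = 0.2)
  ## looser clouds leak more charge than tighter ones
  loose <- charge_outside_cavity(
    solute_model(data.frame(x = 0, y = 0, z = 0, Z = 8),
                 data.frame(x = 0, y = 0, z = 0, q = -9,
                            alpha = a$solute$clouds$alpha / 4)),
    a$spheres)
  expect_gt(abs(loose), abs(out))
  ## the rest of the catalogue builds and is neutral
  for (nm in c("diatomic", "water_like", "chain9")) {
    fx <- make_fixture(nm)
    expect_equal(fx$solute$Q_N + fx$solute$Q_e, 0)
    expect_equal(nrow(fx$spheres), nrow(fx$solute$nuclei))
  }
  expect_error(make_fixture("no_such_fixture"), "arg")
})
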