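test_that("a single fully exposed sphere is kept intact", {
  cav <- build_vdw_cavity(make_spheres(c(0, 0, 0), 1.0), "fine")
  expect_equal(n_segments(cav$segments), 240L)
  expect_equal(cav$area, 4 * pi, tolerance = 5e-3)
  expect_equal(cav$volume, 4 * pi / 3, tolerance = 1e-2)
  expect_error(build_vdw_cavity(make_spheres(c(0, 0, 0), 1.0)[0, ], "fine"),
               "at least one sphere")
})

test_that("non-overlapping spheres tessellate independently", {
  sp <- make_spheres(rbind(c(0, 0, 0), c(5, 0, 0)), 1.0)
  cav <- build_vdw_cavity(sp, "fine")
  expect_equal(n_segments(cav$segments), 480L)
  expect_equal(cav$area, 8 * pi, tolerance = 5e-3)
})

test_that("two-sphere clipping matches the analytic spherical-cap area", {
  ## unit spheres 1 Angstrom apart: each loses a cap of height 0.5
  ## (cap area 2*pi*R*h = pi), exposed area 6*pi
  sp <- make_spheres(rbind(c(0, 0, 0), c(1, 0, 0)), 1.0)
  cav <- build_vdw_cavity(sp, "fine")
  expect_equal(cav$area, 6 * pi, tolerance = 2e-2)
  ## exact analytic union volume: 2 * (4/3 pi) - 2 * cap volume,
  ## cap volume = pi h^2 (R - h/3)
  vol_exact <- 2 * (4 * pi / 3) - 2 * pi * 0.5^2 * (1 - 0.5 / 3)
  expect_equal(cav$volume, vol_exact, tolerance = 2e-2)
})

test_that("adding a sphere never increases any existing sphere's exposed area", {
  sp2 <- make_spheres(rbind(c(0, 0, 0), c(1.2, 0, 0)), 1.0)
  sp3 <- make_spheres(rbind(c(0, 0, 0), c(1.2, 0, 0), c(0.5, 1.0, 0)), 1.0)
  cav2 <- build_vdw_cavity(sp2, "fine")
  cav3 <- build_vdw_cavity(sp3, "fine")
  for (k in 1:2) {
    a2 <- sum(cav2$segments$areas[cav2$segments$sphere == k])
    a3 <- sum(cav3$segments$areas[cav3$segments$sphere == k])
    expect_lte(a3, a2 + 1e-10)
  }
})

test_that("cavity volume matches a Monte Carlo inside-test oracle", {
  sp <- make_spheres(rbind(c(0, 0, 0), c(1.3, 0.2, -0.1)), c(1.4, 1.1))
  cav <- build_vdw_cavity(sp, "fine")
  set.seed(42)
  n <- 1e6
  lo <- c(-1.4, -1.4, -1.4); hi <- c(2.4, 1.6, 1.4)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  inside <- rep(FALSE, n)
  for (k in 1:2) {
    d2 <- (pts[, 1] - sp$x[k])^2 + (pts[, 2] - sp$y[k])^2 +
      (pts[, 3] - sp$z[k])^2
    inside <- inside | d2 < sp$radius[k]^2
  }
  box <- prod(hi - lo)
  p <- mean(inside)
  v_mc <- box * p
  se <- box * sqrt(p * (1 - p) / n)
  expect_lt(abs(cav$volume - v_mc), 3 * se + 0.02 * v_mc)
})

test_that("area and volume scale as R^2 and R^3 under coordinate scaling", {
  sp <- make_spheres(rbind(c(0, 0, 0), c(1.2, 0, 0)), 1.0)
  cav1 <- build_vdw_cavity(sp, "coarse")
  sp2 <- make_spheres(rbind(c(0, 0, 0), c(2.4, 0, 0)), 2.0)
  cav2 <- build_vdw_cavity(sp2, "coarse")
  expect_equal(cav2$area, 4 * cav1$area, tolerance = 1e-10)
  expect_equal(cav2$volume, 8 * cav1$volume, tolerance = 1e-10)
})

test_that("GEPOL adds auxiliary spheres only where the probe cannot fit", {
  one <- make_spheres(c(0, 0, 0), 2.0)
  expect_identical(gepol_add_spheres(one, 1.3), one)
  ## surface gap 3 > 2 * rsolv: probe passes, nothing added
  far <- make_spheres(rbind(c(0, 0, 0), c(7, 0, 0)), 2.0)
  expect_equal(nrow(gepol_add_spheres(far, 1.3)), 2L)
  ## surface gap 1 < 2.6: blocked; at least one on-axis auxiliary sphere
  pair <- make_spheres(rbind(c(0, 0, 0), c(5, 0, 0)), 2.0)
  aug <- gepol_add_spheres(pair, 1.3)
  aux <- aug[is.na(aug$atom), ]
  expect_gte(nrow(aux), 1L)
  expect_lt(max(abs(aux$y)), 1e-9)
  expect_lt(max(abs(aux$z)), 1e-9)
  expect_true(all(aux$x > 0 & aux$x < 5))
  expect_true(all(aux$radius >= 0.5))
})

test_that("SES area does not exceed vdW area on the alkane-like chain", {
  fx <- make_fixture("chain9")
  vdw <- build_vdw_cavity(fx$spheres, "fine")
  ses <- build_ses_cavity(fx$spheres, cavity_params("ses", level = "fine"))
  expect_lt(ses$area, vdw$area)
  ## single atom: SES construction degenerates to the vdW cavity
  one <- make_spheres(c(0, 0, 0), 2.0)
  sv <- build_vdw_cavity(one, "fine")
  ss <- build_ses_cavity(one, cavity_params("ses", level = "fine"))
  expect_equal(ss$area, sv$area, tolerance = 1e-12)
  expect_equal(n_segments(ss$segments), n_segments(sv$segments))
})

test_that("d_min is linear in mfactor and decreases with finer levels", {
  expect_identical(compute_d_min("fine", 1.3, 0), 0)
  expect_equal(compute_d_min("fine", 1.3, 2), 2 * compute_d_min("fine", 1.3, 1))
  d <- vapply(c("coarse", "fine", "xfine"), compute_d_min,
              numeric(1), rsolv = 1.3, mfactor = 1.0)
  expect_true(d[["xfine"]] < d[["fine"]] && d[["fine"]] < d[["coarse"]])
})

test_that("segment merging conserves area and respects the d_min contract", {
  ## two collocated segments merge into one with summed area
  s <- make_segments(rbind(c(0, 0, 1), c(0, 0, 1)), c(0.3, 0.5),
                     rbind(c(0, 0, 1), c(0, 0, 1)), c(1L, 1L))
  m <- merge_segments(s, 0.1)
  expect_equal(n_segments(m), 1L)
  expect_equal(m$areas, 0.8)
  expect_equal(m$centers[1, ], c(0, 0, 1))
  expect_equal(m$merged, 2L)
  ## all pairs farther than d_min: identity
  s2 <- tessellate_sphere(c(0, 0, 0), 2.0, "coarse")
  expect_identical(merge_segments(s2, 1e-6), s2)
  expect_identical(merge_segments(s2, 0), s2)
})

test_that("chained near-coincident segments collapse to one, matching a component oracle", {
  ## chain a-b-c of near-collocated segments merges to a single segment
  centers <- rbind(c(0, 0, 1), c(0.01, 0, 1), c(0.02, 0, 1),
                   c(2, 0, 0), c(0, 2, 0))
  areas <- c(0.2, 0.3, 0.4, 1.0, 1.1)
  normals <- centers / sqrt(rowSums(centers^2))
  s <- make_segments(centers, areas, normals, rep(1L, 5))
  d_min <- 0.1
  m <- merge_segments(s, d_min)
  ## oracle: connected components of the closer-than-d_min graph by BFS
  dm <- as.matrix(dist(centers))
  adj <- dm < d_min & dm > 0
  comp <- rep(0L, 5); cid <- 0L
  for (i in 1:5) if (comp[i] == 0L) {
    cid <- cid + 1L; queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  expect_equal(n_segments(m), length(unique(comp)))
  expect_equal(sum(m$areas), sum(areas), tolerance = 1e-12)
  ## merged chain center is the area-weighted centroid
  chain <- which(comp == comp[1])
  expected_center <- colSums(centers[chain, ] * areas[chain]) / sum(areas[chain])
  got <- m$centers[which.max(m$merged), ]
  expect_equal(got, expected_center, tolerance = 1e-12)
  ## post-merge minimum pairwise distance honours d_min
  expect_gte(min(dist(m$centers)), d_min)
})

test_that("SES pipeline output honours the post-merge distance contract", {
  fx <- make_fixture("water_like")
  params <- cavity_params("ses", level = "fine")
  cav <- build_ses_cavity(fx$spheres, params)
  d_min <- compute_d_min(params$level, params$rsolv, params$mfactor)
  expect_gte(min(dist(cav$segments$centers)), d_min)
  ## area bookkeeping: cavity$area equals the (merge-conserved) segment sum
  expect_equal(sum(cav$segments$areas), cav$area, tolerance = 1e-10)
})
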