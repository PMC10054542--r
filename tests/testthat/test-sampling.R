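geom <- membrane_geometry()
mem <- planar_membrane(geom)

test_that("elastic networks have the declared spring structure", {
  ps <- particle_system(data.frame(resname = "X", resno = 1:3,
                                   name = "B", x = c(0, 5, 20),
                                   y = 0, z = 0, radius = 2))
  enm <- build_enm(ps, cutoff = 9)
  expect_equal(nrow(enm), 1)               # only the 5 A pair
  expect_equal(c(enm$i, enm$j), c(1, 2))
  expect_equal(enm$rest, 5)
  # zero energy and force at the build geometry
  expect_equal(enm_energy(enm, ps_coords(ps)), 0)
  expect_equal(enm_forces(enm, ps_coords(ps)),
               matrix(0, 3, 3))
})

test_that("elastic network forces obey Newton's third law and invariance", {
  ps <- random_system(15, seed = 8, spread = 6)
  enm <- build_enm(ps, cutoff = 9)
  expect_gt(nrow(enm), 0)
  xyz <- ps_coords(ps) + matrix(rnorm(45, sd = 0.3), 15, 3)
  f <- enm_forces(enm, xyz)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-9)
  # energy invariant under global rotation + translation
  e0 <- enm_energy(enm, xyz)
  R <- rotation_matrix(c(1, 2, 3), 37)
  xyz2 <- sweep(xyz %*% t(R), 2, c(5, -3, 11), `+`)
  expect_equal(enm_energy(enm, xyz2), e0, tolerance = 1e-9)
})

test_that("identical seeds give bitwise identical trajectories", {
  ps <- make_fixture("hydrophobic_helix", size = 12)
  t1 <- run_monte_carlo(ps, mem, steps = 300, seed = 42)
  t2 <- run_monte_carlo(ps, mem, steps = 300, seed = 42)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(ps_coords(trajectory_final(t1)),
                   ps_coords(trajectory_final(t2)))
  t3 <- run_monte_carlo(ps, mem, steps = 300, seed = 43)
  expect_false(identical(t1$e_imp, t3$e_imp))
  # stored energies re-evaluate to the same values at the final pose
  e <- total_energy(trajectory_final(t1), mem)
  expect_equal(t1$e_imp[nrow(t1)], e$e_imp, tolerance = 1e-9)
})

test_that("Metropolis limits behave: greedy at T->0, free at high T", {
  ps <- ps_translate(make_fixture("hydrophobic_helix", size = 12),
                     c(0, 0, 14))
  cold <- run_monte_carlo(ps, mem, temperature = 1e-9, steps = 500,
                          seed = 1)
  e <- cold$e_imp
  expect_true(all(diff(e) <= 1e-9))
  hot <- run_monte_carlo(ps, mem, temperature = 1e9, steps = 1000,
                         seed = 1)
  expect_gt(mean(hot$accepted), 0.99)
})

test_that("visit frequencies match Boltzmann weights on a two-state landscape", {
  # a bounded discretized landscape plugged in through the membrane
  # contract: energy 0 on z in [0, 10), delta on [10, 20), walls outside
  delta <- 0.0019872 * 300  # one kT
  twostate <- structure(list(geom = geom), class = c("twostate", "membrane"))
  registerS3method("membrane_depth", "twostate",
                   function(membrane, xyz) {
                     if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
                     list(z = xyz[, 3],
                          normal = matrix(rep(c(0, 0, 1),
                                              each = nrow(xyz)),
                                          nrow(xyz), 3))
                   }, envir = asNamespace("implimem"))
  registerS3method("profile_at", "twostate",
                   function(membrane, z) {
                     ifelse(z < 0 | z >= 20, 1e6,
                            ifelse(z < 10, 0, delta))
                   }, envir = asNamespace("implimem"))
  # single particle with S*etr = -1 so E_int = C(z) numerically
  ps <- single_bead(z = 5, sasa = 1, etr = -1)
  g0 <- membrane_geometry(a_lip = -1e-30)  # perturbation term off
  twostate$geom <- g0
  traj <- run_monte_carlo(ps, twostate, temperature = 300,
                          steps = 100000, max_rotation = 0, seed = 13)
  z <- traj$depth
  pB <- mean(z >= 10 & z < 20)
  pA <- mean(z < 10)
  expect_gt(pA, 0); expect_gt(pB, 0)
  # equal-width states: N_B/N_A -> exp(-delta/kT) = e^-1
  expect_equal(pB / pA, exp(-1), tolerance = 0.2)
})

test_that("MC equilibrates fixtures where the energy landscape says", {
  # grid-scan oracle over depth at fixed orientation
  phob <- make_fixture("hydrophobic_helix", size = 18)
  amph <- make_fixture("amphipathic_helix", size = 18)
  scan_min <- function(ps) {
    sc <- energy_scan(ps, mem, range = c(-40, 40), step = 0.5)
    sc$coordinate[which.min(sc$e_imp)]
  }
  expect_equal(scan_min(phob), 0, tolerance = 0.51)
  amph_min <- scan_min(amph)
  expect_gt(abs(amph_min), geom$z0 - geom$beta)   # interface, not core
  expect_lt(abs(amph_min), geom$z0 + geom$beta)
  # start in contact with the headgroup region, as an interactive
  # insertion experiment would
  depths <- function(ps, seed) {
    start <- ps_translate(ps, c(0, 0, 18 - ps_center(ps)[3]))
    tr <- run_monte_carlo(start, mem, steps = 15000, seed = seed,
                          record_every = 10L, max_depth = 40)
    tail(tr$depth, 500)
  }
  # the median |depth| locates the occupied basin robustly against
  # transient excursions into bulk water
  for (seed in 1:2) {
    dp <- stats::median(abs(depths(phob, seed)))
    da <- stats::median(abs(depths(amph, seed)))
    expect_lt(dp, geom$z0 - geom$beta)    # core
    expect_gt(da, geom$z0 - geom$beta)    # interface band
    expect_lt(da, geom$z0 + geom$beta)
    expect_lt(dp, da)
  }
})

test_that("gradient relaxation descends into the membrane", {
  ps <- ps_translate(make_fixture("hydrophobic_helix", size = 12),
                     c(0, 0, 18))
  e0 <- total_energy(ps, mem)$e_imp
  res <- minimize(ps, mem)
  expect_lte(res$energy$e_imp, e0)
  expect_true(res$converged)
  # a single hydrophobic particle relaxes into the degenerate core
  # plateau, reaching the z = 0 minimum energy to numerical precision
  one <- single_bead(z = 16, sasa = 60, etr = -0.03)
  r1 <- minimize(one, mem, tol = 1e-15)
  expect_lt(abs(ps_center(r1$system)[3]), 2)
  e_min <- total_energy(single_bead(z = 0, sasa = 60, etr = -0.03),
                        mem)$e_imp
  expect_equal(r1$energy$e_imp, e_min, tolerance = 1e-9)
})

test_that("scan minima and relaxation minima coincide within one step", {
  ps <- ps_translate(make_fixture("amphipathic_helix", size = 18),
                     c(0, 0, 20))
  sc <- energy_scan(ps, mem, range = c(-40, 40), step = 0.5)
  zstar <- sc$coordinate[which.min(sc$e_imp)]
  res <- minimize(ps, mem, tol = 1e-12)
  expect_equal(unname(ps_center(res$system)[3]), zstar,
               tolerance = 0.5 + 1e-6)
  # scans are symmetric for a symmetric fixture and flat in bulk water
  sym <- single_bead(z = 0, sasa = 50, etr = -0.02)
  ss <- energy_scan(sym, mem, range = c(-30, 30), step = 1)
  expect_equal(ss$e_imp, rev(ss$e_imp), tolerance = 1e-9)
  aq <- energy_scan(sym, mem, range = c(60, 80), step = 1)
  expect_lt(diff(range(aq$e_imp)), 1e-6)
})

test_that("insertion metrics recover constructed poses in closed form", {
  bar <- make_fixture("barrel_shell", size = 30)
  vp <- c(bar$id[1], bar$id[nrow(bar)])
  # axis along z: the rim-to-rim insertion vector tilts with the body
  m0 <- insertion_metrics(ps_translate(bar, c(0, 0, 4)), mem, vp)
  expect_equal(m0$depth, 4, tolerance = 1e-9)
  for (ang in c(0, 20, 55, 90)) {
    rot <- ps_rotate(bar, rotation_matrix(c(0, 1, 0), ang))
    m <- insertion_metrics(rot, mem, vp)
    # the fixture's rim vector is not exactly axial; compare to its own
    # closed form
    v0 <- ps_coords(bar)[nrow(bar), ] - ps_coords(bar)[1, ]
    vr <- rotation_matrix(c(0, 1, 0), ang) %*% v0
    want <- acos(abs(vr[3]) / sqrt(sum(vr^2))) * 180 / pi
    expect_equal(m$tilt, want, tolerance = 1e-6)
  }
  # roll changes by exactly the applied rotation about the z axis when
  # the insertion vector is axial (third particle shifts the centroid
  # off-axis so the body marker is well defined)
  axial <- particle_system(data.frame(resname = "X", resno = 1:3,
                                      name = "B", x = c(0, 0, 6),
                                      y = 0, z = c(-5, 5, 0), radius = 2,
                                      sasa = 10, etr = 0,
                                      sidechain = TRUE))
  r0 <- insertion_metrics(axial, mem, c(1, 2))$roll
  rot <- ps_rotate(axial, rotation_matrix(c(0, 0, 1), 35),
                   pivot = c(0, 0, 0))
  r35 <- insertion_metrics(rot, mem, c(1, 2))$roll
  dd <- (r35 - r0) %% 360
  expect_equal(min(dd, 360 - dd), 35, tolerance = 1e-6)
  expect_error(insertion_metrics(axial, mem, c(1, 1)), "degenerate")
})

test_that("depth profiles report per-residue positions and deviations", {
  # ideal transmembrane helix normal to the membrane: slope 1.5 A per
  # residue along the sequence
  n <- 20
  i <- seq_len(n)
  tm <- particle_system(data.frame(
    resname = "ALA", resno = i, name = "B",
    x = 2.3 * cos((i - 1) * 100 * pi / 180),
    y = 2.3 * sin((i - 1) * 100 * pi / 180),
    z = (i - 1) * 1.5 - (n - 1) * 0.75,
    radius = 3, sasa = 60, etr = -0.02, sidechain = TRUE))
  prof <- depth_profile(tm, mem)
  fit <- stats::lm(depth ~ resno, data = prof)
  expect_equal(unname(stats::coef(fit)[2]), 1.5, tolerance = 1e-9)
  # static profile equals instantaneous depths
  expect_equal(prof$depth, tm$z)
  # deviation against itself is zero
  ref <- stats::setNames(prof$depth, prof$resno)
  prof2 <- depth_profile(tm, mem, reference = ref)
  expect_equal(prof2$deviation, rep(0, n))
  # frame averaging
  frames <- list(tm, ps_translate(tm, c(0, 0, 2)))
  pm <- depth_profile(frames, mem)
  expect_equal(pm$depth, tm$z + 1)
  expect_error(depth_profile(list(), mem), "empty")
  expect_error(depth_profile(tm, mem, selection = 999), "empty")
})
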