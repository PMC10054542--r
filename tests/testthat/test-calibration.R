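geom <- membrane_geometry()

# a toy residue with two types and controlled surfaces, centred at z = 0
two_type_toy <- function(s1 = 10, s2 = 20) {
  ps <- particle_system(data.frame(
    resname = "TOY", resno = 1, name = c("A1", "A2"),
    x = c(-1, 1), y = 0, z = 0, radius = 2,
    sasa = c(s1, s2), type = c("T1", "T2"), etr = NA,
    sidechain = TRUE))
  ps
}

toy_params <- function(e1 = -0.02, e2 = 0.012) {
  atom_type_params(data.frame(residue = "TOY", type = c("T1", "T2"),
                              etr = c(e1, e2)))
}

test_that("linearization matches the hand-evaluated coefficients", {
  ps <- single_bead(z = 0, sasa = 10, etr = NA)
  ps$type <- "T1"
  lin <- linearize_residue(ps, geom)
  expect_equal(unname(lin$A), 5, tolerance = 1e-9)       # -S*C(0)
  expect_equal(lin$B, 0.09, tolerance = 1e-9)            # a_lip*S*C(0)
  # doubling surfaces doubles both coefficients
  ps2 <- ps; ps2$sasa <- 20
  lin2 <- linearize_residue(ps2, geom)
  expect_equal(lin2$A, 2 * lin$A, tolerance = 1e-12)
  expect_equal(lin2$B, 2 * lin$B, tolerance = 1e-12)
})

test_that("the linear form reproduces the direct transfer prediction", {
  params <- default_atom_params()
  for (rn in c("LEU", "TRP", "ASP", "GLY", "PRO")) {
    ps <- compute_sasa(assign_atom_types(residue_template(rn), params))
    lin <- linearize_residue(ps, geom)
    E <- lookup_etr(params, rn, names(lin$A))
    expect_equal(sum(lin$A * E) + lin$B,
                 predict_transfer_energy(ps, geom), tolerance = 1e-9,
                 info = rn)
  }
  # no exposed surface is unsolvable
  ps0 <- two_type_toy(0, 0)
  expect_error(linearize_residue(ps0, geom), "unsolvable")
})

test_that("MAAPE matches its direct arctangent definition", {
  expect_equal(maape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(maape(2, 1), atan(0.5) * 100)
  expect_equal(maape(1, 0), atan(1) * 100)
  expect_equal(maape(1, 0), 78.53982, tolerance = 1e-5)
  expect_equal(maape(c(2, 1), c(1, 0)),
               mean(atan(c(0.5, 1))) * 100)
  # zero adjusted parameter falls back to the capped ratio
  expect_equal(maape(0, 1), atan(1 / 1e-12) * 100, tolerance = 1e-6)
})

test_that("every strategy satisfies the calibration constraint exactly", {
  ps <- two_type_toy()
  for (strat in c("least_norm", "proportional", "single_type",
                  "uniform_shift", "auto")) {
    res <- calibrate_residue(ps, target = -1.3, initial = toy_params(),
                             geom = geom, strategy = strat)
    expect_equal(res$achieved, -1.3, tolerance = 1e-6, info = strat)
  }
  # iterative mode converges to the closed form
  a <- calibrate_residue(ps, -1.3, toy_params(), geom, "least_norm")
  b <- calibrate_residue(ps, -1.3, toy_params(), geom, "least_norm",
                         iterate = TRUE)
  expect_equal(a$adjusted, b$adjusted, tolerance = 1e-9)
})

test_that("an already-achieved target leaves parameters untouched", {
  ps <- two_type_toy()
  lin <- linearize_residue(ps, geom)
  E0 <- lookup_etr(toy_params(), "TOY", names(lin$A))
  target <- sum(lin$A * E0) + lin$B
  for (strat in c("least_norm", "proportional", "single_type",
                  "uniform_shift")) {
    res <- calibrate_residue(ps, target, toy_params(), geom, strat)
    expect_equal(unname(res$adjusted), unname(E0), info = strat)
    expect_equal(res$maape, 0, info = strat)
  }
})

test_that("a one-type residue has a unique solution shared by all strategies", {
  ps <- single_bead(z = 0, sasa = 25, etr = NA)
  ps$type <- "T1"
  init <- atom_type_params(data.frame(residue = "*", type = "T1",
                                      etr = -0.01))
  sols <- lapply(c("least_norm", "proportional", "single_type",
                   "uniform_shift"), function(s)
    unname(calibrate_residue(ps, -0.9, init, geom, s)$adjusted))
  for (s in sols[-1]) expect_equal(s, sols[[1]], tolerance = 1e-9)
})

test_that("least-norm calibration minimizes the parameter change", {
  ps <- two_type_toy(12, 33)
  res <- calibrate_residue(ps, -0.8, toy_params(), geom, "least_norm")
  lin <- linearize_residue(ps, geom)
  E0 <- lookup_etr(toy_params(), "TOY", names(lin$A))
  best <- sum((res$adjusted - E0)^2)
  # brute-force grid over solutions of the constraint line
  e1 <- seq(-0.2, 0.2, length.out = 4001)
  e2 <- (-0.8 - lin$B - lin$A[1] * e1) / lin$A[2]
  norms <- (e1 - E0[1])^2 + (e2 - E0[2])^2
  expect_true(all(norms >= best - 1e-12))
})

test_that("proportional calibration preserves pairwise energy ratios", {
  ps <- two_type_toy(18, 7)
  res <- calibrate_residue(ps, -2.1, toy_params(-0.03, 0.012), geom,
                           "proportional")
  expect_equal(res$adjusted[["T1"]] / res$adjusted[["T2"]],
               -0.03 / 0.012, tolerance = 1e-9)
  expect_equal(res$achieved, -2.1, tolerance = 1e-9)
})

test_that("proportional falls back when the prediction sits at the offset", {
  ps <- two_type_toy(10, 10)
  # choose initial energies whose prediction equals B (E.E = 0 net)
  init <- toy_params(0, 0)
  expect_warning(
    res <- calibrate_residue(ps, -1, init, geom, "proportional"),
    "least_norm")
  expect_equal(res$achieved, -1, tolerance = 1e-9)
})

test_that("auto calibration never does worse than any single strategy", {
  set.seed(21)
  ps <- two_type_toy(15, 40)
  for (k in 1:20) {
    target <- runif(1, -3, 3)
    init <- toy_params(runif(1, -0.05, -0.001), runif(1, 0.001, 0.05))
    auto <- calibrate_residue(ps, target, init, geom, "auto")
    for (strat in c("least_norm", "proportional", "single_type",
                    "uniform_shift")) {
      single <- calibrate_residue(ps, target, init, geom, strat)
      expect_lte(auto$maape, single$maape + 1e-9)
    }
  }
})

test_that("full-scale calibration reproduces a random scale on the template DB", {
  db <- default_conformation_db()
  set.seed(5)
  vals <- stats::setNames(runif(20, -3, 3), standard_residues())
  scale <- hydrophobicity_scale(vals, name = "random")
  out <- calibrate_scale(scale, db)
  expect_length(out$failures, 0)
  expect_equal(nrow(out$report), 20)
  expect_true(all(abs(out$report$calibrated_prediction -
                        out$report$target) < 1e-6))
  # verify through the full prediction path with the new parameters
  for (rn in c("TRP", "GLY", "LYS", "ILE")) {
    ps <- db[[rn]]
    ps$etr <- lookup_etr(out$params, rn, ps$type)
    expect_equal(predict_transfer_energy(ps, geom), vals[[rn]],
                 tolerance = 1e-6, info = rn)
  }
  # idempotence: recalibrating to the already-achieved predictions
  # returns the same parameters
  pred <- stats::setNames(out$report$calibrated_prediction,
                          out$report$residue)
  out2 <- calibrate_scale(hydrophobicity_scale(pred, "self"),
                          db, initial = out$params)
  expect_true(all(abs(out2$report$maape) < 1e-9))
})

test_that("kJ scales are converted before calibration", {
  db <- default_conformation_db()
  sc_kcal <- hydrophobicity_scale(c(LEU = -1.7), "x", units = "kcal/mol")
  sc_kj <- hydrophobicity_scale(c(LEU = -1.7 * 4.184), "x",
                                units = "kJ/mol")
  a <- calibrate_scale(sc_kcal, db)
  b <- calibrate_scale(sc_kj, db)
  expect_equal(a$report$calibrated_prediction,
               b$report$calibrated_prediction, tolerance = 1e-9)
})
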