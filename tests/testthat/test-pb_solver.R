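test_that("grid construction covers the padded bounding box", {
  fr <- point_charge_frame()
  g <- build_grid(fr, 0.5, 10)
  expect_equal(g$dims, c(41L, 41L, 41L))
  g2 <- build_grid(fr, 0.5, 20)
  expect_equal(g2$dims, c(81L, 81L, 81L))
  expect_error(build_grid(fr, -1, 10))
})

test_that("dielectric map assigns region permittivities correctly", {
  fr <- point_charge_frame(radius = 2)
  g <- build_grid(fr, 1, 10)
  memb <- structure(list(midplane_z = -6, core_half_thickness = 2,
                         headgroup_thickness = 2, total_thickness = 8),
                    class = "membrane_geometry")
  d <- build_dielectric_map(fr, g, memb)
  at <- function(p) d$epsilon[
    round((p[1] - g$origin[1])) + 1, round((p[2] - g$origin[2])) + 1,
    round((p[3] - g$origin[3])) + 1]
  expect_equal(at(c(0, 0, 0)), 8)        # inside the atom sphere
  expect_equal(at(c(9, 9, 9)), 80)       # far solvent
  expect_equal(at(c(8, 0, -6)), 4)       # membrane midplane outside protein
  expect_equal(at(c(8, 0, -3)), 8)       # headgroup shell
  # zero-radius atoms contribute no protein voxels
  d2 <- build_dielectric_map(point_charge_frame(radius = 0), g, NULL)
  expect_false(any(d2$epsilon != 80))
})

test_that("zero charge gives an identically zero potential", {
  r <- solve_point_charge(1, 8, q = 0)
  expect_true(all(r$potential$phi == 0))
})

test_that("uniform-dielectric solve matches the Coulomb law within 5%", {
  r <- solve_point_charge(0.5, 12, eps = 80, ionic = 0)
  d <- seq(3, 10, 1)
  phi <- interp_phi(r$potential, cbind(d, 0, 0))
  exact <- 332.06 / (80 * d)
  expect_lt(max(abs(phi - exact) / exact), 0.05)
})

test_that("screened solve matches the Debye-Hueckel form within 7%", {
  cst <- pb_constants(ionic_strength = 0.15, kbt = 0.593)
  r <- solve_point_charge(0.5, 12, eps = 80, ionic = 0.15)
  kappa <- sqrt(pbpka:::screening_coefficient(cst) / 80)
  d <- seq(3, 10, 1)
  phi <- interp_phi(r$potential, cbind(d, 0, 0))
  exact <- 332.06 * exp(-kappa * d) / (80 * d)
  expect_lt(max(abs(phi - exact) / exact), 0.07)
  # screening strictly reduces the far potential
  r0 <- solve_point_charge(0.5, 12, eps = 80, ionic = 0)
  expect_lt(abs(interp_phi(r$potential, c(10, 0, 0))),
            abs(interp_phi(r0$potential, c(10, 0, 0))))
})

test_that("solution is linear in the source charges", {
  r1 <- solve_point_charge(1, 8, q = 1)
  r3 <- solve_point_charge(1, 8, q = 3)
  expect_equal(r3$potential$phi, 3 * r1$potential$phi, tolerance = 1e-5)
})

test_that("mirror-symmetric problems give mirror-symmetric potentials", {
  cst <- pb_constants(ionic_strength = 0.15)
  fr <- structure_frame(data.frame(
    atom_name = c("Q1", "Q2"), element = "C", residue_name = "BCK",
    residue_id = 1:2, chain_id = "X", x = c(-3, 3), y = 0, z = 0,
    charge = c(1, 1), radius = 1.5, stringsAsFactors = FALSE))
  g <- build_grid(fr, 1, 8)
  d <- build_dielectric_map(fr, g, NULL)
  s <- build_screening_map(d, cst)
  ch <- data.frame(x = c(-3, 3), y = c(0, 0), z = c(0, 0), charge = c(1, 1))
  pot <- solve_linearized_pb(ch, d, s, cst)
  flipped <- pot$phi[rev(seq_len(g$dims[1])), , ]
  expect_lt(max(abs(pot$phi - flipped)), 1e-6 * max(abs(pot$phi)))
})

test_that("Born solvation energy converges to the closed form", {
  errs <- vapply(c(2, 1, 0.5), function(h)
    abs(born_energy_grid(h) - born_exact()) / abs(born_exact()), numeric(1))
  expect_lt(errs[3], 0.10)
  expect_true(all(diff(errs) < 0))       # refinement improves monotonically
})

test_that("grid focusing is self-consistent and helps accuracy", {
  cst <- pb_constants(ionic_strength = 0)
  fr <- point_charge_frame(radius = 0)
  ch <- data.frame(x = 0, y = 0, z = 0, charge = 1)
  rv <- uniform_region_values(80)
  foc <- focused_solve(ch, fr, NULL, cst, coarse_spacing = 1.5,
                       fine_spacing = 0.5, padding = 10, center = c(0, 0, 0),
                       fine_extent = 10, region_values = rv)
  # against a direct fine solve of the same problem
  direct <- solve_point_charge(0.5, 10, eps = 80)
  d <- seq(2, 4, 0.5)
  pf <- interp_phi(foc, cbind(d, 0, 0))
  pd <- interp_phi(direct$potential, cbind(d, 0, 0))
  expect_lt(max(abs(pf - pd) / abs(pd)), 0.02)
  # equal spacings collapse to the single-pass solve
  single <- focused_solve(ch, fr, NULL, cst, coarse_spacing = 1.0,
                          fine_spacing = 1.0, padding = 8,
                          region_values = rv)
  ref <- solve_point_charge(1.0, 8, eps = 80)
  expect_equal(single$phi, ref$potential$phi, tolerance = 1e-10)
})

test_that("focusing reduces the Born-energy grid error over coarse-only", {
  cst <- pb_constants(ionic_strength = 0)
  fr <- point_charge_frame(radius = 2)
  ch <- data.frame(x = 0, y = 0, z = 0, charge = 1)
  rv_het <- c(reference = 1, membrane_core = 1, headgroups = 1,
              protein = 1, solvent = 80)
  rv_hom <- uniform_region_values(1)
  energy <- function(coarse, fine) {
    p1 <- focused_solve(ch, fr, NULL, cst, coarse, fine, padding = 9,
                        center = c(0, 0, 0), fine_extent = 10,
                        region_values = rv_het)
    p0 <- focused_solve(ch, fr, NULL, cst, coarse, fine, padding = 9,
                        center = c(0, 0, 0), fine_extent = 10,
                        region_values = rv_hom)
    electrostatic_free_energy(p1, ch) - electrostatic_free_energy(p0, ch)
  }
  err_coarse <- abs(energy(1.5, 1.5) - born_exact())
  err_foc <- abs(energy(1.5, 0.5) - born_exact())
  expect_lt(err_foc, err_coarse)
})

test_that("electrostatic free energy is bilinear and null for no charges", {
  r <- solve_point_charge(1, 8, q = 1, radius = 1.5)
  e1 <- electrostatic_free_energy(r$potential, r$charges)
  r2 <- solve_point_charge(1, 8, q = 2, radius = 1.5)
  e2 <- electrostatic_free_energy(r2$potential,
                                  transform(r$charges, charge = 2))
  expect_equal(e2, 4 * e1, tolerance = 1e-5)
  expect_equal(electrostatic_free_energy(r$potential,
                                         r$charges[0, ]), 0)
  expect_error(electrostatic_free_energy(r$potential,
                                         data.frame(x = 1e3, y = 0, z = 0,
                                                    charge = 1)), "outside")
})

test_that("Coulomb energy reproduces the salt-bridge magnitude", {
  expect_equal(coulomb_energy(-1, 1, 5, 78), -0.852, tolerance = 0.002)
  expect_equal(coulomb_energy(0, 1, 5, 78), 0)
  expect_equal(coulomb_energy(1, 1, 2.5, 78),
               2 * coulomb_energy(1, 1, 5, 78))
  expect_error(coulomb_energy(1, 1, 0, 78), "positive")
})

test_that("linearization error report reproduces the worked example", {
  rep <- linearization_error_report(-0.852, 0.593, 3)
  expect_equal(rep$exact, 4.207, tolerance = 5e-4)
  expect_equal(rep$table$approximation[1], 2.437, tolerance = 5e-4)
  expect_equal(rep$table$approximation[2], 3.469, tolerance = 5e-4)
  expect_equal(rep$table$approximation[3], 3.964, tolerance = 2e-3)
  expect_equal(round(rep$table$relative_error_pct), c(42, 18, 6))
  expect_equal(round(rep$table$pka_error[1], 2), 0.24)
  # zero interaction: every approximation is exact
  z <- linearization_error_report(0, 0.593, 4)
  expect_true(all(z$table$approximation == 1))
  expect_true(all(z$table$relative_error_pct == 0))
  # high orders converge to the exponential
  h <- linearization_error_report(-0.852, 0.593, 10)
  expect_lt(abs(h$table$approximation[10] - h$exact) / h$exact, 1e-6)
})
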