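# Fixtures built in code: toy frames, cheap solver settings, and small
# constructors shared across the test files.

toy_atoms <- function(n = 3, chain = "A", resname = "BCK", resid = 1L,
                      charge = 0, radius = 1.5) {
  data.frame(
    atom_name = paste0("Q", seq_len(n)), element = "C",
    residue_name = resname, residue_id = resid, chain_id = chain,
    x = seq_len(n) * 2.0, y = 0, z = 0,
    charge = charge, radius = radius, stringsAsFactors = FALSE)
}

# a single titratable fragment, optionally with fixed background charges
single_site_frame <- function(residue = "GLU", background = NULL) {
  make_toy_membrane_system(toy_system_spec(
    sites = data.frame(residue_name = residue, chain_id = "A",
                       residue_id = 10L, x = 0, y = 0, z = 0,
                       stringsAsFactors = FALSE),
    background = background))
}

# settings cheap enough for per-test pKa evaluations: single-pass solve on
# a 1.2 A grid with modest padding
cheap_settings <- function(ionic = 0.15, ...) {
  pka_settings(constants = pb_constants(ionic_strength = ionic, kbt = 0.593),
               coarse_spacing = 1.2, fine_spacing = 1.2,
               padding = 6, fine_extent = 8, ...)
}

point_charge_frame <- function(q = 1, radius = 0) {
  structure_frame(data.frame(
    atom_name = "Q1", element = "C", residue_name = "BCK", residue_id = 1L,
    chain_id = "X", x = 0, y = 0, z = 0, charge = q, radius = radius,
    stringsAsFactors = FALSE))
}

uniform_region_values <- function(eps) {
  c(reference = 1, membrane_core = eps, headgroups = eps, protein = eps,
    solvent = eps)
}

# direct single-grid solve of a point charge in a uniform dielectric
solve_point_charge <- function(spacing, padding, eps = 80, ionic = 0,
                               q = 1, radius = 0, kbt = 0.593) {
  cst <- pb_constants(ionic_strength = ionic, kbt = kbt)
  fr <- point_charge_frame(q, radius)
  grid <- build_grid(fr, spacing, padding)
  rv <- uniform_region_values(eps)
  diel <- build_dielectric_map(fr, grid, NULL, rv)
  scr <- build_screening_map(diel, cst)
  ch <- data.frame(x = 0, y = 0, z = 0, charge = q)
  list(potential = solve_linearized_pb(ch, diel, scr, cst),
       grid = grid, charges = ch, constants = cst)
}

# grid Born solvation energy: heterogeneous (eps_in sphere in eps_out
# solvent) minus homogeneous eps_in reference, same grid
born_energy_grid <- function(spacing, R = 2, eps_in = 1, eps_out = 80,
                             padding = 10) {
  cst <- pb_constants(ionic_strength = 0)
  fr <- point_charge_frame(1, R)
  grid <- build_grid(fr, spacing, padding)
  ch <- data.frame(x = 0, y = 0, z = 0, charge = 1)
  rv_het <- c(reference = 1, membrane_core = eps_in, headgroups = eps_in,
              protein = eps_in, solvent = eps_out)
  rv_hom <- uniform_region_values(eps_in)
  d1 <- build_dielectric_map(fr, grid, NULL, rv_het)
  d0 <- build_dielectric_map(fr, grid, NULL, rv_hom)
  p1 <- solve_linearized_pb(ch, d1, build_screening_map(d1, cst), cst)
  p0 <- solve_linearized_pb(ch, d0, build_screening_map(d0, cst), cst)
  electrostatic_free_energy(p1, ch) - electrostatic_free_energy(p0, ch)
}

born_exact <- function(R = 2, eps_in = 1, eps_out = 80) {
  -332.06 / (2 * R) * (1 / eps_in - 1 / eps_out)
}

interp_phi <- function(pot, pts) {
  pbpka:::interp_grid(pot$phi, pot$grid, matrix(pts, ncol = 3))
}

# Table-3-style printed activation rows used by the classification tests
printed_activation_rows <- function() {
  data.frame(
    site_id = c("His73", "Lys246", "Lys374", "Glu238"),
    f_closed = c(0.01, 0.82, 0.16, 0.00),
    f_start_activation = c(0.20, 0.99, 0.83, 0.00),
    f_end_activation = c(0.22, 0.42, 0.00, 0.63),
    f_start_ssd = c(0.04, 0.95, 0.44, 0.00),
    f_end_ssd = c(0.01, 0.21, 0.00, 0.91),
    complete = TRUE, stringsAsFactors = FALSE)
}
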