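test_that("PQR read/write round-trips charges and coordinates", {
  fr <- structure_frame(toy_atoms(3, charge = c(0.5, 1.0, 0.5)))
  p1 <- withr::local_tempfile(fileext = ".pqr")
  p2 <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(fr, p1)
  rd <- read_structure(p1, "pqr")
  expect_equal(nrow(rd$atoms), 3)
  expect_equal(rd$atoms$charge, c(0.5, 1.0, 0.5))
  expect_equal(sum(rd$atoms$charge), 2.0)
  expect_equal(rd$atoms$x, fr$atoms$x, tolerance = 1e-3)
  # idempotence to printed precision
  write_pqr(rd, p2)
  rd2 <- read_structure(p2, "pqr")
  expect_identical(rd2$atoms[, c("x", "y", "z", "charge", "radius")],
                   rd$atoms[, c("x", "y", "z", "charge", "radius")])
})

test_that("malformed PQR records raise errors naming the line", {
  p <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c("ATOM 1 Q1 BCK A 1 0.0 0.0 0.0 0.5 1.5",
               "ATOM 2 Q2 BCK A 1 bad 0.0 0.0 0.5 1.5"), p)
  expect_error(read_structure(p, "pqr"), "line 2")
})

test_that("PDB input gets charges/radii from the parameter table", {
  spec <- toy_system_spec(sites = data.frame(
    residue_name = "GLU", chain_id = "A", residue_id = 5L,
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  fr <- make_toy_membrane_system(spec)
  p <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(xyz = as.numeric(t(as.matrix(fr$atoms[, c("x", "y", "z")]))),
                   resno = fr$atoms$residue_id, resid = fr$atoms$residue_name,
                   eleno = seq_len(nrow(fr$atoms)), elety = fr$atoms$atom_name,
                   chain = fr$atoms$chain_id, file = p)
  rd <- read_structure(p, "pdb")
  expect_equal(nrow(rd$atoms), nrow(fr$atoms))
  # GLU carboxylate got its default-form charges and is titratable downstream
  expect_equal(sum(rd$atoms$charge), -1, tolerance = 1e-9)
  sites <- identify_titratable_sites(rd)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$residue_name, "GLU")
  # unknown element fails the lookup with the atom named
  tab <- default_parameter_table()
  tab$radii <- tab$radii[setdiff(names(tab$radii), "O")]
  expect_error(pbpka:::assign_parameters(rd$atoms, tab), "O")
})

test_that("titratable-site identification follows the include set and chains", {
  sites_df <- data.frame(
    residue_name = c("GLU", "GLU", "LYS"), chain_id = c("A", "A", "B"),
    residue_id = c(1L, 2L, 1L), x = c(0, 8, 16), y = 0, z = 0,
    stringsAsFactors = FALSE)
  fr <- make_toy_membrane_system(toy_system_spec(sites = sites_df))
  expect_length(identify_titratable_sites(fr), 3)
  expect_length(identify_titratable_sites(fr, include = "GLU"), 2)
  expect_length(identify_titratable_sites(fr, include = character(0)), 0)
  expect_error(identify_titratable_sites(fr, include = "ARG"), "ARG")
  # homotrimer: one LYS per chain -> counts divisible by 3
  tri <- make_toy_membrane_system(toy_system_spec(sites = data.frame(
    residue_name = "LYS", chain_id = c("A", "B", "C"), residue_id = 7L,
    x = c(0, 10, 20), y = 0, z = 0, stringsAsFactors = FALSE)))
  st <- identify_titratable_sites(tri)
  expect_length(st, 3)
  expect_equal(length(st) %% 3, 0)
  # deterministic order by (chain, residue_id)
  ids <- vapply(st, `[[`, "", "site_id")
  expect_identical(ids, sort(ids))
})

test_that("charge sets differ by exactly +1 e and carry reference pKas", {
  defs <- default_site_definitions()
  expect_setequal(names(defs), c("ASP", "GLU", "HIS", "LYS"))
  for (d in defs)
    expect_equal(sum(d$charge_sets$protonated) - sum(d$charge_sets$deprotonated),
                 1, tolerance = 1e-12)
  expect_equal(defs$ASP$reference_pka, 3.90)
  expect_equal(defs$GLU$reference_pka, 4.07)
  expect_equal(defs$HIS$reference_pka, 6.04)
  expect_equal(defs$LYS$reference_pka, 10.54)
})

test_that("min side-chain distance matches brute force and is rigid-motion invariant", {
  set.seed(42)
  mk <- function(chain, resid, center) {
    data.frame(atom_name = c("N", "CA", "C", "O", paste0("CB", 1:5)),
               element = c("N", "C", "C", "O", rep("C", 5)),
               residue_name = "XXX", residue_id = resid, chain_id = chain,
               x = center[1] + c(rnorm(4, 0, 0.5), rnorm(5, 0, 1.5)),
               y = center[2] + c(rnorm(4, 0, 0.5), rnorm(5, 0, 1.5)),
               z = center[3] + c(rnorm(4, 0, 0.5), rnorm(5, 0, 1.5)),
               charge = 0, radius = 1.5, stringsAsFactors = FALSE)
  }
  a <- mk("A", 1L, c(0, 0, 0)); b <- mk("A", 2L, c(6, 1, -2))
  fr <- structure_frame(rbind(a, b))
  d <- min_sidechain_distance(fr, "A:1", "A:2")
  # independent brute force over all side-chain heavy-atom pairs
  sca <- a[grepl("CB", a$atom_name), c("x", "y", "z")]
  scb <- b[grepl("CB", b$atom_name), c("x", "y", "z")]
  brute <- min(apply(sca, 1, function(p)
    apply(scb, 1, function(q) sqrt(sum((p - q)^2)))))
  expect_equal(d, brute, tolerance = 1e-12)
  expect_equal(min_sidechain_distance(fr, "A:2", "A:1"), d)
  expect_equal(min_sidechain_distance(fr, "A:1", "A:1"), 0)
  # rigid rotation + translation leaves the distance unchanged
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(fr$atoms[, c("x", "y", "z")]) %*% Rz +
    matrix(c(5, -3, 2), nrow(fr$atoms), 3, byrow = TRUE)
  fr2 <- fr; fr2$atoms[, c("x", "y", "z")] <- xyz
  expect_equal(min_sidechain_distance(fr2, "A:1", "A:2"), d, tolerance = 1e-9)
  # glycine-like residue with no side chain errors
  g <- mk("A", 3L, c(12, 0, 0)); g <- g[g$atom_name %in% c("N", "CA", "C", "O"), ]
  fr3 <- structure_frame(rbind(a, g))
  expect_error(min_sidechain_distance(fr3, "A:1", "A:3"), "side-chain")
})

test_that("export_table writes stable CSV that round-trips", {
  tab <- data.frame(site = paste0("s", 1:15), mean_pka = rnorm(15),
                    sd = runif(15), n = 15L)
  p <- withr::local_tempfile(fileext = ".csv")
  export_table(tab, p)
  rd <- utils::read.csv(p)
  expect_equal(nrow(rd), 15)
  expect_identical(names(rd), names(tab))
  expect_equal(rd$mean_pka, tab$mean_pka, tolerance = 1e-6)
  expect_error(export_table(tab[0, ], p), "empty")
})
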