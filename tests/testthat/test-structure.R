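# build a tiny PDB file in code (two models, an altloc pair, a water)
write_mini_pdb <- function(path) {
  atom <- function(serial, name, alt, res, resno, x, y, z, occ,
                  rec = "ATOM", ele = substr(name, 1, 1)) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, alt, res, "A", resno, x, y, z, occ, 20.0, ele)
  }
  lines <- c(
    "MODEL        1",
    atom(1, "N", " ", "ALA", 1, 0, 0, 0, 1),
    atom(2, "CA", " ", "ALA", 1, 1.5, 0, 0, 1),
    atom(3, "CB", "A", "ALA", 1, 2.0, 1.0, 0, 0.7),
    atom(4, "CB", "B", "ALA", 1, 2.2, 1.2, 0, 0.3),
    atom(5, "N", " ", "GLY", 2, 3.0, 0, 0, 1),
    atom(6, "O", " ", "HOH", 90, 9, 9, 9, 1, rec = "HETATM"),
    "ENDMDL",
    "MODEL        2",
    atom(1, "N", " ", "ALA", 1, 10, 0, 0, 1),
    atom(2, "CA", " ", "ALA", 1, 11.5, 0, 0, 1),
    atom(3, "CB", "A", "ALA", 1, 12.0, 1.0, 0, 0.7),
    atom(4, "CB", "B", "ALA", 1, 12.2, 1.2, 0, 0.3),
    atom(5, "N", " ", "GLY", 2, 13.0, 0, 0, 1),
    atom(6, "O", " ", "HOH", 90, 9, 9, 9, 1, rec = "HETATM"),
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}

test_that("radius of gyration: exact small cases and invariances", {
  two <- data.frame(x = c(0, 2), y = c(0, 0), z = c(0, 0), mass = c(12, 12))
  expect_equal(radius_of_gyration(two), 1)

  dup <- data.frame(x = c(1, 1), y = c(2, 2), z = c(3, 3), mass = c(1, 1))
  expect_equal(radius_of_gyration(dup), 0)

  set.seed(11)
  cloud <- data.frame(x = rnorm(200), y = rnorm(200), z = rnorm(200),
                      mass = runif(200, 1, 32))
  rg0 <- radius_of_gyration(cloud)
  expect_equal(rg0, rg_direct(as.matrix(cloud[, 1:3]), cloud$mass))

  # rigid rotation + translation leaves Rg unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- as.matrix(cloud[, 1:3]) %*% R + 5
  rot <- data.frame(x = xyz2[, 1], y = xyz2[, 2], z = xyz2[, 3],
                    mass = cloud$mass)
  expect_equal(radius_of_gyration(rot), rg0, tolerance = 1e-10)

  # equal masses: weighted and unweighted identical
  eq <- cloud; eq$mass <- 14
  expect_equal(radius_of_gyration(eq),
               radius_of_gyration(eq, mass_weighted = FALSE))
  expect_error(radius_of_gyration(two[1, , drop = FALSE]), "2 atoms")
})

test_that("PDB loading: models, altloc policy, protein filtering, masses", {
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f)

  a1 <- load_structure(f, model = 1)
  # highest-occupancy altloc kept: one CB, the occ 0.70 one
  expect_equal(sum(a1$name == "CB"), 1)
  expect_equal(a1$x[a1$name == "CB"], 2.0)
  # water flagged as non-protein, standard residues flagged as protein
  expect_false(any(a1$is_protein[a1$aa == "HOH"]))
  expect_true(all(a1$is_protein[a1$aa %in% c("ALA", "GLY")]))
  expect_equal(a1$mass[a1$name == "CA"], 12.011)

  a2 <- load_structure(f, model = 2)
  expect_equal(a2$x[a2$name == "N" & a2$resno == 1], 10)
  expect_error(load_structure(f, model = 3), "model")

  all_alt <- load_structure(f, altloc = "all")
  expect_equal(sum(all_alt$name == "CB"), 2)

  rep <- rg_report(f)
  expect_equal(nrow(rep), 2)
  expect_true(all(c("rg_mass", "rg_unweighted") %in% names(rep)))
  # per-model Rg computed on protein atoms only: both models congruent
  expect_equal(rep$rg_mass[1], rep$rg_mass[2], tolerance = 1e-6)
})

test_that("synthetic globular atom sets land near the target Rg", {
  at <- gen_globular_atoms(n_res = 160, rg_target = 15.4, seed = 4)
  expect_equal(radius_of_gyration(at), 15.4, tolerance = 0.05)
  expect_equal(radius_of_gyration(at, mass_weighted = FALSE), 15.4,
               tolerance = 0.05)
  # mass-weighted and unweighted close for homogeneous composition
  rel <- abs(radius_of_gyration(at) -
               radius_of_gyration(at, mass_weighted = FALSE)) /
    radius_of_gyration(at)
  expect_lt(rel, 0.02)
})
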