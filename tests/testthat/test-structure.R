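# PDB I/O, radius assignment, residue centers of mass.

write_lines_pdb <- function(lines) {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("a hand-written glycine PDB parses field-for-field", {
  f <- write_lines_pdb(c(
    "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1      12.560   6.071  -6.342  1.00  0.00           C",
    "ATOM      3  C   GLY A   1      13.075   7.325  -5.650  1.00  0.00           C",
    "END"
  ))
  s <- read_pdb(f)
  expect_equal(nrow(s), 3L)
  expect_equal(nrow(structure_residues(s)), 1L)
  expect_equal(s$x, c(11.104, 12.560, 13.075))
  expect_equal(s$y[1], 6.134)
  expect_equal(s$z[3], -5.650)
  expect_equal(s$element, c("N", "C", "C"))
  expect_true(all(s$mass > 0))
})

test_that("altloc resolution follows the requested policy", {
  # B (occupancy 0.4) printed first, A (0.6) second
  f <- write_lines_pdb(c(
    "ATOM      1  CA BALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "END"
  ))
  s_occ <- read_pdb(f, altloc_policy = "highest_occupancy")
  expect_equal(nrow(s_occ), 1L)
  expect_equal(s_occ$altloc, "A")
  expect_equal(s_occ$x, 1.0)
  s_first <- read_pdb(f, altloc_policy = "first")
  expect_equal(s_first$altloc, "B")
  expect_equal(s_first$x, 0.0)
})

test_that("waters and HETATM ligands are excluded by default", {
  f <- write_lines_pdb(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 101       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3 ZN    ZN A 201       6.000   0.000   0.000  1.00  0.00          ZN",
    "END"
  ))
  expect_equal(nrow(read_pdb(f)), 1L)
  expect_equal(nrow(read_pdb(f, include_hetatm = TRUE)), 2L)
})

test_that("I/O errors are specific", {
  expect_error(read_pdb(tempfile()), class = "porescreen_io_error")
  f_empty <- write_lines_pdb(c("REMARK nothing here", "END"))
  expect_error(read_pdb(f_empty), class = "porescreen_empty_structure")
  f_bad <- write_lines_pdb(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       xx.abc   0.000   0.000  1.00  0.00           C",
    "END"
  ))
  err <- expect_error(read_pdb(f_bad), class = "porescreen_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("write_pdb emits fixed 8.3 coordinate columns without overflow", {
  atoms <- tibble::tibble(
    serial = 1L, name = "CA", element = "C", chain = "A",
    residue_number = 9999L, insertion_code = "", residue_name = "ALA",
    x = 1, y = 2, z = 3, occupancy = 1, altloc = "",
    vdw_radius = 1.85, mass = 12.011
  )
  s <- porescreen:::new_channel_structure(atoms)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  line <- grep("^ATOM", readLines(f), value = TRUE)
  expect_length(line, 1L)
  expect_equal(substr(line, 31, 54), "   1.000   2.000   3.000")
  expect_equal(trimws(substr(line, 23, 26)), "9999")
  s2 <- read_pdb(f)
  expect_equal(s2$residue_number, 9999L)
})

test_that("read(write(s)) round-trips coordinates to 0.001 A", {
  for (seed in c(1, 2)) {
    s <- random_structure(50, seed = seed)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(s, f)
    s2 <- read_pdb(f)
    expect_equal(nrow(s2), nrow(s))
    expect_equal(structure_residues(s2)$key, structure_residues(s)$key)
    expect_lt(max(abs(as.matrix(s2[, c("x", "y", "z")]) -
                        as.matrix(s[, c("x", "y", "z")]))), 0.001)
  }
  toy <- toy_cylinder()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(toy$structure, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s2), nrow(toy$structure))
  expect_lt(max(abs(s2$x - toy$structure$x)), 0.001)
})

test_that("van der Waals radii come from the table with a logged default", {
  atoms <- random_structure(3, seed = 5)
  atoms$element <- c("C", "S", "X")
  atoms$vdw_radius <- NA_real_
  expect_warning(s <- assign_vdw_radii(atoms), "default radius")
  expect_equal(s$vdw_radius, c(1.85, 2.00, 1.70))
  expect_error(
    suppressWarnings(assign_vdw_radii(atoms, table = c(C = 1.85, S = 2.0))),
    class = "porescreen_lookup_error"
  )
})

test_that("radius tables round-trip through plain text", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# element radius", "C 1.85", "N 1.75", "default 1.70"), f)
  tab <- read_radius_table(f)
  expect_equal(tab[["C"]], 1.85)
  expect_equal(tab[["default"]], 1.70)
})

test_that("residue centers of mass match a brute-force accumulation", {
  # singleton residue
  one <- random_structure(1, seed = 9)
  expect_equal(residue_center_of_mass(one, "A:1"),
               c(one$x, one$y, one$z))
  # two equal-mass atoms at (0,0,0) and (2,0,0)
  two <- random_structure(2, seed = 9)
  two$residue_number <- c(1L, 1L)
  two$x <- c(0, 2); two$y <- 0; two$z <- 0
  expect_equal(residue_center_of_mass(two, "A:1"), c(1, 0, 0))
  # 5-atom mixed-element residue vs independent loop
  five <- random_structure(5, seed = 10)
  five$residue_number <- rep(1L, 5)
  five$element <- c("C", "N", "O", "S", "H")
  five$mass <- porescreen:::element_mass(five$element)
  manual <- c(0, 0, 0)
  for (i in 1:5) manual <- manual + five$mass[i] * c(five$x[i], five$y[i], five$z[i])
  manual <- manual / sum(five$mass)
  expect_equal(residue_center_of_mass(five, "A:1"), manual)
  expect_equal(residue_center_of_mass(five, "A:1", scheme = "geometric"),
               c(mean(five$x), mean(five$y), mean(five$z)))
  expect_error(residue_center_of_mass(five, "B:1"),
               class = "porescreen_lookup_error")
})

test_that("centers of mass translate exactly with the structure", {
  s <- toy_hourglass()$structure
  keys <- structure_residues(s)$key[1:20]
  before <- residue_centers(s, keys)
  t_vec <- c(3.5, -1.25, 7)
  s2 <- s
  s2$x <- s2$x + t_vec[1]; s2$y <- s2$y + t_vec[2]; s2$z <- s2$z + t_vec[3]
  after <- residue_centers(s2, keys)
  expect_equal(after$x, before$x + t_vec[1])
  expect_equal(after$y, before$y + t_vec[2])
  expect_equal(after$z, before$z + t_vec[3])
  # and lie inside each residue's bounding box
  ak <- porescreen:::atom_res_keys(s)
  for (k in keys[1:5]) {
    sub <- s[ak == k, ]
    com <- residue_center_of_mass(s, k)
    expect_true(com[1] >= min(sub$x) - 1e-9 && com[1] <= max(sub$x) + 1e-9)
    expect_true(com[3] >= min(sub$z) - 1e-9 && com[3] <= max(sub$z) + 1e-9)
  }
})
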