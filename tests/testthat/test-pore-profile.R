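# Maximal-inscribed-sphere profiling against analytic and grid-search truth.

test_that("a single atom ring gives the analytic R - r sphere", {
  toy <- make_toy_channel(n_rings = 1, atoms_per_ring = 12, ring_radius = 5,
                          atom_vdw = 1.5, seed = 3)
  s <- max_inscribed_sphere(toy$structure, plane_point = c(0, 0, 0),
                            axis = c(0, 0, 1), seed = 1)
  expect_equal(s$radius, 3.5, tolerance = 1e-6)
  expect_equal(c(s$cx, s$cy), c(0, 0), tolerance = 1e-5)
  # off-axis plane point: the optimizer recenters to the same optimum
  s_off <- max_inscribed_sphere(toy$structure, plane_point = c(1, 0, 0),
                                axis = c(0, 0, 1), seed = 1)
  expect_equal(s_off$radius, 3.5, tolerance = 1e-6)
  expect_equal(c(s_off$cx, s_off$cy), c(0, 0), tolerance = 1e-5)
})

test_that("a non-unit axis is normalized with a warning", {
  toy <- toy_cylinder()
  expect_warning(
    s <- max_inscribed_sphere(toy$structure, c(0, 0, 0), c(0, 0, 2), seed = 1),
    "normaliz"
  )
  expect_equal(s$radius, 3.5, tolerance = 1e-6)
})

test_that("cylinder and hourglass profiles match the analytic truth", {
  cyl <- toy_cylinder()
  p <- compute_profile(cyl$structure, axis = c(0, 0, 1), step = 1, seed = 1)
  expect_lt(max(abs(p$radius - cyl$truth_fun(p$z))), 0.1)
  expect_true(all(abs(p$radius - 3.5) < 0.1))
  hg <- toy_hourglass()
  ph <- compute_profile(hg$structure, axis = c(0, 0, 1), step = 0.5, seed = 1)
  expect_lt(max(abs(ph$radius - hg$truth_fun(ph$z))), 0.1)
  # z strictly increasing with constant step
  expect_true(all(diff(ph$z) > 0))
  expect_lt(max(abs(diff(ph$z) - 0.5)), 1e-9)
})

test_that("a step larger than the z-range yields a single station", {
  toy <- toy_cylinder()
  p <- compute_profile(toy$structure, axis = c(0, 0, 1),
                       z_range = c(-0.1, 0.1), step = 5, seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$z, -0.1)
})

test_that("optimizer agrees with an exhaustive 0.05 A grid search", {
  worst <- 0
  for (seed in 1:6) {
    s <- withr::with_seed(seed, {
      n <- 30
      atoms <- tibble::tibble(
        serial = seq_len(n), name = "CA", element = "C", chain = "A",
        residue_number = seq_len(n), insertion_code = "", residue_name = "ALA",
        x = runif(n, -8, 8), y = runif(n, -8, 8), z = rnorm(n, 0, 0.8),
        occupancy = 1, altloc = "", vdw_radius = 1.5, mass = 12.011
      )
      porescreen:::new_channel_structure(atoms)
    })
    opt <- max_inscribed_sphere(s, c(0, 0, 0), c(0, 0, 1),
                                search_radius = 4, seed = seed)
    oracle <- grid_search_radius(s, c(0, 0, 0), c(0, 0, 1), search_radius = 4)
    worst <- max(worst, abs(opt$radius - oracle))
  }
  expect_lt(worst, 0.1)
})

test_that("adding an atom never widens the pore anywhere", {
  toy <- toy_hourglass()
  p0 <- compute_profile(toy$structure, axis = c(0, 0, 1), step = 1, seed = 2)
  extra <- toy$structure[1, ]
  extra$serial <- max(toy$structure$serial) + 1L
  extra$residue_number <- max(toy$structure$residue_number) + 1L
  extra$x <- 0.8; extra$y <- -0.4; extra$z <- 1.3
  s2 <- porescreen:::new_channel_structure(dplyr::bind_rows(toy$structure, extra))
  p1 <- compute_profile(s2, axis = c(0, 0, 1), step = 1, seed = 2)
  expect_true(all(p1$radius <= p0$radius + 1e-6))
})

test_that("profiles are equivariant under rigid motion", {
  toy <- toy_cylinder()
  p0 <- compute_profile(toy$structure, axis = c(0, 0, 1), step = 1, seed = 4)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  # rotate about x-axis too for a non-trivial axis change
  R2 <- matrix(c(1, 0, 0, 0, cos(0.5), -sin(0.5), 0, sin(0.5), cos(0.5)),
               3, 3, byrow = TRUE)
  R <- R2 %*% R
  t_vec <- c(5, -3, 2)
  xyz <- as.matrix(toy$structure[, c("x", "y", "z")]) %*% t(R)
  s2 <- toy$structure
  s2$x <- xyz[, 1] + t_vec[1]
  s2$y <- xyz[, 2] + t_vec[2]
  s2$z <- xyz[, 3] + t_vec[3]
  new_axis <- as.numeric(R %*% c(0, 0, 1))
  p1 <- compute_profile(s2, axis = new_axis, step = 1, seed = 4)
  expect_equal(p1$radius, p0$radius, tolerance = 1e-3)
})

test_that("identical inputs and seed reproduce the profile exactly", {
  toy <- toy_hourglass()
  p1 <- compute_profile(toy$structure, axis = c(0, 0, 1), step = 1, seed = 7)
  p2 <- compute_profile(toy$structure, axis = c(0, 0, 1), step = 1, seed = 7)
  expect_identical(p1$radius, p2$radius)
  expect_identical(p1$cx, p2$cx)
})

test_that("alignment puts the filter minimum at z = 0", {
  hg <- toy_hourglass()
  p <- compute_profile(hg$structure, axis = c(0, 0, 1), step = 0.5, seed = 1)
  pa <- align_on_filter(p, hg$filter_residues, hg$structure, margin = 2)
  expect_equal(pa$z[which.min(abs(pa$radius - min_filter_radius(pa)))], 0)
  expect_equal(min_filter_radius(pa), 2.0, tolerance = 0.1)
  # two mutants of the same toy align their minima at the same z
  hg2 <- make_toy_channel(n_rings = 21, atoms_per_ring = 12, ring_spacing = 1,
                          ring_radius = hourglass_radius(3.0, 0.05),
                          atom_vdw = 1.5, seed = 13)
  p2 <- compute_profile(hg2$structure, axis = c(0, 0, 1), step = 0.5, seed = 1)
  pa2 <- align_on_filter(p2, hg2$filter_residues, hg2$structure, margin = 2)
  z_min1 <- pa$z[which.min(pa$radius)]
  z_min2 <- pa2$z[which.min(pa2$radius)]
  expect_equal(z_min1, z_min2)
})

test_that("flat profiles break alignment ties toward the window midpoint", {
  cyl <- toy_cylinder()
  p <- compute_profile(cyl$structure, axis = c(0, 0, 1), step = 1, seed = 1)
  pa <- align_on_filter(p, cyl$filter_residues, cyl$structure, margin = 3)
  fw <- filter_window(pa)
  # the station mapped to zero was the one nearest the (pre-shift) midpoint
  expect_lt(abs(mean(fw)), attr(pa, "step") / 2 + 1e-9)
  expect_equal(min_filter_radius(pa), 3.5, tolerance = 0.1)
})

test_that("alignment and window errors are reported", {
  hg <- toy_hourglass()
  p <- compute_profile(hg$structure, axis = c(0, 0, 1),
                       z_range = c(5, 9), step = 1, seed = 1)
  expect_error(align_on_filter(p, hg$filter_residues, hg$structure, margin = 1),
               class = "porescreen_alignment_error")
  expect_error(min_filter_radius(p), class = "porescreen_input_error")
  # a window holding exactly one sample returns that sample's radius
  p1 <- porescreen:::`filter_window<-`(p, c(4.9, 5.1))
  expect_equal(min_filter_radius(p1), p$radius[1])
})

test_that("profile TSV export has the documented columns", {
  toy <- toy_cylinder()
  p <- compute_profile(toy$structure, axis = c(0, 0, 1), step = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("z_A", "radius_A", "cx", "cy", "cz", "converged"))
  expect_equal(tab$radius_A, p$radius)
})
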