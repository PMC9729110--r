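# Shared fixtures (built once per test run) and independent oracles.

.toy_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.toy_cache[[name]])) .toy_cache[[name]] <- builder()
  .toy_cache[[name]]
}

toy_cylinder <- function() {
  cached("cylinder", function() {
    make_toy_channel(n_rings = 21, atoms_per_ring = 12, ring_spacing = 1,
                     ring_radius = 5, atom_vdw = 1.5, seed = 11)
  })
}

toy_hourglass <- function() {
  cached("hourglass", function() {
    make_toy_channel(n_rings = 21, atoms_per_ring = 12, ring_spacing = 1,
                     ring_radius = hourglass_radius(3.5, 0.05),
                     atom_vdw = 1.5, seed = 12)
  })
}

# sparse ring lattice used as the clustering universe (3600 residues)
toy_lattice <- function() {
  cached("lattice", function() {
    toy <- make_toy_channel(n_rings = 150, atoms_per_ring = 24,
                            ring_spacing = 3, ring_radius = 13,
                            atom_vdw = 1.5, seed = 42)
    toy$centers <- residue_centers(toy$structure)
    toy
  })
}

toy_residues <- function() {
  cached("residues", function() {
    make_residue_toy_channel(n_rings = 7, residues_per_ring = 8,
                             ring_spacing = 3, ca_radius = 10, seed = 21)
  })
}

# ten single-atom residues on a line, 8 A apart (enumerable universe)
toy_line <- function(n = 10, spacing = 8) {
  atoms <- tibble::tibble(
    serial = seq_len(n), name = "CA", element = "C", chain = "A",
    residue_number = seq_len(n), insertion_code = "", residue_name = "ALA",
    x = 0, y = 0, z = (seq_len(n) - 1) * spacing,
    occupancy = 1, altloc = "", vdw_radius = 1.5, mass = 12.011
  )
  porescreen:::new_channel_structure(atoms, title = "line toy")
}

random_structure <- function(n = 50, seed = 1) {
  withr::with_seed(seed, {
    atoms <- tibble::tibble(
      serial = seq_len(n), name = "CA", element = "C", chain = "A",
      residue_number = seq_len(n), insertion_code = "", residue_name = "ALA",
      x = round(runif(n, -20, 20), 3), y = round(runif(n, -20, 20), 3),
      z = round(runif(n, -20, 20), 3),
      occupancy = 1, altloc = "", vdw_radius = 1.7, mass = 12.011
    )
    porescreen:::new_channel_structure(atoms, title = "random toy")
  })
}

# --- independent oracles ----------------------------------------------------

# exhaustive plane grid search for the maximal inscribed sphere radius
grid_search_radius <- function(structure, plane_point, axis, search_radius,
                               grid_step = 0.05) {
  axis <- axis / sqrt(sum(axis^2))
  b <- porescreen:::plane_basis(axis)
  g <- seq(-search_radius, search_radius, by = grid_step)
  grid <- expand.grid(a = g, b = g)
  grid <- grid[grid$a^2 + grid$b^2 <= search_radius^2, ]
  pts <- cbind(plane_point[1] + grid$a * b$u[1] + grid$b * b$v[1],
               plane_point[2] + grid$a * b$u[2] + grid$b * b$v[2],
               plane_point[3] + grid$a * b$u[3] + grid$b * b$v[3])
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  f <- porescreen:::clearance_at(pts, xyz, structure$vdw_radius)
  max(f)
}

# connected components of the sub-threshold graph via igraph
igraph_components <- function(distances, threshold) {
  adj <- distances < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# exhaustive permutation probability of top-two exceedance on a small universe
exhaustive_top_two_p <- function(distances, k, s1, s2, threshold) {
  n <- nrow(distances)
  combos <- combn(n, k)
  hits <- 0L
  for (i in seq_len(ncol(combos))) {
    sub <- distances[combos[, i], combos[, i]]
    tt <- top_two_statistic(cluster_by_threshold(sub, threshold))
    if (tt[1] >= s1 && tt[2] >= s2) hits <- hits + 1L
  }
  hits / ncol(combos)
}

# exact two-tailed Mann-Whitney p by enumerating all group-label assignments
exhaustive_mwu_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- combn(n, n_a)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-12), mean(u_all >= u_obs - 1e-12)))
}
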