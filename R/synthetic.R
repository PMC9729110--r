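# Synthetic data with known ground truth: toy channel structures whose pore
# profile is analytic, mutation catalogs with planted 3D clusters, and
# stage-labeled catalogs with planted filter-radius effects. Every generator
# is deterministic under its seed and emits its truth alongside the data.

resolve_ring_radius <- function(ring_radius, z) {
  if (is.function(ring_radius)) {
    vapply(z, ring_radius, 1.0)
  } else if (length(ring_radius) == 1L) {
    rep(as.numeric(ring_radius), length(z))
  } else if (length(ring_radius) == length(z)) {
    as.numeric(ring_radius)
  } else {
    abort("ring_radius must be a function, a scalar, or one value per ring",
          class = "porescreen_input_error")
  }
}

#' Hourglass ring-radius profile
#'
#' Convenience constructor for a parabolic constriction
#' `rho(z) = waist + curvature * z^2`, the standard toy shape for a channel
#' with a selectivity filter at z = 0.
#'
#' @param waist Ring radius at the waist (angstrom).
#' @param curvature Quadratic widening per squared angstrom.
#' @return Function of z.
#' @export
hourglass_radius <- function(waist = 3.5, curvature = 0.05) {
  force(waist); force(curvature)
  function(z) waist + curvature * z^2
}

#' Generate a toy channel of stacked atom rings
#'
#' Pseudo-atoms arranged as rings centered on the z axis, one single-atom
#' alanine-coded residue per atom. The exact pore radius at axial position z
#' is known analytically: by symmetry the inscribed sphere sits on the axis,
#' so its radius is `min_j sqrt(rho_j^2 + (z - z_j)^2) - atom_vdw` over the
#' rings j. For gentle radius profiles this reduces to `rho(z) - atom_vdw`.
#'
#' @param n_rings Number of rings; rings are centered on z = 0.
#' @param atoms_per_ring Atoms per ring.
#' @param ring_spacing Axial spacing between rings (angstrom).
#' @param ring_radius Ring radius: scalar, one value per ring, or a function
#'   of z (see [hourglass_radius()]).
#' @param atom_vdw Van der Waals radius assigned to every atom (angstrom);
#'   must be smaller than every ring radius.
#' @param filter_rings Ring indices designated as the selectivity filter;
#'   default the middle ring.
#' @param phase_jitter Randomize each ring's angular phase? Default `TRUE`.
#' @param seed Integer seed for the phase jitter.
#' @return List: `structure` (a `channel_structure` with radii assigned),
#'   `truth` (tibble `z`, `ring_radius`, `pore_radius` at the ring planes),
#'   `truth_fun` (function of z giving the exact pore radius),
#'   `filter_residues` (keys), and the generating parameters as `params`.
#' @export
make_toy_channel <- function(n_rings = 21, atoms_per_ring = 12,
                             ring_spacing = 1, ring_radius = 5,
                             atom_vdw = 1.5, filter_rings = NULL,
                             phase_jitter = TRUE, seed = 1) {
  stopifnot(n_rings >= 1, atoms_per_ring >= 3, ring_spacing > 0, atom_vdw > 0)
  z_rings <- (seq_len(n_rings) - 1) * ring_spacing -
    (n_rings - 1) * ring_spacing / 2
  rho <- resolve_ring_radius(ring_radius, z_rings)
  if (any(rho <= atom_vdw)) {
    abort("ring radius must exceed atom_vdw everywhere (pore self-occluded)",
          class = "porescreen_input_error")
  }
  if (is.null(filter_rings)) filter_rings <- ceiling(n_rings / 2)
  stopifnot(all(filter_rings >= 1 & filter_rings <= n_rings))
  phases <- withr::with_seed(seed, {
    if (phase_jitter) runif(n_rings) else rep(0, n_rings)
  })
  rows <- purrr::map_dfr(seq_len(n_rings), function(j) {
    ang <- 2 * pi * (seq_len(atoms_per_ring) - 1 + phases[j]) / atoms_per_ring
    tibble::tibble(ring = j,
                   x = rho[j] * cos(ang), y = rho[j] * sin(ang),
                   z = z_rings[j])
  })
  n_atoms <- nrow(rows)
  atoms <- tibble::tibble(
    serial = seq_len(n_atoms), name = "CA", element = "C", chain = "A",
    residue_number = seq_len(n_atoms), insertion_code = "",
    residue_name = "ALA", x = rows$x, y = rows$y, z = rows$z,
    occupancy = 1, altloc = "", vdw_radius = atom_vdw, mass = 12.011
  )
  structure <- new_channel_structure(atoms, title = "toy ring-stack channel")
  truth_fun <- function(z) {
    vapply(z, function(zz) min(sqrt(rho^2 + (zz - z_rings)^2)) - atom_vdw, 1.0)
  }
  truth <- tibble::tibble(z = z_rings, ring_radius = rho,
                          pore_radius = truth_fun(z_rings))
  filter_keys <- res_key("A", which(rows$ring %in% filter_rings))
  list(structure = structure, truth = truth, truth_fun = truth_fun,
       filter_residues = filter_keys,
       params = list(n_rings = n_rings, atoms_per_ring = atoms_per_ring,
                   ring_spacing = ring_spacing, atom_vdw = atom_vdw,
                   filter_rings = filter_rings, seed = seed))
}

#' Generate a toy channel of full residues for mutagenesis tests
#'
#' Rings of residues with backbone (N, CA, C), a Cbeta pointing at the pore
#' axis, and the side chain represented in the same effective-sphere form
#' that [mutate_residue()] produces (a single `SCV` pseudo-atom on the
#' CA-CB direction). Because wild-type side chains already live in the
#' mutagenesis model's representation, self-substitution is an exact
#' identity and side-chain volume effects on the pore are directly
#' interpretable.
#'
#' @param n_rings,ring_spacing Ring count and axial spacing (angstrom).
#' @param residues_per_ring Residues per ring.
#' @param ca_radius Distance of the alpha carbons from the axis (angstrom).
#' @param residue 1-letter code lining the pore; default alanine.
#' @param filter_rings Ring indices forming the selectivity filter; default
#'   the middle ring.
#' @param seed Integer seed (angular phase jitter).
#' @return List as in [make_toy_channel()] minus the analytic profile:
#'   `structure`, `filter_residues`, `params`.
#' @export
make_residue_toy_channel <- function(n_rings = 9, residues_per_ring = 8,
                                     ring_spacing = 3, ca_radius = 10,
                                     residue = "A", filter_rings = NULL,
                                     seed = 1) {
  stopifnot(n_rings >= 1, residues_per_ring >= 3)
  if (is.null(filter_rings)) filter_rings <- ceiling(n_rings / 2)
  z_rings <- (seq_len(n_rings) - 1) * ring_spacing -
    (n_rings - 1) * ring_spacing / 2
  res3 <- aa_one_to_three(residue)
  r_eff <- side_chain_effective_radius(residue)
  vdw <- vdw_radii_hole()
  phases <- withr::with_seed(seed, runif(n_rings))
  atom_list <- list()
  resno <- 0L
  serial <- 0L
  for (j in seq_len(n_rings)) {
    ang <- 2 * pi * (seq_len(residues_per_ring) - 1 + phases[j]) / residues_per_ring
    for (i in seq_len(residues_per_ring)) {
      resno <- resno + 1L
      ct <- cos(ang[i]); st <- sin(ang[i])
      e_r <- c(-ct, -st, 0)           # radially inward
      e_t <- c(-st, ct, 0)            # tangent
      ca <- c(ca_radius * ct, ca_radius * st, z_rings[j])
      nn <- ca + 1.46 * (e_t * cos(0.3) + c(0, 0, sin(0.3)))
      cc <- ca + 1.52 * (-e_t * cos(0.3) + c(0, 0, sin(0.3)))
      names_i <- c("N", "CA", "C")
      pos_i <- rbind(nn, ca, cc)
      el_i <- c("N", "C", "C")
      vdw_i <- c(vdw[["N"]], vdw[["C"]], vdw[["C"]])
      if (residue != "G") {
        cb <- ca + 1.53 * e_r
        scv <- ca + max(1.5, r_eff) * e_r
        names_i <- c(names_i, "CB", "SCV")
        pos_i <- rbind(pos_i, cb, scv)
        el_i <- c(el_i, "C", "C")
        vdw_i <- c(vdw_i, vdw[["C"]], r_eff)
      }
      n_i <- length(names_i)
      atom_list[[resno]] <- tibble::tibble(
        serial = serial + seq_len(n_i), name = names_i, element = el_i,
        chain = "A", residue_number = resno, insertion_code = "",
        residue_name = res3,
        x = pos_i[, 1], y = pos_i[, 2], z = pos_i[, 3],
        occupancy = 1, altloc = "",
        vdw_radius = vdw_i,
        mass = element_mass(el_i)
      )
      serial <- serial + n_i
    }
  }
  atoms <- dplyr::bind_rows(atom_list)
  structure <- new_channel_structure(atoms, title = "toy full-residue channel")
  res_of_ring <- matrix(seq_len(n_rings * residues_per_ring),
                        nrow = residues_per_ring)
  filter_keys <- res_key("A", as.integer(res_of_ring[, filter_rings]))
  list(structure = structure, filter_residues = filter_keys,
       params = list(n_rings = n_rings, residues_per_ring = residues_per_ring,
                   ring_spacing = ring_spacing, ca_radius = ca_radius,
                   residue = residue, filter_rings = filter_rings,
                   seed = seed))
}

random_mutant <- function(wt) {
  aa <- amino_acid_table()$code
  vapply(wt, function(w) sample(setdiff(aa, w), 1L), "")
}

#' Plant spatially clustered mutations in a structure
#'
#' Picks cluster seed residues at mutual distance greater than three times
#' the spread, fills each cluster with the nearest residues within the
#' spread of its seed, and draws background mutations uniformly from the
#' remaining residues. The per-record cluster id (0 for background) is the
#' ground truth for recovery tests.
#'
#' @param structure A `channel_structure`.
#' @param cluster_sizes Integer vector of planted cluster sizes.
#' @param cluster_spread Radius (angstrom) around each seed from which its
#'   members are taken; keep below half the clustering threshold for planted
#'   detectability.
#' @param n_background Number of background (unclustered) mutations.
#' @param seed Integer seed.
#' @param scheme Center-of-mass scheme used for distances.
#' @param max_tries Seed-placement retries before giving up.
#' @param centers Optional precomputed [residue_centers()] of the structure.
#' @return Tibble of mutation records (`position`, `wt`, `mut`, `chain`,
#'   `key`, `stage = UNKNOWN`, `true_cluster`).
#' @export
plant_mutation_clusters <- function(structure, cluster_sizes = c(25, 20),
                                    cluster_spread = 6, n_background = 151,
                                    seed = 1,
                                    scheme = c("mass_weighted", "geometric"),
                                    max_tries = 200, centers = NULL) {
  scheme <- match.arg(scheme)
  res <- structure_residues(structure)
  n_clusters <- length(cluster_sizes)
  if (sum(cluster_sizes) + n_background > nrow(res)) {
    abort("catalog larger than the structure's residue count",
          class = "porescreen_generation_error")
  }
  com <- centers %||% residue_centers(structure, res$key, scheme)
  com <- com[match(res$key, com$key), ]
  xyz <- as.matrix(com[, c("x", "y", "z")])
  withr::with_seed(seed, {
    assignment <- NULL
    for (try in seq_len(max_tries)) {
      seeds <- sample(nrow(res), n_clusters)
      if (n_clusters > 1L) {
        sd_mat <- as.matrix(dist(xyz[seeds, , drop = FALSE]))
        if (any(sd_mat[upper.tri(sd_mat)] <= 3 * cluster_spread)) next
      }
      used <- integer(0)
      members <- vector("list", n_clusters)
      ok <- TRUE
      for (ci in seq_len(n_clusters)) {
        d <- sqrt(colSums((t(xyz) - xyz[seeds[ci], ])^2))
        avail <- setdiff(which(d <= cluster_spread), used)
        if (length(avail) < cluster_sizes[ci]) { ok <- FALSE; break }
        members[[ci]] <- avail[order(d[avail])][seq_len(cluster_sizes[ci])]
        used <- c(used, members[[ci]])
      }
      if (ok) {
        assignment <- members
        break
      }
    }
    if (is.null(assignment)) {
      abort("could not place the requested clusters; reduce sizes or spread",
            class = "porescreen_generation_error")
    }
    used <- unlist(assignment)
    background <- sample(setdiff(seq_len(nrow(res)), used), n_background)
    idx <- c(used, background)
    truth <- c(rep(seq_len(n_clusters), cluster_sizes), rep(0L, n_background))
    wt <- aa_three_to_one(res$residue_name[idx])
    wt[is.na(wt)] <- "A"
    tibble::tibble(
      position = res$residue_number[idx],
      wt = wt,
      mut = random_mutant(wt),
      chain = res$chain[idx],
      key = res$key[idx],
      cancer_type = "synthetic",
      stage = factor("UNKNOWN", levels = stage_levels),
      site_resolved = TRUE,
      true_cluster = truth
    )
  })
}

#' Simulate a stage-labeled catalog with planted filter-radius effects
#'
#' Each record's true mutant minimum filter radius is
#' `base_radius + offset + effect[stage] + N(0, noise_sd)`. When
#' `close_fraction` is given, the global offset is solved so the expected
#' fraction of records falling more than `epsilon` below `base_radius`
#' (i.e. classified `close`) equals it; otherwise the offset is 0. The
#' per-record true delta and the analytic expected closed fraction are the
#' ground truth for estimator checks.
#'
#' @param structure A `channel_structure` supplying mutation sites.
#' @param n_per_stage Named integer vector of records per stage. The default
#'   mirrors a pan-cancer staged cohort (47, 73, 74, 27 for stages I-IV).
#' @param stage_effects Named numeric vector: mean shift (angstrom) of the
#'   mutant filter radius per stage.
#' @param noise_sd Gaussian noise s.d. (angstrom).
#' @param base_radius Wild-type minimum filter radius (angstrom).
#' @param close_fraction Optional target overall closed fraction in (0, 1).
#' @param epsilon Neutral band used to define "close" for the target.
#' @param seed Integer seed.
#' @return Tibble of records with `stage`, `wt_min_radius`,
#'   `mut_min_radius`, `true_delta`, plus attribute
#'   `"expected_closed_fraction"`.
#' @export
simulate_stage_catalog <- function(structure,
                                   n_per_stage = c(I = 47, II = 73, III = 74, IV = 27),
                                   stage_effects = c(I = 0, II = -0.05,
                                                     III = -0.1, IV = -0.5),
                                   noise_sd = 0.2, base_radius = 2,
                                   close_fraction = NULL, epsilon = 0.05,
                                   seed = 1) {
  stopifnot(length(n_per_stage) >= 1, all(n_per_stage >= 1))
  if (!all(names(n_per_stage) %in% stage_levels) ||
      !all(names(n_per_stage) %in% names(stage_effects))) {
    abort("n_per_stage and stage_effects must be named by stage",
          class = "porescreen_input_error")
  }
  stages <- rep(names(n_per_stage), n_per_stage)
  eff <- stage_effects[stages]
  w <- n_per_stage / sum(n_per_stage)
  offset <- 0
  if (!is.null(close_fraction)) {
    stopifnot(close_fraction > 0, close_fraction < 1)
    if (noise_sd <= 0) {
      abort("close_fraction needs noise_sd > 0", class = "porescreen_input_error")
    }
    expected_close <- function(off) {
      sum(w * pnorm((-epsilon - off - stage_effects[names(n_per_stage)]) / noise_sd))
    }
    offset <- stats::uniroot(function(off) expected_close(off) - close_fraction,
                             interval = c(-20, 20))$root
  }
  if (base_radius + offset + min(stage_effects[names(n_per_stage)]) -
      4 * noise_sd < 0) {
    abort("planted effects imply negative filter radii; raise base_radius",
          class = "porescreen_input_error")
  }
  res <- structure_residues(structure)
  n <- length(stages)
  withr::with_seed(seed, {
    idx <- sample(nrow(res), n, replace = n > nrow(res))
    wt <- aa_three_to_one(res$residue_name[idx])
    wt[is.na(wt)] <- "A"
    true_delta <- offset + unname(eff) + rnorm(n, 0, noise_sd)
    out <- tibble::tibble(
      position = res$residue_number[idx],
      wt = wt,
      mut = random_mutant(wt),
      chain = res$chain[idx],
      key = res$key[idx],
      cancer_type = "synthetic",
      stage = factor(stages, levels = stage_levels),
      site_resolved = TRUE,
      wt_min_radius = base_radius,
      mut_min_radius = pmax(0, base_radius + true_delta),
      true_delta = true_delta
    )
    attr(out, "expected_closed_fraction") <- if (is.null(close_fraction)) {
      sum(w * pnorm((-epsilon - offset - stage_effects[names(n_per_stage)]) / noise_sd))
    } else {
      close_fraction
    }
    out
  })
}
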