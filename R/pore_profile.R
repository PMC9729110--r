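# HOLE-style pore profiling: at each axial station, find the largest sphere
# centered in the station plane that fits between the van der Waals surfaces
# of the channel atoms. The objective at plane point c is
#   f(c) = min_i( |c - x_i| - r_i )
# maximized over c; the pore radius at the station is f at the optimum,
# capped at radius_cap (beyond which the pore is open to bulk).

normalize_axis <- function(axis) {
  n <- sqrt(sum(axis^2))
  if (n == 0) abort("axis must be non-zero", class = "porescreen_input_error")
  if (abs(n - 1) > 1e-6) {
    warn("axis was not unit length; normalizing")
  }
  axis / n
}

plane_basis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(axis[2] * ref[3] - axis[3] * ref[2],
         axis[3] * ref[1] - axis[1] * ref[3],
         axis[1] * ref[2] - axis[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v)
}

# clearance f at a batch of 3D points: m-vector of min_i(|p - x_i| - r_i)
clearance_at <- function(points, xyz, radii) {
  dx <- outer(points[, 1], xyz[, 1], "-")
  dy <- outer(points[, 2], xyz[, 2], "-")
  dz <- outer(points[, 3], xyz[, 3], "-")
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  apply(sweep(d, 2, radii), 1, min)
}

#' Maximal inscribed sphere in one station plane
#'
#' Finds the point of the plane through `plane_point` normal to `axis` that
#' maximizes the clearance to the nearest atom surface, i.e. the center of
#' the largest sphere inscribed in the pore at that station. The search is
#' derivative-free: a coarse grid over the plane disk of radius
#' `search_radius` seeds multi-start Nelder-Mead refinement.
#'
#' @param structure A `channel_structure` with assigned van der Waals radii.
#' @param plane_point Numeric length-3 point the station plane passes through.
#' @param axis Unit length-3 channel axis (normalized with a warning if not).
#' @param radius_cap Radius (angstrom) above which the pore counts as open to
#'   bulk; default 15.
#' @param search_radius Lateral bound (angstrom) of the center search around
#'   `plane_point`; default 5. The pore center is assumed to lie within this
#'   distance of the seed point (it tracks the previous station's center
#'   during profiling), which keeps the search inside the pore rather than
#'   drifting past the channel wall, where clearance grows again.
#' @param seed Optional integer seed making the jittered starts reproducible;
#'   leave `NULL` when the caller manages the RNG state.
#' @param n_starts Number of local searches (coarse-grid best points plus
#'   jittered copies, or jittered seeds in local mode); default 6.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param coarse_step Spacing (angstrom) of the seeding grid.
#' @param global_starts Seed the local searches from the best points of a
#'   coarse grid over the whole search disk (default). Set `FALSE` to start
#'   only from `plane_point` plus jittered copies: the station then reports
#'   the pocket containing the seed point rather than the best pocket in the
#'   disk. Profiling uses the local mode so the sphere follows the pore path
#'   instead of jumping through gaps in the channel wall.
#' @return One-row tibble: `z` (axial coordinate of the station), `radius`,
#'   `cx`, `cy`, `cz` (sphere center) and `converged`. `converged` is `FALSE`
#'   when the radius was clipped at `radius_cap` or the optimizer hit its
#'   iteration limit.
#' @export
max_inscribed_sphere <- function(structure, plane_point, axis,
                                 radius_cap = 15, search_radius = 5,
                                 seed = NULL,
                                 n_starts = 9, maxit = 400,
                                 coarse_step = 0.5, global_starts = TRUE) {
  if (nrow(structure) == 0L) {
    abort("empty structure", class = "porescreen_empty_structure")
  }
  if (anyNA(structure$vdw_radius)) {
    abort("structure has unassigned van der Waals radii; call assign_vdw_radii()",
          class = "porescreen_input_error")
  }
  stopifnot(radius_cap > 0, search_radius > 0)
  axis <- normalize_axis(axis)
  run <- function() {
    xyz <- as.matrix(structure[, c("x", "y", "z")])
    radii <- structure$vdw_radius
    # only atoms whose sphere can reach a sphere of radius_cap centered in
    # the plane matter; drop the rest for speed (result unchanged)
    axial <- as.numeric((xyz %*% axis) - sum(plane_point * axis))
    keep <- abs(axial) <= radius_cap + radii
    z_station <- sum(plane_point * axis)
    if (!any(keep)) {
      return(tibble::tibble(z = z_station, radius = radius_cap,
                            cx = plane_point[1], cy = plane_point[2],
                            cz = plane_point[3], converged = FALSE))
    }
    xyz <- xyz[keep, , drop = FALSE]
    radii <- radii[keep]
    basis <- plane_basis(axis)
    to3d <- function(ab) {
      plane_point + ab[1] * basis$u + ab[2] * basis$v
    }
    fneg <- function(ab) {
      p <- to3d(ab)
      f <- min(sqrt(colSums((t(xyz) - p)^2)) - radii)
      lateral <- sqrt(sum(ab^2))
      -(f - 10 * max(0, lateral - search_radius)^2)
    }
    starts <- list(c(0, 0))
    if (global_starts) {
      # coarse seeding grid over the search disk
      g <- seq(-search_radius, search_radius, by = coarse_step)
      grid <- as.matrix(expand.grid(a = g, b = g))
      grid <- grid[grid[, 1]^2 + grid[, 2]^2 <= search_radius^2, , drop = FALSE]
      pts <- cbind(plane_point[1] + grid[, 1] * basis$u[1] + grid[, 2] * basis$v[1],
                   plane_point[2] + grid[, 1] * basis$u[2] + grid[, 2] * basis$v[2],
                   plane_point[3] + grid[, 1] * basis$u[3] + grid[, 2] * basis$v[3])
      fg <- clearance_at(pts, xyz, radii)
      ord <- order(fg, decreasing = TRUE)
      n_grid_starts <- min(6L, nrow(grid))
      for (i in seq_len(n_grid_starts)) starts <- c(starts, list(grid[ord[i], ]))
      jitter_base <- grid[ord[1], ]
    } else {
      jitter_base <- c(0, 0)
    }
    n_jit <- max(0L, n_starts - length(starts))
    for (i in seq_len(n_jit)) {
      starts <- c(starts, list(jitter_base + runif(2, -max(coarse_step, 0.5),
                                                   max(coarse_step, 0.5))))
    }
    best <- NULL
    any_conv <- FALSE
    for (s in starts) {
      opt <- stats::optim(s, fneg, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-12))
      if (is.null(best) || opt$value < best$value) best <- opt
      if (opt$convergence == 0L) any_conv <- TRUE
    }
    center <- to3d(best$par)
    f_star <- -best$value
    clipped <- f_star >= radius_cap
    radius <- min(max(f_star, 0), radius_cap)
    tibble::tibble(z = z_station, radius = radius,
                   cx = center[1], cy = center[2], cz = center[3],
                   converged = any_conv && !clipped)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

new_pore_profile <- function(samples, axis, step, radius_cap,
                             filter_window = NULL, structure_label = "") {
  out <- tibble::as_tibble(samples)
  attr(out, "axis") <- axis
  attr(out, "step") <- step
  attr(out, "radius_cap") <- radius_cap
  attr(out, "filter_window") <- filter_window
  attr(out, "structure_label") <- structure_label
  class(out) <- c("pore_profile", class(tibble::tibble()))
  out
}

#' @export
print.pore_profile <- function(x, ...) {
  fw <- attr(x, "filter_window")
  cat(sprintf("<pore_profile> %d stations, z in [%.2f, %.2f]\n",
              nrow(x), min(x$z), max(x$z)))
  if (!is.null(fw)) {
    cat(sprintf("filter window: [%.2f, %.2f], min filter radius %.3f A\n",
                fw[1], fw[2], min_filter_radius(x)))
  }
  NextMethod()
}

#' Filter window of an aligned profile
#'
#' @param profile A `pore_profile`.
#' @return Numeric length-2 `(z_lo, z_hi)` or `NULL` if unset.
#' @export
filter_window <- function(profile) attr(profile, "filter_window")

`filter_window<-` <- function(profile, value) {
  attr(profile, "filter_window") <- value
  profile
}

#' Compute a pore-radius profile along the channel axis
#'
#' One maximal-inscribed-sphere search per axial station, stepping along the
#' axis; each station's search is seeded from the previous station's center
#' so the profile follows a continuous pore path.
#'
#' @inheritParams max_inscribed_sphere
#' @param axis Unit length-3 channel axis, or `NULL`/"principal" to use
#'   [principal_axis()].
#' @param z_range Length-2 axial range in angstrom (projections onto the
#'   axis); default the structure's full axial extent.
#' @param step Station spacing in angstrom; default 0.25.
#' @param search_radius Lateral center-search bound per station (angstrom).
#' @param seed Integer seed; the whole profile is computed under it.
#' @return A `pore_profile` tibble (`z`, `radius`, `cx`, `cy`, `cz`,
#'   `converged`) ordered by `z` with constant step.
#' @export
compute_profile <- function(structure, axis = NULL, z_range = NULL,
                            step = 0.25, radius_cap = 15, search_radius = 5,
                            seed = 1, n_starts = 6, coarse_step = 0.5) {
  stopifnot(step > 0)
  if (is.null(axis) || identical(axis, "principal")) {
    axis <- principal_axis(structure)
  } else {
    axis <- normalize_axis(axis)
  }
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  proj <- as.numeric(xyz %*% axis)
  if (is.null(z_range)) z_range <- range(proj)
  if (z_range[2] < z_range[1]) {
    abort("empty z_range", class = "porescreen_input_error")
  }
  stations <- seq(z_range[1], z_range[2], by = step)
  centroid <- colMeans(xyz)
  withr::with_seed(seed, {
    prev_center <- centroid
    rows <- vector("list", length(stations))
    for (i in seq_along(stations)) {
      zi <- stations[i]
      plane_point <- prev_center + (zi - sum(prev_center * axis)) * axis
      s <- max_inscribed_sphere(structure, plane_point, axis,
                                radius_cap = radius_cap,
                                search_radius = search_radius, seed = NULL,
                                n_starts = n_starts, coarse_step = coarse_step,
                                global_starts = FALSE)
      s$z <- zi
      rows[[i]] <- s
      if (s$converged) prev_center <- c(s$cx, s$cy, s$cz)
    }
    samples <- dplyr::bind_rows(rows)
    if (!any(samples$converged)) {
      abort("no station converged; pore profile is undefined",
            class = "porescreen_profile_error")
    }
    new_pore_profile(samples, axis = axis, step = step,
                     radius_cap = radius_cap,
                     structure_label = attr(structure, "title") %||% "")
  })
}

filter_z_window <- function(structure, filter_residues, axis, margin) {
  keys <- if (is.data.frame(filter_residues)) filter_residues$key else filter_residues
  ak <- atom_res_keys(structure)
  sel <- ak %in% keys
  if (!any(sel)) {
    abort("no filter residues found in structure",
          class = "porescreen_lookup_error")
  }
  xyz <- as.matrix(structure[sel, c("x", "y", "z")])
  proj <- as.numeric(xyz %*% axis)
  c(min(proj) - margin, max(proj) + margin)
}

#' Align a profile on its selectivity filter
#'
#' Sets the filter window to the axial span of the filter residues' atoms
#' plus/minus `margin`, then shifts the z scale so the minimum-radius station
#' inside the window sits at z = 0. Ties for the minimum break toward the
#' station nearest the window midpoint (stable for flat-bottomed profiles),
#' then toward lower z.
#'
#' @param profile A `pore_profile`.
#' @param filter_residues Character vector of residue keys (or a data frame
#'   with a `key` column) designating the selectivity filter.
#' @param structure The `channel_structure` the profile was computed from.
#' @param margin Window padding in angstrom; default 2.
#' @return The profile with shifted `z` and the `filter_window` attribute set.
#' @export
align_on_filter <- function(profile, filter_residues, structure, margin = 2) {
  axis <- attr(profile, "axis")
  win <- filter_z_window(structure, filter_residues, axis, margin)
  inside <- which(profile$z >= win[1] & profile$z <= win[2])
  if (length(inside) == 0L) {
    abort("filter residues lie outside the profiled z range",
          class = "porescreen_alignment_error")
  }
  r <- profile$radius[inside]
  tied <- inside[r <= min(r) + 1e-9]
  mid <- mean(win)
  tied <- tied[order(abs(profile$z[tied] - mid), profile$z[tied])]
  shift <- profile$z[tied[1]]
  profile$z <- profile$z - shift
  profile$cx <- profile$cx - shift * axis[1]
  profile$cy <- profile$cy - shift * axis[2]
  profile$cz <- profile$cz - shift * axis[3]
  filter_window(profile) <- win - shift
  profile
}

#' Minimum selectivity-filter radius
#'
#' The minimum pore radius over stations inside the filter window; the
#' per-structure readout used to compare mutant against wild type.
#'
#' @param profile A `pore_profile` with a set filter window (see
#'   [align_on_filter()]).
#' @return Radius in angstrom.
#' @export
min_filter_radius <- function(profile) {
  fw <- filter_window(profile)
  if (is.null(fw)) {
    abort("profile has no filter window; run align_on_filter() first",
          class = "porescreen_input_error")
  }
  inside <- profile$z >= fw[1] & profile$z <= fw[2]
  if (!any(inside)) {
    abort("no profile samples inside the filter window",
          class = "porescreen_input_error")
  }
  min(profile$radius[inside])
}

#' Write a profile as a tab-separated table
#'
#' Columns `z_A`, `radius_A`, `cx`, `cy`, `cz`, `converged`.
#'
#' @param profile A `pore_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  out <- tibble::tibble(z_A = profile$z, radius_A = profile$radius,
                        cx = profile$cx, cy = profile$cy, cz = profile$cz,
                        converged = profile$converged)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
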