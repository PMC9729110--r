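# Channel structures are tibbles of atoms (one row per atom) with class
# "channel_structure". Columns: serial, name, element, chain, residue_number,
# insertion_code, residue_name, x, y, z, occupancy, altloc, vdw_radius, mass.

structure_cols <- c("serial", "name", "element", "chain", "residue_number",
                    "insertion_code", "residue_name", "x", "y", "z",
                    "occupancy", "altloc", "vdw_radius", "mass")

new_channel_structure <- function(atoms, title = "") {
  atoms <- tibble::as_tibble(atoms)
  missing <- setdiff(structure_cols, names(atoms))
  if (length(missing) > 0L) {
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")),
          class = "porescreen_input_error")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite", class = "porescreen_input_error")
  }
  out <- atoms[, structure_cols]
  attr(out, "title") <- title
  class(out) <- c("channel_structure", class(tibble::tibble()))
  out
}

#' @export
print.channel_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat(sprintf("<channel_structure> %d atoms, %d residues, %d chain(s)\n",
              nrow(x), nrow(res), length(unique(x$chain))))
  if (nzchar(attr(x, "title") %||% "")) cat("title:", attr(x, "title"), "\n")
  NextMethod()
}

# Residue keys are "chain:resnum" with any insertion code appended
# ("A:42", "A:42A"). Vectorized over atom rows.
res_key <- function(chain, residue_number, insertion_code = "") {
  paste0(chain, ":", residue_number,
         ifelse(is.na(insertion_code) | insertion_code == "", "", insertion_code))
}

atom_res_keys <- function(structure) {
  res_key(structure$chain, structure$residue_number, structure$insertion_code)
}

parse_res_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(paste0("malformed residue key(s): ", paste(keys[bad], collapse = ", ")),
          class = "porescreen_input_error")
  }
  chain <- vapply(parts, `[`, "", 1L)
  rest <- vapply(parts, `[`, "", 2L)
  num <- as.integer(sub("([0-9]+).*", "\\1", rest))
  icode <- sub("[0-9]+", "", rest)
  tibble::tibble(key = keys, chain = chain, residue_number = num,
                 insertion_code = icode)
}

#' List the residues of a structure
#'
#' @param structure A `channel_structure`.
#' @return A tibble with one row per residue in file order: `key`, `chain`,
#'   `residue_number`, `insertion_code`, `residue_name`, `n_atoms`.
#' @export
structure_residues <- function(structure) {
  structure |>
    tibble::as_tibble() |>
    dplyr::mutate(key = atom_res_keys(structure)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(chain = dplyr::first(.data$chain),
                     residue_number = dplyr::first(.data$residue_number),
                     insertion_code = dplyr::first(.data$insertion_code),
                     residue_name = dplyr::first(.data$residue_name),
                     n_atoms = dplyr::n(),
                     .first = min(dplyr::cur_group_rows()),
                     .groups = "drop") |>
    dplyr::arrange(.data$.first) |>
    dplyr::select(-".first")
}

guess_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  # CA/NA are ambiguous with protein alpha-carbon / amide names; since the
  # fallback only runs on ATOM records, resolve those to C/N
  known2 <- c("FE", "ZN", "MG", "MN", "SE", "CL", "BR")
  ifelse(nm %in% known2, nm, substr(nm, 1, 1))
}

element_mass <- function(element) {
  m <- element_masses()[toupper(element)]
  unname(ifelse(is.na(m), 12.011, m))
}

validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in atom_idx) {
    flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
              substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(flds))
    if (anyNA(vals)) {
      abort(sprintf("malformed coordinate field on line %d: %s", i,
                    trimws(lines[i])),
            class = "porescreen_parse_error")
    }
  }
  length(atom_idx)
}

#' Read a channel structure from a PDB file
#'
#' Parses fixed-column ATOM records into an atom tibble. Waters and HETATM
#' ligands are excluded by default (the pore profile of the protein channel
#' is the object of interest); alternate locations are resolved per
#' `altloc_policy`. Coordinates are kept exactly as printed (angstrom).
#' Van der Waals radii are not stored in PDB files; call
#' [assign_vdw_radii()] before profiling.
#'
#' @param path Path to a PDB file.
#' @param altloc_policy `"highest_occupancy"` (default; ties broken by file
#'   order) or `"first"`.
#' @param include_hetatm Keep non-water HETATM records? Default `FALSE`.
#' @return A `channel_structure` tibble.
#' @export
read_pdb <- function(path, altloc_policy = c("highest_occupancy", "first"),
                     include_hetatm = FALSE) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) {
    abort(paste0("cannot read PDB file: ", path), class = "porescreen_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  n_atom_records <- validate_pdb_lines(lines)
  if (n_atom_records == 0L) {
    abort(paste0("no ATOM records in ", path),
          class = "porescreen_empty_structure")
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  if (!include_hetatm) at <- dplyr::filter(at, .data$type == "ATOM")
  at <- dplyr::filter(at, !(.data$resid %in% c("HOH", "WAT", "DOD")))
  if (nrow(at) == 0L) {
    abort(paste0("no protein ATOM records retained from ", path),
          class = "porescreen_empty_structure")
  }
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$o[is.na(at$o)] <- 1.0
  # altloc resolution: one atom per (residue, atom name)
  at <- at |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::slice(if (altloc_policy == "highest_occupancy") {
      which.max(.data$o)
    } else {
      1L
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)
  elesy <- as.character(at$elesy)
  elesy[is.na(elesy) | elesy == ""] <- guess_element(at$elety[is.na(elesy) | elesy == ""])
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = as.character(at$elety),
    element = toupper(elesy),
    chain = as.character(at$chain),
    residue_number = as.integer(at$resno),
    insertion_code = as.character(at$insert),
    residue_name = as.character(at$resid),
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    altloc = as.character(at$alt),
    vdw_radius = NA_real_,
    mass = element_mass(elesy)
  )
  new_channel_structure(atoms, title = basename(path))
}

#' Write a channel structure to a PDB file
#'
#' Emits fixed-column ATOM records (8.3 coordinate fields), so a read/write
#' round trip preserves coordinates to the format's 0.001-angstrom precision.
#'
#' @param structure A `channel_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  if (nrow(structure) == 0L) {
    abort("refusing to write an empty structure",
          class = "porescreen_empty_structure")
  }
  ok <- tryCatch({
    bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = as.numeric(t(as.matrix(structure[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(structure)),
      resno = structure$residue_number,
      resid = structure$residue_name,
      eleno = structure$serial,
      elety = structure$name,
      chain = ifelse(structure$chain == "", " ", structure$chain),
      insert = ifelse(structure$insertion_code == "", "", structure$insertion_code),
      alt = ifelse(structure$altloc == "", "", structure$altloc),
      o = structure$occupancy,
      b = rep(0, nrow(structure)),
      elesy = structure$element
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write PDB file: ", path, " (", conditionMessage(ok), ")"),
          class = "porescreen_io_error")
  }
  invisible(path)
}

#' Assign van der Waals radii to every atom
#'
#' @param structure A `channel_structure`.
#' @param table Named numeric vector mapping element symbols to radii in
#'   angstrom; a `default` entry covers unknown elements (see
#'   [vdw_radii_hole()], [read_radius_table()]).
#' @return The structure with `vdw_radius` filled in. Atoms whose element is
#'   missing from the table receive the default radius, with a warning.
#' @export
assign_vdw_radii <- function(structure, table = vdw_radii_hole()) {
  el <- toupper(structure$element)
  r <- unname(table[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (!"default" %in% names(table)) {
      abort(paste0("no radius and no default for element(s): ",
                   paste(unique(el[unknown]), collapse = ", ")),
            class = "porescreen_lookup_error")
    }
    warn(paste0("assigned default radius ", table[["default"]],
                " to element(s): ", paste(unique(el[unknown]), collapse = ", ")))
    r[unknown] <- table[["default"]]
  }
  if (any(r <= 0)) {
    abort("van der Waals radii must be positive", class = "porescreen_input_error")
  }
  structure$vdw_radius <- r
  structure
}

#' Residue centers of mass
#'
#' @param structure A `channel_structure`.
#' @param keys Residue keys (`"chain:resnum"`); default all residues.
#' @param scheme `"mass_weighted"` (default) or `"geometric"` (unweighted
#'   mean of atom positions).
#' @return A tibble `key`, `x`, `y`, `z` in the order of `keys`.
#' @export
residue_centers <- function(structure, keys = NULL,
                            scheme = c("mass_weighted", "geometric")) {
  scheme <- match.arg(scheme)
  ak <- atom_res_keys(structure)
  if (is.null(keys)) keys <- unique(ak)
  missing <- setdiff(keys, unique(ak))
  if (length(missing) > 0L) {
    abort(paste0("residue key(s) not in structure: ",
                 paste(missing, collapse = ", ")),
          class = "porescreen_lookup_error")
  }
  w <- if (scheme == "mass_weighted") structure$mass else rep(1, nrow(structure))
  df <- tibble::tibble(key = ak, x = structure$x, y = structure$y,
                       z = structure$z, w = w) |>
    dplyr::filter(.data$key %in% keys) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(x = sum(.data$x * .data$w) / sum(.data$w),
                     y = sum(.data$y * .data$w) / sum(.data$w),
                     z = sum(.data$z * .data$w) / sum(.data$w),
                     .groups = "drop")
  df[match(keys, df$key), ]
}

#' Center of mass of one residue
#'
#' @inheritParams residue_centers
#' @param key A single residue key.
#' @return Numeric length-3 vector (x, y, z) in angstrom.
#' @export
residue_center_of_mass <- function(structure, key,
                                   scheme = c("mass_weighted", "geometric")) {
  stopifnot(length(key) == 1L)
  df <- residue_centers(structure, key, scheme)
  c(df$x, df$y, df$z)
}

#' Principal axis of a structure
#'
#' Returns the principal axis of the atom distribution (eigenvector of the
#' coordinate covariance) closest to the laboratory z axis, oriented toward
#' positive z. Used as the default channel axis when none is supplied: the
#' pore of a membrane channel runs along its longest principal direction,
#' conventionally deposited near z.
#'
#' @param structure A `channel_structure`.
#' @return Unit numeric length-3 vector.
#' @export
principal_axis <- function(structure) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  cc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(cc), symmetric = TRUE)$vectors
  dots <- abs(ev[3, ])
  ax <- ev[, which.max(dots)]
  if (ax[3] < 0) ax <- -ax
  ax / sqrt(sum(ax^2))
}
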