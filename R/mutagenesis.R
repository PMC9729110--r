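# Effective-sphere point mutagenesis. A mutant side chain is modeled as one
# pseudo-atom ("SCV") on the Cα→Cβ direction: center at
# max(1.5 A, effective_radius) from Cα, van der Waals radius equal to the
# side chain's effective radius. No backbone relaxation and no neighbor
# repacking: clashes are warned about, not resolved. This ranks steric pore
# occlusion deterministically; it does not reproduce rotamer detail.

backbone_atom_names <- c("N", "CA", "C", "O", "OXT",
                         "H", "HA", "H1", "H2", "H3", "HXT")

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Idealized Cβ position from backbone N, CA, C (standard tetrahedral
# construction); used when the residue is glycine.
ideal_cb <- function(n, ca, cc) {
  b <- ca - n
  c2 <- cc - ca
  a <- cross3(b, c2)
  ca - 0.58273431 * a + 0.56802827 * b - 0.54067466 * c2
}

#' Introduce a point mutation with the effective-sphere side-chain model
#'
#' Removes the residue's side-chain atoms beyond Cβ and places a single
#' pseudo-atom (name `SCV`) along the Cα→Cβ direction at distance
#' `max(1.5, effective_radius(mutant))` from Cα, with van der Waals radius
#' equal to the mutant's side-chain effective radius. Backbone and Cβ are
#' retained. Mutating to glycine removes the side chain (including Cβ)
#' entirely; mutating a glycine reconstructs an idealized Cβ direction from
#' the backbone. All other residues are untouched and the input structure is
#' not modified.
#'
#' @param structure A `channel_structure`.
#' @param key Residue key (`"chain:resnum"`).
#' @param expected_wt Expected wild-type 1-letter code; mismatch with the
#'   structure's residue name is an error (catches coordinate-numbering
#'   offsets).
#' @param mutant Mutant 1-letter code.
#' @return A new `channel_structure` with the mutated residue renamed to the
#'   mutant's 3-letter code.
#' @export
mutate_residue <- function(structure, key, expected_wt, mutant) {
  ak <- atom_res_keys(structure)
  rows <- which(ak == key)
  if (length(rows) == 0L) {
    abort(paste0("residue ", key, " is not resolved in the structure"),
          class = "porescreen_unresolved_site")
  }
  wt3 <- structure$residue_name[rows[1]]
  exp3 <- aa_one_to_three(expected_wt)
  if (!identical(toupper(wt3), exp3)) {
    abort(sprintf("wild-type mismatch at %s: structure has %s, expected %s",
                  key, wt3, exp3),
          class = "porescreen_identity_error")
  }
  mut3 <- aa_one_to_three(mutant)
  nm <- structure$name[rows]
  side <- rows[!(nm %in% backbone_atom_names)]
  beyond_cb <- side[structure$name[side] != "CB"]
  drop <- if (mutant == "G") side else beyond_cb
  out <- tibble::as_tibble(structure)
  keep_idx <- setdiff(seq_len(nrow(out)), drop)
  new_rows <- NULL
  if (mutant != "G") {
    ca_row <- rows[nm == "CA"]
    if (length(ca_row) != 1L) {
      abort(paste0("residue ", key, " has no unique CA atom; cannot mutate"),
            class = "porescreen_unresolved_site")
    }
    ca <- as.numeric(out[ca_row, c("x", "y", "z")])
    cb_row <- rows[nm == "CB"]
    if (length(cb_row) == 1L) {
      cb <- as.numeric(out[cb_row, c("x", "y", "z")])
    } else {
      n_row <- rows[nm == "N"]
      c_row <- rows[nm == "C"]
      if (length(n_row) != 1L || length(c_row) != 1L) {
        abort(paste0("residue ", key,
                     " lacks backbone atoms needed to rebuild a side chain"),
              class = "porescreen_unresolved_site")
      }
      cb <- ideal_cb(as.numeric(out[n_row, c("x", "y", "z")]), ca,
                     as.numeric(out[c_row, c("x", "y", "z")]))
    }
    dir <- cb - ca
    dn <- sqrt(sum(dir^2))
    if (dn < 1e-6) {
      abort(paste0("degenerate CA-CB geometry at ", key),
            class = "porescreen_input_error")
    }
    dir <- dir / dn
    r_eff <- side_chain_effective_radius(mutant)
    d <- max(1.5, r_eff)
    pos <- ca + d * dir
    new_rows <- tibble::tibble(
      serial = max(out$serial) + 1L,
      name = "SCV", element = "C",
      chain = out$chain[rows[1]],
      residue_number = out$residue_number[rows[1]],
      insertion_code = out$insertion_code[rows[1]],
      residue_name = mut3,
      x = pos[1], y = pos[2], z = pos[3],
      occupancy = 1, altloc = "",
      vdw_radius = r_eff, mass = 12.011
    )
    # clash report (D13): overlap with other residues' spheres
    others <- out[ak != key, , drop = FALSE]
    if (nrow(others) > 0L && !anyNA(others$vdw_radius)) {
      dd <- sqrt((others$x - pos[1])^2 + (others$y - pos[2])^2 +
                   (others$z - pos[3])^2)
      n_clash <- sum(dd < others$vdw_radius + r_eff - 0.4)
      if (n_clash > 0L) {
        warn(sprintf("mutant side chain at %s clashes with %d neighboring atom(s); not resolved",
                     key, n_clash))
      }
    }
  }
  out$residue_name[rows] <- mut3
  out <- out[keep_idx, , drop = FALSE]
  if (!is.null(new_rows)) {
    # keep the residue's atoms contiguous: insert after its last kept atom
    last_kept <- max(which(atom_res_keys(out) == key))
    out <- dplyr::bind_rows(out[seq_len(last_kept), , drop = FALSE],
                            new_rows,
                            if (last_kept < nrow(out)) {
                              out[(last_kept + 1):nrow(out), , drop = FALSE]
                            })
  }
  new_channel_structure(out, title = attr(structure, "title") %||% "")
}
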