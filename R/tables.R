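# Reference tables: van der Waals radii, element masses, amino-acid
# side-chain volumes. All radii/volumes in angstrom units.

#' HOLE-style "simple" van der Waals radius set
#'
#' The element radii used by convention in HOLE-type pore profiling:
#' C 1.85, N 1.75, O 1.65, S 2.00, H 1.00, P 2.10 angstrom, with a fallback
#' of 1.70 angstrom for anything else. The `default` entry is consulted for
#' elements missing from the table.
#'
#' @return Named numeric vector of radii in angstrom, including a `default`
#'   entry.
#' @export
vdw_radii_hole <- function() {
  c(C = 1.85, N = 1.75, O = 1.65, S = 2.00, H = 1.00, P = 2.10,
    default = 1.70)
}

#' Read a van der Waals radius table from a plain-text file
#'
#' Two whitespace-separated columns: element symbol (or the word `default`)
#' and radius in angstrom. Lines starting with `#` are comments.
#'
#' @param path Path to the table file.
#' @return Named numeric vector usable as the `table` argument of
#'   [assign_vdw_radii()].
#' @export
read_radius_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("radius table not found: ", path), class = "porescreen_io_error")
  }
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("element", "radius"),
                    colClasses = c("character", "numeric"))
  if (nrow(tab) == 0L) {
    abort("radius table is empty", class = "porescreen_input_error")
  }
  setNames(tab$radius, tab$element)
}

# Atomic masses (u) for elements commonly seen in protein models.
element_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
    P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
    CA = 40.078, `NA` = 22.990, K = 39.098, CL = 35.45, MN = 54.938)
}

#' Amino-acid side-chain volumes and effective radii
#'
#' Mean side-chain volumes for the 20 canonical amino acids, obtained as the
#' Zamyatnin mean residue volume minus the glycine (backbone-only) volume of
#' 60.1 cubic angstrom. The effective radius is that of the sphere with the
#' side-chain volume, `(3V / 4 pi)^(1/3)`; glycine has no side chain beyond
#' the alpha carbon, so its volume and radius are zero.
#'
#' @return A tibble with columns `code` (1-letter), `three_letter`,
#'   `side_chain_volume` (cubic angstrom) and `effective_radius` (angstrom).
#' @export
amino_acid_table <- function() {
  aa <- tibble::tribble(
    ~code, ~three_letter, ~side_chain_volume,
    "A", "ALA",  28.5,
    "R", "ARG", 113.3,
    "N", "ASN",  54.0,
    "D", "ASP",  51.0,
    "C", "CYS",  48.4,
    "Q", "GLN",  83.7,
    "E", "GLU",  78.3,
    "G", "GLY",   0.0,
    "H", "HIS",  93.1,
    "I", "ILE", 106.6,
    "L", "LEU", 106.6,
    "K", "LYS", 108.5,
    "M", "MET", 102.8,
    "F", "PHE", 129.8,
    "P", "PRO",  52.6,
    "S", "SER",  28.9,
    "T", "THR",  56.0,
    "W", "TRP", 167.7,
    "Y", "TYR", 133.5,
    "V", "VAL",  79.9
  )
  aa$effective_radius <- (3 * aa$side_chain_volume / (4 * pi))^(1 / 3)
  aa
}

aa_one_to_three <- function(code) {
  tab <- amino_acid_table()
  out <- tab$three_letter[match(code, tab$code)]
  if (anyNA(out)) {
    abort(paste0("unknown amino-acid code(s): ",
                 paste(unique(code[is.na(out)]), collapse = ", ")),
          class = "porescreen_lookup_error")
  }
  out
}

aa_three_to_one <- function(three) {
  tab <- amino_acid_table()
  tab$code[match(toupper(three), tab$three_letter)]
}

#' Effective side-chain radius of an amino acid
#'
#' Radius of the sphere whose volume equals the residue's mean side-chain
#' volume. Used by the effective-sphere mutagenesis model.
#'
#' @param code Character vector of 1-letter amino-acid codes.
#' @return Numeric vector of radii in angstrom (0 for glycine).
#' @export
#' @examples
#' side_chain_effective_radius(c("G", "A", "W"))
side_chain_effective_radius <- function(code) {
  tab <- amino_acid_table()
  idx <- match(code, tab$code)
  if (anyNA(idx)) {
    abort(paste0("unknown amino-acid code(s): ",
                 paste(unique(code[is.na(idx)]), collapse = ", ")),
          class = "porescreen_lookup_error")
  }
  tab$effective_radius[idx]
}
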