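# Built-in physico-chemical lookup tables.
#
# All tables are keyed by upper-case identifiers (element symbol or
# three-letter residue code) and exposed through accessor functions so the
# defaults can be swapped per call without touching package state.

# van der Waals radii (Angstrom), Bondi-style values for the elements that
# dominate protein/ligand structures; anything else falls back to carbon.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

.vdw_default <- 1.70

# standard atomic masses (u)
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, F = 18.998, CL = 35.45,
                    BR = 79.904, I = 126.904)

.mass_default <- 12.011

#' Van der Waals radius lookup
#'
#' Returns the built-in van der Waals radius for each element symbol.
#' Unknown elements get the carbon radius (1.70 A) with a warning.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "O", "H"))
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(as.character(element)))
  r <- unname(.vdw_radii[key])
  miss <- is.na(r) | is.na(key) | key == ""
  if (any(miss)) {
    unknown <- unique(key[miss])
    warn(paste0("unknown element(s) ", paste(unknown, collapse = ", "),
                "; using default vdW radius ", .vdw_default, " A"))
    r[miss] <- .vdw_default
  }
  r
}

# internal: mass lookup, silent default (masses only feed the centre of mass)
atomic_mass <- function(element) {
  key <- toupper(trimws(as.character(element)))
  m <- unname(.atomic_masses[key])
  m[is.na(m)] <- .mass_default
  m
}

#' Kyte-Doolittle hydropathy scale
#'
#' The standard Kyte-Doolittle hydropathy index for the 20 proteinogenic
#' amino acids, keyed by three-letter residue code. Positive values are
#' hydrophobic.
#'
#' @return Named numeric vector of length 20.
#' @examples
#' kyte_doolittle()[["ILE"]]  # 4.5
#' @export
kyte_doolittle <- function() {
  c(ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
    MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
    TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
    GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5)
}

#' Load a hydrophobicity scale from a two-column file
#'
#' Reads a whitespace- or comma-separated file with residue code in the
#' first column and scale value in the second, for use in place of the
#' built-in Kyte-Doolittle table.
#'
#' @param path Path to the table.
#' @return Named numeric vector keyed by upper-case residue code.
#' @export
load_hydrophobicity_scale <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           col.names = c("residue", "value"),
                           stringsAsFactors = FALSE)
  if (!is.numeric(tab$value)) abort("second column of a scale file must be numeric")
  setNames(tab$value, toupper(tab$residue))
}

# residue-level hydrogen-bond donor/acceptor classes (static default table)
.donor_acceptor <- c(
  ASP = "acceptor", GLU = "acceptor",
  LYS = "donor", ARG = "donor", TRP = "donor",
  SER = "both", THR = "both", TYR = "both",
  ASN = "both", GLN = "both", HIS = "both"
)

#' Donor/acceptor class of residues
#'
#' Static residue-level classification used to colour lining-residue
#' timelines: Asp/Glu acceptors; Lys/Arg/Trp donors; Ser/Thr/Tyr/Asn/Gln/His
#' both; all other residues "none".
#'
#' @param resname Character vector of three-letter residue codes.
#' @return Character vector with values "donor", "acceptor", "both", "none".
#' @export
donor_acceptor_class <- function(resname) {
  cls <- unname(.donor_acceptor[toupper(resname)])
  cls[is.na(cls)] <- "none"
  cls
}

# residue-level formal charge used for timeline colouring by charge
residue_formal_charge <- function(resname) {
  chg <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)[toupper(resname)]
  chg[is.na(chg)] <- 0
  unname(chg)
}

# the four positional categories, in classification priority order
.categories <- c("active_site", "outside", "inside", "surface")

#' Category colour map for the trajectory overview
#'
#' Outside is white, surface blue, inside orange and active site red.
#'
#' @return Named character vector of colours.
#' @export
category_colors <- function() {
  c(outside = "white", surface = "#3465a4", inside = "#f57900",
    active_site = "#cc0000")
}
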