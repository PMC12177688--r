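#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices for the 20 standard amino acids,
#' positive = hydrophobic, range -4.5 (Arg) to 4.5 (Ile).
#'
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
kyte_doolittle <- function() {
  c(ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
    MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
    TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
    GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5)
}

#' Van der Waals radii used for SASA
#'
#' Per-element radii in Angstrom. Elements not listed fall back to the
#' carbon radius (1.70) with a warning at the point of use.
#'
#' @return Named numeric vector keyed by element symbol.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

# e*Angstrom -> Debye
EA_TO_DEBYE <- 4.8032

# Formal-charge scheme: unit charges placed on single side-chain atoms.
# Asp/Glu carry -1 on the carboxylate carbon, Lys +1 on NZ, Arg +1 on CZ;
# His neutral; chain termini ignored.
formal_charge_table <- function() {
  data.frame(
    resname = c("ASP", "GLU", "LYS", "ARG"),
    atom    = c("CG",  "CD",  "NZ",  "CZ"),
    charge  = c(-1,    -1,    +1,    +1),
    stringsAsFactors = FALSE
  )
}

# Coarse heavy-atom partial-charge table (hydrogens lumped onto their
# parent heavy atom). Backbone identical for all residues; side-chain
# charges sum, with the backbone, to the residue's formal charge.
# This is a deliberately simple bundled scheme, selectable next to the
# formal scheme so outputs always record which one produced them.
partial_charge_table <- function() {
  bb <- function(res) data.frame(
    resname = res, atom = c("N", "CA", "C", "O"),
    charge = c(-0.30, 0.05, 0.50, -0.25), stringsAsFactors = FALSE)
  sc <- rbind(
    data.frame(resname = "SER", atom = c("CB", "OG"),  charge = c(0.25, -0.25)),
    data.frame(resname = "THR", atom = c("CB", "OG1"), charge = c(0.25, -0.25)),
    data.frame(resname = "CYS", atom = c("CB", "SG"),  charge = c(0.11, -0.11)),
    data.frame(resname = "TYR", atom = c("CZ", "OH"),  charge = c(0.25, -0.25)),
    data.frame(resname = "ASN", atom = c("CG", "OD1", "ND2"), charge = c(0.55, -0.55, 0.00)),
    data.frame(resname = "GLN", atom = c("CD", "OE1", "NE2"), charge = c(0.55, -0.55, 0.00)),
    data.frame(resname = "MET", atom = c("CG", "SD", "CE"),   charge = c(0.05, -0.10, 0.05)),
    data.frame(resname = "HIS", atom = c("ND1", "CE1"),       charge = c(-0.20, 0.20)),
    data.frame(resname = "TRP", atom = c("CD1", "NE1"),       charge = c(0.15, -0.15)),
    data.frame(resname = "ASP", atom = c("CG", "OD1", "OD2"), charge = c(0.40, -0.70, -0.70)),
    data.frame(resname = "GLU", atom = c("CD", "OE1", "OE2"), charge = c(0.40, -0.70, -0.70)),
    data.frame(resname = "LYS", atom = c("CE", "NZ"),         charge = c(0.30, 0.70)),
    data.frame(resname = "ARG", atom = c("NE", "CZ", "NH1", "NH2"),
               charge = c(-0.10, 0.50, 0.30, 0.30))
  )
  res <- unique(c("ALA", "GLY", "VAL", "LEU", "ILE", "PRO", "PHE", sc$resname))
  rbind(do.call(rbind, lapply(res, bb)), sc)
}

standard_residues <- function() names(kyte_doolittle())
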