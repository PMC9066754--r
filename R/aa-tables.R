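# Amino-acid tables: name maps, side-chain heavy-atom topology as
# internal-coordinate templates, and ring-closure bonds for the bond graph.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- AA3
names(AA3_FROM_1) <- AA1

#' Convert between three-letter and one-letter residue codes
#' @param x character vector of residue codes.
#' @return Character vector of converted codes; unknown codes become `NA`.
#' @export
aa_three_to_one <- function(x) unname(AA1[toupper(x)])

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) unname(AA3_FROM_1[toupper(x)])

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Ideal backbone geometry used for chain extension (lengths in Angstrom,
# angles in degrees).
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5
)

# Side-chain internal-coordinate templates.  Each row places one heavy atom
# d from references (a, b, c) with dihedral(a, b, c, d) = chi[tref] + toff
# (tref = 0 means a fixed torsion, value in toff).  CB rows are implicit and
# shared by all residue types (except GLY).
sidechain_zmat <- local({
  row <- function(atom, a, b, c, bond, angle, tref, toff)
    data.frame(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle,
               tref = tref, toff = toff, stringsAsFactors = FALSE)
  g <- function(atom, bond, angle) row(atom, "N", "CA", "CB", bond, angle, 1L, 0)
  list(
    ALA = NULL,
    GLY = NULL,
    SER = g("OG", 1.417, 110.8),
    CYS = g("SG", 1.808, 113.8),
    THR = rbind(g("OG1", 1.433, 109.6),
                row("CG2", "N", "CA", "CB", 1.521, 111.5, 1L, -120)),
    VAL = rbind(g("CG1", 1.527, 110.5),
                row("CG2", "N", "CA", "CB", 1.527, 110.5, 1L, 122)),
    ILE = rbind(g("CG1", 1.530, 110.4),
                row("CG2", "N", "CA", "CB", 1.521, 110.5, 1L, -122),
                row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2L, 0)),
    LEU = rbind(g("CG", 1.530, 116.3),
                row("CD1", "CA", "CB", "CG", 1.521, 110.7, 2L, 0),
                row("CD2", "CA", "CB", "CG", 1.521, 110.7, 2L, 122)),
    PRO = rbind(g("CG", 1.492, 104.5),
                row("CD", "CA", "CB", "CG", 1.503, 106.1, 2L, 0)),
    MET = rbind(g("CG", 1.520, 114.1),
                row("SD", "CA", "CB", "CG", 1.803, 112.7, 2L, 0),
                row("CE", "CB", "CG", "SD", 1.791, 100.2, 3L, 0)),
    ASP = rbind(g("CG", 1.516, 112.6),
                row("OD1", "CA", "CB", "CG", 1.249, 118.5, 2L, 0),
                row("OD2", "CA", "CB", "CG", 1.249, 118.5, 2L, 180)),
    ASN = rbind(g("CG", 1.516, 112.6),
                row("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L, 0),
                row("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
    GLU = rbind(g("CG", 1.520, 114.1),
                row("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
                row("OE1", "CB", "CG", "CD", 1.249, 118.5, 3L, 0),
                row("OE2", "CB", "CG", "CD", 1.249, 118.5, 3L, 180)),
    GLN = rbind(g("CG", 1.520, 114.1),
                row("CD", "CA", "CB", "CG", 1.516, 112.6, 2L, 0),
                row("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L, 0),
                row("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
    LYS = rbind(g("CG", 1.520, 114.1),
                row("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
                row("CE", "CB", "CG", "CD", 1.520, 111.3, 3L, 0),
                row("NZ", "CG", "CD", "CE", 1.489, 111.7, 4L, 0)),
    ARG = rbind(g("CG", 1.520, 114.1),
                row("CD", "CA", "CB", "CG", 1.520, 111.3, 2L, 0),
                row("NE", "CB", "CG", "CD", 1.461, 111.8, 3L, 0),
                row("CZ", "CG", "CD", "NE", 1.329, 124.4, 4L, 0),
                row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0L, 0),
                row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 0L, 180)),
    HIS = rbind(g("CG", 1.497, 113.8),
                row("ND1", "CA", "CB", "CG", 1.378, 122.7, 2L, 0),
                row("CD2", "ND1", "CB", "CG", 1.354, 129.1, 0L, 180),
                row("CE1", "CB", "CG", "ND1", 1.321, 109.3, 0L, 180),
                row("NE2", "CB", "CG", "CD2", 1.374, 107.0, 0L, 180)),
    PHE = rbind(g("CG", 1.502, 113.8),
                row("CD1", "CA", "CB", "CG", 1.391, 120.7, 2L, 0),
                row("CD2", "CD1", "CB", "CG", 1.391, 120.7, 0L, 180),
                row("CE1", "CB", "CG", "CD1", 1.391, 120.7, 0L, 180),
                row("CE2", "CB", "CG", "CD2", 1.391, 120.7, 0L, 180),
                row("CZ", "CG", "CD1", "CE1", 1.391, 120.0, 0L, 0)),
    TYR = rbind(g("CG", 1.502, 113.8),
                row("CD1", "CA", "CB", "CG", 1.391, 120.7, 2L, 0),
                row("CD2", "CD1", "CB", "CG", 1.391, 120.7, 0L, 180),
                row("CE1", "CB", "CG", "CD1", 1.391, 120.7, 0L, 180),
                row("CE2", "CB", "CG", "CD2", 1.391, 120.7, 0L, 180),
                row("CZ", "CG", "CD1", "CE1", 1.391, 120.0, 0L, 0),
                row("OH", "CD1", "CE1", "CZ", 1.377, 119.9, 0L, 180)),
    TRP = rbind(g("CG", 1.498, 113.6),
                row("CD1", "CA", "CB", "CG", 1.365, 126.9, 2L, 0),
                row("CD2", "CD1", "CB", "CG", 1.433, 126.8, 0L, 180),
                row("NE1", "CB", "CG", "CD1", 1.374, 110.2, 0L, 180),
                row("CE2", "CB", "CG", "CD2", 1.409, 107.2, 0L, 180),
                row("CE3", "CD1", "CG", "CD2", 1.398, 133.9, 0L, 180),
                row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 0L, 180),
                row("CZ3", "CE2", "CD2", "CE3", 1.382, 118.6, 0L, 0),
                row("CH2", "CD2", "CE3", "CZ3", 1.400, 121.1, 0L, 0))
  )
})

# Ring-closure bonds not captured by the z-matrix parent chain.
RING_CLOSURES <- list(
  HIS = list(c("CE1", "NE2")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  TRP = list(c("NE1", "CE2"), c("CZ2", "CH2")),
  PRO = list(c("CD", "N"))
)

# Preferred chi values per rotamer: chi1 in {-60, 180, 60}; later chis take
# the residue's canonical values.
DEFAULT_CHI_TAIL <- list(
  SER = 0, CYS = 0, THR = 0, VAL = 0, ALA = 0, GLY = 0,
  ILE = 170, LEU = 175, MET = c(180, 75), ASP = -15, ASN = -20,
  GLU = c(180, -10), GLN = c(180, 20), LYS = c(180, 180, 180),
  ARG = c(180, 180, 180), HIS = 75, PHE = 85, TYR = 85, TRP = 95,
  PRO = 18
)

#' Heavy side-chain atom names for a residue type
#' @param res_type three-letter residue code.
#' @return Character vector of side-chain heavy-atom names (may be empty).
#' @export
sidechain_atom_names <- function(res_type) {
  res_type <- toupper(res_type)
  if (!res_type %in% AA3) stop("unknown residue type: ", res_type)
  if (res_type == "GLY") return(character(0))
  c("CB", sidechain_zmat[[res_type]]$atom)
}

# Intra-residue heavy-atom bond list (pairs of atom names) for the clash graph.
residue_bonds <- function(res_type) {
  res_type <- toupper(res_type)
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (res_type != "GLY") bonds <- c(bonds, list(c("CA", "CB")))
  zm <- sidechain_zmat[[res_type]]
  if (!is.null(zm))
    bonds <- c(bonds, lapply(seq_len(nrow(zm)), function(i) c(zm$c[i], zm$atom[i])))
  cl <- RING_CLOSURES[[res_type]]
  if (!is.null(cl)) bonds <- c(bonds, cl)
  bonds
}
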