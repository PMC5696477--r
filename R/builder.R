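#' Build an idealized dipeptide geometry from internal coordinates
#'
#' Constructs a toy 3D model of an H2N-Xaa-Gly-COOH dipeptide (aromatic
#' residue first) with ideal bond lengths and angles, realising the requested
#' torsions exactly. The model carries only polar hydrogens; it is intended
#' for exercising the geometric classifiers (hydrogen bonds, backbone,
#' swing, orientation, terminus), not for energetics.
#'
#' @param phi2,psi2 backbone dihedrals of the second residue, degrees.
#'   `psi2` is measured to the carboxyl hydroxyl oxygen.
#' @param chi1 side-chain N-CA-CB-CG dihedral, degrees.
#' @param orientation side-chain hydroxyl dihedral in degrees (tyrosine
#'   phenol H; its sign is the fourth part of the structural type). For the
#'   tryptophan template the ring-twist chi2 carries the orientation sign
#'   instead and this argument is ignored.
#' @param amino_swing dihedral of the first amino hydrogen about the N-CA
#'   bond, degrees; its sign separates the A1/A2 terminus classes.
#' @param psi1 backbone dihedral of residue 1 (N1-CA1-C1-N2), degrees. The
#'   default points the amide N-H back toward the amino nitrogen, the
#'   near-universal arrangement in these dipeptides.
#' @param chi2 aromatic ring twist (CA-CB-CG-CD1), degrees.
#' @param cooh_oh carboxyl hydroxyl dihedral (CA2-C2-OT-H), degrees; 180 is
#'   the syn arrangement that can donate back to the peptide carbonyl in
#'   folded gamma-turn structures.
#' @param residue `"Y"` (phenol side chain), `"W"` (indole) or `"G"` (no side
#'   chain).
#' @param label conformer id.
#' @return A [geometry()].
#' @examples
#' g <- build_dipeptide_geometry(phi2 = -84, psi2 = 68, chi1 = 175)
#' classify_backbone(typing_dihedrals(g)$phi2, typing_dihedrals(g)$psi2)
#' @export
build_dipeptide_geometry <- function(phi2, psi2, chi1 = 180,
                                     orientation = 60, amino_swing = 60,
                                     psi1 = -20, chi2 = 80, cooh_oh = 180,
                                     residue = c("Y", "W", "G"),
                                     label = "synthetic") {
  residue <- match.arg(residue)
  el <- character()
  xyz <- NULL
  put <- function(element, pos) {
    el[length(el) + 1L] <<- element
    xyz <<- rbind(xyz, pos)
    nrow(xyz)
  }
  at <- function(i) xyz[i, ]
  # backbone
  n1 <- put("N", c(0, 0, 0))
  ca1 <- put("C", c(1.46, 0, 0))
  th <- (180 - 110.5) * pi / 180
  c1 <- put("C", c(1.46 + 1.52 * cos(th), 1.52 * sin(th), 0))
  o1 <- put("O", place_atom(at(n1), at(ca1), at(c1), 1.23, 121, psi1 + 180))
  n2 <- put("N", place_atom(at(n1), at(ca1), at(c1), 1.335, 115, psi1))
  hn2 <- put("H", place_atom(at(ca1), at(c1), at(n2), 1.01, 119, 0))
  ca2 <- put("C", place_atom(at(ca1), at(c1), at(n2), 1.45, 122, 180))
  c2 <- put("C", place_atom(at(c1), at(n2), at(ca2), 1.52, 111, phi2))
  ot <- put("O", place_atom(at(n2), at(ca2), at(c2), 1.34, 111.5, psi2))
  oct_ <- put("O", place_atom(at(n2), at(ca2), at(c2), 1.21, 125, psi2 + 180))
  hot <- put("H", place_atom(at(ca2), at(c2), at(ot), 0.97, 106, cooh_oh))
  if (residue != "G") {
    cb <- put("C", place_atom(at(c1), at(n1), at(ca1), 1.53, 110, -122))
    cg <- put("C", place_atom(at(n1), at(ca1), at(cb), 1.51, 114, chi1))
    if (residue == "Y") {
      cd1 <- put("C", place_atom(at(ca1), at(cb), at(cg), 1.40, 120, chi2))
      ce1 <- put("C", place_atom(at(cb), at(cg), at(cd1), 1.40, 120, 180))
      cz <- put("C", place_atom(at(cg), at(cd1), at(ce1), 1.40, 120, 0))
      ce2 <- put("C", place_atom(at(cd1), at(ce1), at(cz), 1.40, 120, 0))
      put("C", place_atom(at(ce1), at(cz), at(ce2), 1.40, 120, 0))  # cd2
      os <- put("O", place_atom(at(cd1), at(ce1), at(cz), 1.36, 120, 180))
      put("H", place_atom(at(ce1), at(cz), at(os), 0.97, 110, orientation))
    } else {
      # indole: regular pentagon fused to a regular hexagon, planar
      cd1 <- put("C", place_atom(at(ca1), at(cb), at(cg), 1.40, 126, chi2))
      ne1 <- put("N", place_atom(at(cb), at(cg), at(cd1), 1.40, 108, 180))
      ce2 <- put("C", place_atom(at(cg), at(cd1), at(ne1), 1.40, 108, 0))
      cd2 <- put("C", place_atom(at(cd1), at(ne1), at(ce2), 1.40, 108, 0))
      # six-ring grown from the shared CD2-CE2 edge, coplanar
      cz2 <- put("C", place_atom(at(cd1), at(ne1), at(ce2), 1.40, 132, 180))
      ch2 <- put("C", place_atom(at(cd2), at(ce2), at(cz2), 1.40, 120, 0))
      cz3 <- put("C", place_atom(at(ce2), at(cz2), at(ch2), 1.40, 120, 0))
      put("C", place_atom(at(cz2), at(ch2), at(cz3), 1.40, 120, 0))  # ce3
      put("H", place_atom(at(cg), at(cd1), at(ne1), 1.01, 125, 180))
    }
  }
  put("H", place_atom(at(c1), at(ca1), at(n1), 1.01, 109.5, amino_swing))
  put("H", place_atom(at(c1), at(ca1), at(n1), 1.01, 109.5, amino_swing + 120))
  geometry(el, xyz, label = label)
}
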