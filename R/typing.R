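# display strings for backbone classes (internal names are ASCII)
.BB_DISPLAY <- c(gamma_L = "\u03b3_L", gamma_D = "\u03b3_D", beta = "\u03b2",
                 eps_L = "\u03b5_L", eps_D = "\u03b5_D", alpha_L = "\u03b1_L")

# canonical (phi2, psi2) centres of the backbone classes
.BB_CENTERS <- rbind(
  gamma_L = c(-84, 68),
  gamma_D = c(84, -68),
  beta    = c(-180, 180),
  eps_L   = c(-75, 160),
  eps_D   = c(75, -160),
  alpha_L = c(60, 45))

.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y <= -180, y + 360, y)
}

#' Classify the side-chain swing angle
#'
#' Maps the chi1 dihedral (N-CA-CB-CG) to its swing class by nearest canonical
#' value on the circle: +180 is `g+`, +60 is `g-` and -60 is `a`. Ties are
#' resolved in the order g+, g-, a.
#'
#' @param chi1 dihedral in degrees, interval (-180, 180].
#' @return One of `"g+"`, `"g-"`, `"a"`.
#' @examples
#' classify_swing(175)  # "g+"
#' classify_swing(58)   # "g-"
#' @export
classify_swing <- function(chi1) {
  stopifnot(is.finite(chi1))
  canon <- c("g+" = 180, "g-" = 60, "a" = -60)
  d <- abs(.wrap180(chi1 - canon))
  names(canon)[which.min(d)]
}

#' Classify the backbone dihedrals
#'
#' Assigns the (phi2, psi2) backbone dihedral pair of the second residue to
#' the nearest canonical Ramachandran centre on the torus (Euclidean distance
#' with periodic wrapping). Gamma-turn classes are folded (`F`); beta,
#' epsilon and alpha classes are extended (`E`).
#'
#' @param phi2,psi2 backbone dihedrals in degrees.
#' @return A list with `backbone` (one of `gamma_L`, `gamma_D`, `beta`,
#'   `eps_L`, `eps_D`, `alpha_L`) and `fold` (`"F"` or `"E"`).
#' @examples
#' classify_backbone(-84, 68)    # gamma_L, folded
#' classify_backbone(170, -175)  # beta by periodic wrap
#' @export
classify_backbone <- function(phi2, psi2) {
  stopifnot(is.finite(phi2), is.finite(psi2))
  d2 <- .wrap180(phi2 - .BB_CENTERS[, 1])^2 +
    .wrap180(psi2 - .BB_CENTERS[, 2])^2
  bb <- rownames(.BB_CENTERS)[which.min(d2)]
  list(backbone = bb, fold = if (startsWith(bb, "gamma")) "F" else "E")
}

#' Classify the amino-terminus configuration
#'
#' The terminus class records how the free amino group engages the peptide
#' bond: `B` when the amine donates to the peptide carbonyl (label
#' `N_1_H...OC_PB` present, `N_PB_H...N_1` absent); otherwise the A family,
#' split into `A1`/`A2` by the sign of the amino-swing dihedral (positive is
#' `A1`). With neither diagnostic hydrogen bond the class is `"U"` (untyped).
#'
#' @param hbond_labels character vector of hydrogen-bond labels (see
#'   [detect_hbonds()]); an `hbond_table` is also accepted.
#' @param amino_swing amino-swing dihedral in degrees.
#' @return One of `"A1"`, `"A2"`, `"B"`, `"U"`.
#' @export
classify_terminus <- function(hbond_labels, amino_swing = NA_real_) {
  if (inherits(hbond_labels, "hbond_table"))
    hbond_labels <- hbond_labels$label
  has <- function(don, acc) any(grepl(paste0("^", don, "_?H"), hbond_labels) &
                                  endsWith(hbond_labels, acc))
  n1_to_ocpb <- has("N_1", "OC_PB")
  npb_to_n1 <- has("N_PB", "N_1")
  if (n1_to_ocpb && !npb_to_n1) return("B")
  if (npb_to_n1) {
    if (!is.finite(amino_swing)) return("U")
    return(if (amino_swing > 0) "A1" else "A2")
  }
  "U"
}

#' Structural type of a conformer
#'
#' A four-part structural code `<terminus>-<backbone>(<fold>)-<swing>/<orient>`
#' such as `A1-gamma_D(F)-g+/+`, rendered with Greek backbone letters by
#' [format_type_label()].
#'
#' @param terminus one of `"A1"`, `"A2"`, `"B"`, `"U"`.
#' @param backbone backbone class name (see [classify_backbone()]).
#' @param swing `"g+"`, `"g-"`, `"a"` or `NA` (no side chain).
#' @param orientation `"+"`, `"-"` or `NA`.
#' @return An object of class `"structural_type"`.
#' @export
structural_type <- function(terminus, backbone, swing = NA_character_,
                            orientation = NA_character_) {
  stopifnot(terminus %in% c("A1", "A2", "B", "U"),
            backbone %in% rownames(.BB_CENTERS))
  if (!is.na(swing)) stopifnot(swing %in% c("g+", "g-", "a"))
  if (!is.na(orientation)) stopifnot(orientation %in% c("+", "-"))
  structure(list(terminus = terminus, backbone = backbone,
                 fold = if (startsWith(backbone, "gamma")) "F" else "E",
                 swing = swing, orientation = orientation),
            class = "structural_type")
}

#' @rdname structural_type
#' @param x a `structural_type`.
#' @export
format_type_label <- function(x) {
  stopifnot(inherits(x, "structural_type"))
  side <- if (is.na(x$swing)) "" else
    paste0("-", x$swing, if (!is.na(x$orientation))
      paste0("/", x$orientation) else "")
  paste0(x$terminus, "-", .BB_DISPLAY[[x$backbone]], "(", x$fold, ")", side)
}

#' @export
format.structural_type <- function(x, ...) format_type_label(x)

#' @export
print.structural_type <- function(x, ...) {
  cat(format_type_label(x), "\n")
  invisible(x)
}

#' @rdname structural_type
#' @param label a type label string; Greek letters and the Unicode minus sign
#'   are both accepted.
#' @export
parse_type_label <- function(label) {
  lab <- gsub("\u2212", "-", trimws(label))
  m <- regmatches(lab, regexec(
    paste0("^(A1|A2|B|U)-(\u03b3_D|\u03b3_L|\u03b2|\u03b5_D|\u03b5_L|",
           "\u03b1_L|gamma_D|gamma_L|beta|eps_D|eps_L|alpha_L)",
    "\\(([FE])\\)(?:-(g\\+|g-|a)(?:/([+-]))?)?$"), lab))[[1]]
  if (!length(m)) stop("cannot parse type label: ", label)
  bb <- m[3]
  if (bb %in% .BB_DISPLAY) bb <- names(.BB_DISPLAY)[match(bb, .BB_DISPLAY)]
  st <- structural_type(m[2], bb,
                        if (nzchar(m[5])) m[5] else NA_character_,
                        if (nzchar(m[6])) m[6] else NA_character_)
  if (st$fold != m[4])
    stop("fold annotation '", m[4], "' contradicts backbone ", bb)
  st
}

# locate the atom quadruples used for typing from perceived roles;
# any entry can be overridden through `config` (a list of 4 atom indices).
.typing_quadruples <- function(geom, info, config = list()) {
  roles <- info$roles
  adj <- info$adj
  el <- geom$element
  idx <- function(role) which(roles == role)[1]
  quad <- list()
  n_pb <- idx("N_PB"); c_pb <- idx("C_PB"); c_t <- idx("C_T")
  o_t <- idx("O_T"); n_1 <- idx("N_1")
  ca2 <- NA_integer_
  if (!is.na(n_pb) && !is.na(c_t)) {
    cand <- intersect(.neighbors(adj, n_pb), .neighbors(adj, c_t))
    cand <- cand[el[cand] == "C"]
    if (length(cand)) ca2 <- cand[1]
  }
  if (!anyNA(c(c_pb, n_pb, ca2, c_t))) quad$phi2 <- c(c_pb, n_pb, ca2, c_t)
  if (!anyNA(c(n_pb, ca2, c_t, o_t))) quad$psi2 <- c(n_pb, ca2, c_t, o_t)
  # side chain: CB = non-ring C bonded to a ring atom (CG) and to a CA
  ring_atoms <- unique(unlist(info$rings))
  if (length(ring_atoms)) {
    for (cb in which(el == "C")) {
      if (cb %in% ring_atoms) next
      nb <- .neighbors(adj, cb)
      cg <- nb[nb %in% ring_atoms]
      ca <- nb[el[nb] == "C" & !(nb %in% ring_atoms)]
      ca <- ca[vapply(ca, function(a)
        any(el[.neighbors(adj, a)] == "N"), TRUE)]
      if (length(cg) && length(ca)) {
        ca <- ca[1]
        nref <- .neighbors(adj, ca)[el[.neighbors(adj, ca)] == "N"][1]
        quad$chi1 <- c(nref, ca, cb, min(cg))
        # chi2-style quadruple doubles as the W orientation dihedral
        ring_nb <- sort(.neighbors(adj, min(cg))[
          .neighbors(adj, min(cg)) %in% ring_atoms])
        if (length(ring_nb))
          quad$chi2 <- c(ca, cb, min(cg), ring_nb[1])
        break
      }
    }
  }
  # orientation: side-chain hydroxyl H dihedral when an O_S exists,
  # otherwise the chi2 quadruple (ring twist) as a residue-specific fallback
  o_s <- idx("O_S")
  if (!is.na(o_s)) {
    h_os <- .neighbors(adj, o_s)[el[.neighbors(adj, o_s)] == "H"]
    cz <- .neighbors(adj, o_s)[el[.neighbors(adj, o_s)] != "H"]
    if (length(h_os) && length(cz)) {
      cz <- cz[1]
      ref <- sort(.neighbors(adj, cz)[.neighbors(adj, cz) %in% ring_atoms])
      if (length(ref)) quad$orient <- c(ref[1], cz, o_s, h_os[1])
    }
  } else if (!is.null(quad$chi2)) {
    quad$orient <- quad$chi2
  }
  # amino swing: heavy substituent on CA1 - CA1 - N_1 - first amino H
  if (!is.na(n_1)) {
    ca1 <- .neighbors(adj, n_1)[el[.neighbors(adj, n_1)] == "C"]
    h_n1 <- sort(.neighbors(adj, n_1)[el[.neighbors(adj, n_1)] == "H"])
    if (length(ca1) && length(h_n1)) {
      ca1 <- ca1[1]
      ref <- .neighbors(adj, ca1)
      ref <- sort(ref[el[ref] == "C" & ref != ca1])
      if (length(ref))
        quad$amino_swing <- c(ref[1], ca1, n_1, h_n1[1])
    }
  }
  utils::modifyList(quad, config)
}

.quad_dihedral <- function(geom, q) {
  xyz <- geom$coords
  dihedral(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
}

#' Extract the typing dihedrals of a conformer
#'
#' @param geom a [geometry()] of a capped aromatic dipeptide.
#' @param config optional named list overriding the auto-detected atom
#'   quadruples (`phi2`, `psi2`, `chi1`, `orient`, `amino_swing`), each a
#'   vector of 4 atom indices.
#' @return A list of dihedrals in degrees (entries `NA` when the
#'   corresponding atoms are absent, e.g. `chi1` for glycine).
#' @export
typing_dihedrals <- function(geom, config = list()) {
  info <- assign_atom_roles(geom)
  quad <- .typing_quadruples(geom, info, config)
  want <- c("phi2", "psi2", "chi1", "orient", "amino_swing")
  out <- stats::setNames(as.list(rep(NA_real_, length(want))), want)
  for (w in want)
    if (!is.null(quad[[w]])) out[[w]] <- .quad_dihedral(geom, quad[[w]])
  out
}

#' Derive the full structural type of a conformer geometry
#'
#' Runs hydrogen-bond detection and the dihedral classifiers and composes the
#' four-part structural type.
#'
#' @inheritParams typing_dihedrals
#' @param cutoff hydrogen-bond distance cutoff in Angstrom.
#' @return A [structural_type()].
#' @export
type_label <- function(geom, config = list(), cutoff = 2.8) {
  dih <- typing_dihedrals(geom, config)
  if (!is.finite(dih$phi2) || !is.finite(dih$psi2))
    stop("backbone dihedrals could not be located for ", geom$label)
  hb <- detect_hbonds(geom, cutoff)
  bb <- classify_backbone(dih$phi2, dih$psi2)
  term <- classify_terminus(hb, dih$amino_swing)
  swing <- if (is.finite(dih$chi1)) classify_swing(dih$chi1) else NA_character_
  orient <- if (is.finite(dih$orient)) {
    if (dih$orient > 0) "+" else "-"
  } else NA_character_
  structural_type(term, bb$backbone, swing, orient)
}
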