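# element symbols accepted in geometries (main-group subset covers peptides;
# the full table is not needed but cheap)
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

# single-bond covalent radii (Angstrom) for bond perception
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, F = 0.57,
                P = 1.07, Cl = 1.02, Br = 1.20, I = 1.39)

#' Molecular geometry container
#'
#' A minimal container for one conformer: element symbols, Cartesian
#' coordinates in Angstrom and a conformer id.
#'
#' @param element character vector of element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param label conformer id string.
#' @return An object of class `"geometry"`: a list with fields `element`,
#'   `coords` and `label`.
#' @examples
#' g <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'               label = "water")
#' n_atoms(g)
#' @export
geometry <- function(element, coords, label = "conf_1") {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("`coords` must be an n x 3 matrix")
  if (nrow(coords) < 1L) stop("a geometry needs at least one atom")
  if (length(element) != nrow(coords))
    stop("`element` length must match the number of coordinate rows")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  element <- as.character(element)
  bad <- setdiff(unique(element), .ELEMENTS)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  dimnames(coords) <- NULL
  structure(list(element = element, coords = coords,
                 label = as.character(label)[1]),
            class = "geometry")
}

#' @rdname geometry
#' @param x a `geometry`.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "geometry"))
  nrow(x$coords)
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %s: %d atoms (%s)\n", x$label, n_atoms(x),
              paste(utils::head(x$element, 8), collapse = " ")))
  invisible(x)
}

#' Rigid-body and mirror transforms of a geometry
#'
#' Helpers used mainly in invariance tests: rotate/translate a geometry, or
#' reflect it through the xy-plane (which inverts all torsion angles).
#'
#' @param geom a [geometry()].
#' @param rotation 3x3 rotation matrix.
#' @param shift length-3 numeric translation.
#' @return A transformed `geometry`.
#' @export
transform_geometry <- function(geom, rotation = diag(3), shift = c(0, 0, 0)) {
  stopifnot(inherits(geom, "geometry"))
  geom$coords <- geom$coords %*% t(rotation) +
    matrix(shift, nrow(geom$coords), 3, byrow = TRUE)
  geom
}

#' @rdname transform_geometry
#' @export
mirror_geometry <- function(geom) {
  stopifnot(inherits(geom, "geometry"))
  geom$coords[, 3] <- -geom$coords[, 3]
  geom
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(v) sqrt(sum(v * v))

#' Signed torsion angle of four points
#'
#' Computes the dihedral angle p1-p2-p3-p4 with the biomolecular sign
#' convention: looking down the p2->p3 bond, a clockwise rotation of the
#' far bond relative to the near bond is positive. A cis (eclipsed)
#' arrangement gives 0 degrees, trans gives +180.
#'
#' @param p1,p2,p3,p4 numeric length-3 Cartesian points.
#' @return Angle in degrees in the half-open interval (-180, 180].
#' @examples
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))  # +90
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-10 || .norm3(n2) < 1e-10)
    stop("collinear points: torsion undefined")
  b2h <- b2 / .norm3(b2)
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2h)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle of three points (degrees)
#' @param p1,p2,p3 numeric length-3 points; `p2` is the vertex.
#' @return Angle in degrees in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  ct <- sum(v1 * v2) / (.norm3(v1) * .norm3(v2))
  acos(max(-1, min(1, ct))) * 180 / pi
}

# NeRF atom placement: position D bonded to C with |CD| = r,
# angle(B, C, D) = theta and dihedral(A, B, C, D) = phi (degrees).
place_atom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  bc <- c - b
  bc <- bc / .norm3(bc)
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / .norm3(n)
  m <- .cross3(n, bc)
  mat <- cbind(bc, m, n)
  as.numeric(c + mat %*% d2)
}

# pairwise distance matrix of a coordinate matrix
.dist_matrix <- function(coords) {
  as.matrix(stats::dist(coords))
}

#' Covalent bond perception
#'
#' Two heavy atoms are bonded when their distance is below 1.25 times the sum
#' of single-bond covalent radii; a hydrogen is bonded to the nearest N/O/C
#' within 1.2 Angstrom. Returns the symmetric logical adjacency matrix.
#'
#' @param geom a [geometry()].
#' @return Logical n x n adjacency matrix.
#' @export
covalent_bonds <- function(geom) {
  stopifnot(inherits(geom, "geometry"))
  n <- n_atoms(geom)
  d <- .dist_matrix(geom$coords)
  el <- geom$element
  rad <- .COV_RADII[el]
  rad[is.na(rad)] <- 0.9
  thr <- outer(rad, rad, "+") * 1.25
  adj <- d <= thr & d > 1e-6
  ish <- el == "H"
  # hydrogens: strict 1.2 A rule, single bond to the closest heavy atom
  if (any(ish)) {
    adj[ish, ] <- FALSE
    adj[, ish] <- FALSE
    for (i in which(ish)) {
      heavy <- which(!ish)
      dd <- d[i, heavy]
      ok <- heavy[dd <= 1.2]
      if (length(ok)) {
        j <- ok[which.min(d[i, ok])]
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  diag(adj) <- FALSE
  adj
}
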