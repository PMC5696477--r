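# unicode bits used in hydrogen-bond and structural-type labels
.HB_SEP <- "\u00b7\u00b7\u00b7"   # mid-dot connector
.PI_SYM <- "\u03c0"

.neighbors <- function(adj, i) which(adj[i, ])

# Find 5- and 6-membered rings of C/N atoms in the covalent graph.
# For every edge, drop it and look for a short alternative path between its
# endpoints; endpoint sets of size 5 or 6 are rings. Returns a list of atom
# index vectors (unique by atom set).
.find_rings <- function(adj, element) {
  heavy <- which(element != "H")
  if (length(heavy) < 5) return(list())
  g <- igraph::graph_from_adjacency_matrix(adj[heavy, heavy, drop = FALSE],
                                           mode = "undirected")
  rings <- list()
  es <- igraph::as_edgelist(g)
  for (k in seq_len(nrow(es))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, es[k, ]))
    sp <- suppressWarnings(igraph::shortest_paths(g2, es[k, 1], es[k, 2]))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) %in% c(5L, 6L)) {
      ring <- sort(heavy[path])
      if (all(element[ring] %in% c("C", "N")))
        rings[[length(rings) + 1L]] <- ring
    }
  }
  unique(rings)
}

# group rings sharing >= 2 atoms into fused aromatic systems
.ring_systems <- function(rings) {
  if (!length(rings)) return(list())
  n <- length(rings)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- length(intersect(rings[[i]], rings[[j]])) >= 2L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(k) rings[comp == k])
}

#' Assign chemical roles to atoms of a capped dipeptide
#'
#' Perceives the covalent bond graph and identifies the atoms referenced in
#' hydrogen-bond labels: the N-terminal amine nitrogen (`N_1`), the
#' peptide-bond amide nitrogen (`N_PB`) and its carbonyl oxygen (`OC_PB`),
#' the C-terminal carboxyl hydroxyl (`O_T`) and carbonyl (`O=C_T`) oxygens,
#' a side-chain hydroxyl (`O_S`), an aromatic-ring amide nitrogen (`N_ind`),
#' and aromatic 5-/6-rings (pi acceptors). Atoms with no special role are
#' labelled `<element><index>`.
#'
#' @param geom a [geometry()].
#' @return A list with `roles` (character per atom), `adj` (bond adjacency),
#'   `rings` (list of ring atom-index vectors) and `ring_systems` (rings
#'   grouped into fused systems).
#' @export
assign_atom_roles <- function(geom) {
  stopifnot(inherits(geom, "geometry"))
  adj <- covalent_bonds(geom)
  el <- geom$element
  n <- length(el)
  roles <- paste0(el, seq_len(n))
  rings <- .find_rings(adj, el)
  ring_atoms <- unique(unlist(rings))

  has_h <- function(i) any(el[.neighbors(adj, i)] == "H")
  # carbonyl oxygens: O, no H, single heavy neighbour that is C
  is_carbonyl_o <- vapply(seq_len(n), function(i) {
    el[i] == "O" && !has_h(i) && {
      nb <- .neighbors(adj, i)
      length(nb) == 1L && el[nb] == "C"
    }
  }, TRUE)
  carbonyl_c <- unique(unlist(lapply(which(is_carbonyl_o),
                                     function(i) .neighbors(adj, i))))
  carbonyl_c <- carbonyl_c[!carbonyl_c %in% ring_atoms]

  for (cc in carbonyl_c) {
    nb <- .neighbors(adj, cc)
    oxy <- nb[el[nb] == "O"]
    o_double <- oxy[is_carbonyl_o[oxy]]
    o_hydroxyl <- oxy[!is_carbonyl_o[oxy] & vapply(oxy, has_h, TRUE)]
    nn <- nb[el[nb] == "N" & !(nb %in% ring_atoms)]
    if (length(o_hydroxyl)) {          # carboxyl group
      roles[cc] <- "C_T"
      roles[o_hydroxyl[1]] <- "O_T"
      if (length(o_double)) roles[o_double[1]] <- "O=C_T"
    } else if (length(nn)) {           # amide / peptide bond
      roles[cc] <- "C_PB"
      roles[nn[1]] <- "N_PB"
      if (length(o_double)) roles[o_double[1]] <- "OC_PB"
    }
  }
  # amine nitrogen: not amide, not in a ring
  for (i in which(el == "N")) {
    if (roles[i] != paste0("N", i)) next
    if (i %in% ring_atoms) roles[i] <- "N_ind"
    else if (!any(carbonyl_c %in% .neighbors(adj, i))) roles[i] <- "N_1"
  }
  # side-chain hydroxyl: O-H on a ring carbon
  for (i in which(el == "O")) {
    if (!startsWith(roles[i], "O") || roles[i] %in% c("O_T", "O=C_T")) next
    nb <- .neighbors(adj, i)
    if (has_h(i) && any(nb %in% ring_atoms)) roles[i] <- "O_S"
  }
  list(roles = roles, adj = adj, rings = rings,
       ring_systems = .ring_systems(rings))
}

# shortest bond-path length between two atoms (Inf if disconnected)
.bond_path_len <- function(adj, i, j) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g, v = i, to = j)
  as.numeric(d)
}

#' Detect hydrogen bonds geometrically
#'
#' A hydrogen bond is a contact between a polar hydrogen (covalently bound to
#' N or O within 1.2 Angstrom) and an acceptor, with the H-to-acceptor
#' distance at or below `cutoff`. Acceptors are all N and O atoms plus
#' aromatic-ring centroids (pi acceptors); for fused ring systems only the
#' centroid nearest to the hydrogen is considered. Contacts between atoms
#' separated by three or fewer covalent bonds are excluded, which removes
#' intra-amide and intra-carboxyl contacts that are not hydrogen bonds.
#'
#' @param geom a [geometry()].
#' @param cutoff maximum H-to-acceptor distance in Angstrom (default 2.8,
#'   inclusive).
#' @return A data.frame of class `"hbond_table"` with columns `donor`,
#'   `hydrogen`, `acceptor` (atom index, `NA` for pi centroids), `distance`
#'   and `label` (grammar `<donor>_H...<acceptor>` with roles from
#'   [assign_atom_roles()]). Zero rows when no bond is found.
#' @export
detect_hbonds <- function(geom, cutoff = 2.8) {
  stopifnot(inherits(geom, "geometry"))
  info <- assign_atom_roles(geom)
  adj <- info$adj
  el <- geom$element
  xyz <- geom$coords
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  bp <- igraph::distances(g)

  donors_h <- which(el == "H" & vapply(seq_along(el), function(i)
    any(el[.neighbors(adj, i)] %in% c("N", "O")), TRUE))
  out <- list()
  add <- function(don, hyd, acc, dist, acc_role) {
    don_role <- info$roles[don]
    out[[length(out) + 1L]] <<- data.frame(
      donor = don, hydrogen = hyd, acceptor = acc, distance = dist,
      donor_role = don_role, acceptor_role = acc_role,
      label = paste0(don_role, "_H", .HB_SEP, acc_role),
      stringsAsFactors = FALSE)
  }
  acceptors <- which(el %in% c("N", "O"))
  for (h in donors_h) {
    don <- .neighbors(adj, h)[1]
    for (a in acceptors) {
      if (a == don || adj[h, a]) next
      if (is.finite(bp[h, a]) && bp[h, a] <= 3) next
      d <- sqrt(sum((xyz[h, ] - xyz[a, ])^2))
      if (d <= cutoff) add(don, h, a, d, info$roles[a])
    }
    # pi acceptors: nearest centroid per fused ring system
    for (sys in info$ring_systems) {
      cents <- t(vapply(sys, function(r) colMeans(xyz[r, , drop = FALSE]),
                        numeric(3)))
      dc <- sqrt(rowSums((cents - matrix(xyz[h, ], nrow(cents), 3,
                                         byrow = TRUE))^2))
      best <- which.min(dc)
      ratoms <- sys[[best]]
      if (min(bp[h, ratoms]) <= 3) next
      if (dc[best] <= cutoff) add(don, h, NA_integer_, dc[best], .PI_SYM)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
               distance = numeric(), donor_role = character(),
               acceptor_role = character(), label = character(),
               stringsAsFactors = FALSE)
  class(res) <- c("hbond_table", "data.frame")
  res
}
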