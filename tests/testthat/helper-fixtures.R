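# shared fixture builders and independent oracles

HB <- function(donor, acceptor) paste0(donor, "_H···", acceptor)
PI <- "π"

# folded geometry constructed to the canonical folded H-bond network:
# amide H back to the amine N, carboxyl OH to the peptide carbonyl,
# amino H onto the ring face
folded_pattern_geometry <- function() {
  build_dipeptide_geometry(phi2 = 84, psi2 = -68, chi1 = -30,
                           orientation = 60, amino_swing = 130,
                           psi1 = -20, chi2 = 90, cooh_oh = -30,
                           residue = "Y", label = "folded_pattern")
}

# folded geometry at the literal canonical dihedrals of the yg1-like type
folded_type_geometry <- function() {
  build_dipeptide_geometry(phi2 = 84, psi2 = -68, chi1 = 175,
                           orientation = 60, amino_swing = 60,
                           residue = "Y", label = "folded_type")
}

extended_type_geometry <- function() {
  build_dipeptide_geometry(phi2 = -180, psi2 = 180, chi1 = 60,
                           orientation = 60, amino_swing = -60,
                           residue = "Y", label = "extended_type")
}

toy_energy_table <- function(e_rel, ids = sprintf("c%d", seq_along(e_rel)),
                             gcorr = NULL) {
  df <- data.frame(id = ids, e_rel = e_rel, stringsAsFactors = FALSE)
  if (!is.null(gcorr)) for (nm in names(gcorr)) df[[nm]] <- gcorr[[nm]]
  class(df) <- c("energy_table", "data.frame")
  df
}

# brute-force connected components by boolean transitive closure
oracle_components <- function(ids, edges) {
  n <- length(ids)
  reach <- diag(TRUE, n)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    i <- match(edges[k, 1], ids); j <- match(edges[k, 2], ids)
    reach[i, j] <- reach[j, i] <- TRUE
  }
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    k <- k + 1L
    comp[which(reach[i, ] > 0)] <- k
  }
  split(ids, comp)
}

# plain direct-sum Boltzmann evaluation (no stabilisation shift)
oracle_boltzmann <- function(g, temp) {
  kb <- 1.98720425864083e-3
  w <- numeric(length(g))
  for (i in seq_along(g)) w[i] <- exp(-g[i] / (kb * temp))
  100 * w / sum(w)
}

# graph over the packaged YG table with low edges inside each cooling group
yg_fixture_graph <- function(fx = table1_fixture(),
                             grp = yg_cooling_groups()) {
  g <- igraph::make_empty_graph(n = nrow(fx$energies), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = fx$energies$id)
  for (m in grp$groups)
    for (k in seq_len(length(m) - 1L))
      g <- igraph::add_edges(g, c(m[k], m[k + 1L]))
  g
}
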