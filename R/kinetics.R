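#' Classify a conversion barrier
#'
#' Transition free-energy barriers fall into three classes: low (fast enough
#' to equilibrate during the supersonic expansion), medium and high (both
#' effectively frozen on the cooling timescale). Boundaries are inclusive:
#' a barrier of exactly `low_max` is low, exactly `high_min` is high.
#'
#' @param dg barrier height, kcal/mol (non-negative).
#' @param low_max upper bound of the low class (default 2 kcal/mol).
#' @param high_min lower bound of the high class (default 8 kcal/mol).
#' @return `"low"`, `"medium"` or `"high"`.
#' @examples
#' classify_barrier(1.5)  # low
#' classify_barrier(2.5)  # medium
#' @export
classify_barrier <- function(dg, low_max = 2, high_min = 8) {
  if (!is.finite(dg) || dg < 0) stop("barrier must be non-negative")
  stopifnot(low_max < high_min)
  if (dg <= low_max) "low" else if (dg >= high_min) "high" else "medium"
}

#' Predict the barrier class from two structural types
#'
#' Encodes the empirical barrier rules: conversions that change the backbone
#' fold (folded vs extended), or connect two differently folded backbones,
#' break strong hydrogen bonds and face a high barrier. Conversions between
#' extended conformers with different side-chain types (swing/orientation)
#' face a medium, sterically hindered barrier. Only conversions that keep the
#' side-chain type - terminal-group rotations, or beta/epsilon/alpha
#' exchanges of an extended backbone - are low.
#'
#' @param a,b `structural_type` objects or parseable type-label strings.
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
predict_barrier_class <- function(a, b) {
  if (is.character(a)) a <- parse_type_label(a)
  if (is.character(b)) b <- parse_type_label(b)
  stopifnot(inherits(a, "structural_type"), inherits(b, "structural_type"))
  if (a$terminus == "U" || b$terminus == "U")
    stop("cannot predict a barrier class for untyped conformers")
  side_same <- identical(a$swing, b$swing) &&
    identical(a$orientation, b$orientation)
  if (a$fold != b$fold) return("high")
  if (a$fold == "F") {
    if (a$backbone != b$backbone) return("high")
    return(if (side_same) "low" else "medium")
  }
  if (side_same) "low" else "medium"
}

#' Build the low-barrier conversion graph
#'
#' Nodes are conformers; an edge connects a pair whose conversion barrier is
#' classified low. Explicit barrier values always override type-based
#' predictions for the pairs they cover; remaining pairs use
#' [predict_barrier_class()] when types are supplied, and are otherwise
#' disconnected.
#'
#' @param ids character vector of conformer ids.
#' @param barriers optional `barrier_table` (columns `from`, `to`,
#'   `dg_barrier`).
#' @param types optional named list (or character vector of labels) of
#'   `structural_type`s covering `ids`.
#' @param low_max,high_min barrier-class boundaries, kcal/mol.
#' @return An igraph undirected graph whose vertices are named by `ids`.
#' @export
build_conversion_graph <- function(ids, barriers = NULL, types = NULL,
                                   low_max = 2, high_min = 8) {
  ids <- as.character(ids)
  stopifnot(!anyDuplicated(ids))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (!length(ids)) return(g)
  edges <- character(0)
  covered <- character(0)
  pkey <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "\r")
  if (!is.null(barriers)) {
    stopifnot(all(c("from", "to", "dg_barrier") %in% names(barriers)))
    miss <- setdiff(unique(c(barriers$from, barriers$to)), ids)
    if (length(miss))
      stop("barrier table names unknown conformer(s): ",
           paste(miss, collapse = ", "))
    for (k in seq_len(nrow(barriers))) {
      covered <- c(covered, pkey(barriers$from[k], barriers$to[k]))
      if (classify_barrier(barriers$dg_barrier[k], low_max,
                           high_min) == "low")
        edges <- c(edges, barriers$from[k], barriers$to[k])
    }
  }
  if (!is.null(types)) {
    if (is.character(types))
      types <- stats::setNames(lapply(types, parse_type_label), names(types))
    if (is.null(names(types)) || !all(ids %in% names(types)))
      stop("`types` must be named and cover all ids")
    if (length(ids) > 1L) {
      cmb <- utils::combn(ids, 2L)
      for (k in seq_len(ncol(cmb))) {
        i <- cmb[1, k]; j <- cmb[2, k]
        if (pkey(i, j) %in% covered) next
        if (predict_barrier_class(types[[i]], types[[j]]) == "low")
          edges <- c(edges, i, j)
      }
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

#' Pool populations over kinetic basins
#'
#' Connected components of the low-barrier conversion graph are kinetic
#' basins: during the rapid expansion cooling each basin's population
#' collapses onto its sink, the member with the lowest free energy at the
#' relaxation reference temperature (default 10 K). The pooled population of
#' a basin is the sum of its members' equilibrium populations at the
#' effective pre-expansion temperature.
#'
#' @param graph conversion graph from [build_conversion_graph()].
#' @param pops named numeric vector of equilibrium populations (percent) at
#'   the effective temperature, covering every vertex.
#' @param g_ref optional named numeric vector of relative free energies at
#'   the reference temperature; the sink is its argmin within each basin
#'   (ties: lower `e_rel`, then lexicographic id).
#' @param sinks optional character vector of known sink conformers (e.g. the
#'   local minima read off published free-energy profiles); overrides
#'   `g_ref` for the basins that contain them. Multi-member basins need a
#'   sink from one of the two sources; singletons are their own sink.
#' @param e_rel optional named numeric vector of relative electronic
#'   energies, used only to break `g_ref` ties.
#' @param threshold observability threshold in percent (default 8,
#'   exclusive: a basin is observable when pooled population > threshold).
#' @return A data.frame of class `"basin_table"` with one row per basin:
#'   `sink`, `n_members`, `pooled`, `observable` and a `members`
#'   list-column. Rows are sorted by decreasing pooled population.
#' @export
pool_populations <- function(graph, pops, g_ref = NULL, sinks = NULL,
                             e_rel = NULL, threshold = 8) {
  ids <- igraph::V(graph)$name
  miss <- ids[!ids %in% names(pops)]
  if (length(miss))
    stop("missing population for conformer(s): ",
         paste(miss, collapse = ", "))
  comp <- igraph::components(graph)$membership
  if (!length(ids)) {
    out <- data.frame(sink = character(), n_members = integer(),
                      pooled = numeric(), observable = logical())
    out$members <- list()
    class(out) <- c("basin_table", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(max(comp, 0)), function(k) {
    members <- ids[comp == k]
    sink <- .basin_sink(members, g_ref, sinks, e_rel)
    data.frame(sink = sink, n_members = length(members),
               pooled = sum(pops[members]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(seq_len(max(comp, 0)),
                        function(k) ids[comp == k])
  out$observable <- out$pooled > threshold
  out <- out[order(-out$pooled, out$sink),
             c("sink", "n_members", "pooled", "observable", "members")]
  rownames(out) <- NULL
  class(out) <- c("basin_table", "data.frame")
  out
}

.basin_sink <- function(members, g_ref, sinks, e_rel) {
  if (!is.null(sinks)) {
    hit <- intersect(sinks, members)
    if (length(hit) > 1L)
      stop("multiple designated sinks in one basin: ",
           paste(hit, collapse = ", "))
    if (length(hit) == 1L) return(hit)
  }
  if (length(members) == 1L) return(members)
  if (is.null(g_ref)) {
    stop("basin {", paste(members, collapse = ", "),
         "} has no designated sink and no reference free energies")
  }
  miss <- members[!members %in% names(g_ref)]
  if (length(miss))
    stop("missing reference free energy for: ", paste(miss, collapse = ", "))
  g <- g_ref[members]
  cand <- members[g <= min(g) + 1e-12]
  if (length(cand) > 1L && !is.null(e_rel)) {
    e <- e_rel[cand]
    cand <- cand[e <= min(e) + 1e-12]
  }
  sort(cand)[1]
}

#' @export
print.basin_table <- function(x, ...) {
  cat(sprintf("<basin_table> %d basin(s), %.2f%% total mass\n",
              nrow(x), sum(x$pooled)))
  df <- as.data.frame(x)
  df$members <- vapply(df$members, paste, "", collapse = ",")
  print(df, ...)
  invisible(x)
}

#' Observable conformers after jet cooling
#'
#' @param basins a `basin_table` from [pool_populations()].
#' @param threshold observability threshold in percent (exclusive).
#' @return data.frame with columns `sink` and `pooled`, the basins whose
#'   pooled population exceeds the threshold, sorted descending.
#' @export
observable_conformers <- function(basins, threshold = 8) {
  stopifnot(inherits(basins, "basin_table"))
  keep <- as.data.frame(basins)[basins$pooled > threshold,
                                c("sink", "pooled")]
  keep <- keep[order(-keep$pooled), ]
  rownames(keep) <- NULL
  keep
}
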