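#' Specification for a synthetic conformer ensemble
#'
#' Describes an ensemble with the structure seen in jet-cooled aromatic
#' dipeptides: a few folded low-energy conformers that are mutually isolated,
#' plus families of extended conformers grouped by side-chain type, with
#' low barriers inside a family and medium/high barriers elsewhere.
#'
#' @param n_folded number of folded conformers.
#' @param group_layout named integer vector: extended-family side-chain type
#'   (e.g. `"g+/+"`) to member count.
#' @param energy_scale spread of relative electronic energies, kcal/mol.
#' @param entropy_bias free-energy advantage of extended conformers at the
#'   top of the temperature grid, kcal/mol (grows linearly with T).
#' @param barrier_draws list of numeric ranges the barrier heights are drawn
#'   from, per class; must respect the class boundaries.
#' @param temps temperature grid (K) for the free-energy corrections.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_folded = 1,
                           group_layout = c("g+/+" = 4, "g+/-" = 3,
                                            "g-/+" = 6, "g-/-" = 7),
                           energy_scale = 4, entropy_bias = 1.5,
                           barrier_draws = list(low = c(0.2, 1.8),
                                                medium = c(2.5, 7.5),
                                                high = c(8.5, 14)),
                           temps = c(10, 98, 298, 450), seed = 1) {
  stopifnot(n_folded >= 0, all(group_layout >= 0),
            energy_scale > 0, length(temps) >= 1, all(temps > 0))
  if (is.null(names(group_layout)) && length(group_layout))
    stop("group_layout must be named by side-chain type")
  chk <- function(rng, lo, hi) all(rng >= lo & rng <= hi)
  if (!chk(barrier_draws$low, 0, 2) || !chk(barrier_draws$medium, 2, 8) ||
      !chk(barrier_draws$high, 8, Inf))
    stop("barrier_draws ranges must respect the low/medium/high boundaries")
  structure(list(n_folded = n_folded, group_layout = group_layout,
                 energy_scale = energy_scale, entropy_bias = entropy_bias,
                 barrier_draws = barrier_draws, temps = temps, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic conformer ensemble with known basin structure
#'
#' Draws energies, free-energy corrections, structural types and pairwise
#' barriers according to a [synthetic_spec()], and returns the ground-truth
#' kinetic basins computed by construction (each extended family is one
#' basin, each folded conformer its own). Extended conformers receive an
#' entropic free-energy advantage growing linearly with temperature, which
#' reproduces the inversion from a folded-dominated ensemble at low
#' temperature to an extended-dominated one at high temperature.
#'
#' @param spec a [synthetic_spec()].
#' @param t_eff effective pre-expansion temperature (K) for the ground-truth
#'   pooled populations.
#' @param t_ref relaxation reference temperature (K) for the ground-truth
#'   sinks.
#' @return A list with `energies` (an `energy_table` with `gcorr_*` columns),
#'   `types` (named character vector of type labels), `barriers` (a
#'   `barrier_table` over all pairs) and `truth` (data.frame: `sink`,
#'   `pooled`, `n_members`, plus a `members` list-column).
#' @export
generate_ensemble <- function(spec, t_eff = 450, t_ref = 10) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_ext <- sum(spec$group_layout)
  n <- spec$n_folded + n_ext
  if (n == 0L) {
    et <- data.frame(id = character(), e_rel = numeric())
    class(et) <- c("energy_table", "data.frame")
    bt <- data.frame(from = character(), to = character(),
                     dg_barrier = numeric())
    class(bt) <- c("barrier_table", "data.frame")
    truth <- data.frame(sink = character(), pooled = numeric(),
                        n_members = integer())
    truth$members <- list()
    return(list(energies = et, types = character(), barriers = bt,
                truth = truth))
  }
  ids <- sprintf("syn%02d", seq_len(n))
  folded <- seq_len(spec$n_folded)
  group_of <- c(rep(NA_integer_, spec$n_folded),
                rep(seq_along(spec$group_layout), spec$group_layout))

  # types: folded conformers get distinct gamma combinations; each extended
  # family shares its side-chain type but varies the extended backbone
  folded_pool <- expand.grid(bb = c("gamma_D", "gamma_L"),
                             sw = c("g+", "g-", "a"), o = c("+", "-"),
                             term = c("A1", "A2"),
                             stringsAsFactors = FALSE)
  if (spec$n_folded > nrow(folded_pool))
    stop("at most ", nrow(folded_pool), " distinct folded conformers")
  types <- character(n)
  for (i in folded)
    types[i] <- format_type_label(structural_type(
      folded_pool$term[i], folded_pool$bb[i], folded_pool$sw[i],
      folded_pool$o[i]))
  for (i in setdiff(seq_len(n), folded)) {
    side <- strsplit(names(spec$group_layout)[group_of[i]], "/",
                     fixed = TRUE)[[1]]
    types[i] <- format_type_label(structural_type(
      sample(c("A1", "A2"), 1), sample(c("beta", "eps_L", "eps_D"), 1),
      side[1], side[2]))
  }
  names(types) <- ids

  # energies: folded low-lying, extended higher; referenced to zero
  e_rel <- numeric(n)
  e_rel[folded] <- sort(stats::runif(spec$n_folded, 0,
                                     spec$energy_scale / 2))
  e_rel[-folded] <- stats::runif(n_ext, spec$energy_scale / 4,
                                 spec$energy_scale)
  e_rel <- e_rel - min(e_rel)
  bias <- ifelse(is.na(group_of), 0,
                 spec$entropy_bias * stats::runif(n, 0.8, 1.2))
  et <- data.frame(id = ids, e_rel = e_rel, stringsAsFactors = FALSE)
  tmax <- max(spec$temps)
  for (tt in spec$temps)
    et[[sprintf("gcorr_%g", tt)]] <- -bias * tt / tmax
  class(et) <- c("energy_table", "data.frame")

  # barriers: low inside a family, medium between extended families,
  # high whenever a folded conformer is involved
  pair <- utils::combn(ids, 2)
  cls <- apply(pair, 2, function(p) {
    i <- match(p[1], ids); j <- match(p[2], ids)
    if (!is.na(group_of[i]) && !is.na(group_of[j])) {
      if (group_of[i] == group_of[j]) "low" else "medium"
    } else "high"
  })
  draw <- function(cl) stats::runif(1, spec$barrier_draws[[cl]][1],
                                    spec$barrier_draws[[cl]][2])
  bt <- data.frame(from = pair[1, ], to = pair[2, ],
                   dg_barrier = vapply(cls, draw, 0),
                   stringsAsFactors = FALSE)
  class(bt) <- c("barrier_table", "data.frame")

  # ground truth by construction
  pops <- boltzmann_populations(free_energies(et, t_eff), t_eff)
  g_ref <- free_energies(et, t_ref)
  basin_id <- ifelse(is.na(group_of), paste0("f", seq_len(n)),
                     paste0("g", group_of))
  truth <- do.call(rbind, lapply(unique(basin_id), function(b) {
    members <- ids[basin_id == b]
    data.frame(sink = members[which.min(g_ref[members])],
               pooled = sum(pops[members]), n_members = length(members),
               stringsAsFactors = FALSE)
  }))
  truth$members <- lapply(unique(basin_id),
                          function(b) ids[basin_id == b])
  truth <- truth[order(-truth$pooled, truth$sink), ]
  rownames(truth) <- NULL
  list(energies = et, types = types, barriers = bt, truth = truth)
}

#' Enumerate trial dihedral combinations
#'
#' Full Cartesian product of per-bond angle grids, in lexicographic order
#' (the first bond varies slowest).
#'
#' @param bond_grid named list: rotatable bond name to numeric vector of
#'   angles (degrees).
#' @return data.frame with one column per bond and `prod(lengths(bond_grid))`
#'   rows.
#' @export
enumerate_trial_dihedrals <- function(bond_grid) {
  stopifnot(is.list(bond_grid), length(bond_grid) >= 1)
  if (any(lengths(bond_grid) == 0L))
    stop("every bond needs at least one grid angle: ",
         paste(names(bond_grid)[lengths(bond_grid) == 0L], collapse = ", "))
  out <- expand.grid(rev(bond_grid), KEEP.OUT.ATTRS = FALSE)
  out <- out[, rev(seq_along(bond_grid)), drop = FALSE]
  rownames(out) <- NULL
  out
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "jetcool")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  if (!file.exists(path)) stop("packaged fixture not found: ", file)
  path
}

#' Packaged YG reference table
#'
#' The 37 tyrosyl-glycine conformers of interest with their relative
#' electronic energies (kcal/mol), hydrogen-bond networks, structural types
#' and equilibrium distributions (%) at 98, 298 and 450 K. Distribution
#' entries below 1% are not printed in the source table and are stored as
#' `NA`.
#'
#' @return A list with `energies` (an `energy_table`), `types` (named
#'   character), `hbonds` (named character, `;`-separated labels) and
#'   `distributions` (37 x 3 matrix, columns `T98`, `T298`, `T450`).
#' @export
table1_fixture <- function() {
  df <- utils::read.csv(.extdata("yg_table1.csv"), stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  et <- data.frame(id = df$id, e_rel = df$e_rel, stringsAsFactors = FALSE)
  class(et) <- c("energy_table", "data.frame")
  dist <- as.matrix(df[, c("d98", "d298", "d450")])
  dimnames(dist) <- list(df$id, c("T98", "T298", "T450"))
  list(energies = et,
       types = stats::setNames(df$type, df$id),
       hbonds = stats::setNames(df$hbonds, df$id),
       distributions = dist)
}

#' Cooling groups of the YG ensemble
#'
#' The four families of extended conformers that interconvert over low
#' barriers during jet cooling, keyed by side-chain type, together with each
#' family's relaxation sink (the local free-energy minimum of the published
#' low-temperature free-energy profiles).
#'
#' @return A list with `groups` (named list of conformer-id vectors) and
#'   `sinks` (named character vector, one sink per group).
#' @export
yg_cooling_groups <- function() {
  list(groups = list(
    "g+/+" = c("yg12", "yg14", "yg19", "yg58"),
    "g+/-" = c("yg17", "yg18", "yg25"),
    "g-/+" = c("yg6", "yg31", "yg35", "yg52", "yg57", "yg67"),
    "g-/-" = c("yg27", "yg32", "yg33", "yg51", "yg56", "yg63", "yg71")),
    sinks = c("g+/+" = "yg14", "g+/-" = "yg17",
              "g-/+" = "yg31", "g-/-" = "yg32"))
}

#' Packaged glycine-tryptophan high-frequency band list
#'
#' Scaled M062X theoretical N-H/O-H stretch frequencies of the two
#' observable GW conformers and the experimental band positions they are
#' assigned to (cm-1).
#'
#' @return data.frame with columns `conformer`, `mode_label`, `theory`,
#'   `experiment`.
#' @export
gw_band_fixture <- function() {
  utils::read.csv(.extdata("gw_highfreq_bands.csv"), stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}
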