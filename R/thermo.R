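#' Boltzmann constant in kcal mol-1 K-1
#'
#' CODATA-derived value used throughout the package.
#' @export
kB_KCAL <- 1.98720425864083e-3

#' Relative free energies at a temperature
#'
#' Adds the per-conformer free-energy correction at temperature `temp` to the
#' relative electronic energy and re-references the result so the ensemble
#' minimum is zero. Corrections are linearly interpolated between the
#' tabulated temperatures and held constant outside their range; a table
#' without corrections falls back to the electronic energies with a warning.
#'
#' @param records an `energy_table` (see [read_energy_table()]).
#' @param temp temperature in Kelvin.
#' @return Named numeric vector of relative free energies (kcal/mol),
#'   minimum exactly 0.
#' @export
free_energies <- function(records, temp) {
  stopifnot(inherits(records, "data.frame"), temp > 0)
  gc <- .gcorr_at(records, temp)
  g <- records$e_rel + gc
  g <- g - min(g)
  stats::setNames(g, records$id)
}

# interpolate the gcorr_<T> columns at temperature `temp`
.gcorr_at <- function(records, temp) {
  gcols <- grep("^gcorr_", names(records), value = TRUE)
  if (!length(gcols)) {
    warning("no free-energy corrections in table; using g_corr = 0",
            call. = FALSE)
    return(rep(0, nrow(records)))
  }
  temps <- as.numeric(sub("^gcorr_", "", gcols))
  ord <- order(temps)
  temps <- temps[ord]
  gcols <- gcols[ord]
  if (length(temps) == 1L)
    return(records[[gcols]])
  mat <- as.matrix(records[gcols])
  tt <- min(max(temp, temps[1]), temps[length(temps)])  # constant outside
  apply(mat, 1L, function(y) stats::approx(temps, y, xout = tt)$y)
}

#' Equilibrium Boltzmann populations
#'
#' Converts relative free energies to equilibrium fractions in percent,
#' \eqn{p_i = 100 \exp(-G_i/k_B T) / \sum_j \exp(-G_j/k_B T)}. The minimum is
#' subtracted before exponentiation for numerical stability.
#'
#' @param g_rel numeric vector of relative free energies, kcal/mol (names are
#'   carried through).
#' @param temp temperature in Kelvin (> 0).
#' @return Numeric vector of percentages summing to 100.
#' @examples
#' boltzmann_populations(c(0, 1), 450)  # ~ c(75.37, 24.63)
#' @export
boltzmann_populations <- function(g_rel, temp) {
  if (!length(g_rel)) stop("empty free-energy vector")
  if (!is.finite(temp) || temp <= 0) stop("temperature must be positive")
  w <- exp(-(g_rel - min(g_rel)) / (kB_KCAL * temp))
  100 * w / sum(w)
}

#' Populations across a temperature grid
#'
#' @param records an `energy_table`.
#' @param temps numeric vector of temperatures in Kelvin.
#' @return An object of class `"population_table"`: a list with `temperatures`
#'   and `populations`, a conformer-by-temperature matrix of percentages
#'   (rows named by conformer id, columns `T<K>`). Columns each sum to 100.
#' @export
populations_vs_T <- function(records, temps) {
  stopifnot(length(temps) >= 1L, all(temps > 0))
  pops <- vapply(temps, function(tt)
    boltzmann_populations(free_energies(records, tt), tt),
    numeric(nrow(records)))
  pops <- matrix(pops, nrow = nrow(records),
                 dimnames = list(records$id, sprintf("T%g", temps)))
  structure(list(temperatures = temps, populations = pops),
            class = "population_table")
}

#' @export
print.population_table <- function(x, digits = 2, hide_below = 1, ...) {
  m <- x$populations
  disp <- matrix(formatC(round(m, digits), format = "f", digits = digits),
                 nrow(m), ncol(m), dimnames = dimnames(m))
  disp[m < hide_below] <- "\u2014"   # sub-1% entries rendered as an em dash
  print(as.data.frame(disp), ...)
  invisible(x)
}

#' Select the conformers of interest
#'
#' A conformer is of interest when it is among the `n_lowest` lowest relative
#' electronic energies, or when its equilibrium population exceeds
#' `pop_threshold` percent at any grid temperature up to `t_max`.
#'
#' @param records an `energy_table`.
#' @param t_grid temperature grid in Kelvin (default 10 to 450 step 10).
#' @param n_lowest rank cutoff (default 10).
#' @param pop_threshold percent threshold (default 1).
#' @return Character vector of selected conformer ids (input order).
#' @export
select_conformers_of_interest <- function(records,
                                          t_grid = seq(10, 450, by = 10),
                                          n_lowest = 10, pop_threshold = 1) {
  stopifnot(inherits(records, "data.frame"))
  low <- records$id[order(records$e_rel)][seq_len(min(n_lowest,
                                                      nrow(records)))]
  pt <- populations_vs_T(records, t_grid)
  hot <- rownames(pt$populations)[apply(pt$populations > pop_threshold, 1,
                                        any)]
  records$id[records$id %in% union(low, hot)]
}
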