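#' Scale harmonic frequencies
#'
#' Multiplies every harmonic frequency by a scalar factor to correct for
#' anharmonicity; intensities are unchanged. Commonly used factors are
#' shipped as [scale_factors].
#'
#' @param lines data.frame with columns `mode_label`, `frequency`,
#'   `intensity` (see [read_frequency_table()]).
#' @param factor positive scaling factor in (0, 1.2].
#' @return The same data.frame with scaled `frequency`.
#' @examples
#' scale_frequencies(data.frame(mode_label = "OH", frequency = 3600,
#'                              intensity = 1), 0.9602)
#' @export
scale_frequencies <- function(lines, factor) {
  stopifnot(is.data.frame(lines), "frequency" %in% names(lines))
  if (!is.finite(factor) || factor <= 0 || factor > 1.2)
    stop("scaling factor must be in (0, 1.2]")
  lines$frequency <- lines$frequency * factor
  lines
}

#' Default harmonic scaling factors
#'
#' Literature factor for B3LYP/6-31G** harmonic frequencies and the
#' mid-frequency-calibrated factor for M062X/6-31G**.
#' @export
scale_factors <- c(b3lyp_631gss = 0.9602, m062x_631gss = 0.943)

#' Calibrate a scaling factor against experimental bands
#'
#' The factor is the ratio of the mean experimental frequency to the mean
#' raw harmonic frequency, so that scaling reproduces the experimental mean
#' exactly.
#'
#' @param raw_freqs numeric vector of unscaled harmonic frequencies, cm-1.
#' @param exp_freqs numeric vector of matched experimental band positions,
#'   cm-1 (same length and order).
#' @return The scaling factor (scalar).
#' @examples
#' calibrate_scale_factor(c(1000, 1100), c(943.0, 1037.3))  # 0.943
#' @export
calibrate_scale_factor <- function(raw_freqs, exp_freqs) {
  if (length(raw_freqs) != length(exp_freqs))
    stop("raw and experimental frequency lists differ in length")
  if (!length(raw_freqs)) stop("need at least one frequency pair")
  mean(exp_freqs) / mean(raw_freqs)
}

#' Lorentzian broadening of a stick spectrum
#'
#' Sums one Lorentzian per line over a frequency grid:
#' \deqn{L(\nu) = I \, (\Gamma/2)^2 / ((\nu - \nu_0)^2 + (\Gamma/2)^2)}
#' with \eqn{\Gamma} the full width at half maximum, so the curve reaches the
#' stick intensity at the line centre and half of it at
#' \eqn{\nu_0 \pm \Gamma/2}.
#'
#' @param lines data.frame with `frequency` and `intensity` columns.
#' @param grid strictly increasing numeric vector of frequencies, cm-1.
#' @param fwhm full width at half maximum, cm-1 (default 20).
#' @return data.frame with columns `frequency` (the grid) and `intensity`.
#' @export
broaden <- function(lines, grid, fwhm = 20) {
  stopifnot(is.data.frame(lines), fwhm > 0)
  if (!length(grid)) stop("empty frequency grid")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  hw2 <- (fwhm / 2)^2
  y <- rep(0, length(grid))
  for (k in seq_len(nrow(lines)))
    y <- y + lines$intensity[k] * hw2 /
      ((grid - lines$frequency[k])^2 + hw2)
  data.frame(frequency = grid, intensity = y)
}

# round half away from zero to match printed integer wavenumbers
.round_half_up <- function(x) floor(x + 0.5)

#' Score a theory-to-experiment band assignment
#'
#' Pairs theoretical lines with experimental bands and reports per-pair
#' absolute deviations plus their mean and maximum. When both sides carry
#' mode labels, pairing is by label (an error lists any label without a
#' partner); otherwise both lists are taken in frequency order and paired
#' positionally (requiring equal lengths).
#'
#' @param theory data.frame with `mode_label`, `frequency` (scaled theory).
#' @param experiment data.frame with `mode_label`, `frequency` (observed).
#' @return An object of class `"assignment_score"`: list with `pairs` (a
#'   data.frame: `mode_label`, `theory`, `experiment`, `abs_dev`),
#'   `mean_dev`/`max_dev` (raw floats, cm-1) and `mean_dev_report` /
#'   `max_dev_report` (integers, rounded half-up as printed in band tables).
#' @export
score_assignment <- function(theory, experiment) {
  stopifnot(is.data.frame(theory), is.data.frame(experiment))
  has_labels <- all(nzchar(theory$mode_label)) &&
    all(nzchar(experiment$mode_label)) &&
    !anyDuplicated(theory$mode_label) && !anyDuplicated(experiment$mode_label)
  if (has_labels && setequal(theory$mode_label, experiment$mode_label)) {
    m <- match(theory$mode_label, experiment$mode_label)
    pairs <- data.frame(mode_label = theory$mode_label,
                        theory = theory$frequency,
                        experiment = experiment$frequency[m],
                        stringsAsFactors = FALSE)
  } else if (has_labels) {
    miss <- c(setdiff(theory$mode_label, experiment$mode_label),
              setdiff(experiment$mode_label, theory$mode_label))
    stop("unmatched mode label(s): ", paste(miss, collapse = ", "))
  } else {
    if (nrow(theory) != nrow(experiment))
      stop("unlabelled lists must have equal length for positional matching")
    ot <- order(theory$frequency)
    oe <- order(experiment$frequency)
    pairs <- data.frame(mode_label = sprintf("pair_%d", seq_len(nrow(theory))),
                        theory = theory$frequency[ot],
                        experiment = experiment$frequency[oe],
                        stringsAsFactors = FALSE)
  }
  if (!nrow(pairs)) stop("no pairs to score")
  pairs$abs_dev <- abs(pairs$theory - pairs$experiment)
  structure(list(pairs = pairs,
                 mean_dev = mean(pairs$abs_dev),
                 max_dev = max(pairs$abs_dev),
                 mean_dev_report = .round_half_up(mean(pairs$abs_dev)),
                 max_dev_report = .round_half_up(max(pairs$abs_dev))),
            class = "assignment_score")
}

#' @export
print.assignment_score <- function(x, ...) {
  cat(sprintf("<assignment_score> %d pairs: mean |dv| = %d cm-1, max = %d cm-1\n",
              nrow(x$pairs), x$mean_dev_report, x$max_dev_report))
  print(x$pairs, ...)
  invisible(x)
}
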