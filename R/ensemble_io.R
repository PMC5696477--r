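#' Read a multi-structure XYZ file
#'
#' Parses a concatenated-frames XYZ file (atom-count line, comment line,
#' atom lines). The comment line is used as the conformer id; blank comment
#' lines get auto-assigned ids `conf_<k>` (1-based frame index).
#'
#' @param path path to an XYZ file.
#' @return A list of [geometry()] objects, in file order. An empty file gives
#'   an empty list.
#' @export
read_xyz_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only; blanks inside frames are errors
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  geoms <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    k <- k + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("frame %d: malformed atom-count line: '%s'", k, lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf("frame %d: count line says %d atoms but file ends early",
                   k, nat))
    id <- trimws(lines[i + 1L])
    # take the first whitespace token as id when the comment carries more
    if (nzchar(id)) id <- strsplit(id, "\\s+")[[1]][1] else
      id <- sprintf("conf_%d", k)
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad))
      stop(sprintf("frame %d (%s): atom line %d has fewer than 4 fields",
                   k, id, bad[1]))
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      if (anyNA(v)) stop(sprintf("frame %d (%s): non-numeric coordinate", k, id))
      v
    }, numeric(3)))
    geoms[[k]] <- geometry(el, xyz, label = id)
    i <- i + 2L + nat
  }
  ids <- vapply(geoms, `[[`, "", "label")
  if (anyDuplicated(ids))
    stop("duplicate conformer id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  geoms
}

#' @rdname read_xyz_ensemble
#' @param geoms list of [geometry()] objects.
#' @param path output file path.
#' @export
write_xyz_ensemble <- function(geoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geoms) {
    stopifnot(inherits(g, "geometry"))
    writeLines(as.character(n_atoms(g)), con)
    writeLines(g$label, con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", g$element,
                       g$coords[, 1], g$coords[, 2], g$coords[, 3]), con)
  }
  invisible(path)
}

.HARTREE_KCAL <- 627.5094740631

# detect comma vs tab vs whitespace delimiter from the header line
.detect_sep <- function(header) {
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
}

#' Read a conformer energy table
#'
#' Reads a delimited text table (comma or tab, auto-detected) with columns
#' `id`, `e_rel` (relative electronic energy, kcal/mol) and optional
#' free-energy-correction columns named like `g_corr@450` (temperature in
#' Kelvin in the header token). Energies must be referenced to the ensemble
#' minimum: exactly one record with `e_rel == 0` is required unless
#' `reference_check = FALSE`.
#'
#' @param path path to the table.
#' @param reference_check require a unique zero-energy reference record.
#' @param hartree if `TRUE`, input energies are absolute hartree; they are
#'   converted to kcal/mol and re-referenced to the minimum.
#' @return A data.frame of class `"energy_table"` with columns `id`, `e_rel`
#'   and zero or more `gcorr_<T>` columns.
#' @export
read_energy_table <- function(path, reference_check = TRUE, hartree = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- .detect_sep(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          strip.white = TRUE, comment.char = "")
  nms <- tolower(trimws(names(df)))
  idc <- which(nms %in% c("id", "conf", "conformer", "conf."))
  ec <- which(nms %in% c("e_rel", "energy", "e"))
  if (!length(idc) || !length(ec))
    stop("energy table needs 'id' and 'e_rel' columns")
  gcols <- grep("^g_?corr\\s*@", nms)
  temps <- as.numeric(sub("^g_?corr\\s*@\\s*", "", nms[gcols]))
  if (length(gcols) && anyNA(temps))
    stop("could not parse temperature from header token(s): ",
         paste(names(df)[gcols][is.na(temps)], collapse = ", "))
  if (any(temps <= 0)) stop("g_corr temperatures must be positive")
  out <- data.frame(id = as.character(df[[idc[1]]]),
                    e_rel = .num_or_stop(df[[ec[1]]], "e_rel"),
                    stringsAsFactors = FALSE)
  for (j in seq_along(gcols))
    out[[sprintf("gcorr_%g", temps[j])]] <-
      .num_or_stop(df[[gcols[j]]], names(df)[gcols[j]])
  if (anyDuplicated(out$id))
    stop("duplicate conformer id(s) in energy table")
  if (hartree) {
    out$e_rel <- (out$e_rel - min(out$e_rel)) * .HARTREE_KCAL
  }
  if (reference_check) {
    nzero <- sum(abs(out$e_rel) < 1e-12)
    if (nzero != 1L)
      stop("energy table must contain exactly one zero-energy reference ",
           "record (found ", nzero, "); use reference_check = FALSE to skip")
  }
  if (any(out$e_rel < 0))
    stop("negative relative energies: table is not referenced to its minimum")
  class(out) <- c("energy_table", "data.frame")
  out
}

.num_or_stop <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) stop("non-numeric or missing value in column ", what)
  v
}

#' @rdname read_energy_table
#' @param x an `energy_table`.
#' @export
write_energy_table <- function(x, path) {
  stopifnot(inherits(x, "energy_table"))
  out <- as.data.frame(x)
  gn <- grep("^gcorr_", names(out))
  names(out)[gn] <- sub("^gcorr_", "g_corr@", names(out)[gn])
  # full float precision for lossless round trips
  for (j in seq_along(out)[-1]) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a conformer-pair barrier table
#'
#' Columns `from`, `to`, `dg_barrier` (transition free-energy barrier,
#' kcal/mol). Barriers are treated as symmetric between the pair.
#'
#' @param path path to a comma/tab-delimited table.
#' @return data.frame of class `"barrier_table"` with character `from`, `to`
#'   and numeric `dg_barrier`.
#' @export
read_barrier_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(header),
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("from", "to", "dg_barrier")
  if (!all(need %in% names(df)))
    stop("barrier table needs columns: ", paste(need, collapse = ", "))
  df$from <- as.character(df$from)
  df$to <- as.character(df$to)
  df$dg_barrier <- .num_or_stop(df$dg_barrier, "dg_barrier")
  if (any(df$dg_barrier < 0)) stop("barriers must be non-negative")
  if (any(df$from == df$to)) stop("barrier pair ids must be distinct")
  df <- df[, need]
  class(df) <- c("barrier_table", "data.frame")
  df
}

#' Read a harmonic-frequency line list
#'
#' Columns `mode_label`, `frequency` (cm-1), `intensity` (arbitrary units,
#' optional, defaults to 1).
#'
#' @param path path to a comma/tab-delimited table.
#' @return data.frame with columns `mode_label`, `frequency`, `intensity`.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(header),
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  if (!all(c("mode_label", "frequency") %in% names(df)))
    stop("frequency table needs columns mode_label, frequency")
  if (!"intensity" %in% names(df)) df$intensity <- 1
  df$frequency <- .num_or_stop(df$frequency, "frequency")
  df$intensity <- .num_or_stop(df$intensity, "intensity")
  if (any(df$frequency <= 0)) stop("frequencies must be positive")
  if (any(df$intensity < 0)) stop("intensities must be non-negative")
  df[, c("mode_label", "frequency", "intensity")]
}

#' Write / read a basin report
#'
#' Serialises a basin table (see [pool_populations()]) to a machine-readable
#' key-value text report and reads it back losslessly. Numeric fields are
#' written at full double precision so `read_report(write_report(x))`
#' reproduces `x` exactly.
#'
#' @param basins a `basin_table` as returned by [pool_populations()].
#' @param path output path.
#' @param threshold observability threshold (percent) recorded in the header.
#' @return `write_report` returns `path` invisibly; `read_report` returns the
#'   `basin_table`.
#' @export
write_report <- function(basins, path, threshold = NULL) {
  stopifnot(inherits(basins, "basin_table"))
  if (nrow(basins) == 0L) stop("basin list is empty")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# jetcool basin report", con)
  writeLines(sprintf("n_basins=%d", nrow(basins)), con)
  if (!is.null(threshold))
    writeLines(sprintf("observable_threshold=%.17g", threshold), con)
  for (i in seq_len(nrow(basins))) {
    writeLines(sprintf("basin.%d.sink=%s", i, basins$sink[i]), con)
    writeLines(sprintf("basin.%d.members=%s", i,
                       paste(sort(basins$members[[i]]), collapse = ",")), con)
    writeLines(sprintf("basin.%d.pooled_pct=%.17g", i, basins$pooled[i]), con)
    writeLines(sprintf("basin.%d.observable=%s", i,
                       tolower(as.character(basins$observable[i]))), con)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  n <- as.integer(vals[keys == "n_basins"])
  get <- function(i, field) vals[keys == sprintf("basin.%d.%s", i, field)]
  basins <- data.frame(
    sink = vapply(seq_len(n), function(i) get(i, "sink"), ""),
    pooled = vapply(seq_len(n), function(i)
      as.numeric(get(i, "pooled_pct")), 0),
    observable = vapply(seq_len(n), function(i)
      get(i, "observable") == "true", TRUE),
    stringsAsFactors = FALSE)
  basins$members <- lapply(seq_len(n), function(i)
    strsplit(get(i, "members"), ",", fixed = TRUE)[[1]])
  basins$n_members <- lengths(basins$members)
  basins <- basins[, c("sink", "n_members", "pooled", "observable", "members")]
  class(basins) <- c("basin_table", "data.frame")
  basins
}
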