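# Readers and writers for the plain-text interchange formats used throughout:
# two-column peak lists / ATDs, FASTA sequences, CSV/JSON result tables.
# mzML input is delegated to the mzR package when it is installed.

#' Read a spectrum from disk
#'
#' Text format: whitespace- or comma-delimited `m/z intensity` pairs, with
#' `#` comment lines. Unsorted input is sorted on read with a warning. mzML
#' files are read through the mzR package (one scan at a time).
#'
#' @param path File path.
#' @param kind `"auto"` (by extension), `"text"`, or `"mzml"`.
#' @param scan Scan number for mzML input (default 1).
#' @param label Label attached to the spectrum (default the file name).
#' @return A `mass_spectrum`.
#' @export
read_spectrum <- function(path, kind = c("auto", "text", "mzml"), scan = 1L,
                          label = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (kind == "auto") {
    kind <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "text"
  }
  if (kind == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the mzR package", call. = FALSE)
    }
    handle <- mzR::openMSfile(path)
    on.exit(try(close(handle), silent = TRUE))
    pk <- mzR::peaks(handle, scan)
    return(mass_spectrum(pk[, 1], pk[, 2], label = label))
  }
  df <- .read_two_column(path)
  if (is.unsorted(df[[1]], strictly = TRUE)) {
    warning("m/z axis not sorted in ", basename(path), "; sorting on read")
    df <- df[order(df[[1]]), , drop = FALSE]
  }
  mass_spectrum(df[[1]], df[[2]], label = label)
}

.read_two_column <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no data lines in ", path, call. = FALSE)
  parts <- strsplit(lines, "[,[:space:]]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d in %s: '%s'", bad[1], basename(path),
                 lines[bad[1]]), call. = FALSE)
  }
  x <- as.numeric(vapply(parts, `[[`, character(1), 1))
  y <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (anyNA(x) || anyNA(y)) {
    stop("non-numeric values in ", basename(path), call. = FALSE)
  }
  data.frame(x = x, y = y)
}

#' Read an arrival-time distribution from a two-column text/CSV file
#'
#' @param path File path (time in ms, intensity; `#` comments allowed).
#' @param mass,charge Ion identity required to interpret the ATD.
#' @param label,tw_set Passed to [atd()].
#' @return An `atd`.
#' @export
read_atd <- function(path, mass, charge, label = basename(path),
                     tw_set = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- .read_two_column(path)
  if (is.unsorted(df[[1]], strictly = TRUE)) df <- df[order(df[[1]]), ]
  atd(df[[1]], df[[2]], mass = mass, charge = charge, label = label,
      tw_set = tw_set)
}

#' Read a protein sequence from FASTA
#'
#' Single-record files are read directly; multi-record files require `id`.
#' Sequences are uppercased and validated against the 20 canonical residues.
#'
#' @param path FASTA file path.
#' @param id Record identifier (prefix match against the FASTA headers) when
#'   the file holds more than one record.
#' @return A `protein_sequence` named after the FASTA header word.
#' @export
read_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  if (length(set) > 1) {
    if (is.null(id)) {
      stop("multi-record FASTA: specify `id`", call. = FALSE)
    }
    hit <- grep(id, names(set), fixed = TRUE)
    if (length(hit) == 0) stop("no FASTA record matching id: ", id,
                               call. = FALSE)
    set <- set[hit[1]]
  }
  name <- strsplit(names(set)[1], "[[:space:]]")[[1]][1]
  protein_sequence(as.character(set[[1]]), name = name)
}

#' Write a results table to CSV or JSON
#'
#' Deterministic column order (as supplied); floats written at fixed
#' precision — 6 decimal places for m/z-like columns, 1 for CCS columns, 4
#' otherwise — so outputs are byte-stable across runs.
#'
#' @param results A data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default by extension).
#' @return Invisibly, the formatted data.frame that was written.
#' @export
write_results <- function(results, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- as.data.frame(results)
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    digits <- if (grepl("mz|mass|ppm", nm, ignore.case = TRUE)) 6
      else if (grepl("ccs|apex|fwhm", nm, ignore.case = TRUE)) 1
      else 4
    out[[nm]] <- round(out[[nm]], digits)
  }
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(out, path, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
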