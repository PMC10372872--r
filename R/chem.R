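# Elemental-composition arithmetic for proteins and metal-loaded, partially
# oxidized complexes. Compositions are named non-negative integer vectors
# (element symbol -> atom count) with class "elemental_composition".

# proton mass used for all m/z conversions (proton, not hydrogen atom)
PROTON_MASS <- 1.007276

.metims <- new.env(parent = emptyenv())

# Monoisotopic residue compositions of the 20 canonical amino acids
# (residue = amino acid minus H2O).
.RESIDUES <- list(
  A = c(C = 3, H = 5,  N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6,  N = 2, O = 2),
  D = c(C = 4, H = 5,  N = 1, O = 3),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7,  N = 1, O = 3),
  Q = c(C = 5, H = 8,  N = 2, O = 2),
  G = c(C = 2, H = 3,  N = 1, O = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9,  N = 1, O = 1),
  P = c(C = 5, H = 7,  N = 1, O = 1),
  S = c(C = 3, H = 5,  N = 1, O = 2),
  T = c(C = 4, H = 7,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9,  N = 1, O = 2),
  V = c(C = 5, H = 9,  N = 1, O = 1)
)

#' Bundled isotope table
#'
#' Returns the packaged table of isotopic masses and abundances (H, C, N, O,
#' S, Cu, Zn; IUPAC/CIAAW values, pinned in `inst/extdata/isotope_table.csv`
#' so that simulated patterns are reproducible across installations).
#'
#' @return A data.frame with columns `element`, `isotope`, `mass` (Da) and
#'   `abundance` (fraction; abundances sum to 1 within each element).
#' @export
isotope_table <- function() {
  if (is.null(.metims$isotope_table)) {
    path <- system.file("extdata", "isotope_table.csv", package = "metims")
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .metims$isotope_table <- tab
  }
  .metims$isotope_table
}

.element_isotopes <- function(element) {
  tab <- isotope_table()
  rows <- tab[tab$element == element, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown element: ", element, call. = FALSE)
  }
  list(mass = rows$mass, abundance = rows$abundance / sum(rows$abundance))
}

#' Construct an elemental composition
#'
#' @param ... Named integer atom counts, e.g. `ec(C = 2, H = 5, N = 1, O = 2)`.
#'   All counts must be non-negative integers; element symbols must be present
#'   in the bundled isotope table.
#' @return An `elemental_composition` object.
#' @examples
#' ec(H = 2, O = 1)            # water
#' ec(C = 2, H = 5, N = 1, O = 2)  # glycine
#' @export
ec <- function(...) {
  counts <- c(...)
  if (is.null(counts)) counts <- integer(0)
  as_elemental_composition(counts)
}

#' @rdname ec
#' @param x A named numeric vector of atom counts.
#' @export
as_elemental_composition <- function(x) {
  if (inherits(x, "elemental_composition")) return(x)
  if (length(x) > 0 && (is.null(names(x)) || any(names(x) == ""))) {
    stop("composition counts must be named by element symbol", call. = FALSE)
  }
  if (any(x < 0)) stop("atom counts must be non-negative", call. = FALSE)
  if (any(x != round(x))) stop("atom counts must be integers", call. = FALSE)
  known <- unique(isotope_table()$element)
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  # collapse duplicates, drop zeros, fix a deterministic element order
  counts <- tapply(as.numeric(x), names(x), sum)
  counts <- counts[counts > 0]
  ord <- match(names(counts), known)
  counts <- counts[order(ord)]
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Format a composition as a molecular formula string
#' @param x An `elemental_composition`.
#' @return A string such as `"C2H5NO2"`.
#' @export
format_formula <- function(x) {
  x <- as_elemental_composition(x)
  if (length(x) == 0) return("(empty)")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  a <- as_elemental_composition(e1); b <- as_elemental_composition(e2)
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] + unclass(b)
  as_elemental_composition(out)
}

#' @export
`-.elemental_composition` <- function(e1, e2) {
  a <- as_elemental_composition(e1); b <- as_elemental_composition(e2)
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + unclass(a)
  out[names(b)] <- out[names(b)] - unclass(b)
  if (any(out < 0)) {
    neg <- names(out)[out < 0]
    stop("subtraction yields negative count for: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  as_elemental_composition(out)
}

#' @export
`*.elemental_composition` <- function(e1, e2) {
  if (is.numeric(e1)) { n <- e1; x <- e2 } else { n <- e2; x <- e1 }
  if (length(n) != 1 || n < 0 || n != round(n)) {
    stop("composition multiplier must be a single non-negative integer",
         call. = FALSE)
  }
  x <- as_elemental_composition(x)
  as_elemental_composition(stats::setNames(unclass(x) * n, names(x)))
}

#' Protein sequence
#'
#' Validates a one-letter amino-acid sequence (20 canonical residues only)
#' and wraps it with a name.
#'
#' @param residues A single string of one-letter codes (case-insensitive).
#' @param name Label for the protein.
#' @return A `protein_sequence` object.
#' @examples
#' protein_sequence("GG", "diglycine")
#' @export
protein_sequence <- function(residues, name = "protein") {
  if (!is.character(residues) || length(residues) != 1) {
    stop("residues must be a single string", call. = FALSE)
  }
  residues <- toupper(residues)
  if (nchar(residues) < 1) stop("sequence must have length >= 1", call. = FALSE)
  aa <- strsplit(residues, "")[[1]]
  bad <- which(!aa %in% names(.RESIDUES))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue code '%s' at position %d", aa[bad[1]], bad[1]),
         call. = FALSE)
  }
  structure(list(residues = aa, name = name), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein> %s (%d residues, %d Cys)\n", x$name,
              length(x$residues), sum(x$residues == "C")))
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' Number of cysteines in a protein sequence
#' @param seq A `protein_sequence`.
#' @return Integer count of Cys residues.
#' @export
n_cys <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  sum(seq$residues == "C")
}

#' Bundled human MT3 sequence
#'
#' The 68-residue, 20-cysteine human metallothionein-3 polypeptide
#' (UniProt P25713), shipped as a FASTA fixture and used as the default base
#' protein throughout the package.
#'
#' @return A `protein_sequence`.
#' @export
mt3_sequence <- function() {
  if (is.null(.metims$mt3)) {
    path <- system.file("extdata", "mt3_human_P25713.fasta", package = "metims")
    .metims$mt3 <- read_fasta(path)
  }
  .metims$mt3
}

#' Neutral elemental composition of a protein
#'
#' Sums residue compositions and adds one water for the free amine / free acid
#' termini. The result is the neutral, fully reduced form (all cysteine thiols
#' protonated).
#'
#' @param seq A `protein_sequence` (or a plain string, which is validated).
#' @return An `elemental_composition`.
#' @examples
#' composition_from_sequence(protein_sequence("G"))  # C2H5NO2
#' @export
composition_from_sequence <- function(seq) {
  if (is.character(seq)) seq <- protein_sequence(seq)
  stopifnot(inherits(seq, "protein_sequence"))
  counts <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # start from H2O
  tab <- table(factor(seq$residues, levels = names(.RESIDUES)))
  for (aa in names(tab)) {
    n <- tab[[aa]]
    if (n > 0) {
      r <- .RESIDUES[[aa]]
      counts[names(r)] <- counts[names(r)] + n * r
    }
  }
  as_elemental_composition(counts)
}

#' Metal/disulfide complex species
#'
#' Describes a protein carrying `n_cu` Cu(I), `n_zn` Zn(II) and `n_ss`
#' intramolecular disulfides under the charge-neutral hydrogen-displacement
#' model: each Cu(I) displaces one thiol proton, each Zn(II) two, and each
#' disulfide removes two hydrogens, so `n_H = n_cu + 2*n_zn + 2*n_ss`.
#'
#' Two budgets are enforced by default (both derived from the cysteine count
#' of the base protein): the displaced hydrogens must all be available as
#' thiol protons (`n_H <= n_Cys`), and the thiolate/disulfide ligand budget
#' `n_cu + n_zn + 2*n_ss <= n_Cys` must hold (each metal requires at least one
#' dedicated thiolate; each disulfide consumes two cysteines). True bridging
#' coordination is richer, so both budgets can be relaxed via `check_budget`.
#'
#' @param base A `protein_sequence`.
#' @param n_cu,n_zn,n_ss Non-negative integer counts of Cu(I), Zn(II) and
#'   disulfides.
#' @param label Optional species label; a default such as `"Cu4Zn4SS2"` is
#'   constructed.
#' @param check_budget Enforce the thiol-derived budgets (default TRUE).
#' @return A `metal_complex` object.
#' @examples
#' mt3 <- mt3_sequence()
#' metal_complex(mt3, n_zn = 7)                 # Zn7, reduced
#' metal_complex(mt3, n_cu = 4, n_zn = 4, n_ss = 2)  # Cu4Zn4, two disulfides
#' @export
metal_complex <- function(base, n_cu = 0, n_zn = 0, n_ss = 0, label = NULL,
                          check_budget = TRUE) {
  stopifnot(inherits(base, "protein_sequence"))
  for (v in c(n_cu, n_zn, n_ss)) {
    if (length(v) != 1 || v < 0 || v != round(v)) {
      stop("metal and disulfide counts must be single non-negative integers",
           call. = FALSE)
    }
  }
  n_h <- n_cu + 2 * n_zn + 2 * n_ss
  if (check_budget) {
    ncys <- n_cys(base)
    if (n_cu + n_zn + 2 * n_ss > ncys) {
      stop(sprintf(
        "thiol budget violated: n_cu + n_zn + 2*n_ss = %d > %d cysteines",
        n_cu + n_zn + 2 * n_ss, ncys), call. = FALSE)
    }
    if (n_h > ncys) {
      stop(sprintf(
        "hydrogen displacement n_H = %d exceeds the %d available thiol protons",
        n_h, ncys), call. = FALSE)
    }
  }
  if (is.null(label)) {
    parts <- c(if (n_cu > 0) paste0("Cu", n_cu),
               if (n_zn > 0) paste0("Zn", n_zn),
               if (n_ss > 0) paste0("SS", n_ss))
    label <- if (length(parts)) paste(parts, collapse = "") else "apo"
    label <- paste0(label, "-", base$name)
  }
  structure(list(base = base, n_cu = as.integer(n_cu), n_zn = as.integer(n_zn),
                 n_ss = as.integer(n_ss), n_h = as.integer(n_h), label = label),
            class = "metal_complex")
}

#' @export
print.metal_complex <- function(x, ...) {
  cat(sprintf("<metal complex> %s: %d Cu(I), %d Zn(II), %d S-S (n_H = %d)\n",
              x$label, x$n_cu, x$n_zn, x$n_ss, x$n_h))
  invisible(x)
}

#' Neutral composition of a metal complex
#'
#' Applies the hydrogen-displacement model: apo reduced composition
#' plus `n_cu` Cu and `n_zn` Zn minus `n_cu + 2*n_zn + 2*n_ss` hydrogens.
#' With all counts zero this is exactly the apo composition.
#'
#' @param sp A `metal_complex`.
#' @return An `elemental_composition`.
#' @export
species_composition <- function(sp) {
  stopifnot(inherits(sp, "metal_complex"))
  comp <- composition_from_sequence(sp$base)
  if (sp$n_cu > 0) comp <- comp + ec(Cu = sp$n_cu)
  if (sp$n_zn > 0) comp <- comp + ec(Zn = sp$n_zn)
  if (sp$n_h > 0) comp <- comp - ec(H = sp$n_h)
  comp
}

#' Average (abundance-weighted) mass of a composition
#' @param c An `elemental_composition`.
#' @return Mass in Da.
#' @examples
#' average_mass(ec(Zn = 1)) - average_mass(ec(Cu = 1))  # ~1.8 Da
#' @export
average_mass <- function(c) {
  c <- as_elemental_composition(c)
  if (length(c) == 0) return(0)
  m <- vapply(names(c), function(el) {
    iso <- .element_isotopes(el)
    sum(iso$mass * iso$abundance)
  }, numeric(1))
  sum(m * unclass(c))
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of the most-abundant-isotope mass times the atom count.
#'
#' @param c An `elemental_composition`.
#' @return Mass in Da (0 for the empty composition).
#' @export
monoisotopic_mass <- function(c) {
  c <- as_elemental_composition(c)
  if (length(c) == 0) return(0)
  m <- vapply(names(c), function(el) {
    iso <- .element_isotopes(el)
    iso$mass[which.max(iso$abundance)]
  }, numeric(1))
  sum(m * unclass(c))
}

# monoisotopic mass of a single element's most abundant isotope (cached use)
.mono_element <- function(el) {
  iso <- .element_isotopes(el)
  iso$mass[which.max(iso$abundance)]
}
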