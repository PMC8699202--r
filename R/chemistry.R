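#' pepccs: peptide collision cross section prediction
#'
#' Predicts peptide collision cross sections (CCS, in squared angstroms) from
#' the amino-acid sequence and charge state with a two-branch convolutional +
#' dense neural network, and converts predicted CCS to ion-mobility drift
#' times. See `vignette("pepccs-methods")` for the model and its assumptions.
#'
#' @keywords internal
"_PACKAGE"

# Monoisotopic element masses (Da). Single source of truth for all masses.
.ELEMENT_MASS <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)
.PROTON_MASS <- 1.00727646688
.WATER <- c(H = 2, C = 0, N = 0, O = 1, S = 0)
.ACETYL <- c(H = 2, C = 2, N = 0, O = 1, S = 0)  # net addition of CH3CO minus H

.OXMET <- "m"   # internal symbol for methionine sulfoxide
.STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.chem_cache <- new.env(parent = emptyenv())

#' Residue chemistry table
#'
#' Loads the 21-row residue chemistry table: one-hot index, elemental residue
#' composition (H, C, N, O, S), ten side-chain class flags, the two dyad flags
#' for \{N,D\} and \{E,Q\}, six float literature descriptors, and the
#' monoisotopic residue mass (computed from the element counts). The 21st
#' symbol `"m"` is oxidized methionine (methionine sulfoxide).
#'
#' The shipped file is plain TSV under `inst/extdata` and may be replaced by a
#' user table with the same columns, e.g. to supply a different six-descriptor
#' scale or different class sets.
#'
#' @param path Path to a chemistry TSV; default is the shipped table.
#' @return A data.frame with one row per residue symbol, and a `mass` column
#'   in Da. The result for the default path is cached.
#' @export
residue_chemistry <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.chem_cache$tab)) return(.chem_cache$tab)
  if (default)
    path <- system.file("extdata", "residue_chemistry.tsv", package = "pepccs",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 21L, !anyDuplicated(tab$symbol))
  if (!setequal(tab$index, 0:20))
    stop("chemistry table one-hot indices must be a bijection onto 0..20")
  el <- as.matrix(tab[, c("H", "C", "N", "O", "S")])
  if (any(el < 0)) stop("element counts must be non-negative")
  tab$mass <- as.numeric(el %*% .ELEMENT_MASS[colnames(el)])
  rownames(tab) <- tab$symbol
  if (default) .chem_cache$tab <- tab
  tab
}

#' Parse a peptide sequence string
#'
#' Accepts the canonical internal dialect and the bracketed modification
#' dialect used by the published CCS data sets:
#' \itemize{
#'   \item canonical: uppercase residue letters, lowercase `m` for oxidized
#'     Met, a leading `*` for an acetylated N-terminus, e.g. `"*AAmK"`;
#'   \item bracketed: `(ac)` prefix for N-terminal acetylation and `(ox)`
#'     following `M` for oxidized Met, e.g. `"(ac)AAM(ox)K"`; surrounding
#'     underscores (MaxQuant style `_..._`) are stripped.
#' }
#'
#' @param text Modified-sequence string.
#' @param charge Charge state; only 2, 3 and 4 are supported (other charge
#'   states are rejected, mirroring the training-data filtering).
#' @return A `peptide` object: list with `residues` (character vector over the
#'   21-symbol alphabet), `acetyl` (logical) and `charge` (integer).
#' @examples
#' p <- parse_peptide("(ac)AAM(ox)K", 2)
#' format(p)  # "*AAmK"
#' @export
parse_peptide <- function(text, charge) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("invalid-sequence: `text` must be a single string")
  charge <- suppressWarnings(as.integer(charge))
  if (length(charge) != 1L || is.na(charge) || !charge %in% 2:4)
    stop("invalid-charge: charge state must be 2, 3 or 4")
  s <- gsub("^_|_$", "", text)
  acetyl <- FALSE
  if (startsWith(s, "(ac)")) {
    acetyl <- TRUE
    s <- substr(s, 5L, nchar(s))
  } else if (startsWith(s, "*")) {
    acetyl <- TRUE
    s <- substr(s, 2L, nchar(s))
  }
  # bracketed modifications after a residue letter
  while (grepl("(", s, fixed = TRUE)) {
    m <- regmatches(s, regexpr("\\(([a-zA-Z]+)\\)", s))
    if (length(m) == 0L) stop("invalid-sequence: unbalanced parentheses in ", text)
    mod <- gsub("[()]", "", m)
    pos <- regexpr("\\(([a-zA-Z]+)\\)", s)[1]
    if (mod != "ox")
      stop("unsupported-modification: (", mod, ") is not supported")
    if (pos == 1L || substr(s, pos - 1L, pos - 1L) != "M")
      stop("unsupported-modification: (ox) may only follow M")
    s <- paste0(substr(s, 1L, pos - 2L), .OXMET,
                substr(s, pos + attr(regexpr("\\(([a-zA-Z]+)\\)", s), "match.length"),
                       nchar(s)))
  }
  if (nchar(s) == 0L) stop("invalid-sequence: empty sequence")
  residues <- strsplit(s, "")[[1]]
  bad <- !(residues %in% c(.STANDARD_AA, .OXMET))
  if (any(bad))
    stop("invalid-sequence: unknown residue letter(s): ",
         paste(unique(residues[bad]), collapse = ", "))
  structure(list(residues = residues, acetyl = acetyl, charge = charge),
            class = "peptide")
}

#' @export
format.peptide <- function(x, ...) {
  paste0(if (x$acetyl) "*" else "", paste(x$residues, collapse = ""))
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s  n=%d  z=%d%s\n", format(x), length(x$residues),
              x$charge, if (x$acetyl) "  N-term acetylated" else ""))
  invisible(x)
}

#' @export
length.peptide <- function(x) length(x$residues)

#' Elemental composition of a residue
#'
#' Residue (not free amino acid) composition; oxidized Met is Met plus one O.
#'
#' @param symbol Residue symbol from the 21-letter internal alphabet.
#' @param chem Chemistry table from [residue_chemistry()].
#' @return Named integer vector with counts for H, C, N, O, S.
#' @export
residue_composition <- function(symbol, chem = residue_chemistry()) {
  if (!symbol %in% chem$symbol) stop("invalid-sequence: unknown residue ", symbol)
  unlist(chem[symbol, c("H", "C", "N", "O", "S")])
}

#' Molecular formula of a peptide
#'
#' Sum of residue compositions plus one H2O (condensation), plus C2H2O if the
#' N-terminus is acetylated. The acetyl group contributes here (and hence to
#' the ion mass) but never to the per-residue features of the first residue;
#' acetylation enters the featurization only through its dedicated flags.
#'
#' @param p A `peptide`.
#' @param chem Chemistry table.
#' @return Named integer vector with counts for H, C, N, O, S.
#' @export
peptide_formula <- function(p, chem = residue_chemistry()) {
  stopifnot(inherits(p, "peptide"))
  el <- as.matrix(chem[p$residues, c("H", "C", "N", "O", "S"), drop = FALSE])
  counts <- colSums(el) + .WATER
  if (p$acetyl) counts <- counts + .ACETYL
  counts
}

#' Neutral and ion mass of a peptide
#'
#' `peptide_mass()` is the monoisotopic neutral mass; `ion_mass()` adds z
#' proton masses for the protonated species observed in the instrument.
#'
#' @param p A `peptide`.
#' @param chem Chemistry table.
#' @return Mass in Da.
#' @export
peptide_mass <- function(p, chem = residue_chemistry()) {
  counts <- peptide_formula(p, chem)
  sum(counts * .ELEMENT_MASS[names(counts)])
}

#' @rdname peptide_mass
#' @export
ion_mass <- function(p, chem = residue_chemistry()) {
  peptide_mass(p, chem) + p$charge * .PROTON_MASS
}
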