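# Featurization: per-residue feature vectors, cumulative window features,
# the fixed-length 323-channel spatial encoding and the multi-scale global
# feature vector.

.N_RESIDUE_FEATURES <- 45L
.N_SPATIAL_CHANNELS <- 323L  # 4 leading + 7*45 + 3 position + 1 charge
.PAD_FEATURE <- 45L          # 1-based column of the padding indicator (feature 44)

# column blocks of the residue feature vector (1-based)
.F_CLASS_COLS <- c("acidic", "modified", "amide", "nonpolar", "small",
                   "uncharged_polar", "aliphatic", "aromatic", "positive",
                   "hydroxyl", "dyad_ND", "dyad_EQ")
.F_DESC_COLS <- c("hydropathy", "volume", "polarity", "pi", "helix", "bulkiness")

#' Per-residue feature vector
#'
#' The 45 features that characterize a single residue: one-hot identity over
#' the 21-symbol alphabet (features 0-20, oxidized Met is index 20), elemental
#' composition H/C/N/O/S (21-25), ten side-chain class flags (26-35), the
#' \{N,D\} and \{E,Q\} dyad flags (36-37), six float descriptors (38-43) and a
#' padding indicator (44) that is 0 for every real residue and 1 only for the
#' padding symbol.
#'
#' @param symbol Residue symbol, or `NA` for the padding symbol.
#' @param chem Chemistry table from [residue_chemistry()].
#' @return Numeric vector of length 45. Feature `i` (0-based, as used in the
#'   docs) is element `i + 1`.
#' @export
residue_features <- function(symbol, chem = residue_chemistry()) {
  v <- numeric(.N_RESIDUE_FEATURES)
  if (is.na(symbol)) {          # padding symbol
    v[.PAD_FEATURE] <- 1
    return(v)
  }
  if (!symbol %in% chem$symbol) stop("invalid-sequence: unknown residue ", symbol)
  row <- chem[symbol, ]
  v[row$index + 1L] <- 1
  v[22:26] <- as.numeric(row[c("H", "C", "N", "O", "S")])
  v[27:38] <- as.numeric(row[.F_CLASS_COLS])
  v[39:44] <- as.numeric(row[.F_DESC_COLS])
  v
}

#' Residue feature matrix of a peptide
#'
#' @param p A `peptide`.
#' @param chem Chemistry table.
#' @return n x 45 matrix; row j holds the feature vector of residue j.
#' @export
feature_matrix <- function(p, chem = residue_chemistry()) {
  stopifnot(inherits(p, "peptide"))
  idx <- chem[p$residues, "index"] + 1L
  n <- length(idx)
  F <- matrix(0, n, .N_RESIDUE_FEATURES)
  F[cbind(seq_len(n), idx)] <- 1
  F[, 22:26] <- as.matrix(chem[p$residues, c("H", "C", "N", "O", "S")])
  F[, 27:38] <- as.matrix(chem[p$residues, .F_CLASS_COLS])
  F[, 39:44] <- as.matrix(chem[p$residues, .F_DESC_COLS])
  F
}

#' Cumulative window features
#'
#' The three cumulative operators over a window of residue positions:
#' \describe{
#'   \item{kind 1}{window sum divided by 100 (the division keeps input
#'     magnitudes small for the network);}
#'   \item{kind 2}{window sum divided by the full-sequence sum, defined as 0
#'     for features absent from the whole peptide;}
#'   \item{kind 3}{window mean (window sum divided by the window length).}
#' }
#'
#' @param F n x 45 residue feature matrix from [feature_matrix()].
#' @param kind 1, 2 or 3.
#' @param j_start,j_end 1-based inclusive window bounds.
#' @return Numeric vector of length 45.
#' @export
cumulative_features <- function(F, kind, j_start, j_end) {
  n <- nrow(F)
  if (j_start < 1L || j_end > n || j_start > j_end)
    stop("window [", j_start, ", ", j_end, "] out of bounds for n = ", n)
  s <- colSums(F[j_start:j_end, , drop = FALSE])
  switch(as.character(kind),
    "1" = s / 100,
    "2" = {
      tot <- colSums(F)
      out <- numeric(length(s))
      nz <- tot != 0
      out[nz] <- s[nz] / tot[nz]
      out
    },
    "3" = s / (j_end - j_start + 1L),
    stop("kind must be 1, 2 or 3"))
}

# All prefix and suffix cumulative features of a peptide in one pass:
# returns list of six n x 45 matrices (C1/C2/C3 over [1, j] and [j, n]).
.prefix_suffix_cumulative <- function(F) {
  n <- nrow(F)
  cs <- apply(F, 2L, cumsum)
  if (n == 1L) cs <- matrix(cs, 1L)
  tot <- cs[n, ]
  suf <- sweep(-rbind(0, cs[-n, , drop = FALSE]), 2L, tot, "+")  # sum over [j, n]
  inv_tot <- ifelse(tot == 0, 0, 1 / tot)
  list(
    c1_pre = cs / 100,
    c2_pre = sweep(cs, 2L, inv_tot, "*"),
    c3_pre = cs / seq_len(n),
    c1_suf = suf / 100,
    c2_suf = sweep(suf, 2L, inv_tot, "*"),
    c3_suf = suf / (n - seq_len(n) + 1L)
  )
}

#' Subsequence window layout
#'
#' Configuration of the multi-scale subsequence windows whose kind-1
#' cumulative features make up the bulk of the global feature vector: windows
#' of fixed lengths anchored at both termini, plus tilings of the peptide into
#' 2, 4, 8 and 16 consecutive pieces.
#'
#' @param fixed_lengths Fixed window lengths, each anchored at the N- and at
#'   the C-terminus (clamped when the peptide is shorter).
#' @param fractions Fractional levels; level `f` tiles the peptide into `1/f`
#'   consecutive windows with round-half-up borders, repaired so that every
#'   window keeps at least one residue.
#' @return A `subsequence_layout` object.
#' @export
subsequence_layout <- function(fixed_lengths = c(5L, 10L, 20L),
                               fractions = c(1 / 2, 1 / 4, 1 / 8, 1 / 16)) {
  stopifnot(all(fixed_lengths >= 1L), all(fractions > 0 & fractions <= 1))
  structure(list(fixed_lengths = as.integer(fixed_lengths),
                 fractions = fractions),
            class = "subsequence_layout")
}

#' @rdname subsequence_layout
#' @export
n_layout_windows <- function(layout = subsequence_layout()) {
  2L * length(layout$fixed_lengths) + sum(as.integer(round(1 / layout$fractions)))
}

.round_half_up <- function(x) floor(x + 0.5)

#' Subsequence windows for a peptide length
#'
#' @param n Peptide length.
#' @param layout A [subsequence_layout()].
#' @return Data frame with 1-based inclusive `start`/`end` columns and a
#'   `label` column; the number and order of rows depend only on the layout,
#'   never on `n`. For `n` at least the number of tiles, each fractional
#'   tiling is disjoint and covers `1..n`; for shorter peptides windows are
#'   clamped so each keeps at least one residue.
#' @export
subsequence_windows <- function(n, layout = subsequence_layout()) {
  stopifnot(n >= 1L)
  starts <- integer(0); ends <- integer(0); labels <- character(0)
  for (k in layout$fixed_lengths) {
    starts <- c(starts, 1L, max(1L, n - k + 1L))
    ends <- c(ends, min(n, k), n)
    labels <- c(labels, sprintf("nterm%d", k), sprintf("cterm%d", k))
  }
  for (f in layout$fractions) {
    tiles <- as.integer(round(1 / f))
    b <- .round_half_up((0:tiles) * n / tiles)
    for (t in seq_len(tiles)) {
      lo <- min(b[t] + 1L, n)
      hi <- max(lo, min(b[t + 1L], n))
      starts <- c(starts, lo); ends <- c(ends, hi)
      labels <- c(labels, sprintf("frac%d_%d", tiles, t))
    }
  }
  data.frame(start = as.integer(starts), end = as.integer(ends),
             label = labels, stringsAsFactors = FALSE)
}

#' Fixed-length spatial encoding of a peptide
#'
#' Encodes a peptide as an `L x 323` multi-channel matrix for the
#' convolutional branch. Residues occupy rows `1..n` (left-aligned); remaining
#' rows are padding. Channels per row: amino-acid indicator; N-terminus,
#' acetylated-N-terminus and C-terminus flags; the 315-feature block (seven
#' 45-wide blocks: the residue features F, then the three cumulative
#' operators over the prefix ending at the residue and over the suffix
#' starting at it); relative position (0 at the N-terminus, 1 at the
#' C-terminus, 0 for a single residue); raw residue distances from the N- and
#' C-terminus; and the charge state replicated across every row, padding
#' included. Padding rows carry the padding feature vector in the F block and
#' zeros elsewhere (apart from the charge channel).
#'
#' @param p A `peptide`.
#' @param L Encoding length; must exceed the peptide length by more than 40.
#' @param chem Chemistry table.
#' @return `L x 323` numeric matrix.
#' @export
spatial_encoding <- function(p, L = 96L, chem = residue_chemistry()) {
  stopifnot(inherits(p, "peptide"))
  n <- length(p$residues)
  if (L < n + 41L)
    stop("encoding-length: L = ", L, " must be at least peptide length + 41 (n = ", n, ")")
  F <- feature_matrix(p, chem)
  cum <- .prefix_suffix_cumulative(F)
  E <- matrix(0, L, .N_SPATIAL_CHANNELS)
  j <- seq_len(n)
  E[j, 1L] <- 1                       # amino-acid indicator
  E[1L, 2L] <- 1                      # N-terminus (modified or not)
  if (p$acetyl) E[1L, 3L] <- 1        # acetylated N-terminus
  E[n, 4L] <- 1                       # C-terminus
  blocks <- list(F, cum$c1_pre, cum$c2_pre, cum$c3_pre,
                 cum$c1_suf, cum$c2_suf, cum$c3_suf)
  for (b in seq_along(blocks))
    E[j, (4L + (b - 1L) * 45L + 1L):(4L + b * 45L)] <- blocks[[b]]
  if (n > 1L) E[-j, 4L + .PAD_FEATURE] <- 1 else E[-1L, 4L + .PAD_FEATURE] <- 1
  E[j, 320L] <- if (n == 1L) 0 else (j - 1L) / (n - 1L)  # relative position
  E[j, 321L] <- j - 1L                # residues before (distance from N-term)
  E[j, 322L] <- n - j                 # residues after (distance from C-term)
  E[, 323L] <- p$charge               # charge state, padding included
  E
}

#' Global feature vector for the dense branch
#'
#' The first six features are peptide length, integer charge, the one-hot
#' charge encoding over \{2,3,4\} and the N-terminal acetylation flag. In the
#' full feature set these are followed by the kind-1 cumulative 45-vector of
#' every window of the subsequence layout, in layout order; the reduced
#' feature set keeps only the six scalars.
#'
#' @param p A `peptide`.
#' @param layout A [subsequence_layout()].
#' @param reduced If `TRUE`, return only the six scalars.
#' @param chem Chemistry table.
#' @return Numeric vector of length 6 (reduced) or
#'   `6 + 45 * n_layout_windows(layout)` (full); the length is identical for
#'   all peptides under one layout.
#' @export
global_features <- function(p, layout = subsequence_layout(), reduced = FALSE,
                            chem = residue_chemistry()) {
  stopifnot(inherits(p, "peptide"))
  n <- length(p$residues)
  head6 <- c(n, p$charge, as.numeric(p$charge == 2:4), as.numeric(p$acetyl))
  if (reduced) return(head6)
  F <- feature_matrix(p, chem)
  w <- subsequence_windows(n, layout)
  feats <- vapply(seq_len(nrow(w)),
                  function(i) colSums(F[w$start[i]:w$end[i], , drop = FALSE]) / 100,
                  numeric(.N_RESIDUE_FEATURES))
  c(head6, as.numeric(feats))
}

#' Channel layout manifest
#'
#' Machine-readable names for the 323 spatial channels and the global feature
#' slots, for export alongside encoded tensors.
#'
#' @param layout A [subsequence_layout()].
#' @param reduced Reduced global feature set?
#' @return List with `spatial` (length 323) and `global` character vectors.
#' @export
encoding_manifest <- function(layout = subsequence_layout(), reduced = FALSE) {
  fnames <- sprintf("F%02d", 0:44)
  spatial <- c("aa_indicator", "n_terminus", "acetyl_n_terminus", "c_terminus",
               paste0(rep(c("F", "C1_pre", "C2_pre", "C3_pre",
                            "C1_suf", "C2_suf", "C3_suf"), each = 45L),
                      "_", rep(sprintf("%02d", 0:44), 7L)),
               "relative_position", "dist_from_nterm", "dist_from_cterm",
               "charge")
  glob <- c("length", "charge", "charge_is_2", "charge_is_3", "charge_is_4",
            "acetylated")
  if (!reduced) {
    w <- subsequence_windows(30L, layout)   # labels depend only on layout
    glob <- c(glob, paste0(rep(w$label, each = 45L), "_C1_",
                           rep(sprintf("%02d", 0:44), nrow(w))))
  }
  list(spatial = spatial, global = glob)
}

#' Encode a set of peptides for the network
#'
#' Builds the spatial tensor and global feature matrix for a list of peptides,
#' together with the encoding configuration that models store and check at
#' prediction time.
#'
#' @param peptides List of `peptide` objects.
#' @param ccs Optional reference CCS values in squared angstroms.
#' @param L Spatial encoding length.
#' @param layout A [subsequence_layout()].
#' @param reduced Use the reduced (six-scalar) global feature set?
#' @param chem Chemistry table.
#' @return A `ccs_encoding` object: list with `spatial` (n x L x 323 array),
#'   `global` (n x G matrix), `ccs`, `charge`, `mass` (neutral monoisotopic
#'   masses) and `config`.
#' @export
encode_dataset <- function(peptides, ccs = NULL, L = 96L,
                           layout = subsequence_layout(), reduced = FALSE,
                           chem = residue_chemistry()) {
  stopifnot(length(peptides) >= 1L)
  if (!is.null(ccs)) stopifnot(length(ccs) == length(peptides))
  n <- length(peptides)
  G <- length(global_features(peptides[[1L]], layout, reduced, chem))
  spatial <- array(0, c(n, L, .N_SPATIAL_CHANNELS))
  glob <- matrix(0, n, G)
  for (i in seq_len(n)) {
    spatial[i, , ] <- spatial_encoding(peptides[[i]], L, chem)
    glob[i, ] <- global_features(peptides[[i]], layout, reduced, chem)
  }
  structure(list(
    spatial = spatial, global = glob, ccs = ccs,
    charge = vapply(peptides, function(p) p$charge, integer(1)),
    mass = vapply(peptides, peptide_mass, numeric(1), chem = chem),
    config = list(L = as.integer(L), layout = layout, reduced = reduced,
                  n_spatial_channels = .N_SPATIAL_CHANNELS, global_length = G)
  ), class = "ccs_encoding")
}
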