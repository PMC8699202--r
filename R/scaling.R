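# Static input scaling: fixed per-channel divisors derived from the
# chemistry table and the encoding length alone (never from data). They
# condition the optimization; encodings themselves are untouched.

#' Static input scales for the network
#'
#' Per-channel divisors for the spatial encoding and the global feature
#' vector: each residue-feature channel is bounded by its maximum absolute
#' value over the 21 symbols, kind-1 cumulative channels by that bound times
#' the longest encodable peptide over 100, kind-2 channels by 1, kind-3
#' channels by the per-residue bound, distance and length channels by the
#' longest encodable peptide, and the charge channel by 4. All scales are at
#' least 1. These constants are stored in the network configuration so
#' training and prediction apply them identically.
#'
#' @param L Spatial encoding length.
#' @param global_length Length of the global feature vector.
#' @param chem Chemistry table.
#' @return List with `spatial` (length 323) and `global` (length
#'   `global_length`) divisor vectors.
#' @export
static_input_scales <- function(L, global_length, chem = residue_chemistry()) {
  F21 <- vapply(chem$symbol, function(s) residue_features(s, chem),
                numeric(.N_RESIDUE_FEATURES))
  fmax <- pmax(1, apply(abs(F21), 1L, max))
  n_max <- L - 41L                       # longest encodable peptide
  c1max <- pmax(1, fmax * n_max / 100)
  spatial <- c(rep(1, 4), fmax, c1max, rep(1, 45), fmax, c1max, rep(1, 45),
               fmax, 1, n_max, n_max, 4)
  if (global_length == 6L) {
    glob <- c(n_max, 4, 1, 1, 1, 1)
  } else {
    n_windows <- (global_length - 6L) / 45L
    if (n_windows != round(n_windows))
      stop("configuration: global_length ", global_length,
           " is not 6 + 45 * windows")
    glob <- c(n_max, 4, 1, 1, 1, 1, rep(c1max, n_windows))
  }
  list(spatial = spatial, global = glob)
}
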