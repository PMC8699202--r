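# Synthetic tryptic-like peptides with a known, position-dependent
# ground-truth CCS function, so featurization, training, ensembling and
# drift calibration are testable without any external data.

# Approximate natural amino-acid frequencies; K/R are down-weighted at
# internal positions because tryptic peptides rarely contain internal
# cleavage sites (missed cleavages are rare).
.AA_FREQ <- c(A = 8.3, C = 1.4, D = 5.4, E = 6.7, F = 3.9, G = 7.1, H = 2.3,
              I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 4.0,
              R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)

#' Synthetic peptide generator configuration
#'
#' Defaults emulate the published data set's composition: tryptic-like
#' peptides of 7-45 residues with a strong C-terminal K/R bias, occasional
#' methionine oxidation and N-terminal acetylation, and length-dependent
#' charge states 2-4.
#'
#' @param n_peptides Number of peptides to draw.
#' @param length_range Inclusive length range.
#' @param c_term_kr_prob Probability that the C-terminal residue is K or R.
#' @param met_ox_prob Per-Met oxidation probability.
#' @param acetyl_prob N-terminal acetylation probability.
#' @param noise_sd Gaussian noise added to the ground-truth CCS (squared
#'   angstroms).
#' @param seed Random seed.
#' @return A `ccs_generator_config` list.
#' @export
generator_config <- function(n_peptides = 1000L, length_range = c(7L, 45L),
                             c_term_kr_prob = 0.9, met_ox_prob = 0.1,
                             acetyl_prob = 0.05, noise_sd = 5, seed = 1L) {
  stopifnot(length_range[1] >= 1L, length_range[2] >= length_range[1],
            c_term_kr_prob >= 0, c_term_kr_prob <= 1,
            met_ox_prob >= 0, met_ox_prob <= 1,
            acetyl_prob >= 0, acetyl_prob <= 1, noise_sd >= 0)
  structure(list(n_peptides = as.integer(n_peptides),
                 length_range = as.integer(length_range),
                 c_term_kr_prob = c_term_kr_prob, met_ox_prob = met_ox_prob,
                 acetyl_prob = acetyl_prob, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ccs_generator_config")
}

# length-dependent categorical charge assignment: short peptides are mostly
# doubly charged, long ones increasingly 3+/4+.
.charge_probs <- function(n) {
  if (n <= 15L) c(0.85, 0.13, 0.02)
  else if (n <= 25L) c(0.55, 0.40, 0.05)
  else c(0.25, 0.60, 0.15)
}

#' Generate synthetic tryptic-like peptides
#'
#' @param cfg A [generator_config()].
#' @return List of `peptide` objects; reproducible given the seed.
#' @export
generate_peptides <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "ccs_generator_config"))
  set.seed(cfg$seed)
  internal_freq <- .AA_FREQ
  internal_freq[c("K", "R")] <- internal_freq[c("K", "R")] * 0.1
  lapply(seq_len(cfg$n_peptides), function(i) {
    n <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
    res <- sample(names(.AA_FREQ), n, replace = TRUE, prob = internal_freq)
    if (stats::runif(1) < cfg$c_term_kr_prob)
      res[n] <- sample(c("K", "R"), 1L)
    is_met <- res == "M"
    ox <- is_met & stats::runif(length(res)) < cfg$met_ox_prob
    res[ox] <- .OXMET
    charge <- sample(2:4, 1L, prob = .charge_probs(n))
    structure(list(residues = res,
                   acetyl = stats::runif(1) < cfg$acetyl_prob,
                   charge = as.integer(charge)),
              class = "peptide")
  })
}

#' Ground-truth CCS parameters
#'
#' The synthetic ground truth is a physically motivated stand-in, not the
#' published model: per-charge intercept and slope on the neutral mass to the
#' power 2/3 (globular-ion surface scaling), additive per-residue offsets
#' derived from residue volume, and a positional term that shifts the CCS of
#' designated residues (proline and histidine by default) linearly with their
#' relative position, exercising the position dependence of CCS.
#'
#' @param intercept Per-charge intercepts (z = 2, 3, 4), squared angstroms.
#' @param slope Per-charge slopes on mass^(2/3); must be positive.
#' @param positional_residues Residues carrying the positional term.
#' @param positional_weight Full N-to-C-terminus CCS shift per positional
#'   residue, squared angstroms.
#' @param volume_scale Divisor turning centred residue volumes into CCS
#'   offsets.
#' @return A `ccs_ground_truth` list.
#' @export
ground_truth_params <- function(intercept = c(130, 150, 170),
                                slope = c(2.2, 2.3, 2.4),
                                positional_residues = c("P", "H"),
                                positional_weight = 25,
                                volume_scale = 10) {
  stopifnot(all(slope > 0), length(intercept) == 3L, length(slope) == 3L)
  structure(list(intercept = intercept, slope = slope,
                 positional_residues = positional_residues,
                 positional_weight = positional_weight,
                 volume_scale = volume_scale),
            class = "ccs_ground_truth")
}

#' Ground-truth CCS of a peptide
#'
#' @param p A `peptide`.
#' @param params A [ground_truth_params()].
#' @param noise_sd Gaussian noise standard deviation in squared angstroms; 0
#'   gives the deterministic ground truth.
#' @param chem Chemistry table.
#' @return CCS in squared angstroms.
#' @export
ground_truth_ccs <- function(p, params = ground_truth_params(), noise_sd = 0,
                             chem = residue_chemistry()) {
  stopifnot(inherits(p, "peptide"))
  zi <- p$charge - 1L  # 2 -> index 1
  M <- peptide_mass(p, chem)
  vol <- chem[p$residues, "volume"]
  offsets <- sum((vol - 139) / params$volume_scale)
  n <- length(p$residues)
  pos_idx <- which(p$residues %in% params$positional_residues)
  relpos <- if (n == 1L) rep(0, length(pos_idx)) else (pos_idx - 1) / (n - 1)
  positional <- params$positional_weight * sum(relpos)
  ccs <- params$intercept[zi] + params$slope[zi] * M^(2 / 3) +
    offsets + positional
  if (noise_sd > 0) ccs <- ccs + stats::rnorm(1L, sd = noise_sd)
  ccs
}

#' Generate a labelled synthetic data set with train/validation/test splits
#'
#' Draws peptides, deduplicates by modified sequence + charge, labels them
#' with the ground-truth CCS plus noise, shuffles, and splits 85/5/10 so that
#' no peptide occurs in more than one split.
#'
#' @param cfg A [generator_config()] (`n_peptides` at least 20).
#' @param params A [ground_truth_params()].
#' @param chem Chemistry table.
#' @return List with `train`, `validation` and `test`, each a list with
#'   `peptides` (list of `peptide`) and `ccs`, plus the generating `cfg` and
#'   `params`.
#' @export
make_dataset <- function(cfg = generator_config(), params = ground_truth_params(),
                         chem = residue_chemistry()) {
  stopifnot(cfg$n_peptides >= 20L)
  peps <- generate_peptides(cfg)
  key <- vapply(peps, function(p) paste0(format(p), "/", p$charge), character(1))
  peps <- peps[!duplicated(key)]
  ccs <- vapply(peps, ground_truth_ccs, numeric(1), params = params,
                noise_sd = cfg$noise_sd, chem = chem)
  n <- length(peps)
  perm <- sample.int(n)
  n_test <- round(0.10 * n)
  n_val <- round(0.05 * n)
  i_test <- perm[seq_len(n_test)]
  i_val <- perm[n_test + seq_len(n_val)]
  i_train <- perm[(n_test + n_val + 1L):n]
  split <- function(i) list(peptides = peps[i], ccs = ccs[i])
  list(train = split(i_train), validation = split(i_val), test = split(i_test),
       cfg = cfg, params = params)
}
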