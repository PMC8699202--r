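# Shared helpers: independent brute-force oracles and small fixtures.

# Random synthetic peptides for property tests.
rand_peptides <- function(n, length_range = c(1L, 30L), seed = 1L) {
  generate_peptides(generator_config(
    n_peptides = n, length_range = length_range, met_ox_prob = 0.2,
    acetyl_prob = 0.2, seed = seed))
}

# Independent elemental-composition oracle: free amino-acid molecular
# formulas written down independently of the shipped chemistry table, minus
# one water per residue.
.FREE_AA_FORMULA <- c(
  A = "C3H7NO2",  R = "C6H14N4O2", N = "C4H8N2O3", D = "C4H7NO4",
  C = "C3H7NO2S", E = "C5H9NO4",   Q = "C5H10N2O3", G = "C2H5NO2",
  H = "C6H9N3O2", I = "C6H13NO2",  L = "C6H13NO2",  K = "C6H14N2O2",
  M = "C5H11NO2S", F = "C9H11NO2", P = "C5H9NO2",   S = "C3H7NO3",
  T = "C4H9NO3",  W = "C11H12N2O2", Y = "C9H11NO3", V = "C5H11NO2",
  m = "C5H11NO3S")

parse_formula <- function(f) {
  counts <- c(H = 0L, C = 0L, N = 0L, O = 0L, S = 0L)
  for (m in regmatches(f, gregexpr("[A-Z][a-z]?\\d*", f))[[1]]) {
    el <- gsub("\\d", "", m)
    k <- gsub("\\D", "", m)
    counts[el] <- counts[el] + if (k == "") 1L else as.integer(k)
  }
  counts
}

oracle_peptide_formula <- function(p) {
  water <- c(H = 2L, C = 0L, N = 0L, O = 1L, S = 0L)
  counts <- c(H = 0L, C = 0L, N = 0L, O = 0L, S = 0L)
  for (r in p$residues)
    counts <- counts + parse_formula(.FREE_AA_FORMULA[[r]]) - water
  counts <- counts + water   # one condensation water remains
  if (p$acetyl) counts <- counts + c(H = 2L, C = 2L, N = 0L, O = 1L, S = 0L)
  counts
}

# Naive cumulative-feature oracle: literal summation, no prefix trick.
oracle_cumulative <- function(F, kind, j_start, j_end) {
  out <- numeric(ncol(F))
  for (i in seq_len(ncol(F))) {
    s <- 0
    for (j in j_start:j_end) s <- s + F[j, i]
    if (kind == 1) out[i] <- s / 100
    if (kind == 2) {
      tot <- 0
      for (j in seq_len(nrow(F))) tot <- tot + F[j, i]
      out[i] <- if (tot == 0) 0 else s / tot
    }
    if (kind == 3) out[i] <- s / (j_end - j_start + 1)
  }
  out
}

# Tiny trained model fixture shared across model tests (built once per run).
tiny_trained <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    peps <- rand_peptides(24, c(5L, 7L), seed = 5L)
    ccs <- vapply(peps, ground_truth_ccs, numeric(1))
    enc <- encode_dataset(peps, ccs, L = 48L)
    net <- ccs_network(L = 48L, global_length = ncol(enc$global), seed = 1L)
    tc <- training_config(batch_size = 8L, max_epochs = 2L,
                          validate_every = 3L, validate_at_epoch_end = FALSE,
                          seed = 7L)
    model <- train_ccs_model(net, enc, enc, tc)
    cache <<- list(peptides = peps, ccs = ccs, enc = enc, model = model)
    cache
  }
})
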