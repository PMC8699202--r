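test_that("per-residue feature vectors follow the 45-feature layout", {
  chem <- residue_chemistry()
  # padding symbol: everything 0 except the padding indicator (feature 44)
  pad <- residue_features(NA)
  expect_length(pad, 45)
  expect_identical(which(pad != 0), 45L)
  expect_identical(pad[45], 1)

  # Asp carries the acidic flag (feature 26) and the {N,D} dyad flag (36)
  d <- residue_features("D")
  expect_identical(d[27], 1)  # acidic
  expect_identical(d[37], 1)  # N/D dyad
  expect_identical(d[38], 0)  # not E/Q dyad

  # every residue symbol: exactly one one-hot among features 0-20, padding 0
  for (s in chem$symbol) {
    v <- residue_features(s)
    expect_identical(sum(v[1:21] == 1), 1L)
    expect_identical(sum(v[1:21] == 0), 20L)
    expect_identical(v[45], 0)
  }

  # oxidized Met: one-hot index 20, modified + uncharged-polar flags,
  # one more oxygen than Met, Met's float descriptors
  m <- residue_features("m"); M <- residue_features("M")
  expect_identical(which(m[1:21] == 1), 21L)
  expect_identical(m[28], 1)           # modified (non-standard)
  expect_identical(m[32], 1)           # uncharged polar
  expect_identical(m[25] - M[25], 1)   # O count
  expect_identical(m[39:44], M[39:44])
})

test_that("feature matrix stacks residue vectors row-wise", {
  F <- feature_matrix(parse_peptide("GG", 2))
  expect_identical(dim(F), c(2L, 45L))
  expect_identical(F[1, ], F[2, ])

  F1 <- feature_matrix(parse_peptide("W", 2))
  expect_identical(dim(F1), c(1L, 45L))

  F3 <- feature_matrix(parse_peptide("GM(ox)K", 2))
  expect_identical(F3[2, ], residue_features("m"))
  expect_identical(F3[2, 25], residue_features("M")[25] + 1)
})

test_that("cumulative operators match their definitions", {
  F <- feature_matrix(parse_peptide("GGG", 2))
  gcol <- residue_chemistry()["G", "index"] + 1L
  c1 <- cumulative_features(F, 1, 1, 3)
  expect_equal(c1[gcol], 0.03)   # three G's summed, divided by 100

  # kind 2 over the full window normalizes every present feature to 1
  p <- parse_peptide("ADEK", 3)
  F <- feature_matrix(p)
  c2 <- cumulative_features(F, 2, 1, 4)
  tot <- colSums(F)
  expect_true(all(c2[tot != 0] == 1))
  expect_true(all(c2[tot == 0] == 0))

  # kind 3 over a single-residue window is that residue's feature vector
  expect_identical(cumulative_features(F, 3, 2, 2), F[2, ])

  expect_error(cumulative_features(F, 1, 0, 2), "out of bounds")
  expect_error(cumulative_features(F, 1, 3, 2), "out of bounds")
  expect_error(cumulative_features(F, 1, 1, 5), "out of bounds")
})

test_that("cumulative operators satisfy their invariants on random peptides", {
  peps <- rand_peptides(40, c(2L, 30L), seed = 9L)
  for (p in peps) {
    F <- feature_matrix(p)
    n <- nrow(F)
    j <- sample(n - 1L, 1L)
    # additivity of the kind-1 sums across a split point
    expect_equal(cumulative_features(F, 1, 1, j) + cumulative_features(F, 1, j + 1L, n),
                 cumulative_features(F, 1, 1, n), tolerance = 1e-12)
    w <- sort(sample(n, 2L, replace = TRUE))
    c2 <- cumulative_features(F, 2, w[1], w[2])
    expect_true(all(c2 >= 0 & c2 <= 1))
    c3 <- cumulative_features(F, 3, w[1], w[2])
    sub <- F[w[1]:w[2], , drop = FALSE]
    expect_true(all(c3 >= apply(sub, 2, min) - 1e-12 &
                    c3 <= apply(sub, 2, max) + 1e-12))
  }
})

test_that("subsequence windows tile the peptide as configured", {
  w <- subsequence_windows(30)
  expect_identical(nrow(w), 36L)  # 6 fixed + 2 + 4 + 8 + 16 tiles
  # count depends only on the layout, never on n
  for (n in c(1L, 7L, 16L, 45L)) {
    wn <- subsequence_windows(n)
    expect_identical(nrow(wn), 36L)
    expect_true(all(wn$start >= 1L & wn$end <= n & wn$start <= wn$end))
  }
  # degenerate single-residue peptide: every window is [1, 1]
  w1 <- subsequence_windows(1)
  expect_true(all(w1$start == 1L & w1$end == 1L))
  # each fractional tiling is disjoint and covers 1..n when it fits
  for (n in c(16L, 23L, 45L)) {
    wn <- subsequence_windows(n)
    for (tiles in c(2L, 4L, 8L, 16L)) {
      tw <- wn[grepl(sprintf("^frac%d_", tiles), wn$label), ]
      covered <- unlist(Map(seq, tw$start, tw$end))
      expect_identical(sort(covered), seq_len(n))  # disjoint + complete
    }
  }
  # fixed-length windows anchor at both termini, clamped for short peptides
  w7 <- subsequence_windows(7)
  expect_identical(w7$start[w7$label == "nterm5"], 1L)
  expect_identical(w7$end[w7$label == "nterm5"], 5L)
  expect_identical(w7$start[w7$label == "cterm10"], 1L)
  expect_identical(w7$end[w7$label == "cterm20"], 7L)
  w45 <- subsequence_windows(45)
  expect_identical(w45$start[w45$label == "cterm20"], 26L)
  expect_identical(w45$end[w45$label == "nterm20"], 20L)
})

test_that("spatial encoding has the documented channel layout", {
  p <- parse_peptide("AAK", 2)
  E <- spatial_encoding(p, L = 57)
  expect_identical(dim(E), c(57L, 323L))  # 4 + 315 + 3 + 1 channels
  # amino-acid indicator marks exactly the residue rows
  expect_identical(which(E[, 1] == 1), 1:3)
  # exactly one N-terminus and one C-terminus row
  expect_identical(which(E[, 2] == 1), 1L)
  expect_identical(which(E[, 4] == 1), 3L)
  expect_true(all(E[, 3] == 0))  # not acetylated
  Ea <- spatial_encoding(parse_peptide("*AAK", 2), L = 57)
  expect_identical(which(Ea[, 3] == 1), 1L)
  # padding rows: indicator 0, F-block padding slot 1, cumulative slots 0
  pad_rows <- 4:57
  expect_true(all(E[pad_rows, 1] == 0))
  expect_true(all(E[pad_rows, 4 + 45] == 1))          # feature 44 slot
  expect_true(all(E[pad_rows, 50:319] == 0))          # six cumulative blocks
  # position channels
  expect_equal(E[1:3, 320], c(0, 0.5, 1))             # relative position
  expect_identical(E[1:3, 321], c(0, 1, 2))           # residues before
  expect_identical(E[1:3, 322], c(2, 1, 0))           # residues after
  expect_true(all(E[pad_rows, 320:322] == 0))
  # charge is replicated across all rows, padding included
  expect_true(all(E[, 323] == 2))
  # single-residue peptide: relative position defined as 0
  E1 <- spatial_encoding(parse_peptide("K", 2), L = 57)
  expect_identical(E1[1, 320], 0)

  expect_error(spatial_encoding(parse_peptide("AAK", 2), L = 43),
               "encoding-length")
})

test_that("spatial encoding does not depend on L beyond extra padding rows", {
  p <- parse_peptide("SAMPLEK", 3)
  E1 <- spatial_encoding(p, L = 48)
  E2 <- spatial_encoding(p, L = 96)
  expect_identical(E2[1:48, ], E1)
  for (j in 49:96)
    expect_identical(E2[j, ], E2[48, ])  # padding rows all identical
  # determinism: bit-identical re-encoding
  expect_identical(spatial_encoding(p, L = 96), E2)
})

test_that("the F-block and cumulative blocks of the encoding match direct computation", {
  p <- parse_peptide("*GM(ox)APK", 3)
  E <- spatial_encoding(p, L = 48)
  F <- feature_matrix(p)
  n <- nrow(F)
  for (j in seq_len(n)) {
    expect_equal(E[j, 5:49], F[j, ])
    expect_equal(E[j, 50:94], oracle_cumulative(F, 1, 1, j))
    expect_equal(E[j, 95:139], oracle_cumulative(F, 2, 1, j))
    expect_equal(E[j, 140:184], oracle_cumulative(F, 3, 1, j))
    expect_equal(E[j, 185:229], oracle_cumulative(F, 1, j, n))
    expect_equal(E[j, 230:274], oracle_cumulative(F, 2, j, n))
    expect_equal(E[j, 275:319], oracle_cumulative(F, 3, j, n))
  }
})

test_that("global features follow the documented layout", {
  p3 <- parse_peptide("SAMPLER", 3)
  g <- global_features(p3, reduced = TRUE)
  expect_length(g, 6)
  expect_equal(g, c(7, 3, 0, 1, 0, 0))  # length, z, one-hot(2,3,4), acetyl

  gf <- global_features(p3)
  expect_length(gf, 6 + 45 * 36)  # 1626 with the default layout
  # windowed blocks are the kind-1 cumulative features in layout order
  F <- feature_matrix(p3)
  w <- subsequence_windows(7)
  expect_equal(gf[7:51], oracle_cumulative(F, 1, w$start[1], w$end[1]))
  k <- nrow(w)
  expect_equal(gf[(6 + 45 * (k - 1) + 1):(6 + 45 * k)],
               oracle_cumulative(F, 1, w$start[k], w$end[k]))

  ga <- global_features(parse_peptide("*SAMPLER", 2), reduced = TRUE)
  expect_equal(ga[2:6], c(2, 1, 0, 0, 1))
  # identical length for all peptides under one layout
  expect_length(global_features(parse_peptide("K", 4)), 1626)
})

test_that("encoding manifest names every channel", {
  man <- encoding_manifest()
  expect_length(man$spatial, 323)
  expect_length(man$global, 1626)
  expect_length(encoding_manifest(reduced = TRUE)$global, 6)
  expect_identical(man$spatial[323], "charge")
})
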