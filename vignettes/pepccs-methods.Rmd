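---
title: "Predicting peptide collision cross sections with pepccs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting peptide collision cross sections with pepccs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In bottom-up proteomics, peptide identifications from tandem mass spectra can
be corroborated by orthogonal observables. Ion mobility spectrometry (IMS)
adds one: the collision cross section (CCS, in Å²), the effective area that
governs how often a peptide ion collides with the buffer gas. If CCS can be
predicted accurately from sequence and charge state, observed values can be
compared against predictions to reject wrong candidate peptides. pepccs
implements such a predictor: a comprehensive sequence featurization feeding a
two-branch convolutional + dense neural network, the standard accuracy
measures used in this field, ensemble averaging, and conversion of CCS to
instrument drift times for cross-instrument comparison.

Everything runs on synthetic data generated by the package itself, so the
entire pipeline is testable without downloads or a GPU.

## Featurization

Each residue is described by 45 features: a one-hot identity over a 21-symbol
alphabet (the 20 standard amino acids plus an internal symbol `m` for
methionine sulfoxide, i.e. oxidized Met), the residue's elemental composition
(H, C, N, O, S), ten binary side-chain class flags, two dyad flags for
\{N, D\} and \{E, Q\}, six float descriptors, and a padding indicator that is
1 only for the padding symbol. We write `F(i, j)` for feature `i` (0–44) of
residue `j`.

Three cumulative operators summarize a window of positions
`[j_start, j_end]`:

* `C1 = sum(F) / 100` — the division keeps input magnitudes manageable;
* `C2 = sum(F) / total(F)` — the window's share of the whole sequence,
  defined as 0 when the feature is absent from the whole peptide (zero
  carries exactly the "absent" meaning, and it keeps the encoding total);
* `C3 = sum(F) / window length` — the window mean. The printed form of this
  denominator in the source material is negative for real windows
  (`j_start − j_end + 1`); the window length is the only reading that yields
  a well-defined average, and that is what is implemented.

The convolutional branch consumes a fixed-length `L × 323` spatial encoding:
an amino-acid indicator; N-terminus, acetylated-N-terminus and C-terminus
flags; seven 45-wide blocks (`F`, the three cumulative operators over the
prefix `[0, j]`, and the three over the suffix `[j, n−1]`); relative position
`j/(n−1)` (defined as 0 for a single residue); raw residue distances from
both termini; and the charge state. The charge channel is replicated across
every position, padding included, so convolution kernels see it everywhere.
Distances are left unscaled: the /100 scaling belongs to `C1` only. Padding
rows carry the dedicated padding feature, not zeros, in the `F` block.
`L` defaults to 96 — more than 40 positions beyond the longest peptide the
published training data contain — and is configurable; the encoding of a
peptide does not depend on `L` beyond additional padding rows.

The dense branch consumes a global feature vector: peptide length, integer
charge, one-hot charge over \{2, 3, 4\}, an acetylation flag, and the `C1`
45-vector of every window of a multi-scale subsequence layout. The default
layout uses fixed-length windows of 5, 10 and 20 residues anchored at each
terminus (clamped for short peptides) and tilings of the peptide into 2, 4,
8 and 16 consecutive pieces — 36 windows, hence a global vector of
6 + 45 × 36 = 1626 features. The original figure describing the layout is
not machine-readable; terminal anchoring was chosen because terminal
residues are known to affect CCS disproportionately, and the layout is fully
configurable through `subsequence_layout()`. Fractional borders are placed
at `round(k·n/tiles)` (round half up) and repaired left-to-right so every
window keeps at least one residue; for peptides at least as long as the tile
count each tiling is an exact disjoint cover.

Two featurization choices deserve explicit flags:

* The printed non-polar class lists valine twice; the shipped table reads
  the duplicate as tryptophan (chemically consistent), and the class table
  is a plain-text file the user can replace.
* The six float descriptors are cited but not printed in the source
  material. The shipped defaults are well-known published scales
  (Kyte–Doolittle hydropathy shifted by +4.5, Zamyatnin residue volume,
  Grantham polarity, isoelectric point, Chou–Fasman helix propensity,
  Zimmerman bulkiness), with oxidized Met inheriting Met's values. They are
  a documented stand-in and are user-replaceable via
  `residue_chemistry(path)`. Descriptors must be non-negative: `C2` divides
  a window sum by the full-sequence sum, and a signed scale can cancel that
  denominator arbitrarily close to zero, making the feature unbounded for
  perfectly ordinary sequences. The shift removes the pathology without
  changing the scale's ordering.

## The network

The full variant has two branches. The convolutional branch applies six
valid 1D convolutions (kernel 6, stride 1) to the spatial encoding — 150
output channels each except the last with 50 — with a subsampling layer
(kernel and stride 2) between the third and fourth convolutions, then
flattens. The dense branch applies two 250-node layers to the global vector.
The branches are concatenated and followed by a 600-node layer and a single
linear output node; every hidden activation is ReLU and weights use He
initialization. The reduced variant drops the windowed features and the
dense branch entirely: the six global scalars are concatenated directly to
the flatten output.

Training uses Adam (learning rate 0.0003), batch size 256, mean absolute
error loss, and targets divided by 1000 (predictions are multiplied back).
Validation runs every 1000 iterations and at each epoch end; the model
returned is the checkpoint with the lowest recorded validation MAE, exactly
as recorded (argmin contract). The seed drives weight initialization,
shuffling and batch order, making runs bit-reproducible.

Design choices where the description was open:

* **Subsampling type** is unspecified; max-pooling is implemented as the
  default (the dominant convention) with average-pooling as an option.
* **Convolution boundary handling** is unspecified; valid (no zero-padding)
  convolution is used because padded positions already carry an explicit
  padding feature, and the choice is exposed in the configuration.
* **No learning-rate schedule, weight decay or dropout** — none are part of
  the stated protocol.
* **Static input scaling.** The protocol says nothing about input
  normalization, and the feature definitions put channels on wildly
  different scales (binary flags next to residue volumes near 230 Å³ and
  window sums near 100). With plain He initialization, which assumes
  roughly unit-variance inputs, this mis-scaling conditions CPU-scale
  optimization very poorly. The network therefore divides every input channel by a
  fixed constant derived from the chemistry table and the encoding length
  alone (for example, each `F` channel by its maximum absolute value over
  the 21 symbols, distance channels by the longest encodable peptide). The
  constants are part of the model configuration — never estimated from
  data — so encodings remain exactly as specified and predictions remain
  deterministic. This is an implementation-level conditioning device in the
  same spirit as the /100 and /1000 scalings of the original protocol.
* The engine itself (im2col convolutions over BLAS matrix products,
  backpropagation, Adam) is implemented in the package: no deep-learning
  framework is assumed anywhere.

Ensembling averages the predictions of several networks of the same
architecture trained from different seeds; `ccs_ensemble()` enforces
identical encoding configurations across members and an ensemble of one is
exactly its member.

## Evaluation and drift-time conversion

`evaluate_ccs()` reports RMSE, MAE (Å²), mean and median absolute percentage
error (MPE, MdPE), the 90th percentile of absolute percentage errors (Δ90),
`R² = 1 − SSres/SStot` and Pearson's r. Percentage errors are magnitudes;
signed variants are out of scope. Δ90 uses linear interpolation between
order statistics (quantile type 7), fixed and documented. Reports can be
stratified by charge state or by the standard CCS ranges 0–400, 400–800,
800–1200 Å².

Drift times relate to CCS through a Mason–Schamp-type relation
`t_d = A·Ω·sqrt(μ)/z + B`, with `μ = mM/(M+m)` the reduced mass of the ion
(mass `M`) and buffer gas molecule (mass `m`, nitrogen 28.006 Da by
default). The printed form of this equation omits the square root; because
`A` and `B` are refitted per instrument either way, the square-root form is
the default (it is the physically expected proportionality) and the literal
linear-μ form is available behind a flag. `fit_drift_calibration()` recovers
`A` and `B` by ordinary least squares of reference drift times on
`Ω·sqrt(μ)/z`, and `drift_report_by_charge()` reports per-charge R² and MSE
under a single global calibration.

## The synthetic world

The generator emulates the published data's composition: tryptic-like
peptides (lengths 7–45, C-terminal K/R with probability 0.9, internal K/R
strongly down-weighted as missed cleavages are rare), natural-ish amino-acid
frequencies, Met oxidation at 0.1 per Met, N-terminal acetylation at 0.05,
and length-dependent charge states (short peptides mostly 2+, long ones
increasingly 3+/4+). Labels come from a known ground-truth function: a
per-charge intercept plus a per-charge slope on `mass^(2/3)` (globular-ion
surface scaling), additive per-residue offsets derived from residue volume,
a positional term that shifts CCS linearly with the relative position of
proline and histidine, and Gaussian noise (σ = 5 Å² by default). The
defaults put CCS in the plausible 250–1100 Å² range. This ground truth is a
physically motivated stand-in — deliberately learnable at desk scale — and
**not** the published model; a green test establishes that the pipeline can
recover a known sequence- and position-dependent signal, not that it
reproduces published accuracies. Real peptide data differ in ways the
generator does not emulate: instrument noise structure, conformer
multiplicity, modification biases, and the long tail of unusual sequences.
Data sets are deduplicated by modified sequence + charge and split 85/5/10
with no peptide in more than one split.

## Scaled-down verification runs

The learning-behaviour checks in the test suite (overfit sanity, beating a
charge-stratified mean baseline, full-versus-reduced feature ablation) are
specified for a GPU-class training budget. On a single CPU this package runs
them scaled down — shorter peptides (7–16 residues, so `L = 57`), a few
thousand training records, batch size 32 and bounded iteration counts —
chosen once from arithmetic on the compute budget. The acceptance thresholds
themselves (training MAE below 5 Å², at least 50 % improvement over the
baseline, full ≤ reduced) are unchanged. The same applies to
`scripts/acceptance.R`, which runs the full pipeline end to end at a reduced
size.

## Known limitations

* Charge states outside \{2, 3, 4\} are rejected, mirroring the training
  data's filtering, and only N-terminal acetylation and Met oxidation are
  supported as modifications.
* The shipped descriptor scales are a stand-in (see above).
* Training at the published scale (~450k records, tens of thousands of
  iterations) is out of desk-scale reach; the package makes no claims about
  reproducing published benchmark accuracies.
* The drift-time module refits `A` and `B`; it does not compute CCS from
  first-principles instrument parameters.
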