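---
title: "deepMRE: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deepMRE: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MicroRNAs (miRNAs) repress messenger RNAs by guiding Argonaute to short
target sites — miRNA response elements (MREs) — mostly in 3' UTRs but also
in coding sequence. Canonical sites pair the miRNA *seed* (positions 2–7 or
2–8, optionally with an adenosine opposite position 1), but a substantial
fraction of functional binding is non-canonical: centered sites with ~11
contiguous central pairs, and 3' compensatory sites where an imperfect seed
is rescued by pairing to miRNA positions ~13–17. deepMRE predicts both the
location of such sites and, per (miRNA, gene) pair, whether the interaction
is functional.

## The two-layer model

**Layer 1 (site level).** An exact enumerative scanner proposes candidate
sites of seven categories (6mer, 7mer-A1, 7mer-m8, 8mer, 9mer, centered,
compensatory), with a fixed precedence so each locus carries exactly one
category. Each candidate is framed in a 30-nt window (the target base
opposite miRNA position 1 at window offset 22) with 60-nt flanks, and
encoded as five channels:

1. the 150-nt extended MRE sequence (one-hot, 4 channels, N = all-zero);
2. the 53-nt miRNA–MRE chimera (23-nt right-padded miRNA + 30-nt window);
3. the miRNA–window duplex structure, dot-bracket serialized as
   `structure(miRNA) & structure(window)` padded to 60 symbols, plus its
   free energy;
4. the MFE fold of the 150-nt context (dot-bracket, 3 channels);
5. per-base conservation in [0,1] over the 150-nt frame.

Each channel feeds a dedicated convolutional branch (filters 35/50 with
strides 2/3 for the sequence branch; 16/32/62 with strides 2/3/4 for the
chimera and duplex branches; 35/50 with strides 4/5 for the fold branch;
20/40/60 with strides 3/4/5 for conservation; max-pool width 2 after each
convolution, no padding), then a 24-unit GRU with dropout 0.1. Branch
outputs are flattened, concatenated, and passed through dense layers of
90/55/35 units (leaky ReLU, batch normalization, dropout 0.1) to a sigmoid
MRE score. Separate models are trained for the 3' UTR and the CDS.

**Layer 2 (gene level).** Per (miRNA, gene) interaction the maximum MRE
score is taken separately for the 3' UTR and CDS (0 when a region has no
site); a gradient-boosted tree ensemble over these two features yields the
interaction probability, evaluated by stratified 5-fold cross-validation.
For meta-learner training, sites in positive interactions are retained only
with first-layer score > 0.5 and negative ones only < 0.5 (a score of
exactly 0.5 is dropped from both sets).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| learning rate | 1e-4 | Adam step size for layer 1 |
| epochs / patience | 200 / 15 | early stopping on validation loss |
| batch size | 64 | minibatch size (batches of 1 are skipped: batch norm) |
| dropout | 0.1 | GRU and dense-head regularization |
| GBM trees / depth / shrinkage | 200 / 3 / 0.1 | layer-2 ensemble |
| retention threshold | 0.5 | strict >/< retention for meta training |
| decision threshold | 0.5 | default call threshold, both layers |

Youden-index thresholds are reported by the evaluation module alongside the
0.5 default; dataset-specific optima are deliberately not hard-coded.

## Design choices where the design was open

- **Kernel widths.** The reference design fixes filter *counts*,
  strides and the pool width, but not kernel widths ("filter sizes of 16,
  32, and 62" must be counts — a width-62 kernel cannot slide over a
  53-symbol input). A single default width per branch cannot work either:
  with pooling after every convolution, the three-conv branches reach
  length 1–2 by the third layer, so any fixed width ≥ 3 is unbuildable.
  Defaults are therefore per layer — (9,9) for the two 150-input conv
  pairs, (6,3,2) for chimera/duplex, (9,5,2) for conservation — and
  max-pooling is skipped when the incoming length is shorter than the pool
  window. All are configurable via `branch_spec()`, and the layer-length
  arithmetic is asserted against the closed forms
  `L' = floor((L - k)/s) + 1` and `floor(L/2)` in the tests.
- **Optimizer and loss** are unstated upstream: Adam with binary
  cross-entropy, the standard pairing for a sigmoid output.
- **Batch normalization** is applied after every convolution and dense
  layer, before the activation.
- **Validation split** for early stopping: 10% stratified, seeded.
- **Window anchor.** Only the 30/60/60 lengths are fixed upstream; the
  anchor (A1-opposite base at offset 22) leaves 22 nt upstream for the full
  3'-supplementary pairing span of a 23-nt miRNA and 7 nt downstream.
- **Duplex serialization.** Whether the 60-symbol duplex string includes a
  separator is unstated; this package writes
  `miRNA-structure & 30-frame-target-structure` right-padded with `-`
  (all-zero one-hot), which always fits: 23 + 1 + 30 ≤ 60.
- **Folding engine.** No thermodynamic folding library is available in the
  supported environment, so the package ships a compact nearest-neighbor
  engine (Rcpp): duplex-only co-folding with bounded bulges for the hybrid
  channel, and a simplified Zuker recursion (stacking + hairpin + bounded
  interior loops, lightly penalized bifurcation) for the 150-nt context.
  Its energies approximate the Turner parameters; it is *not* a Vienna
  re-implementation, and its contracts are structural: determinism,
  balanced brackets, non-positive duplex MFE whenever pairs are reported,
  no pairs reported when no favorable duplex exists. N is folded as A
  (engines reject N) while encoded sequences keep N.
- **Conservation** is used raw (clipped to [0,1]), missing data scored 0
  (phastCons gaps are typically unalignable, i.e. unconserved regions).
  Flanks and windows never cross the annotated region boundary, keeping the
  two region models strictly region-specific.
- **Negative "no response" band.** Perturbation-based negatives require
  |log2FC| < 0.1 and no retained AGO peak; background-peak negatives are
  taken as-is. Positive/negative (miRNA, gene) pairs are mutually
  exclusive, positives winning.
- **Wilcoxon implementation.** Exact enumeration when both groups have ≤ 8
  observations without ties (where the test suite checks it against an
  independent enumeration oracle), normal approximation with tie
  correction otherwise. The AUC bootstrap (2000 seeded replicates) is this
  package's choice of CI method.

## What the synthetic generator emulates — and what it does not

`generate_mre_dataset()` builds a fully self-contained training world:
random transcripts (300–1500 nt, GC 0.5, CDS = first 60%), planted sites
whose category mix is dominated by canonical seeds (30% 8mer, 25% 7mer-m8,
15% 7mer-A1, 10% 6mer, 5% 9mer, 7.5% centered, 7.5% compensatory), and
per-base conservation drawn at mean 0.7 (SD 0.15, clipped) over planted
windows versus 0.3 elsewhere. Positive-class signal is thus carried by both
sequence and conservation; duplex and fold channels are computed by the
real feature pipeline, not simulated. Negatives are random loci verified
site-free by the scanner. The conservation means were chosen once for
desk-scale learnability and are configurable.

What this does **not** emulate: CLIP read pileups and crosslinking biases,
sequencing noise, expression-dependent site availability, isoform
complexity, codon constraints inside CDS, or realistic genome-scale
conservation autocorrelation. A green recovery test therefore establishes
that the implementation can learn the planted signal end-to-end with this
architecture — not that it attains any particular accuracy on biological
data, which would require a real training corpus and genome-wide
conservation tracks.

`generate_interaction_dataset()` draws per-region maxima from Beta(5,2)
(positives) versus Beta(2,5) (negatives); the meta-learner's
cross-validated AUC is checked against a Monte-Carlo estimate of the
Bayes-optimal AUC for that mixture.

## Numerical notes and degenerate inputs

- One-hot padding rows are all-zero, so padding contributes nothing to
  convolutions; conservation padding is 0.
- Training aborts with a diagnostic on NaN loss; single-class labels are
  rejected up front.
- Scoring uses running batch-norm statistics, so results are batch-size
  invariant (tested to 1e-5) and byte-stable across repeated calls.
- Ties in the Youden search resolve to the smallest optimal score; a
  non-positive maximal J triggers a warning.
- miRNAs shorter than 17 nt are rejected by the scanner; longer than 23 nt
  are rejected by the chimera builder rather than silently truncated.
- All coordinates are 0-based half-open throughout; FASTA ingest uppercases,
  maps T to U and anything else to N, and rejects duplicate ids.

## Known limitations

- The folding engine's absolute energies are approximate; downstream use
  is as a *feature*, trained on, not as a thermodynamic reference.
- The pure-R network engine is designed for desk-scale corpora (10^3–10^5
  sites); a corpus of ~10^5 sites trains in minutes-to-hours,
  not seconds.
- Bit-exact reproducibility is promised for a fixed seed on one platform
  and BLAS; cross-platform agreement is threshold-based, not bitwise.
- GFF3 exon stitching and genome alignment are out of scope; conservation
  can be supplied genome-anchored (bigWig + chrom map) or per-transcript.
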