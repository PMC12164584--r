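---
title: "Predicting chromatin features from sequence and prioritizing noncoding variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chromatin features from sequence and prioritizing noncoding variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most disease-associated variants from GWAS and eQTL studies fall in
noncoding DNA, where their effect — if any — is regulatory: they change
chromatin accessibility, histone-modification state or transcription-factor
(TF) binding in particular cell types. `chromattn` addresses this in three
stages:

1. **Dataset construction.** Epigenomic peak calls (ENCODE-style narrowPeak)
   are converted to a multi-label dataset over 200-bp genomic bins. A bin is
   positive for a track when the track's merged peaks cover *strictly more
   than half* of the bin (overlap > 100 bp). Bins overlapping a
   low-mappability blacklist by even 1 bp are removed. Whole chromosomes are
   held out for validation and testing so that performance estimates are not
   inflated by positional proximity between train and test windows.
2. **Sequence model.** A network maps the 2000-bp window around each bin
   (the bin plus 1800 bp of flank) to per-track probabilities.
3. **Variant prioritization.** For a single-nucleotide variant, the model
   predicts label probabilities for the reference window and for the same
   window with the alternate allele substituted; the per-label SNP activity
   difference is `SAD = |P_ref - P_alt|`. Significance is calibrated
   empirically against a pool of non-regulatory control variants.

## The model

Each nucleotide is encoded as a small integer (A=1, C=2, G=3, T=4, N=0; only
the N→0 assignment is semantically meaningful, since the mask is derived
from it). The network is:

* **Embedding + masked positional encoding.** Each code indexes a learned
  embedding row; sinusoidal positional encodings
  `PE(p, 2i) = sin(p / 10000^(2i/dim))`, `PE(p, 2i+1) = cos(·)` are added,
  scaled by the N-mask so unknown bases receive no positional term.
* **Two convolution/pooling blocks.** Valid 1-D convolutions (kernel 10,
  stride 1, ReLU) with 64 then 32 filters; max pooling of size 3, stride 3
  after each. Kernel width 10 matches typical TF binding sites (6–20 bp).
* **Multi-head self-attention.** Q, K, V are affine projections of the
  pooled feature map, split into heads; each head applies
  `softmax(QK'/sqrt(d_k))V`; heads are concatenated. Attention lets distal
  sequence context influence each position.
* **Head.** A position-wise dense layer to one unit, a squeeze of the
  channel axis, then a dense layer to `n_targets` with sigmoid outputs —
  independent per-label probabilities (multi-label, not softmax).

With the default geometry the position axis evolves as
2000 → 1991 (conv) → 664 (pool) → 655 (conv) → 219 (pool). Pooled length is
`ceiling(n/stride)`; a trailing partial window takes the max over the
remaining elements. The alternative valid-window count
(`floor((n - pool)/stride) + 1`, giving 663) is available behind
`ceil_pool = FALSE`; the ceiling form is the default because it is the one
consistent with the output-shape bookkeeping above.

Training minimizes mean per-label binary cross-entropy with Adam
(default learning rate 1e-3); batches are reshuffled each epoch under the
run seed, and runs are bit-for-bit reproducible given that seed. Evaluation
reports per-label AUROC (rank-based, ties counted half) and PR-AUC
(average precision over distinct score thresholds), plus the baseline
PR-AUC of a no-skill classifier, which equals the positive-class prevalence
`p = N+/(N+ + N-)` exactly. Labels with a single class in the evaluated set
are reported as `NA` and excluded from assay-class means.

## Open design points and how they were fixed

The architecture leaves several details unstated; the package's choices are:

* **ACGT codes**: A=1, C=2, G=3, T=4 (fixed constant; only N→0 matters).
* **Attention geometry**: 8 heads over 32 channels (`d_k = 4`), 2 layers at
  full scale; both configurable.
* **Residual connections / normalization**: off by default
  (`attn_residual` flag); no layer norm, no dropout inside attention.
* **Head**: position-wise dense(1) → squeeze → dense(`n_targets`); an
  optional hidden layer (`head_hidden_units`) is available but off by
  default.
* **Strand**: predictions are on the plus strand only; no
  reverse-complement averaging.
* **Windows past chromosome ends** are padded with N (masked), so edge bins
  remain usable.
* **Coordinates** are 0-based half-open internally; 1-based only at the VCF
  boundary.
* **Indels** are rejected: only single-nucleotide substitutions are modeled.

## Variant scoring and empirical E-values

`sad_scores()` extracts the 2000-bp window centered on the 200-bp grid bin
*harboring* the variant (the window is centered on the bin, not on the
variant), verifies the reference allele against the genome — a mismatch is
an explicit per-variant error, catching build/liftover mix-ups — and scores
every label. Variants at conversion-unstable positions (coordinates that
lift over inconsistently between builds) can be excluded with a plain
interval filter.

The empirical E-value of a (variant, label) pair is the fraction of
negative-control variants whose SAD for the same label strictly exceeds the
variant's SAD ("higher" is read strictly: ties do not count against the
variant). The negative pool is built by exclusion filtering (GWAS/eQTL
rsIDs, exonic intervals, candidate cis-regulatory elements). Resamples are
drawn without replacement; 10 resamples are averaged, using seeds
`seed, seed+1, ..., seed+9` per variant for auditability, and each variant
redraws its own resamples under one master seed. The per-pair flag is
`E <= 1e-5` (inclusive), and a variant is significant when at least one
label is flagged.

One structural caveat the package surfaces rather than hides: with
resample size equal to the number of positive variants, the smallest
attainable nonzero E-value is `1/resample_size`. Whenever that resolution
limit exceeds 1e-5 (e.g. resample size 7663 gives ≈1.3e-4), only exact
zeros — variants whose SAD exceeds *every* sampled control — can be called
significant. The report records `1/resample_size` as `resolution` so users
can interpret calls at their pool size.

## The synthetic universe

`synthetic_spec()` defines a fully self-contained test world: 3 chromosomes
of 300 kb with i.i.d. uniform base composition, two distinct 10-bp consensus
motifs planted at 150 non-overlapping positions per chromosome each, one
peak track per motif (peaks are ±150 bp around each occurrence), 50
motif-disrupting variants (a consensus base inside an occurrence is
substituted) and 50 background variants (≥ 1 kb from every occurrence;
reference alleles always match the genome). Two motifs — rather than one —
are used so the two tracks carry distinct labels and per-track
discrimination is measurable; with a single motif both tracks would be
identical. Binning the three chromosomes yields the full 4500-bin grid
(3 × 300 kb / 200 bp); the desk-scale experiment keeps all grid bins
(`keep_all_bins = TRUE`), so each track has ≈ 14% positive bins and the
learning task is motif presence near the bin against genomic background.

What the generator does *not* emulate: realistic peak-width and signal
distributions, GC composition and repeats, nucleosome structure,
reverse-strand motifs, overlapping/correlated tracks, and the sheer scale
of production corpora (hundreds of tracks, millions of bins). Passing the
desk-scale experiment therefore demonstrates that the pipeline's mechanics
— binning, labeling, training, evaluation, mutagenesis, calibration — are
correct and that the model can learn sequence determinants end-to-end; it
does not certify performance on real epigenomes.

## Desk-scale problem sizes and optimization choices

The experiment behind `run_synthetic_experiment()` trains on ~1500 bins
(one chromosome; the other two are held out), a factor of ~6000 fewer
examples than a production run. Three consequences shaped the defaults of
`compact_model_config()` / `compact_train_config()`:

* **Window 400 bp, embedding 16, filters 32/16, one 4-head residual
  attention layer.** The label rule is decided by sequence within ~125 bp
  of the bin center, so the 400-bp window (bin + 100-bp flanks) contains
  the decisive motif for every bin while cutting the decoy motifs that the
  1800-bp flanks would add. At this sample size the full-width model
  memorizes its training windows instead of generalizing; the compact
  configuration is the same architecture at smaller problem size.
* **Orthogonal embedding initialization.** The four base embeddings start
  mutually orthogonal, scaled to the positional-encoding amplitude, with N
  at the origin. Bases are categorical; starting orthogonal encodes exactly
  the "no assumed similarity" premise and makes sequence identity visible
  next to the ±1 positional terms from the first step.
* **k-mer-seeded first-layer filters.** On small data, gradient descent
  struggles to discover position-invariant motif detectors: the gradient
  reaching a first-layer filter is multiplied by position-specific
  downstream weights whose signs vary with where a motif lands, so detector
  gradients largely cancel. `seed_conv_filters()` initializes half of the
  first conv bank as matched filters for the k-mers most enriched in
  positive vs negative training windows (central bin region, training split
  only — no ground-truth leak), with a negative bias that silences chance
  partial matches. This mirrors the established practice of initializing
  genomic CNNs with motif detectors. The remaining filters stay random and
  trainable; `conv_init = "random"` disables seeding.
* **Regularization.** Decoupled weight decay (1e-4) and dropout (0.2) on
  the squeezed position vector hold memorization in check; both default to
  0 in `train_config()`.

With these defaults the experiment reaches held-out-chromosome mean AUROC
above 0.9 within 8 epochs in about half a minute on one CPU, across seeds.
All of the above are initialization/regularization choices; the forward
model remains exactly the architecture described earlier.

## Numerical notes

* Gradients for every layer are verified against central finite differences
  in the test suite (relative error ≤ 1e-4 at step 1e-5).
* Softmax rows are computed with max-subtraction; BCE clamps probabilities
  at 1e-12 for loss reporting while the gradient uses the exact
  `p - y` form.
* The resample shuffle uses a fixed Fisher–Yates implementation so training
  is reproducible across platforms, not just across runs.
* Max-pool backpropagation routes gradients to the arg-max element; ReLU
  gates are taken from the stored activations.
* `average_precision()` evaluates precision at distinct score thresholds
  only, which makes the constant-score predictor's AP equal prevalence
  exactly rather than approximately.

## Known limitations

* CPU-only, single-threaded aside from BLAS; production-scale corpora
  (10^6+ bins, hundreds of tracks) are out of reach of the training loop.
* Plus-strand only; no reverse-complement augmentation or averaging.
* Only SNVs are scored; indels and multi-nucleotide variants are rejected.
* The mappability filter is a user-supplied blacklist; no mappability
  scores are computed.
* Liftover itself is out of scope: variant coordinates are assumed to be on
  the model's build, with conversion-unstable positions removable via an
  interval filter.
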