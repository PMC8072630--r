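---
title: "Detecting a targeted exon-skipping event with small neural networks"
author: "skipnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a targeted exon-skipping event with small neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(skipnet)
```

## The problem and the modelling idea

MET exon 14 skipping (METΔ14) removes the receptor's juxtamembrane
regulatory exon and is a druggable driver event in non-small cell lung
cancer, expected in only a few percent of samples. Generic splice-site
predictors work from nucleotide sequence; here the question is narrower
and the data different: given the *expression* evidence — the reads a
sample places on one locus — does this sample carry one specific skipping
event?

`skipnet` treats the question as supervised classification of **read
groups**. A sample's locus reads are partitioned into random,
non-overlapping groups of exactly *n* reads; each group is summarised as a
fixed-length numeric vector; a small network scores each vector. Grouping
converts a handful of labelled samples into thousands of training
examples (a cell line with 1.45 million locus reads yields 1447 groups of
1000) and fixes the input scale the networks see, at the price of a
within-sample independence assumption: groups from one sample share its
biology, so group-level accuracy is measured on held-out *groups* of
held-out conditions, and sample-level screening aggregates group calls.

### Feature representations

Four representations are computed over an exon scope $S$ (default
13–15, the skipped exon and flanks):

* **k-mer counts**: a vocabulary is built by sliding a $k$-window over the
  spliced reference sequence of $S$; every read window matching a
  vocabulary k-mer in either orientation credits that slot once (forward
  match preferred, so a window never credits two slots). Matching is
  alignment-free, which keeps the representation usable straight from
  FASTQ. By default the vocabulary is extended with the novel
  exon13–exon15 junction k-mers created by excising exon 14; without
  them, skipping is visible in k-mer space only as the *absence* of
  exon-14 k-mers. The flag `include_skip_junction` reproduces either
  convention.
* **k-mer count frequency**: the counts normalised to sum to one, removing
  depth as a nuisance dimension.
* **coverage**: per-base depth over the concatenated scope exons in
  transcript order, from alignment blocks (match-level positions;
  soft-clips excluded).
* **coverage frequency**: coverage normalised to sum to one. The Δ14
  signature is then an exactly-zero exon-14 block against elevated
  flanking blocks.

Defaults: $k = 16$ (31 supported; the shorter k-mer tolerates
substitution errors better at these read lengths), scope `13:15`,
group sizes 1000 for training and {500, 1000, 5000} for test-depth
sweeps — below roughly 5000 locus reads per *sample* the exon-14 gap
blurs, which motivates the 5000-read sample inclusion filter
(`passes_min_reads`).

### Architectures

* **Dense classifier** (`dense_net_spec`): input → 256 → 256 → 128 →
  128 → 1, ReLU on hidden layers, dropout 0.1 after each activation
  (applied after activation; placement before activation is equivalent
  for ReLU up to scaling), sigmoid output.
* **1-D convolutional classifier** (`conv_net_spec`): one convolution of
  64 filters with kernel size from {2, 5, 7, 10, 15, 50, 75, 100, 150,
  200}, ReLU, max-pooling of width 2, a 50-unit ReLU layer, sigmoid
  output. The kernel size is the interesting hyperparameter: kernels of
  ~100 positions span an exon-sized window of the frequency vector.
* **Sparsely connected autoencoder** (`sca_spec`): encoder
  input → one latent node per exon, with a binary mask admitting only
  connections from a feature to the exon(s) it belongs to
  (`build_connectivity_mask`; junction-spanning k-mers connect to both
  flanking exons), ReLU latent, mirrored (transposed-mask) linear
  decoder, mean-squared reconstruction loss. The latent space is
  therefore *interpretable by construction*: each coordinate is "how much
  of this exon's signal this group carries".

Training is Adam with lr 0.01, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$, no decay, on mean-squared error — kept for the
binary classifiers as the historical configuration of these models;
binary cross-entropy is available via `optimizer_config(loss =
"binary_crossentropy")`. Epochs (50), batch size (32), validation
fraction (0.2) and early-stopping patience (10) are not dictated by the
problem; they are fast, standard values at this model size, and every run
records its per-epoch history. The decision threshold is 0.5 with strict
inequality (a score of exactly 0.5 reads as wild type); it is exposed as
configuration. All randomness — initialisation, dropout, shuffling —
derives from one seed, so training is bitwise reproducible.

Sparsity in the SCA is enforced *hard*: the mask is re-applied
(element-wise multiply) after every optimizer step, so masked weights are
exactly zero at any point of training regardless of the optimizer's
moment estimates.

Hyperparameter search (`grid_search`) is a plain exhaustive Cartesian
sweep ranked by validation loss — at these grid sizes (tens of
configurations) nothing smarter is warranted, and the full table is
returned rather than only the winner.

## The synthetic data generator

The simulator (`simulate_reads`) emulates the data regimes the method was
designed around: paired-end 2 × 150 sequencing of

* the **wild-type** spliced transcript,
* the **Δ14** transcript (`skipped_transcript`), and
* a **chimera** — a fusion-style transcript assembled from a LINE1-like 5′
  segment, the intron-2 window chr7:116,715,690–116,717,329, exon 6 and
  the last exon. This models the observed *transcriptional* signature of
  LINE1–MET fusions (an intron-2 coverage peak with exon-6/last-exon
  accumulation and half-mapped mates matching LINE-1), not the genomic
  rearrangement; the breakpoint is a parameter (`intron_window`) because
  real fusion points vary across intronic positions and the last exon.

Fragments start uniformly along the transcript with normal length
(mean 350, sd 50 — a typical RNA library); errors are independent per-base
substitutions at rate 0.001 (NovaSeq-like; the k-mer features are the
error-sensitive consumers and 16-mers at this rate lose ~1.6% of windows).
Reads carry their true genomic alignment through a transcript-to-genome
map, spliced across exon junctions, so "alignment" downstream is exact by
construction.

What the simulator does **not** model — and what passing synthetic tests
therefore cannot show — includes positional/GC coverage bias, indels and
homopolymer artefacts, intronic background reads from unspliced pre-mRNA,
multi-isoform mixtures of the untargeted kind, and alignment errors
(real BAMs bring mismapping the truth alignments cannot have). Synthetic
AUCs near 1 say the features separate the classes and the optimisation
works, not that cohort-level specificity will be that clean.

The reference itself is synthetic: the 21-exon MET-like model
(`synthetic_met_gene_model`) reproduces the published locus bounds
(chr7:116,672,196–116,798,377, hg38), a 141-nt exon 14 and an intron 2
containing the chimera peak window over seeded random sequence, because
the actual exon table is not reproducible offline. Every operation takes
the gene model as an argument, so a real annotation + genome FASTA swaps
in directly (`load_gene_model`, including `samtools faidx`-style region
slices).

## Evaluation and discovery conventions

* **Confusion arithmetic**: sensitivity is $100 \cdot TP/P$; specificity
  defaults to the cohort-screening form $100 \cdot (N - FP)/N$ (fraction
  of the screened set not falsely flagged), with the classical
  $TN/(TN+FP)$ available as `specificity_classical_pct`; the two agree
  when the cohort holds no true events. Percentages are **truncated**
  (floored) at the reported precision, the convention under which the
  published values of this kind (52.9, 94.11, 99.8) are all consistent —
  rounding would give 94.12/99.9.
* **ROC** is an explicit threshold sweep with trapezoid AUC; tests pin it
  to the Mann–Whitney identity and to an independent implementation.
* **Clustering stability**: each clustering run fits k-means (5 restarts)
  on a random 80% subsample for every candidate k, keeps the best mean
  silhouette, and extends to all samples by nearest centroid; stability
  is the mean best-match Jaccard over random pairs of runs, per cluster
  and overall. Subsampling supplies the run-to-run perturbation:
  structure supported by the data survives it (3 well-separated blobs
  score ~1), arbitrary partitions of unstructured data do not (10-d
  uniform noise scores below 0.5). This is a deliberate, documented
  replacement for the original SOM-based clustering tool, preserving the
  shape of the procedure (repeated runs, thousands of pairwise
  comparisons) rather than its implementation.
* **Input normalisation for the SCA** is per-sample frequencies scaled to
  counts-per-10k, `log1p`, then per-feature z-score with zero-variance
  features set to zero — a documented, dependency-free stand-in for
  single-cell-style expression-recovery normalisation.
* **Repeat screen**: discordant mates match the repeat reference when
  they share an exact 31-mer in either orientation; the putative fusion
  point is the locus-anchored mate's alignment start. Exact seeds replace
  BLAST: deterministic, and at 31 bp a false seed hit is essentially
  impossible.

## Numerical and contract details

* Intervals are Bioconductor-convention 1-based closed (`GRanges`)
  throughout, including region strings; exon ordinals are transcript
  order (exon 1 = 5′ exon on either strand).
* Partition remainders are discarded, never padded — groups have exactly
  *n* reads, which the 1447/846 subgroup arithmetic depends on.
  Re-partitioning with another seed is allowed (augmentation) and shows
  up in group ids.
* Degenerate inputs: all-zero feature vectors stay zero through frequency
  normalisation (with a warning); groups with no alignments yield
  all-zero coverage (warning); single-class training labels, empty
  hyperparameter grids, undefined sensitivities ($P = 0$) and terminal-
  exon "skips" are errors, not silent results.
* Reads counted per primary alignment record; supplementary/secondary
  records excluded; locus membership is ≥ 1 base of alignment overlap
  (the most inclusive reading, matching what one counts by eye in a
  browser). Whether the 5000-read sample filter counts reads or records
  is ambiguous in general; primary records is the convention here.
* A read straddling a fusion breakpoint spans two contigs; its SAM record
  keeps the majority contig with the remainder soft-clipped, and the
  discordant-pair truth in tests uses the same majority rule.
* Model archives are JSON at full precision (`digits = NA`), so reloaded
  models predict identically to ~1e-15.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run, by choice, at: 100 + 100
groups of 1000 reads (50,000 simulated pairs per class) for the
classifier end-to-end checks with a 150/50 train/held-out split; 30 + 30
groups of 500 reads for the autoencoder separation check; 1.447M/0.846M
dummy-read pools for the subgroup-count arithmetic. These sizes reproduce
the study conditions the method targets while staying comfortable on a
single CPU.

## Known limitations

* One event, one gene, one skip at a time: no multi-exon or multi-gene
  models, no isoform quantification.
* The cohort-scale false-positive behaviour (the interesting part of any
  screen) can only be bounded from synthetic data; the chimera class is a
  stylised stand-in for what real cohorts produce.
* The SCA latent space separates classes in the mean-distance sense, but
  — consistent with the discovery-tool framing — its clusters are not
  guaranteed stable; the stability score exists precisely to measure
  that, and low scores on real-like data are an honest outcome.
* MSE on a sigmoid output saturates: a mislabelled or extreme-valued
  training example can park on the wrong side with vanishing gradient.
  Cross-entropy is offered for users who prefer the better-conditioned
  loss over configuration fidelity.
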