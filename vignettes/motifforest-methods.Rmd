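---
title: "Predicting transcription factor binding sites from sequence and DNA biophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting transcription factor binding sites from sequence and DNA biophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifforest)
```

## The problem and the model

Transcription factors (TFs) recognise short, degenerate DNA elements, and a
position weight matrix (PWM) over the primary sequence captures only part of
the recognition code. Protein–DNA specificity has two components: *direct
readout* (base-specific contacts between amino acids and the bases) and
*indirect readout* (sequence-dependent shape and deformability of the double
helix — how easily the site bends, how the base steps stack, how the duplex
melts). motifforest trains a classifier that sees both.

A candidate binding site is a window of `core_width + 2 * flank` bases: the
aligned core motif plus symmetric flanks (default 10 bp per side). Its
feature vector concatenates three blocks:

1. **Direct readout** — `4 * core_width` one-hot base indicators.
2. **Position dependencies** — for `k` selected pairs of core positions
   (default `k = 5`), the 16 ordered-dinucleotide indicators of the bases at
   those two positions. Pairs are chosen on the training alignment by
   mutual information (natural log, maximum-likelihood plug-in, no
   pseudocounts; ties broken by lexicographic pair order so the selection
   is deterministic). Within-motif base correlations of this kind are a
   signature of local three-dimensional structure.
3. **Indirect readout** — for each biophysical property scale, each region
   (core, left flank, right flank) and each aggregator (mean, min, max),
   one summary of the property profile over the region. A profile is the
   k-mer table slid along the region; the shipped registry covers
   trinucleotide DNase-I bendability, dinucleotide propeller twist,
   base-stacking energy, duplex free energy, trinucleotide nucleosome
   positioning preference, and a solvent-excluded-surface *stand-in* that
   is constructed, not published — its manifest entry and file name say so
   (`solvent_excluded_surface_synthetic.tsv`). All shipped tables are
   strand-symmetric: a k-mer and its reverse complement share a value.

The classifier is a random forest of 100 trees (bootstrap per tree,
`floor(sqrt(p))` candidate features per split). The score of a window is
the fraction of trees voting positive, so scores live on the exact grid
`{0, 1/100, ..., 1}`. Out-of-bag error is retained as a generalisation
estimate.

### The maximum-recall pre-filter

Scanning every window of a long sequence through the forest is wasteful.
The scanner therefore pre-screens windows with a *short* PWM: the
contiguous run of filter columns (default `min(8, core_width)`) maximising
total information content (relative entropy against the background
composition, in nats; ties broken leftmost). Its threshold is set a margin
(default 0.5 log-odds units) **below the minimum filter score of the
training positives**, so every training positive passes by construction —
the filter is built to lose nothing, only to discard the bulk of the
background cheaply. Filter mode is the default; switching it off scores
every window and, on data where the filter has full recall, returns the
same hits.

### Threshold calibration

Positives are split (seeded random split) into a training part — at most
100 windows, following the convention of training on 100 sites when more
are available — and a validation part. With fewer than ~140 positives a
70/30 split is used instead so that calibration always has held-out data.
The validation positives and fresh filter-passing background windows give a
precision/recall/F-measure curve over all observed score thresholds, from
which three named operating points are derived:

* **Max. Precision** — smallest threshold achieving the maximal precision
  among thresholds with at least one true positive (the TP ≥ 1 restriction
  removes the vacuous "precision 1 above every score" artifact);
* **Max. F-Measure** — smallest threshold achieving the maximal F;
* **Average** — the arithmetic mean of the two threshold *values* (the
  default operating point).

"Smallest on the plateau" makes ties deterministic and favours recall when
metrics are equal.

### Negative windows: matching the deployment distribution

In filter mode the classifier only ever sees windows that passed the PWM
pre-filter. Training and calibrating against uniformly drawn background
windows therefore misrepresents the negatives the model meets in practice:
windows that *resemble* the motif well enough to pass the filter. The
package consequently trains on a 50/50 mixture of uniform and
filter-passing ("hard") background windows and calibrates thresholds
against filter-passing windows only (at least 200, or four per validation
positive, so precision is resolved finely). The **null distribution** for
P-values is different by design: it is built from uniformly random
background windows (position and strand), because a hit's P-value should
answer "how often does arbitrary background score this high", not "how
often does a filter-passing window score this high". The P-value uses the
add-one estimator `p = (1 + #{null ≥ s}) / (1 + n)` with a default null of
n = 10,000 windows, so the smallest reportable value is `1/(n+1)` and
P-values never underflow to zero.

### Scanning and reporting

Both strands are always scanned. A candidate window is featurised in the
site's own 5'→3' orientation, which makes hit scores exactly
strand-mirror-symmetric: scanning the reverse complement of a sequence
yields the mirrored hit table with identical scores, regardless of the
scale set. Same-strand hits overlapping by more than half the core width
are resolved by keeping the highest score (ties: leftmost). Coordinates are
0-based half-open everywhere, including BED6 output (score column =
`round(1000 * classifier score)`).

## The synthetic-data generator

`fixture_config()` / `make_dataset()` generate the study conditions every
test runs under: i.i.d. background at a configurable GC content, one
implanted site per positive region at uniform position and strand, per-base
consensus mutation at a configurable rate, and aligned positives extracted
core+flank and re-oriented. Defaults emulate a well-characterised
ChIP-derived model: a 12-bp composite CRE/E-box-like consensus
(`TGACGTCACGTG`) at 10% per-position degeneracy, 150 positive regions
(hence the 100/50 train/validation split), 500-bp regions at 50% GC. The
12-bp/10% choice is deliberate: recovering ≥90% of sites at ≤1 false
positive per 10 kb requires roughly 14 bits of discriminative information
(`log2(2 × 10,000)`), which a shorter or more degenerate motif cannot
supply for *any* scorer — an 8-bp motif at 20% degeneracy carries only
about 7 bits.

The **structural signal** is injected through flank composition, never by
writing property values directly, so generated data remain valid DNA and
the property tables transduce composition into property shifts.
`structural_bias = list(scale, shift)` rewrites the flanks of every true
site from a tilted base composition chosen so the named property's mean
moves by `shift` standard deviations of the k-mer table (sign = direction).
The tilt follows the gradient of the i.i.d. mean property surface in small
exponential steps; a single large tilt is not safe because these surfaces
are strongly curved — for bendability, A/T enrichment first raises and then
lowers the mean (A-tracts are rigid, but TCA/ATA steps are the most
flexible), and the i.i.d. mean has an interior maximum close to typical
genomic compositions, so large *upward* bendability shifts are unreachable
by composition alone. The flow stops at the reachable extreme in that case.

What the generator does **not** emulate: chromatin context, nucleosome
occupancy, dinucleotide autocorrelation of real genomic background,
multiple sites per region, and soft-masked repeats. Passing tests on these
fixtures demonstrates the machinery is correct and that structural signal
is usable when present; they do not certify performance on real ChIP data.

## The structure-signal experiment

The package's key benchmark trains on fixtures with a degenerate motif
(mutation rate 0.3) and rigid, low-bendability flanks (`shift = -1`), then
compares held-out ROC AUC of the full model against a PWM-only scorer on
the same windows (fresh site windows vs filter-passing background windows;
n_pos = 300, 500-bp regions, 20 seeded replicates). The degenerate-motif
regime is chosen deliberately — it is where indirect readout matters and
where neither scorer is at ceiling, so the comparison is informative. The
control with `structural_bias` absent shows the full model does *not* beat
the PWM (the forest pays a small variance penalty against the exact PWM
likelihood when sequence is the only signal); the with-bias runs are
therefore measuring the structural signal itself.

## Numerical and design choices

* Natural-log log-odds and nats throughout; PWM pseudocount 1.0 spread in
  background proportion; PWM background defaults to the base composition of
  the supplied background sequences.
* Windows containing `N` are skipped everywhere (property tables are
  undefined on ambiguous bases); `U` is silently mapped to `T`; any other
  non-ACGTN character is a hard error with its position.
* All stochastic operations take mandatory seeds; the model file records
  them, and repeated training with one seed produces byte-identical files
  (the bundle is written uncompressed specifically to avoid
  compression-header timestamps).
* Model bundles are versioned; loading refuses unknown versions and fails
  by name if a property scale used in training is missing from the
  installed registry.
* Flanks must be 0 (core-only property features) or at least the largest
  scale order, since a shorter flank yields no complete k-mer window.

## Problem sizes

The test-suite defaults keep everything desk-scale: models train on 150
positives of 500-bp regions with a 500-window null in the shared fixtures;
the structure-signal benchmark uses 20 replicates at n_pos = 300 with a
100-window null; the acceptance script uses a 2,000-window null for the
headline model and 50 scan regions for recall/false-positive reporting.

## Known limitations

* The **Max. Precision** threshold (and hence **Average**) depends on the
  single highest-scoring calibration negative, so it varies noticeably
  between training runs; Max. F-Measure is more stable. Expect scan recall
  at the Average threshold to move by ±10 percentage points across seeds on
  the default fixtures.
* Property tables are transcriptions of widely circulated published scales;
  the solvent-excluded-surface scale is a constructed stand-in and should
  not be cited as data.
* The forest's vote-fraction score is granular (1/100); score ties across
  candidate windows are common at the extremes (0 and 1), which is why
  P-values rather than raw scores should be used to rank strong hits.
* One site per positive region is assumed by the generator; the scanner
  itself handles any number of sites.
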