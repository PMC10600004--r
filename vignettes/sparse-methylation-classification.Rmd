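---
title: "Classifying tumours from sparse methylation profiles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumours from sparse methylation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparsemeth)
```

This vignette is the package's account of its science: what is being
modelled, which constants matter and why they hold the values they do,
what the synthetic cohorts do and do not emulate, and where the design was
genuinely open.

## The problem

A short nanopore sequencing run started during surgery yields on the order
of 10⁴–10⁵ reads — enough to touch only 0.6–14% of the CpG sites that a
450K methylation array measures, at positions that cannot be chosen in
advance, each typically covered once. Methylation-based tumour
classification is well established on dense array profiles; the question
this package addresses is how to classify from a *random sparse subset* of
those features, within minutes, with calibrated confidence, and how to
validate such a classifier when no large nanopore-sequenced reference
cohort exists.

The answer is simulation: dense, labelled array profiles are binarized and
turned into unlimited sparse pseudo-runs with realistic read geometry and
call noise. The classifier never sees real nanopore data during training,
so the simulator's fidelity — and honest seed hygiene between
cross-validation folds — carries the entire weight of the validation.

## The simulator

A run is the composition of four steps, each with its own defaults:

* **Binarization** at β ≥ 0.6 (cut-off inclusive). Shallow sequencing gives
  ≤ 1× coverage per site, so heterogeneous methylation cannot be
  represented; a hard state per probe is the honest encoding. Missing
  betas are dropped rather than imputed — a dropped probe behaves exactly
  like a never-covered one downstream, which is the only interpretation
  the sparse regime supports.
* **Read placement.** Chromosomes are drawn proportionally to length, the
  start base uniformly, orientation 50/50, and the read extends one read
  length in its orientation, clipped at chromosome ends. Read lengths come
  from a log-normal surrogate with median 5,000 bp (`sdlog` 0.35,
  truncated at 100 bp): rapid intraoperative library preps centre around
  5 kb, and no published length distribution is available, so the family
  is configurable and an empirical length file can replace it.
* **Coverage.** A probe is covered iff its cytosine lies inside at least
  one read interval (half-open, 0-based internally; the manifest speaks
  1-based coordinates at the I/O boundary).
* **Noise.** Each covered call is flipped independently with probability
  0.10, the centre of the 10–15% discrepancy observed between binarized
  arrays and nanopore methylation calls. Placement and noise run on two
  independent substreams derived from the single run seed, so an entire
  run — noise included — is reproducible from `(profile, config, seed)`.
  This is deliberately stricter than reproducibility of placement alone.

Twelve sparsity levels span 0.6–14% of the probe universe. Only the
endpoints and the fine-tuning boundary (6.3%) are fixed by the reference
setting; the interior levels are geometrically spaced, which keeps the
ratio between consecutive levels constant and matches the roughly
multiplicative growth of coverage with sequencing time. The number of
reads for a level is solved analytically from the expected per-read probe
yield (`reads_for_depth()`), rather than by rejection sampling; realized
coverage is recorded in each run's provenance and stays within ±20% of
target in the test suite.

Seed ranges are disjoint by role — test 0–499, validation 500–999,
training 1000–1000999 — and enforced with hard errors. This is what makes
"36 million simulated training runs" compatible with honest test folds:
no simulation can leak across roles even in principle.

## The classifier and its training

The network is small and wide-input: three fully connected layers
(input → 256 → 128 → classes), sigmoid activations after the first two,
dropout 0.5 between layers, softmax output, cross-entropy loss with
uniform class weights. Covered probes enter as +1 (methylated) or −1
(unmethylated) and uncovered probes as 0. The reference setting never
states how missing inputs are encoded; the signed encoding makes
"uncovered" exactly neutral for every downstream unit and keeps the input
size equal to the probe universe. A masked alternative ({0,1} calls plus a
coverage channel, doubling the input) is available and recorded in model
provenance, so the choice is auditable.

Training is a two-stage curriculum. Pretraining draws simulations from
all twelve sparsity levels (easy and hard mixed); fine-tuning restricts to
levels ≤ 6.3% at a constant 10⁻⁴ learning rate. One epoch is defined as
(largest class size × number of classes) simulations — 13,013 at reference
scale — and that budget is held constant while its allocation over
(sparsity level × class) cells adapts: allocations are proportional to the
previous epoch's per-cell error plus 0.3, integerized by largest-remainder
rounding so the total is conserved exactly and no cell starves. Error is
1 − top-1 accuracy measured on the just-finished epoch's training batches
(the reference description does not say which split; training batches are
the cheapest and bias the allocation toward cells the optimizer currently
finds hard, which is the stated intent). Upsampling of small classes means
*drawing more fresh simulations*, never duplicating existing ones — with
seeded simulation the distinction matters.

Checkpoints are taken every 2,000 training batches (reference scale) and
scored on 50 freshly simulated validation batches by mean loss and
macro-averaged per-class recall ("sensitivity"); the checkpoint with the
lowest loss wins, ties broken by higher sensitivity, then recency. Four
submodels are trained on rotating class-stratified folds (two train, one
validation, one test); at prediction time each submodel produces
calibrated, merge-summed scores and the submodel with the highest maximum
supplies the answer. Near-identical subclasses (the two pilocytic
astrocytoma classes, the two SHH medulloblastoma classes in the reference
taxonomy) are merged by summing their scores after softmax.

Location-specific variants reuse the trained trunk: the final layer is
replaced by a freshly initialized head over the reduced class set (with
all irrelevant classes collapsed into a single control-flagged "other"
class), and the temperature is reset — a transferred model is uncalibrated
until refitted.

### Desk-scale schedule

The reference schedule (batch 256, 3,000 + 3,000 epochs, warmup to 10⁻³
over 1,000 batches) is sized for tens of millions of simulations. The
package's own end-to-end experiments — the test suite and the worked
example — run a scaled-down curriculum chosen once for the synthetic
cohort: batch 8, 30 pretraining + 20 fine-tuning epochs, warmup over 20
batches to a peak of 10⁻², decaying to 2 × 10⁻³, checkpoints every 50
batches on 3 validation batches. With an epoch budget of only 72–84
simulations, the reference learning rates leave the optimizer far from
convergence within ~50 epochs; the desk-scale peak is raised accordingly
(roughly inversely with the reduction in total optimization steps). All
other constants — dropout, optimizer moments, weight decay, noise rate,
curriculum boundaries — keep their reference values at every scale.

## Calibration and the outcome rule

A single scalar temperature per submodel is fitted on validation-fold
simulations pooled across all sparsity levels (one scalar per submodel is
what the reference setting describes), by minimizing class-weighted
cross-entropy of `softmax(logits / T)` with a bounded quasi-Newton search
(L-BFGS-B on log T, at most 500 iterations). Class weights are inverse
class frequency normalized to mean 1 — the reference says "class-weighted"
without a formula, and inverse frequency is the convention that makes rare
classes count equally. Dividing logits by a positive scalar never changes
the argmax, so calibration can only move confidence, not decisions. The
fitted temperature is accepted only if it does not increase the weighted
NLL relative to T = 1.

Calibration quality is summarized by the expected calibration error over
10 equal-width confidence bins (equal-count binning is available as an
option). The clinical outcome rule is deliberately asymmetric: a diagnosis
is returned only when the top merged score reaches 0.95 *and* the top
class is not control tissue; a confident control call and a
below-threshold call are both "unclear", with the sub-reason recorded.
Under admixture of normal tissue this converts would-be errors into
abstentions, which is the failure mode a surgeon can live with.

## Probe mapping, pseudotime, regions, CNV

Per-read methylation probabilities are thresholded at < 0.3 / > 0.7
(boundaries discarded) and assigned to every probe whose 100-bp centred
window contains them (distance ≤ 50 bp inclusive; the window convention is
not pinned by the reference, and an inclusive centred window is the
symmetric choice). Voting is read-first: calls within one read vote for
that read's probe call, then reads vote for the probe's final state; a tie
at either level discards that unit rather than guessing. Strands are
pooled — CpG methylation is symmetric.

Pseudotime converts cumulative CpG call counts to equivalent fresh-MinION
minutes through a fixed 12-interval table (51,924 calls in the first 5-min
interval, rising to 258,197 in the twelfth). The counts are interpreted as
*total genomic CpG calls*, not unique probes — accumulated they exceed the
probe universe, so the unique-site reading is untenable; probe-level
coverage is tracked separately. Beyond the table, time extrapolates at the
final interval's rate and is flagged. Read-order robustness resampling
permutes the sequenced read order, accumulates reads to each pseudotime
threshold and classifies at every interval, tallying
correct-confident / wrong-confident / below-threshold outcomes.

Adaptive-sampling targets are probe positions ± 5 kb, clipped at
chromosome ends, merged whenever gaps are ≤ 25 kb (via
`GenomicRanges::reduce`), emitted as sorted 0-based half-open BED. The
design is idempotent and covers every probe by construction.

The CNV profile counts read starts in 2-Mb bins (end bins keep their
reduced width), masks bins with zero reference coverage, and reports
log₂(relative coverage / mean relative coverage), which is exactly
invariant to total sequencing depth. Segmentation is an explicitly
simplified stand-in for circular binary segmentation: recursive binary
splitting at the least-squares changepoint, significance from a normal
statistic whose noise scale is estimated robustly from successive
differences (median absolute difference / (√2 · 0.6745)) with Bonferroni
correction over candidate positions, α = 0.01, minimum 3 bins per
segment. The robust difference-based scale was chosen because a
within-side variance estimate is inflated by any shift contained in that
side, which can mask a focal amplification — the classic binary
segmentation pathology. Externally computed segments can be substituted
wherever segments are consumed.

## The synthetic cohorts

`make_cohort()` generates the study cohort used throughout the tests: by
default 6 classes (one flagged control tissue), 24 samples per class,
5,000 probes on a 2 × 10 Mb genome. Every probe has a shared baseline
state (methylated with probability 0.5); each class deviates from the
baseline on its own disjoint 400-probe signature; sample betas are class
means (0.9 / 0.1) plus clipped Gaussian noise (sd 0.08), binarized at 0.6.
Per-sample tumour fractions are drawn from 40–85%, the purity range of
typical reference material. With `signature_size = 0` the classes are
identical by construction — the negative control.

What this emulates: class-specific CpG signatures, within-class
variability, control tissue, purity mixing, the full file-format surface
(beta TSV, manifest TSV, chromosome sizes, per-read call tables). What it
does not: genome-wide methylation autocorrelation, realistic class
overlap, batch effects, or real tumour biology. Passing the end-to-end
suite therefore demonstrates that the machinery — simulation, curriculum,
balancing, calibration, thresholding — works as specified on separable
data; it says nothing about clinical accuracy on real cohorts, which
requires the restricted reference datasets.

The per-read call generator emits probabilities near 0 or 1 with a
configurable flip rate and a configurable fraction inside the 0.3–0.7
discard zone, emulating the 85–90% array/nanopore concordance regime; the
test suite checks that majority voting lifts probe-level concordance above
read-level concordance, which is the property that makes windowed voting
worth its complexity.

## Numerical and degenerate-input choices

* Largest-remainder rounding keeps every integerized allocation summing
  exactly to its budget; the ≥ 1 floor per balance cell applies whenever
  the budget covers the grid (always, at reference scale) and relaxes to 0
  on tiny desk cohorts rather than overdrawing the fixed epoch total.
* F1 and TPR return 0 on zero denominators. Top-3 false positives are
  charged to the top-1 class only — top-k bookkeeping has no canonical
  definition, and this convention keeps FP counts comparable between
  top-1 and top-3.
* Ties: ensemble ties go to the lowest submodel index; checkpoint ties to
  higher sensitivity then later step; segmentation split ties to the first
  maximum; voting ties discard the unit. All deterministic.
* Classes with fewer than `k` samples are allowed in fold assignment (some
  folds may lack them; the assignment records which classes are small).
* A constant log-ratio vector is never split (an explicit epsilon guards
  floating-point noise in the split score).
* Oversized reads clip to the chromosome; a 5-kb read on a 1-kb chromosome
  yields the segment between its anchor and the end it runs over.

## Problem sizes

The end-to-end suites run the 6 × 24 × 5,000 cohort with the desk-scale
schedule above (four submodels, ~50 epochs each), evaluate 10 held-out
runs per sample at the deepest level, and sweep purity over five seed
blocks at one mid-range depth; the oracle suites use 1,000 randomized
small cases per operation. These sizes were chosen so the whole suite
exercises every stage at full fidelity while remaining a coffee-break run
on one CPU.

## Known limitations

* The read-length surrogate and uniform genome placement ignore
  mappability structure; an empirical length file can replace the former,
  nothing currently replaces the latter.
* Binary segmentation, even with the robust scale, is weaker than full CBS
  for short low-amplitude events; the interface accepts external segments.
* The signed input encoding is an assumption the reference setting leaves
  open; models record their encoding, and retraining with the masked
  encoding is supported but not the default.
* Synthetic cohorts are linearly separable by construction; none of the
  reported desk-scale accuracies transfer to real data.
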