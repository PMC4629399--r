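---
title: "Guide RNA potency modeling and specificity filtering: methods"
author: "sgSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide RNA potency modeling and specificity filtering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

sgSelect predicts the knockout potency of CRISPR/Cas9 guides and filters
them for targeting specificity. This vignette is the package's account of
the underlying method: the feature model and its assumptions, the tunable
parameters, the synthetic data used for calibration and testing, the
numerical conventions, and the places where the design was genuinely open
and a choice had to be made.

# The potency model

## Rationale

Guide activity is shaped by two kinds of properties. *Sequence*
properties — base composition, position-specific identities, and motifs
that interfere with oligo synthesis (repetitive runs) or pol III
transcription (U-runs) — and *structural* properties of the RNA itself.
A guide that folds back on itself, or whose 3' seed end is absorbed into
an extended stem-loop with the scaffold, presents less single-stranded
seed sequence for target recognition; a guide whose RNA/DNA hybrid with
the target is excessively stable is likewise associated with poor
activity. The model therefore mixes both kinds of predictors rather than
relying on position-specific sequence features alone.

## Feature vector

Each 20-nt guide (RNA alphabet internally; DNA input is converted on
read) maps to a fixed 176-entry vector, in this order: GC content;
mono-, di- and trinucleotide overlapping counts (4/16/64; counts of
width $k$ sum to $21-k$); three motif flags (repetitive run, GGGG,
UUU within the last six bases); guide self-folding $\Delta G$; RNA/DNA
duplex $\Delta G$; six accessibility indicators (sgRNA positions 18–20
and 51–53); and the 20×4 one-hot encoding. All trinucleotide counts are
included — rather than a curated significant subset — and the SVM is left
to weight them; this keeps the manifest reproducible from first
principles.

## Structural features

Secondary structures are minimum-free-energy (MFE) predictions by
ViennaRNA's `RNAfold` at 37&nbsp;°C with its default energy parameters;
the engine version is exposed by `foldEngineVersion()`. Accessibility is
a *binary* readout of the MFE dot-bracket string (unpaired = accessible),
not an ensemble base-pairing probability: the modeled quantity is whether
a position is paired in the predicted structure, and the partition
function adds a dependency on ensemble parameters without changing the
downstream binary feature. Sequences for which the engine finds no
stable structure are reported as the open chain with
$\Delta G = 0$; reported MFE is clamped to $\le 0$.

The full sgRNA is the guide followed by the 80-nt *S. pyogenes* scaffold
(`defaultScaffold()`), giving a 100-nt molecule whose positions 51–53
are `AAG` — the bases that can pair with a pyrimidine-rich guide 3' end
and extend the repeat:anti-repeat stem. The scaffold is a configurable
argument everywhere it matters, since scaffold variants exist; the
default is the standard one consistent with that AAG placement.

Duplex stability uses the Sugimoto et al. (1995) nearest-neighbor
$\Delta G_{37}$ parameters for RNA/DNA hybrids, shipped as a plain-text
table in `inst/extdata` so that independent checks can sum the same
source values. Published RNA/DNA parameter sets differ by roughly
constant per-stack offsets; with this set a random 20-mer averages about
$-24$ kcal/mol. Because the choice of set shifts absolute values, the
package's tests assert *oracle equality* (the implementation equals
direct table summation) and *ordering* (GC-rich $\ll$ AU-rich), never a
particular absolute mean. Mismatch energetics are out of scope: the
duplex energy is defined for a guide against its perfect complement, and
anything else is an error.

## Classifier

Features are min–max scaled to $[0,1]$ using constants learned on the
training data and stored with the model (libsvm convention; constant
features scale to 0). The classifier is an RBF-kernel SVM (e1071, the R
libsvm binding). Hyperparameters $(C, \gamma)$ are selected by grid
search over libsvm's recommended ranges, $C \in 2^{-5}..2^{15}$ and
$\gamma \in 2^{-15}..2^{3}$, log-spaced at step $2^4$, by internal
3-fold cross-validation accuracy. The grid is deliberately coarse and
tuning runs on a stratified subsample of at most 600 records: RBF-SVM
accuracy is flat over wide hyperparameter plateaus for this feature
scale, and the package targets interactive use on a single CPU; both
knobs (`tuneSubsample`, `tuneFolds`, and the grid itself) are arguments.
The user-facing score is the calibrated probability of the functional
class, in $[0,1]$. A trained model stores its feature manifest and
scaffold and refuses to score when the manifest does not match the
installed assembler — scores are only comparable within one feature
definition.

`trainGuideModel()` by default trains on records that pass the hard
pre-filters, matching the configuration used for genome-scale design
where the filters run first anyway; `prefilter = FALSE` gives the
unfiltered model that the cross-validation analyses evaluate.

## Evaluation machinery

`crossValidate()` offers a ten-fold random partition and a
leave-one-gene-out mode in which each fold holds out every guide
targeting one gene — the stricter test, since guides from one gene share
sequence context and screen batch effects. Scaling is re-learned inside
each training fold. Hyperparameters are tuned once on the full labeled
set and reused across folds; this admits a small optimistic bias
relative to nested tuning, accepted for runtime and documented here.
Fold scores are SVM decision values: the probability calibration is a
monotone sigmoid, so ROC and PR summaries are unchanged and the extra
internal cross-validation it costs is avoided.

`rocAUC()` is the Mann–Whitney statistic (ties count one half), so AUC
is invariant to monotone transforms; `prCurve()` reports precision and
recall at every distinct threshold with the positive-class fraction as
the random-selection baseline.

# Hard pre-filters

Before any scoring, guides failing any of these rules are excluded:
self-folding $\Delta G < -8$ kcal/mol; duplex $\Delta G < -22$ kcal/mol;
GC $> 0.80$; UUU within the last six bases; a repetitive run (AAAAA,
CCCCC, GGGG, UUUU); U at position 19; C or U at position 20. Rules are
evaluated all-at-once and every failed rule is reported, which is what
makes class-wise audits (`auditPrefilters()`) informative. Boundary
semantics are inclusive passes: the rules are phrased as strict
inequalities, so a guide exactly at a cutoff passes. Thresholds are
configurable (YAML `thresholds` block), and the audit is the tool for
judging them against a labeled screen. Note that with the Sugimoto
parameter set the $-22$ duplex cutoff is strict for random sequence —
see the parameter-set remark above; users who adopt a different
nearest-neighbor table should recalibrate this threshold with the audit.
The position-19/20 rules are hard excludes here; whether they could
instead be soft penalties is an open design question resolved in favor
of the simpler, auditable behavior.

# Off-target screening

Off-target analysis is deliberately restricted to *exon space*: small
indels in noncoding regions rarely have functional consequences, and the
smaller search space permits stricter filters. Two rules:

1. **Seed rule.** A candidate is excluded if its 3'-terminal 13 nt
   occur, as DNA on either strand, immediately 5' of an `NGG` *or*
   `NAG` PAM anywhere else in the exon set. Implementation: every 16-nt
   exon window whose last three bases match NGG/NAG is hash-indexed by
   seed+PAM; lookup is exact. NAG is included because Cas9 tolerates it
   at off-target sites, even though only NGG sites are enumerated as
   design candidates.
2. **Similarity rule.** A candidate is excluded if any other 20-mer
   window (either strand) matches it at $\ge 85\,\%$ identity. This is
   operationalized as *ungapped* matching with $\le 3$ substitutions
   ($17/20 = 85\,\%$): gapped alignment of 20-mers at this scale is
   ill-defined, and the ungapped scan is exactly checkable against a
   brute-force oracle. Similarity hits are PAM-agnostic, which is the
   stricter reading.

Windows containing `N` never match (no wildcard credit). Coordinates
are 0-based half-open internally and in BED export, 1-based in design
reports. The intended target site is excluded by coordinate when
declared; otherwise a unique exact 20-mer match flanked by NGG is
treated as the on-target.

# The design pipeline

`designGuides()` enumerates every 20-mer 5' of an NGG on both strands,
applies the pre-filters, scores survivors with the SVM, off-target
screens them, and ranks by descending score, then fewer similarity hits,
then 5'-most position (a deterministic tie rule; the method itself
defines none). Cheap filters run before the SVM so unpromising
candidates are never folded into feature vectors, and eliminated
candidates are reported unscored rather than silently dropped: the
report always has one row per enumerated candidate.

# The synthetic screen generator

`generateSyntheticScreen()` stands in for a flow-cytometry potency
screen. It emulates: 20-nt guides uniform over the RNA alphabet with
UUUU-containing guides rejected (real screens preselect them out), nine
target genes assigned round-robin (matching the gene count of the screen
this class of model is trained on), and a continuous activity with a
planted linear signal,
$$\text{activity} = \beta \cdot z\!\left(\#A \;-\; \mathbf{1}[\text{GGGG}]
\;-\; |\Delta G_{\text{self}}| \;-\; \mathbf{1}[\text{C/U at 20}]\right)
+ \varepsilon,\qquad \varepsilon \sim N(0,1),$$
with the planted score standardized so the effect size $\beta$ is in
noise-SD units. The default conditions are $n = 2000$ and $\beta = 2$ —
a screen size of the order real screens achieve, and a signal strength
at which the planted rule dominates but does not determine activity.
The planted features deliberately overlap the model's predictors so that
parameter-recovery tests are meaningful: enrichment statistics must
rediscover each planted feature with the planted sign, and
cross-validation must separate the classes while a $\beta = 0$ screen
stays at chance.

What the generator does **not** emulate: linkage between guide sequence
and gene identity (real guides from one gene share a locus; synthetic
genes are arbitrary labels, so leave-one-gene-out CV exercises the fold
bookkeeping but not genuine gene-level confounding), position-specific
composition biases beyond position 20, measurement error structure of
sorting screens, and chromatin or expression context. Passing tests on
synthetic screens therefore demonstrate that the machinery recovers a
known signal of this shape — not that the fitted synthetic model
transfers to real guides; for that, train on a real screen table via
`readScreenTable()`.

# Numerical conventions and degenerate inputs

* **Percentile labeling.** Class size is $\lceil f \cdot n\rceil$ per
  class, computed from order statistics (hence invariant under
  order-preserving activity transforms); records tied with the boundary
  value join the extreme class, maximizing training data. A screen of
  1841 distinct activities at 20/20 splits 369/369. All-identical
  activities are an error, as percentile classes are undefined.
* **Activity column.** Screens report raw and gene-normalized scores;
  which to rank on is the user's choice via the `columnMap` of
  `readScreenTable()`.
* **Folding.** MFE $\le 0$ enforced; structure/MFE parsing is strict and
  any unparseable engine output is an error rather than a guess.
* **Scaling.** Constant training features scale to 0; test-time values
  outside the training range are not clamped (libsvm behavior).
* **Probability calibration.** libsvm's sigmoid fit uses an internal
  random partition; the decision boundary itself is deterministic given
  the data, and AUC-based results never depend on the calibration.
* **Determinism.** The generator takes an explicit seed and restores the
  caller's RNG state; fold assignment and tuning subsampling are seeded;
  reports are row-ordered deterministically, so repeated runs are
  byte-identical.

# Problem sizes used by the checks

The package's own verification runs at sizes chosen for a single CPU:
oracle comparisons use 100–200 random cases and ~10 kb of random exon
sequence; parameter recovery uses the generator's default study
conditions ($n = 2000$, $\beta = 2$, plus a $\beta = 0$ null screen);
unit tests use screens of 200–300 guides. These sizes are stated here as
the package's calibration choices.

# Known limitations

* Absolute duplex energies (and therefore the $-22$ threshold) are tied
  to the shipped nearest-neighbor set; see above.
* Accessibility is a single-structure MFE readout; near-MFE ensembles
  are ignored by design.
* Off-target screening is exon-restricted by construction and performs
  no bulge/gap alignment and no off-target *activity* scoring; hits are
  counted, not weighted.
* The SVM's feature weights are not interpretable effect sizes; use the
  enrichment statistics (`screenFeatureStats()`) for feature-level
  inference.
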