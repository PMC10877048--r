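---
title: "Composition features, discriminative motifs and the hybrid override"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition features, discriminative motifs and the hybrid override}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsubloc)
```

## The problem and the model

mRNAs are routinely present in several subcellular compartments at once,
so localization prediction is a multi-label problem. `mlsubloc` predicts
membership in six compartments — ribosome, cytosol, ER, membrane,
nucleus, exosome, always in that order — from sequence alone, using two
complementary sources of evidence:

1. **Global composition.** A transcript is summarized by 200 k-mer
   frequencies and scored by six independent boosted-tree classifiers
   (binary relevance). Composition is alignment-free and essentially
   free to compute, which is what makes transcriptome-scale prediction
   practical.
2. **Local motifs.** Zip-code-like elements that direct mRNA transport
   are short, location-specific sequence motifs. A discriminative motif
   search finds substrings present in positive training sequences for a
   location and absent from all negatives; at prediction time a hit by
   any such motif overrides the model's probability for that location
   to 1. Sequences without hits are untouched, so the override can only
   raise probabilities.

The override is deliberately one-sided. A "negative" motif rule (forcing
a probability to 0) would be the symmetric counterpart, but strictly
discriminative negative evidence is much weaker — absence of a motif in
the training positives is uninformative — so only the positive override
is implemented.

## Feature definitions and their edge cases

**CDK(k).** For a sequence of length $L$, the entry for k-mer $w$ is
$N_w / (L - k + 1)$: the count of sliding windows equal to $w$ over the
number of windows. With $k = 3$ this gives 64 features that sum to 1 for
an unambiguous sequence.

**RDK(k).** k-mer counting collapsed over reverse-complement pairs: each
window contributes to the class $\{w, \mathrm{revcomp}(w)\}$, named by
the lexicographically smaller member. For $k = 4$, 16 of the 256 4-mers
are their own reverse complement, so there are $(256-16)/2 + 16 = 136$
classes. Collapsing makes the block invariant under reverse
complementation of the input, which is the property that distinguishes
it from plain 4-mer composition; 64 + 136 = 200 features in total.

**Ambiguity.** IUPAC-ambiguous bases (N, R, Y, ...) are retained in the
sequence but any window containing one is excluded from the numerator
while the denominator stays $L - k + 1$; the feature vector of an
ambiguous sequence therefore sums to less than 1 rather than being
redistributed. Sequences with more than 10% ambiguous bases are rejected
outright — at that level the composition vector no longer reflects the
transcript. RNA-alphabet input is accepted and normalized (`U → T`,
uppercase) so that motifs and features live in one alphabet.

## Motif discovery

Motifs are exact, ungapped A/C/G/T strings. Discovery is breadth-first
extension: seed with the four bases, extend surviving candidates one
base to the right, and prune any candidate supported by fewer than
`min_support` distinct positive sequences — support is anti-monotone
under extension, so pruning is safe. Candidates within the configured
length range (default 8–30 nt) that occur in at most
`max_negative_occurrences` negatives (default 0) are collected, then
reduced to *maximal* motifs: a motif is dropped if it is a substring of
another reported motif with an identical set of supporting positives.
Two maximal motifs with the same support set, neither a substring of the
other, are both kept. On instances small enough to enumerate, the
procedure provably matches brute-force substring enumeration followed by
the same filters, and the test suite checks exactly that.

`min_support` defaults to 1 — singleton motifs can be genuinely
discriminative in curated data — but discovery cost grows quickly at
support 1 on large sequence sets, and a support floor near the positive
count of the rarest believable signal is the practical choice (the
worked examples use 20–40 on a few hundred sequences).

## Classifier

One binary `binary:logistic` boosted ensemble per location, trained on
the same 200 columns with that location's label as target. Defaults
(1000 rounds, learning rate 0.01, max_delta_step 1, seed 1) follow
standard practice for imbalanced binary relevance on composition
features; `max_delta_step` bounds per-leaf updates, which matters
because several locations are heavily imbalanced. Training is
single-threaded so a seed fully determines the fit. No per-label class
weighting is applied. A logistic-regression backend is available behind
the same contract for baselines; it carries no performance guarantees.

## Splitting, thresholds, metrics

Plain per-sample stratification is undefined for multi-label data, so
splits and folds use iterative stratification: process labels from
rarest to most common, assigning each sample to the fold with the
largest remaining demand for that label (ties by remaining capacity,
then randomly under the seed). The guarantee checked by the tests is
that each label's prevalence in every fold is within
$\max(0.02, 1/|\text{fold}|)$ of its global prevalence.

The workflow is an 80:20 split, 5-fold cross-validation inside the 80%
producing out-of-fold probabilities, per-location thresholds chosen on
those pooled out-of-fold scores, a final fit on the full training
portion, and evaluation on the untouched 20%. Thresholds minimize
$|\mathrm{sens} - \mathrm{spec}|$ over a candidate grid consisting of
the distinct scores, midpoints between consecutive distinct scores, and
one candidate beyond each extreme; ties go to the smallest threshold.
Choosing thresholds on out-of-fold rather than resubstitution scores
keeps them honest for the validation set.

Reported metrics are sensitivity, specificity, accuracy, F1
($TP / (TP + 0.5(FN+FP))$), MCC (defined as 0 when its denominator
vanishes) and rank-based AUROC (Mann–Whitney with ties counted half),
per location plus an unweighted average row.

## The synthetic generator

Real curated localization datasets are external downloads, so the
package ships a seeded generator reproducing the structural features the
pipeline depends on:

* **Imbalanced, correlated labels.** Marginal prevalences default to
  ribosome 0.30, cytosol 0.15, ER 0.12, membrane 0.19, nucleus 0.69,
  exosome 0.80 — shaped like curated human data, where nucleus and
  exosome dominate, except that the exosome rate is capped well below
  its empirical near-1 value so that simulations of a few hundred
  sequences keep negatives for every label. Co-occurrence comes from a
  shared latent Bernoulli factor OR-ed into independent per-label draws.
* **Composition signal.** Each location owns a signature trinucleotide;
  positive sequences are built from 3-nt blocks that are signature words
  with probability `composition_effect` per positive label (total
  capped at 0.6) and uniform background otherwise. Distinct words per
  location keep the six signals separable — an earlier single-axis GC
  tilt was discarded because all six labels collapsed onto one feature
  direction and confounded each other.
* **Planted motifs.** A location's motif is inserted at a uniform random
  position into each of its positives with a configurable probability
  and never into its negatives (sequences spuriously containing a
  motif of a negative label are resampled).

What the generator does **not** emulate: UTR/CDS architecture, codon
structure, splice isoforms, shared homology between sequences, or
realistic transcript lengths (defaults 200–1000 nt; composition features
are length-normalized, so the shorter lengths change compute, not the
signal model). Passing tests on this generator therefore demonstrates
that the machinery — features, discovery, training, thresholding,
override — behaves correctly and recovers planted structure, not that
any particular accuracy will be achieved on real transcriptomes.

## Numerical and design choices

* Feature columns are named (`CDK3_AAA` ... `RDK4_TTTA`), and prediction
  refuses a matrix whose columns differ from the training order.
* Sums of CDK and RDK blocks equal 1 within $10^{-9}$ on unambiguous
  input; equality tests on features use $10^{-12}$ tolerances.
* The test-scale workflow uses 100–500 sequences, 100 or fewer boosting
  rounds and 3–5 folds; these sizes recover the planted signals
  comfortably while keeping the whole suite fast. Production defaults
  (1000 rounds) are unchanged by test settings.
* Degenerate inputs fail loudly: a location with no positives (or no
  negatives) in training, a truth vector with one class in AUROC, empty
  FASTA records, non-ACGT motif lines — all raise errors naming the
  offender rather than propagating NaNs.

## Known limitations

* Motif discovery at `min_support = 1` on transcriptome-scale input is
  combinatorially expensive; use a support floor.
* The strict zero-negative filter makes discovered motifs brittle to a
  single mislabeled negative; raising `max_negative_occurrences`
  trades purity for robustness.
* Probabilities after the override are not calibrated (a forced 1 is a
  rule, not a likelihood).
* Binary relevance ignores label dependencies at prediction time; the
  generator's latent co-occurrence factor is only exploited indirectly
  through composition.
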