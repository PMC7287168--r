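---
title: "Predicting DNA N6-methyladenine sites from sequence windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA N6-methyladenine sites from sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsite)
library(dplyr)
```

## The problem

N6-methyladenine (6mA) is a DNA epigenetic mark found across bacteria,
archaea and eukaryotes, involved in replication, repair, transcription and
cellular defense. Experimental mapping (e.g. SMRT sequencing) is expensive,
which motivates sequence-based classifiers: given a fixed-width window
centered on a candidate adenine, predict whether that adenine is
methylated. The canonical benchmark for this task is a balanced set of 880
methylated and 880 non-methylated 41-nt rice genome windows, the negatives
drawn from GAGG-motif-containing coding subsequences.

`methsite` implements the full modeling pipeline: two complementary
sequence encoders, feature fusion, ANOVA-F incremental feature selection,
an RBF-kernel SVM with grid-searched hyperparameters, and a stratified
cross-validation harness reporting Sn, Sp, ACC, MCC and AUC.

## Sequence windows

All inputs are 41-nt windows (configurable, always odd) with the candidate
adenine exactly central. When a genomic site sits closer than 20 nt to a
sequence end, the missing flank is padded with the gap character `N` on
whichever side underruns, keeping the site central — both encoders assume
a site-centered window, so padding only one side would shift every
positional feature. Positions are 1-based throughout, following R and
general bioinformatics convention. A non-adenine center is a warning by
default (`center_check = "error"` for strict use), so users can scan
arbitrary positions; `U` is silently mapped to `T` and lowercase input is
accepted.

Windows may contain `N` anywhere. Every encoder defines its `N` behavior
explicitly rather than rejecting such windows: one-hot columns are all
zero at an `N`, and k-mers/dinucleotides containing `N` are dropped from
both numerator and denominator of every frequency or correlation average.

## Encoder 1: nucleotide positional specificity (NPS)

Two descriptors are concatenated:

1. **Positional orthogonal binary code.** Each of the 41 positions
   contributes four 0/1 entries under the code
   A = (0,0,0,1), T = (0,0,1,0), C = (0,1,0,0), G = (1,0,0,0),
   N = (0,0,0,0). This particular assignment (rather than the more common
   A = (1,0,0,0)) is reproduced verbatim from the method this package
   implements; an RBF or linear kernel is invariant to such a column
   permutation, so the choice is cosmetic but kept for fidelity. Slot *j*
   of position *p* is the indicator of the nucleotide whose code carries
   the 1 in slot *j*, and features are named accordingly
   (`nps_pos17_T` is "T at position 17").
2. **Position-independent k-mer frequencies** for k = 2, 3, 4, counted
   over all overlapping k-length windows of the full 41-nt window and
   normalized by the number of N-free windows. Overlapping counting is the
   near-universal convention and the only one that populates a 256-bin
   k = 4 histogram from a 41-nt window at all.

The dimensions are 4·41 = 164 and 16 + 64 + 256 = 336, i.e. 500 features
total. The block order (binary, then k = 2, 3, 4, k-mers lexicographic) is
fixed so that feature indices in selection results are stable across runs.

## Encoder 2: pseudo dinucleotide composition (PseDNC)

PseDNC augments the 16 dinucleotide frequencies \(f_u\) with \(\lambda\)
tiers of *sequence-order correlation factors*

\[
\theta_j \;=\; \frac{1}{L-j-1}\sum_{i=1}^{L-j-1} C_{i,\,i+j},
\qquad
C_{i,\,i+j} \;=\; \frac{1}{\mu}\sum_{g=1}^{\mu}
\bigl[P_g(D_i) - P_g(D_{i+j})\bigr]^2 ,
\]

where \(D_i\) is the dinucleotide starting at position \(i\), and the
\(P_g\) are \(\mu = 3\) physicochemical properties — enthalpy, entropy and
free energy — standardized to mean 0 and SD 1 over the 16 dinucleotides
(population SD, i.e. dividing by 16; the standardization makes the
features invariant to affine rescaling of the raw property values, which
is why the exact provenance of the thermodynamic table matters little).
The final vector is

\[
d_u = \frac{f_u}{\sum_i f_i + w\sum_j \theta_j}\ (u \le 16),
\qquad
d_u = \frac{w\,\theta_{u-16}}{\sum_i f_i + w\sum_j \theta_j}\ (u > 16),
\]

which always sums to 1. Defaults and their rationale:

* **λ = 6** — the documented output dimension of this encoder is 22
  features, which forces 16 + λ = 22. Configurable; λ must satisfy
  λ < L − 1.
* **w = 0.1** — the weight balancing composition against sequence order.
  No value is recoverable from the method's description, so the package
  uses the conventional default of the PseDNC lineage and exposes it as a
  parameter. Larger `w` monotonically shifts mass into the θ block.
* **Property table** — the unified nearest-neighbor thermodynamic
  parameters (ΔH in kcal/mol, ΔS in cal/mol/K, ΔG°₃₇ in kcal/mol) for the
  16 dinucleotide steps, shipped as `dinuc_property_table()` and
  overridable from a TSV via `read_property_table()` for users who want a
  different parameterization.
* **Counting mode** — the dinucleotide frequencies use *overlapping*
  counting by default, the convention of the PseDNC lineage and of every
  standard implementation; a literal non-overlapping mode is available
  behind `overlap = FALSE` and both are tested.

## Fusion, ANOVA-F ranking and incremental selection

The two blocks fuse into 500 + 22 = 522 features. Each feature is scored
by the two-class one-way ANOVA F-value
\(F = \mathrm{MS}_{between}/\mathrm{MS}_{within}\) with df (1, n−2) —
scale- and location-free, so no pre-scaling is needed for ranking.
Conventions: a constant feature scores 0; a perfect separator (zero
within-class variance) scores +∞ and ranks above all finite values, ties
broken by column position.

Features are then added one at a time from the top of the ranking; each
nested top-*d* subset is evaluated by stratified cross-validated SVM
accuracy under fixed default hyperparameters (cost 1, gamma 1/d — grid
search happens only *after* the dimension is fixed, keeping the sweep
cheap and comparable across *d*). The optimal dimension is the smallest
*d* attaining the maximum of the accuracy curve (parsimony tie-break).

Two protocols are provided because the classical one is optimistically
biased:

* `mode = "paper"` (default) ranks once on the full dataset and reports
  CV accuracy of each subset on the same data — the protocol behind
  published accuracy-vs-dimension curves, appropriate for reproducing
  them.
* `mode = "honest"` re-ranks within each training fold, so a fold's
  feature subset never sees its test fold; use this when the curve itself
  is the estimate you care about.

The sweep accepts a `dims` grid; sweeping all 522 nested subsets is
supported, and the package's own analyses use a thinned grid (every
dimension up to 20, then progressively coarser steps) that traces the same
curve shape at a fraction of the cost.

## SVM, probability calibration and evaluation

The classifier is a C-SVM with RBF kernel (linear, polynomial and sigmoid
are configurable but not tuned by default), via libsvm through **e1071**.
Features are standardized with training-set mean/SD before fitting
(stored in the model; constant features get SD 1), since an RBF kernel on
fused mixed-scale features is otherwise dominated by the binary block.
Hyperparameters come from an exhaustive grid search over a cost × gamma
lattice scored by stratified CV accuracy; ties resolve to the smallest
cost, then the smallest gamma. The default lattice is the classic libsvm
guide grid (cost 2⁻⁵…2¹⁵, gamma 2⁻¹⁵…2³ in ×4 steps).

A window is called methylated when its predicted probability strictly
exceeds 50%; a tie at exactly 0.5 is a negative call. Probabilities come
from a Platt sigmoid \(p = 1/(1+e^{Af+B})\) fitted by the standard
regularized Newton procedure on decision values collected out-of-fold
from a seeded internal 3-fold CV. The package deliberately does *not* use
libsvm's built-in probability machinery: its internal calibration folds
are drawn from an unseeded C `rand()`, so two identical training runs
give different probabilities, violating the reproducibility contract this
package guarantees (same data + seed ⇒ bit-identical models and reports).
For a binary problem, libsvm's pairwise coupling reduces to this single
sigmoid anyway.

Evaluation is stratified n-fold cross-validation (10-fold by default;
stratification is chosen because the benchmark is balanced and per-fold
Sn/Sp need both classes in every fold), optionally repeated with shifted
fold seeds ("10 times n-fold"). Per fold and on average it reports

* Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC = (TP+TN)/N,
* MCC = (TP·TN − FP·FN)/√((TN+FN)(TN+FP)(TP+FN)(TP+FP)),
* AUC by trapezoidal integration of the threshold-sweep ROC, which equals
  the Mann–Whitney pair-counting probability with ties counting one half.

Zero-denominator conventions: an undefined Sn or Sp is reported as 0 with
a warning; an MCC with any zero factor is 0.

## The synthetic benchmark generator

`simulate_sites()` emulates the real benchmark's structure without
requiring any download: balanced classes of 41-nt A/C/G/T windows with a
central adenine, where

* positives carry a positional composition bias — at the informative
  positions (default 17–19 and 23–25, flanking the center) a designated
  nucleotide (default T) appears with probability 0.25 + 0.75·*effect*;
* negatives are uniform background with the GAGG motif anchored so its
  adenine is the central base (mirroring how the real negatives were
  drawn from GAGG-containing coding sequence).

This plants exactly the two kinds of signal the two encoders are claimed
to capture — positional specificity for the one-hot block, motif/composition
contrast for the k-mer and dinucleotide terms — so end-to-end recovery of
both is testable. The default effect size of 0.5 represents a moderate,
realistic signal; the package's acceptance analyses use 0.8, a strong
planted signal on which a working pipeline should reach ACC ≥ 0.9. What
the generator does **not** emulate: rice genome base composition,
SMRT-seq error structure, or the CD-HIT redundancy filtering of the real
data — so green tests demonstrate that the machinery works, not that any
particular accuracy will transfer to a real genome.

## Reproducing published-scale analyses

The headline numbers reported for this method on the rice benchmark
(ACC 87.44%, Sn 86.93%, Sp 87.95%, MCC 0.75, AUC 0.929 at 131 selected
features) require that external dataset, which is distributed by the
original authors' server and not bundled here. When a user supplies it as
paired FASTA files, the same harness reproduces the protocol:

```r
records <- dplyr::bind_rows(
  read_site_fasta("6mA_positives.fasta", label = 1L),
  read_site_fasta("non6mA_negatives.fasta", label = 0L)
)
pipe <- train_pipeline(records, selection_mode = "paper",
                       cv_folds = 10, seed = 1)
glance(pipe$report)
```

Exact numeric agreement cannot be promised: the original weight factor
`w`, the exact property table and the CV partition are unrecoverable, and
each shifts the third digit of the metrics.

## Worked example at package scale

```{r example, eval = FALSE}
sim <- simulate_sites(n_pos = 200, n_neg = 200, effect_size = 0.8, seed = 1)
fused <- encode_windows(sim)          # 522 features
sel <- incremental_select(fused, dims = c(1:20, seq(25, 200, 25)),
                          folds = 5, seed = 1)
autoplot(sel)                          # accuracy vs dimension
kept <- select_features(fused, sel)
report <- cross_validate(kept, folds = 10, seed = 1)
glance(report)
autoplot(report)                       # pooled ROC
```

The test suite and the acceptance script run this pipeline at
400 + 400 windows with a thinned selection grid and a reduced
(cost 2⁻¹…2⁷ × gamma 2⁻⁹…2⁻¹) lattice — sizes chosen so the whole
analysis re-runs comfortably on a laptop while leaving the statistical
conclusions unchanged; all full-scale settings remain available as
arguments.

## Known limitations

* The positional one-hot block makes the feature space width-specific: a
  model trained at width 41 cannot score other widths (by design).
* The "paper" selection protocol reports optimistically biased curves;
  use `mode = "honest"` for unbiased dimension selection.
* Platt calibration on small training sets (tens of samples) is noisy;
  probabilities near 0.5 should not be over-interpreted there, though
  calls remain stable.
* The generator's independence between positions means it cannot produce
  higher-order positional dependencies (e.g. correlated motifs at two
  sites); discrimination results on it are a functional check, not a
  biological benchmark.
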