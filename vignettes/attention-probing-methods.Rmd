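---
title: "Probing attention maps for molecular contact structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing attention maps for molecular contact structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnprobe)
```

## The question and the pipeline

Transformer language models trained purely on sequences sometimes place a
surprising amount of their self-attention on residue pairs that are in
physical contact in the folded molecule. `attnprobe` implements the full
pipeline for quantifying that phenomenon and for exploiting it:

1. **Ground truth.** Binary contact maps from 3D coordinates (distance
   cutoff) or from dot-bracket secondary structure (base pairs), with a
   near-diagonal exclusion band.
2. **Head assessment.** The per-head agreement statistic `p(f)`: the
   fraction of (optionally thresholded) attention mass falling on true
   contact pairs, pooled over a molecule set.
3. **Featurization.** Symmetrization and average product correction (APC)
   of each attention map, then one sample per eligible token pair with one
   feature per (layer, head), balanced by undersampling.
4. **Classification.** Logistic regression, decision tree, random forest,
   MLP and gradient boosting on the pair table, plus a convolutional
   map-to-map network; predicted probabilities are mirrored, band-zeroed
   and thresholded into predicted contact maps.
5. **Evaluation.** Per-molecule macro-F1 and MCC on the flattened eligible
   pairs, averaged arithmetically across molecules.

A synthetic generator stands in for the two expensive inputs — curated
structure sets and pretrained-transformer inference — by planting a known
contact pattern into simulated attention at a controlled signal fraction.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| distance cutoff | 9.5 | Å | balances specificity and sensitivity of tertiary contact maps |
| exclusion window `w` | 4 (RNA), 6 (protein) | positions | removes chain-adjacency contacts the model already knows from the primary structure |
| agreement threshold `θ` | 0.3 (or none) | attention weight | counts only confident weights; the threshold-free variant uses all mass |
| test fraction | 0.15 | — | 85–15 molecule-level split; 425 molecules give 362 train / 63 test |
| batch schedule | 5 geometric steps from 20 | molecules | probes learning convergence from a 20-molecule pilot up to the full training set |
| decision threshold | 0.5 | probability | converts predicted probabilities into binary maps |
| signal fraction `α` | experiment-specific | — | share of each aware head's row mass placed on true contacts |

All defaults live in one place per function signature and are echoed into
every artifact's provenance, so no run depends on hidden state.

## The agreement statistic

For head \((l,h)\) over molecules \(x \in X\):

\[
p(f) \;=\; \frac{\sum_x \sum_{(i,j)} f(i,j)\,\ell(a_{ij})}
               {\sum_x \sum_{(i,j)} \ell(a_{ij})},
\qquad
\ell(a) = \begin{cases} a\,[a > \theta] & \theta \text{ set}\\ a & \theta \text{ absent.}\end{cases}
\]

`p(f)` is a weighted mean of the contact indicator, hence always in
\([0,1]\): 0 when no mass touches contacts, 1 when all of it does, and the
contact density of the summed-over pair set under uniform attention. Setting
\(\theta = 0\) reproduces the threshold-free variant exactly on strictly
positive attention; both are tested to agree to \(10^{-12}\).

Two conventions are deliberately explicit because they change the number:

* **Mask policy.** `band_excluded` (the default) removes pairs with
  \(|i-j| \le w\) from numerator *and* denominator, matching the exclusion
  applied to the contact maps; otherwise purely local heads dominate the
  denominator with mass that can never score. `all` keeps every \((i,j)\),
  including the diagonal, and reproduces the unmasked reading.
* **Raw vs processed.** Agreement is computed on raw attention by default,
  since the statistic is defined on attention weights directly;
  `use_processed = TRUE` scores symmetrized/APC maps instead (APC can make
  weights negative, so thresholding then means something different).

Heads whose denominator is zero (e.g. every weight below \(\theta\)) score
0 and are flagged with a warning rather than returning `NaN`.

## Processing order: symmetrize, then APC

Attention is row-stochastic and asymmetric; a token pair should count the
same in both orientations, so maps are symmetrized as \((A + A^\top)/2\)
(the arithmetic mean preserves total mass and is idempotent). APC then
subtracts the rank-1 background \(r_i c_j / T\), removing per-position
attention trends; any rank-1 matrix is annihilated exactly. The order is
fixed — symmetrize first, then correct — and note that the two operations do
not commute: for \(\begin{pmatrix}1&2\\3&4\end{pmatrix}\), symmetrizing
first yields \(\pm 0.225\), while APC alone yields \(\pm 0.2\). A stack of
all-zero maps has no defined APC and raises a structured error naming every
offending head.

## What the synthetic generator emulates

`gen_secondary()` builds nested stem-loop structures by recursive placement
(stems 3–6 bp, loops ≥ 3 nt, occasional multiloops and bulges), optionally
adding one crossing stem on the `[` tier as a pseudoknot.
`gen_tertiary_map()` adds sparse long-range contacts (each residue in at
most two extras) to emulate what a 9.5 Å cutoff picks up beyond base pairs.
Sequences are random ACGU with Watson–Crick partners under stems.

`gen_attention_stack()` plants the signal: each row of an *aware* head is
\(\alpha\,C_{i\cdot}/\deg(i) + (1-\alpha)\,\varepsilon\), where
\(\varepsilon\) is Dirichlet-style noise (normalized Gamma draws) and rows
without contacts put their signal share on the diagonal (self-attention,
which the exclusion band removes from scoring). *Unaware* heads follow a
locality kernel \(e^{-|i-j|/2}\) plus noise — the near-diagonal attention
profile typical of uninformative heads. Every row is non-negative and
renormalized to sum to 1, matching the softmax contract.

What this deliberately does **not** emulate: thermodynamically realistic
folding, the heavy-tailed and highly correlated statistics of real
transformer attention, length-dependent attention artifacts, or
special-token effects (the provider contract requires those rows/columns to
be stripped before the stack enters the pipeline). Passing tests therefore
demonstrate that the pipeline's mathematics and plumbing are correct and
that it recovers planted signal at the stated strength — not that any
particular language model encodes structure.

## Evaluation conventions

* Scoring is restricted to **eligible pairs** (upper triangle,
  \(j - i > w\)) — the same sample space the classifiers saw. Scoring all
  pairs would inflate the non-contact class with band entries that are zero
  by construction on both sides.
* **Macro-F1** is the unweighted mean of the contact-class and
  non-contact-class F1; a class with an empty denominator contributes 0.
* **MCC** is 0 whenever its denominator is 0 (e.g. a contact-free truth);
  such molecules are flagged `degenerate` rather than dropped.
* Dataset means are arithmetic over scored molecules; molecules with no
  eligible pairs are skipped and listed with a reason.
* The few-shot experiment reports two complementary numbers. Sample-level
  macro-F1 is computed on a **balanced** held-out pair table, because that
  is the scale on which a chance-level classifier scores 0.5 (on the raw,
  heavily imbalanced pair space a coin-flip prediction scores macro-F1
  ≈ 0.37 at typical contact densities, which makes "at chance" hard to
  read). Map-level mean MCC over all eligible pairs is reported alongside,
  whose chance level is 0 regardless of imbalance.

## Numerical and design choices

* **Atom mode.** Whether the distance cutoff applies to the minimum over
  heavy-atom pairs or to one representative atom per residue is genuinely
  ambiguous for contact-map construction from coordinates; both are
  provided. The default is the minimum-distance reading (most inclusive);
  `representative_atom` uses C3′ for RNA and CB (CA fallback) for protein.
* **Split arithmetic.** The test-set size is `max(1, floor(f·n))`:
  425 molecules at 15% give exactly 362/63. All splitting is molecule-level,
  so no pair of a held-out molecule can leak into training.
* **Balancing** happens globally on the pooled training table (per batch),
  by undersampling the majority class without replacement; minority samples
  are never discarded, and the subsample is a pure function of the seed.
* **Tie-breaks.** `rank_heads()` orders by descending score, then ascending
  (layer, head), so rankings are total and reproducible.
* **Indices.** The R API is 1-based throughout; on-disk edge lists are
  0-based (documented format) and CT files 1-based (their convention).
  Conversion happens only at IO boundaries.
* **Determinism.** Every stochastic step (corpus generation, balancing,
  splitting, stochastic fitters) flows through explicit integer seeds;
  stochastic backends run single-threaded with fixed seeds. Provenance
  files contain no timestamps, so identical runs are byte-identical.
* **Convolutional predictor.** The map-to-map network is implemented
  natively in R (im2col convolutions on BLAS, Adam, class-weighted binary
  cross-entropy on eligible pixels only, output symmetrized as
  \((P + P^\top)/2\) so predictions are symmetric by construction). The
  default topology is 3×3 kernels with channels \(L\cdot H\)→64→64→32→1 and
  dilations 1-2-4-1 — an explicit stand-in architecture, not a tuned model.
  Training cost grows with the padded length squared, so it is best suited
  to the short-molecule corpora used here.

## Problem sizes

The validation suite runs entirely on synthetic corpora sized for quick,
repeatable feedback: oracle equivalence on hundreds of random instances up
to N = 64; planted-head recovery on 50 molecules with a 6 × 12 head grid;
the few-shot contrast with 20 training and 10 held-out molecules of 40–80 nt
per signal fraction; and the convolutional network on 24–30 nt molecules
with reduced channel widths. These sizes are the package's chosen study
conditions; all of them are parameters, and nothing in the implementation
caps the scale.

## Known limitations

* No adapter to a real pretrained language model ships with the package;
  the `AttentionProvider` contract (see `file_attention_provider()`)
  documents exactly what such an adapter must return — residue-by-residue,
  row-normalized maps with special tokens stripped.
* Tabular hyperparameters are the backing libraries' defaults, recorded in
  provenance; no hyperparameter search is performed.
* Contact-map evaluation is the only benchmark; 3D-superposition metrics
  (RMSD, TM-score) are out of scope, and the report notes when an external
  benchmark would need them.
* Modified residues are rejected rather than remapped; multi-chain
  structures are handled one selected chain at a time, first model only.
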