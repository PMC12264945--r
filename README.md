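# attnprobe

Do the self-attention maps of sequence language models encode molecular
structure? `attnprobe` is an R toolkit for answering that question for RNA
and protein sequences. It builds binary residue contact maps from 3D
coordinates or dot-bracket secondary structure, quantifies how much of each
attention head's weight falls on true contacts, turns processed attention
maps into token-pair feature tables, trains lightweight classifiers that
predict contact maps from those features, and scores the predictions with
macro-F1 and the Matthews correlation coefficient (MCC). A synthetic-data
module plants a tunable amount of structural signal into simulated attention
stacks, so the entire pipeline can be exercised and validated without
downloading any pretrained transformer.

The package is aimed at structural bioinformaticians and interpretability
researchers who want a tested, deterministic reference implementation of the
attention-probing pipeline — from structure files to evaluation reports —
plus a controlled sandbox for studying when the approach can and cannot work.

## The core quantities

**Contact maps.** For tertiary structure, residues *i* and *j* are in
contact when their inter-residue distance is at most a cutoff (9.5 &#8491; by
default; minimum over heavy-atom pairs, or a representative atom per
residue). For secondary structure, contacts are the base pairs of a
dot-bracket string, including pseudoknot tiers (`[]`, `{}`, `<>`,
`Aa`–`Za`). Near-diagonal contacts with |i − j| ≤ *w* (*w* = 4 for
nucleotides, 6 for amino acids) are removed so models must learn long-range
structure rather than chain adjacency.

**Head agreement.** For each attention head, over a molecule set *X*:

```
         Σ_x Σ_{i,j} f(i,j) · ℓ(a_ij)
p(f) =  ------------------------------ ,   ℓ(a) = a·1[a > θ]  (or ℓ(a) = a)
         Σ_x Σ_{i,j} ℓ(a_ij)
```

where `f(i,j)` is 1 for contact pairs and `a_ij` is the attention weight.
With the conventional threshold θ = 0.3 only confident weights count; the
threshold-free variant (`theta = NULL`) uses all of them. `p(f)` is the
fraction of (thresholded) attention mass that lands on true contacts: ~1
for a structurally aware head, and ~the contact density for an
uninformative one.

**Features and classifiers.** Attention maps are symmetrized
(`(A + Aᵀ)/2`) and refined by the average product correction
(`a_ij − rowsum_i·colsum_j/total`), then every eligible token pair becomes
one sample with one feature per (layer, head). The heavily imbalanced
tables are balanced by undersampling the majority class. Five tabular
classifiers (logistic regression, decision tree, random forest, MLP,
gradient boosting) plus a small convolutional map-to-map network are
available; predicted maps are flattened over eligible pairs and scored per
molecule with macro-F1 and MCC, then averaged.

## Worked example

Generate a 30-molecule synthetic corpus whose last-layer heads 10–12 mix
80% true contact pattern with 20% noise, then ask which heads look
structurally aware:

```r
library(attnprobe)

spec   <- synthetic_spec(n_molecules = 30, alpha = 0.8, seed = 42)
corpus <- gen_corpus(spec)
grid   <- agreement_scores(corpus$stacks, corpus$maps, theta = NULL)
rank_heads(grid, 5)
#> # A tibble: 5 × 3
#>   layer  head  score
#>   <int> <int>  <dbl>
#> 1     6    11 0.786
#> 2     6    12 0.785
#> 3     6    10 0.785
#> 4     6     8 0.0154
#> 5     3     7 0.0153
```

The three planted heads (layer 6, heads 10–12) stand out at p(f) ≈ 0.79 —
roughly the planted signal fraction — while every other head sits at the
background contact density (~0.015). `autoplot(grid)` draws the standard
layer-by-head heatmap.

The few-shot contrast between structure-aware and structure-unaware
attention:

```r
fewshot_experiment(alpha = 1, n_train = 20, n_test = 10, seed = 42)
#>   alpha f1_macro mean_mcc n_train n_test n_test_pairs
#> 1     1        1        1      20     10          494
fewshot_experiment(alpha = 0, n_train = 20, n_test = 10, seed = 42)
#>   alpha f1_macro mean_mcc n_train n_test n_test_pairs
#> 1     0    0.517   0.0108      20     10          462
```

With fully structure-aware attention (`alpha = 1`), a logistic probe
trained on just 20 molecules predicts held-out contact maps perfectly
(macro-F1 = 1, MCC = 1); with pure noise (`alpha = 0`) it performs at
chance (macro-F1 ≈ 0.5 on balanced held-out pairs, map-level MCC ≈ 0).

## Command line

Every stage is also a CLI subcommand (1:1 with the functions above), via
the wrapper installed at `inst/cli/attnprobe.R`:

```sh
Rscript inst/cli/attnprobe.R simulate   --out corpus --seed 7 --alpha 0.8
Rscript inst/cli/attnprobe.R assess-heads --corpus corpus --theta none --out heads.tsv
Rscript inst/cli/attnprobe.R featurize  --corpus corpus --out-dir feat --seed 7
Rscript inst/cli/attnprobe.R train      --dataset feat/pairs.tsv --split feat/split.json \
                                        --kind logistic --seed 7 --out model.rds
Rscript inst/cli/attnprobe.R predict    --model model.rds --corpus corpus \
                                        --split feat/split.json --ids test --out-dir pred
Rscript inst/cli/attnprobe.R evaluate   --corpus corpus --pred-dir pred --out report.json
```

Each run echoes its effective configuration and writes a `provenance.json`
(config, seeds, package version, input hashes). Reruns with the same seeds
produce byte-identical outputs.

## File formats

* **Contact maps**: TSV edge list `i<TAB>j` (0-based, i &lt; j, with an
  `# n=... window=...` header), or a dense 0/1 text matrix.
* **Structures**: PDB/mmCIF (read via bio3d), dot-bracket `.dbn`
  (with or without FASTA-style headers), CT, FASTA.
* **Attention stacks**: an RDS array container holding the
  (L, H, N, N) weights plus a JSON sidecar with molecule id, dimensions,
  and processing state; validated on load.
* **Pair datasets**: columnar TSV (`molecule_id`, `i`, `j`, `label`,
  one column per `layerX_headY` feature; indices 0-based on disk).

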