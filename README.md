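# sspipe

Three-state protein secondary-structure prediction in R: sliding-window
PSSM features plus physicochemical descriptors, a one-vs-one RBF-SVM
classifier, rule-based smoothing of the predicted string, and rigorous
segment-level evaluation.

## The problem

Given a protein's amino-acid sequence, predict for every residue whether it
sits in an α-helix (H), a β-sheet (E) or coil (C). Modern predictors reach
70–80% per-residue accuracy by encoding each residue with its evolutionary
profile — the L×20 position-specific scoring matrix (PSSM) produced by
iterative PSI-BLAST searches — and feeding a window of profile columns to a
classifier. This package implements that approach augmented with four
physicochemical signals, and ships everything needed to exercise and test
the pipeline without any external sequence database: a DSSP 8→3 state
reducer, a PSI-BLAST ASCII PSSM parser/writer, and a synthetic-data
generator that emulates segmental structure, class-conditional residue
composition and profile signal.

It is aimed at structural-bioinformatics practitioners and at anyone who
needs a tested, self-contained reference implementation of the classical
SVM/PSSM secondary-structure stack — in particular of the SOV94 and SOV99
segment-overlap scores, which are easy to get subtly wrong.

## The method

For residue *i* with window size *WS* (odd, 7–19), the feature vector
concatenates:

- the 20 PSSM log-odds values of each of the *WS* window positions,
  min-max normalized from fixed bounds (−10, 10) into [0, 1] (positions
  outside the chain contribute zero blocks), and
- six scalars for the central residue: its conformational propensities
  *S<sub>iH</sub>, S<sub>iE</sub>, S<sub>iC</sub>*, where
  *S<sub>ij</sub> = a<sub>ij</sub>/a<sub>i</sub>* is the fraction of
  occurrences of amino acid *i* observed in class *j* over the training
  chains, plus its net charge, Kyte–Doolittle hydropathy and side-chain
  mass, each rescaled to [0, 1],

giving 20·WS + 6 dimensions (266 at the default WS = 13). Classification
is one-vs-one: three binary RBF-SVMs (H/E, E/C, C/H; libsvm via `e1071`)
with max-wins voting, vote ties resolved by training-class frequency and
then the fixed order C > H > E. A grid-search harness evaluates the 6×6
grid C ∈ 2⁰…2⁵, γ ∈ 2⁻⁶…2⁻¹ per window size by 3-fold cross-validation
with folds that partition whole chains. Predictions are then refined by
consensus-length rules — an H with a non-H neighbour, or an E with no E
neighbour, is replaced by the majority label of the surrounding 7-residue
segment — reflecting that a lone residue cannot form a helix (minimum run
3) or a sheet (minimum run 2). Evaluation reports Q3, per-class
precision/recall with the pooled confusion matrix, and both segment
overlap scores (SOV94 and SOV99, which differ in the overlap allowance δ
and the normalization N).

## Worked example

```r
library(sspipe)
d    <- simulate_dataset(sim_spec(n_chains = 60, len_range = c(40, 100), seed = 11))
fold <- make_folds(60, 3, seed = 11)
fit  <- ss_fit(d[fold != 1], ws = 13)
fit
#> One-vs-one RBF-SVM secondary-structure model
#>   3 binary classifiers (H/E, E/C, C/H); C = 2, gamma = 0.0625
#>   window size 13 -> 266 features per residue
#>   trained on 40 chains (2778 residues)

pred <- predict(fit, d[fold == 1])
filt <- apply_filter(pred)
ss_evaluate(d[fold == 1]$states, filt)
#> Secondary-structure evaluation (20 chains, 1404 residues)
#>   Q3    = 76.00
#>   SOV94 = 94.76
#>   SOV99 = 61.81
#>     H   E   C Recall (%)
#> H 402  25 128      72.43
#> E  38 147  66      58.57
#> C  56  24 518      86.62
#> Precision (%): H=81.05  E=75.00  C=72.75
```

Q3 = 76.00 means 76% of the 1404 held-out residues received the correct
class (against a 44% majority-class floor). SOV99 is lower than Q3 because
it scores whole segments and penalizes fragmented predictions; SOV94 is
higher because its looser overlap allowance and normalization are generous
to over-segmented output. The filter's effect is visible on a single
chain — isolated wrong labels are absorbed into their surrounding
segments:

```r
cat(pred[1]); cat(apply_filter(pred[1]))
#> HEECCECCEECCCCCCCCHHHHHHHEHHECCHEEHHHHHHHCCEHCCCCCC...
#> EEECCCCCEECCCCCCCCHHHHHHHHHHHCCEEEHHHHHHHCCCCCCCCCC...
```

Real-data use is the same shape: `read_fasta()` + `read_ss()` +
`parse_pssm()` per chain, `ss_dataset()` to bundle them, then
`ss_fit()`/`predict()`. A command-line front end covering every stage
(`simulate`, `pssm-synth`, `encode`, `gridsearch`, `train`, `predict`,
`filter`, `evaluate`, `reduce`) is installed at
`system.file("cli", "sspipe.R", package = "sspipe")`.

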