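---
title: "Methods: the sspipe secondary-structure prediction pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sspipe secondary-structure prediction pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind `sspipe`, the design
decisions that were genuinely open, the numerical conventions, and what the
package's synthetic benchmark does and does not demonstrate.

## The prediction model

Secondary-structure prediction is a per-residue 3-class problem: each
position of a protein chain is helix (H), sheet (E) or coil (C), with true
labels conventionally obtained by reducing the eight DSSP states. Five
reduction conventions are implemented (`reduce_structure()`); the default
maps {H, G, I}→H, {E}→E and the rest→C, the convention used by most
comparable predictors. The choice matters: schemes differ on the rare
states I and B, and reported accuracies are not comparable across schemes.

### Features

The feature vector of residue *i* concatenates a sliding window of PSSM
columns with six scalars describing the central residue:

* **PSSM block** (20·WS values). PSI-BLAST log-odds scores are integers,
  in practice almost always within ±10. They are mapped into [0, 1] by a
  fixed linear transform `(x + 10)/20`, clipped at the ends. Fixed bounds —
  rather than dataset min/max — make the train-time and prediction-time
  transforms identical without carrying dataset statistics around; the
  bounds are stored in the fitted model regardless, so a model predicts
  correctly even if the default ever changes. A logistic alternative
  `1/(1+e^{-x})`, common in this family of predictors, is available via
  `normalize_profile(method = "logistic")`.
* **Conformational propensities** (3 values). `S[i, j] = a_ij / a_i`, the
  fraction of occurrences of amino acid *i* lying in class *j*, computed by
  pooled counts over the *training* chains only. Computing them from the
  training fold rather than the whole dataset costs a little accuracy but
  avoids leaking test labels into the features; the whole-benchmark
  reference table is shipped separately (`reference_conformation()`) for
  comparison and for driving the simulator. Amino acids never observed get
  a flagged uniform row (1/3, 1/3, 1/3) — "no information" rather than an
  arbitrary zero.
* **Net charge** (1 value). −1/0/+1 per residue (D, E negative; R, H, K
  positive), mapped to {0, 0.5, 1}. Like charges along the chain disrupt
  helix hydrogen bonding, so charge carries structural signal.
* **Hydropathy** (1 value). The Kyte–Doolittle scale, min-max scaled over
  its own range [−4.5, 4.5]. Periodic hydrophobicity is a helix signature.
* **Side-chain mass** (1 value, Da). Scaled over the table range
  [1.0079 (G), 130.1689 (W)]. Bulky side chains destabilize helices; sheet
  residues tend to be small.

Scaling ranges for the three physicochemical scalars are the fixed table
ranges, never data-dependent, and each feature is scaled individually.
The layout — window blocks first, the six central-residue scalars last —
gives dimension 20·WS + 6: 146, 186, 226, 266, 306, 346, 386 for
WS = 7…19. The scalars are computed for the central residue only; making
them per-position would multiply them by WS and break these counts.

**Edge padding.** Window positions falling outside the chain contribute
all-zero PSSM blocks. Zero is "no evidence" under the min-max transform
(it is the image of the lower clip bound); an alternative half-value
padding (0.5, the image of score 0) is available via `pad = "half"` for
users who prefer "neutral score" semantics. The choice measurably affects
only the few residues within WS/2 of the termini.

Non-standard residue codes (B, Z, X, U, O) are accepted by default and
treated as unknowns: uniform propensities, zero charge, mid-range
hydropathy and mass. A strict policy that rejects them is available.

### Classifier

The 3-class problem is decomposed one-vs-one: three binary soft-margin
SVMs with RBF kernel `exp(-γ‖u−v‖²)` on the class pairs H/E, E/C and C/H
(k(k−1)/2 = 3 for k = 3). The binary optimizer is libsvm through
`e1071::svm`; the package owns everything around it — the decomposition,
the (H, E, C) → (−1, +1, +2) label convention used in exported training
files, max-wins voting, and tie handling. With three voters a full
three-way tie (one vote each) is possible; it is resolved deterministically
by highest training-class frequency, then by the fixed order C > H > E
(coil being the safest default call). Defaults C = 2, γ = 2⁻⁴, WS = 13 are
the values found optimal by grid search on the CB513 benchmark in the
literature this implements.

### Model selection

`ss_grid_search()` evaluates the 6×6 grid C ∈ 2⁰…2⁵ × γ ∈ 2⁻⁶…2⁻¹ for
each window size by k-fold cross-validation (default 3), scored by
residue-level Q3 pooled over test folds. Two decisions here were open:

* **Folds partition chains, not residues.** Adjacent residues share most
  of their windows; residue-level folding would place near-duplicates of
  test rows in the training set and inflate CV accuracy. Chains are
  shuffled once (seeded) and dealt round-robin.
* **Conformation tables are recomputed per fold** from that fold's
  training chains, for the same no-leakage reason.
* **Accuracy ties** are broken toward the smallest window size, then the
  smallest C, then the smallest γ — preferring the cheapest model among
  equals.

### Filter

The post-filter encodes minimum-run physics: helices shorter than 3 and
sheets shorter than 2 residues are physically implausible. Scanning every
position *i* of the prediction:

* **Case H** — if `str(i)` is H and both neighbours are H, keep it;
  otherwise replace it with the majority label over positions *i*−3…*i*+3.
* **Case E** — if `str(i)` is E and either neighbour is E, keep it;
  otherwise replace by the same segment majority.

C positions are never examined. Three details the rules leave open are
fixed as follows:

* **Frozen-copy semantics** (default): all reads use the original string,
  all writes go to a fresh copy, so the result is independent of scan
  order and replacements cannot cascade within the pass. A sequential
  in-place mode is provided for comparison (`mode = "sequential"`).
* **Chain ends**: a neighbour beyond the terminus counts as "not H"/"not
  E", so terminal H/E residues are always majority-checked, and the
  examined segment is clipped to the chain. A terminal singleton helix is
  exactly the kind of artifact the filter exists to remove.
* **Majority ties** keep the original label (least intervention).

One pass only; the rules are not iterated to convergence. Note the rules
do not *guarantee* the minimum run lengths — they only remove
locally-unsupported labels — and the package deliberately does not add a
stricter enforcement pass.

### Evaluation

Q3 is the percentage of correctly labelled residues. Precision and recall
per class come from the pooled 3×3 confusion matrix (rows observed,
columns predicted); undefined ratios are reported as `NA`, never 0.

The segment overlap score rewards getting whole segments right. For every
class and every overlapping pair (s1 observed, s2 predicted) of segments
of that class, the pair contributes `(minov + δ)/maxov · len(s1)`, where
`minov` is the actual overlap, `maxov` the total extent, and δ an
allowance. The two published conventions differ exactly where
implementations tend to diverge, so both are spelled out:

* **SOV99**: δ = min(maxov − minov, minov, ⌊len(s1)/2⌋, ⌊len(s2)/2⌋)
  (integer floor division), and the normalization N sums len(s1) over
  every counted pair *plus* every observed segment with no partner.
* **SOV94**: δ = min(maxov − minov, minov), and N is the total observed
  residue count with each observed segment counted once. Because one
  observed segment overlapping several predicted segments contributes
  several numerator terms against a single normalization term, this
  convention can nominally exceed 100 on fragmented predictions; the
  reported score is capped at 100. This permissiveness is visible in
  practice: filtering a fragmented prediction *lowers* SOV94 while
  raising SOV99 — the newer score is the one that actually penalizes
  fragmentation.

Multi-chain evaluation pools numerator and normalization sums (and
confusion counts) across chains before dividing, matching whole-dataset
reporting practice. Scores are kept at full precision; only printing
rounds to 2 decimals. The implementation is verified against an
independent brute-force oracle (literal position-set enumeration) on a
thousand random string pairs to 10⁻⁹ in the test suite.

## The synthetic benchmark

`sim_spec()`/`simulate_dataset()` generate data with exactly the
statistical structure the pipeline exploits, so every stage is testable
offline:

* **Segmental structure**: alternating class runs with hard minimum
  lengths (H ≥ 3, E ≥ 2, C ≥ 1) and geometric-with-floor run lengths,
  mean 9/5/6 for H/E/C — roughly the scale of real helices, strands and
  loops. Structured segments are followed by coil 85% of the time; coil
  is followed by helix 62% of the time, mirroring the roughly 35:21 H:E
  abundance ratio of real benchmarks. Chain lengths are uniform on
  40–100 residues and 200 chains is the default benchmark size — sizes
  chosen so a full simulate→encode→train→predict→filter→evaluate cycle
  completes in a couple of minutes on a single CPU while still containing
  thousands of segments.
* **Class-conditional composition**: residue emission probabilities per
  class are obtained by Bayes inversion of a propensity table under a
  uniform residue prior, sharpened by an exponent (default 3) before
  normalization. The exponent is the difficulty knob: at 1 the
  composition signal is weak and end-to-end Q3 hovers near 60; at the
  default 3 it lands in a discriminative 65–90 band, high enough above
  the ~44% majority baseline to detect regressions and low enough that
  improvements (e.g. from the filter) remain visible.
* **Profile signal**: synthetic PSSMs carry integer background scores
  (discretized normal centred at −2, clipped to [−9, 4]) and, with
  probability `signal` (default 0.8) per row, an elevated true-residue
  score in [5, 10]. At `signal = 1` the true residue is strictly maximal
  in every row; at 0 the profile is pure noise, which the tests verify by
  a chi-square independence check.

What the generator deliberately does **not** emulate: homology between
chains, the long-tailed length distribution of real proteins, correlated
PSSM columns (real profiles reflect substitution matrices and alignment
depth), amphipathic periodicity, and any coupling between the profile and
the *structure* beyond what composition carries. Consequently, passing
the synthetic end-to-end test shows the machinery is correct and the
feature→classifier→filter chain extracts the signal that is present; it
does not certify real-data accuracy figures, which require real PSSMs
from an iterated database search.

## Statistical design of the recovery test

The propensity estimator is validated by recovery: simulate data from a
known table, re-estimate, compare. Two designs are used with deliberately
different roles:

* **Direct recovery** draws 50,000 classes per amino acid from the
  reference table. Each of the 60 estimated cells then has binomial
  standard error at most √(0.25/50,000) ≈ 0.0022, so the asserted bound
  of 0.02 sits at ~9σ — a real implementation error fails it, sampling
  noise essentially never does.
* **Generator recovery** runs the full chain simulator at ~50,000 *total*
  residues (≈2,500 per amino acid). At that size the worst per-cell SE is
  ~0.01, and the *maximum* deviation over 60 cells concentrates around
  2.3–2.5σ ≈ 0.023 — an absolute cap of 0.02 would fail most healthy
  runs purely by chance. The assertion there is therefore the
  statistically meaningful one: every cell within 5 standard errors of
  its expectation under the realized class counts (and a mean absolute
  deviation well under 0.02). This is a general lesson baked into the
  suite: tolerances on max-statistics must be set from the noise scale of
  the maximum, not of a single cell.

## Numerical conventions, degenerate inputs, reproducibility

* PSSM files: the PSI-BLAST ASCII layout is parsed by locating the
  residue-letter header; columns are permuted to the package's canonical
  alphabetical order at parse time; rows with fewer than 20 parseable
  values, or residue letters disagreeing with a supplied chain, raise
  errors naming the line/position. A matching writer round-trips profiles
  for fixtures.
* Empty inputs error explicitly (empty FASTA, empty chain list); an empty
  feature matrix predicts an empty label vector; `segmentize("")` is an
  empty segment table.
* SOV with no observed segments (empty normalization) returns `NA` rather
  than 0.
* All stochastic stages (simulation, profile synthesis, corruption, fold
  assignment, training) take explicit integer seeds and restore the
  caller's RNG state; identical seeds give byte-identical outputs,
  which the suite asserts end-to-end.
* Model objects carry their full preprocessing state (normalization
  bounds, conformation table, window size, padding, class frequencies),
  so `saveRDS()`/`readRDS()` is a complete single-file model bundle.

## Problem sizes in the shipped tests

The suite trains on deliberately small simulated sets (tens of chains,
30–60 residues) for the unit tests, and one full-scale run — 200 chains,
two-thirds/one-third chain split, WS = 13 — for the end-to-end check,
which must beat the majority-class baseline by ≥ 15 Q3 points. Grid-search
tests use restricted grids on separable data, where every grid point
reaches ~100% and the documented tie-breaking order is observable.

## Known limitations

* The SVM backend is exact libsvm; training cost grows steeply with
  residue count, so full-scale grid searches over all 252 combinations are
  practical only on modest datasets or with subsampling.
* The filter is a single local pass; it will not repair a helix broken by
  an interior C (C positions are never examined), nor enforce minimum run
  lengths outright.
* Probability calibration, one-vs-rest decomposition, non-RBF kernels and
  8-state prediction are out of scope.
* Running PSI-BLAST itself is out of scope: the package parses and
  synthesizes profiles but never executes the search. For real
  reproduction, generate PSSMs with 3 iterations against a
  low-complexity-masked non-redundant database under BLOSUM62, then feed
  the resulting ASCII matrices to `parse_pssm()`.
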