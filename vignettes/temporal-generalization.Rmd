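---
title: "Temporal generalization decoding: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal generalization decoding: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgdecode)
```

## The question the method answers

When an evoked response can be decoded from multichannel MEG/EEG recordings
over several hundred milliseconds, two very different neural architectures
can produce that time course. A *serial* chain of short-lived sources
produces decodable information at every moment, but carried by a different
sensor pattern each time. A *sustained* source produces the same pattern
throughout. Time-resolved decoding alone cannot tell these apart.

Temporal generalization does: train a classifier at every time sample
\(t\) and test it at every other sample \(t'\). The resulting
train-time × test-time performance matrix is *diagonal* for serial dynamics
(each classifier works only near its own training time) and *square* for
sustained dynamics (every classifier works everywhere the code is active).
A third signature matters too: when the underlying pattern flips polarity
between \(t\) and \(t'\), the classifier's predictions invert and the AUC
falls *significantly below* 0.5 — anti-generalization, evidence of a
sign-reversed source rather than an uninformative one.

## The decoding model

For one subject, trials are epoched into a `trials × channels × samples`
array (`epochs_set`). A decoding contrast assigns each analyzed trial
\(y \in \{-1, +1\}\) (standard/deviant), from either the *local* factor
(fifth sound differs from the preceding four) or the *global* factor (rare
sequence within the block) of the local–global oddball design.

At every training time, within each fold of a stratified cross-validation:

1. **Per-channel z-scoring**, with mean and SD estimated on the training
   trials only. A channel constant in training gets SD 1, mapping it to
   zeros rather than dividing by zero.
2. **Linear soft-margin SVM** (hinge loss) with the regularization constant
   fixed at \(C = 1\) — no tuning, no feature selection, dimensionality is
   modest by design. Per-trial *sample weights* proportional to the inverse
   subclass frequency (LSGS/LDGS/LSGD/LDGD) equalize each category's total
   contribution to the hyperplane, protecting the local and global contrasts
   from the block-composition imbalance. The weighted dual is solved by an
   SMO solver with per-sample box constraints (`src/svm_smo.cpp`); its
   stopping tolerance (1e-3 on the KKT violation) follows libsvm's default,
   and equal-weight solutions are cross-checked against libsvm (via e1071)
   in the test suite.
3. **Platt calibration**: a sigmoid from decision values to the probability
   of the deviant class, fitted by regularized maximum likelihood on the
   training-fold decision values (Newton iterations with backtracking, the
   shifted-target variant). No inner calibration split is used — the
   calibration is monotone, so per-cell AUC is unaffected; calibration only
   harmonizes the probability scale when predictions are pooled across
   folds.

Each fold's models are then applied to the held-out trials at *every* test
sample. Training trials at time \(t\) never contribute test predictions at
any \(t'\) — with autocorrelated signals this hygiene is what prevents
noise-driven "generalization". Pooling gives exactly one prediction per
trial per (train, test) cell; one AUC per cell summarizes performance
(`run_tgm()`, or the `tgm()` front end). The AUC uses the Mann–Whitney
convention (ties count ½), so `auc(s, y) * n1 * n2` *is* the U statistic —
effect size and test statistic are the same object on two scales.

**Pooled versus fold-averaged AUC.** Per-trial predictions are pooled
across folds before computing one AUC per cell, rather than averaging ten
per-fold AUCs. With five held-out trials per class per fold, per-fold AUCs
are extremely coarse (steps of 0.04 and worse); pooling gives each cell a
single estimate over all trials, with each trial predicted exactly once.

## Statistics

*Within subject*, the per-cell probabilities are tested with the
Mann–Whitney U test, trials as the random variable — no distributional
assumption on the classifier outputs, which are decidedly non-Gaussian.
*Across subjects*, per-subject AUCs are tested against chance (or paired
differences against zero) with the Wilcoxon signed-rank test. All tests are
two-sided by default because below-chance cells are meaningful here.

For \(n \le 25\) subjects the signed-rank p-value is computed from the
exact sign-flip null — including under ties, via a dynamic-programming
convolution over the observed midranks. This matters in practice: in
high-SNR simulations many subjects sit at AUC = 1.0 exactly, the
differences from chance tie, and the tie-corrected normal approximation at
\(n = 10\) (p ≈ 0.0056 where the exact value is 2/1024 ≈ 0.0020) is too
conservative to survive the FDR step-up over thousands of cells.

Multiple comparisons over the \(T^2\) cells are handled with
Benjamini–Hochberg FDR (`fdr_correct()`, a thin wrapper over
`p.adjust(method = "BH")` that also reports the data-dependent threshold).
One family per map: all train × test cells of a subject's matrix for
within-subject masks, all cells of the group p-map for group masks.

**Generalization duration** summarizes a mask: for each training time, the
number of significantly decoded test samples (× 1000/`sample_rate` ms),
averaged over training times whose *diagonal* cell is significant. The
analysis window defaults to the span of diagonal-significant times — the
data-driven analogue of restricting to the window where diagonal decoding
beats chance (e.g. 82–450 ms for an auditory mismatch response) — and a fixed window
can be supplied instead. For the simulation studies the *group-level* mask
is used: within a single subject, a classifier can generalize to another
generator's window by chance (two random 20-dimensional projections are
never quite orthogonal), with a sign that is random per subject; these
chance alignments cancel in the across-subject test but would inflate
per-subject duration estimates. Both aggregations are exposed
(`tgm_group_stats()` / `within_subject_map()`).

## The generative simulator

`simulate_subject()` implements the generator model: generator \(g\)
projects onto the \(n_c\) sensors with coefficients \(C_g \sim N(0, 1)\)
and is active with unit amplitude over a half-open sample window. A trial
of class \(y\) is

\[ S(c, t) = y \sum_g A_g(t)\, s_g(t)\, C_g(c) + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2) \text{ i.i.d.}, \]

where \(s_g(t)\) is the class-coupling sign (+1 except after the flip in
reversal scenarios). Scenarios: `sequential_scenario()` (ten generators
successively active for six samples each, by default), `sustained_scenario()`
(one generator active for sixty samples; duration 0 gives a pure-noise null),
and `reversal_scenario()` (one generator whose coupling flips sign mid-window,
optionally attenuated, producing below-chance generalization).

Defaults are the simulation study conditions: 50 trials (half per class),
20 sensors, 80 samples, SNR 0.5, 10 subjects per group.

**SNR definition.** "Signal-to-noise ratio" admits several conventions;
here \(\sigma\) is chosen so that the root-mean-square of the noiseless
signal over *informative* entries (all trials and channels at samples where
any generator is active) divided by \(\sigma\) equals the requested SNR.
This is scale-invariant, reproducible, and reduces to
\(\sigma = \mathrm{RMS}/\mathrm{SNR}\); with unit activations and standard
normal projections the informative RMS is 1 in expectation. For the null
scenario (no informative entries) \(\sigma = 1\). Noise is added to all
entries, informative or not.

**Seeding.** A master seed deterministically derives one stream per subject,
so groups are reproducible element-wise; all RNG use is wrapped so the
caller's RNG state is untouched.

**Time axis.** The simulation has no physical clock; simulated epochs adopt
a 256 Hz sampling rate (a common MEG epoching rate), so durations are reportable in milliseconds (one sample ≈
3.9 ms).

**What the simulator does not emulate**: correlated sensor noise, realistic
head-model forward fields, induced (non-phase-locked) activity, amplitude
profiles other than a boxcar, and trial-to-trial latency jitter. Passing the
simulation benchmarks therefore validates the machinery — CV hygiene,
calibration, statistics — under the stated generative model, not robustness
to every property of real MEG data.

## Session label sequences

`localglobal_sequence()` generates the trial bookkeeping of the local–global
design: alternating block types (in type 1 the frequent trials are local
standards, in type 2 local deviants), 80%/20% frequent/rare composition,
rare trials placed with runs of 1–6 frequent trials before the first and
between consecutive deviants (the trailing run is free, and kept nonzero
unless a block is deliberately ended on a deviant), a habituation run-in
per block, and `analyzed = FALSE` for habituation trials and trials
immediately following a global deviant. The habituation default of 20
trials approximates a 30 s run-in at the paradigm's trial pacing.

The canonical session totals of the design (780 analyzed trials; local
contrast 390 vs 390; global 600 vs 180) are not reachable with equal per-block deviant
counts (180 deviants do not divide over 14 blocks). `localglobal_session()`
therefore constructs the canonical session explicitly: 14 blocks of 68
trials, per block type seven blocks carrying 13, 13, 13, 13, 13, 13, 12
deviants with exactly four blocks ending on a deviant — which reproduces
all of those analyzed-trial counts exactly. Per-block trial count remains
a free parameter of the general generator.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| `C` (SVM regularization) | 1 | fixed, never tuned |
| `k` (folds) | 10 | stratified by subclass; every subclass needs ≥ k trials |
| `q` (FDR level) | 0.05 | one family per significance map |
| `snr` | 0.5 | RMS(signal over informative entries) / SD(noise) |
| baseline window | 200 ms before the first sound | `[t_start, t_end)`, exposed because epochings vary |
| duration window | diagonal-significant span | fixed window (e.g. 0.082–0.450 s) available |
| SMO tolerance | 1e-3 | libsvm's default stopping criterion |

## Validation scale

The test suite validates the pipeline at the simulation study's full scale:
groups of 10 subjects at 50 × 20 × 80 for the sequential, sustained and
reversal benchmarks, a duration-recovery sweep over generator lifetimes of
4, 8 and 16 samples, and a 100-repetition null calibration on a reduced
20-sample grid (the pipeline's behaviour under the null does not depend on
the grid size, and the reduced grid keeps the calibration study a matter of
minutes). Exact-statistics checks (signed-rank floors, BH step-up,
AUC/U-statistic identity against a brute-force pairwise oracle, bit-level
equality of the matrix diagonal with standalone diagonal decoding) run at
small n where enumeration is feasible.

## Known limitations

- The Platt sigmoid is fitted on the same training fold as the SVM (no
  inner split); probabilities are mildly optimistic near the margins,
  which affects no rank-based quantity in the package.
- The exact signed-rank path covers \(n \le 25\); larger cohorts fall back
  to the tie- and continuity-corrected normal approximation.
- Within-subject Mann–Whitney maps use the normal approximation (the
  per-cell sample is all trials, large enough); exact enumeration is used
  only in the scalar `within_subject_test()` when samples are small and
  untied.
- The repeated-measures F-test sometimes reported alongside this design is
  deliberately not reproduced; the paired signed-rank test covers the same
  question without the sphericity/normality assumptions
  (`anti_generalization_contrast()`).
- Decoding is strictly linear on instantaneous sensor amplitudes: evoked,
  phase-locked activity only.
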