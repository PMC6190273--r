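---
title: "Methods: bilateral-PPG stenosis grading with avfppg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral-PPG stenosis grading with avfppg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avfppg)
```

This vignette is the package's methodological account: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where the problem left them open.

## The problem and the model

An arteriovenous fistula (AVF) gives hemodialysis patients vascular
access; repeated puncturing causes stenosis. Severity is graded by the
degree of stenosis, $\mathrm{DOS} = 1 - (d/D)^2$, from the lesion
diameter $d$ and normal vessel diameter $D$, and partitioned into three
clinical classes: mild ($\mathrm{DOS} \le 30\%$), dialysis-impairing
($30\% < \mathrm{DOS} \le 50\%$) and surgical
($\mathrm{DOS} > 50\%$). The published banding is printed with
overlapping "$\le$" bounds at 30% and 50%; `dos_to_class()` resolves
the ambiguity half-open with the boundary on the lower class — a
deterministic total function whose cut points are arguments, so the
opposite convention is one call away. Negative DOS (a recorded $d > D$,
which does occur in clinical tables) is returned but flagged
implausible.

The physiological signal is bilateral photoplethysmography: synchronous
1 kHz optical recordings at both thumbs. A unilateral obstruction makes
the two arms' pulses asynchronous, and the pipeline classifies that
asynchrony. Its assumptions, in order of strength:

1. both channels are sampled synchronously at the same rate;
2. the pulse waveform has a detectable foot, systolic peak and (usually)
   dicrotic notch after 20 Hz low-pass filtering;
3. inter-arm landmark asymmetry grows monotonically with DOS;
4. within a recording the asymmetry is quasi-stationary, so a per-beat
   median is a fair summary.

Assumption 3 is the load-bearing one; it is exactly what the synthetic
generator encodes and what the cohort-monotonicity tests check.

## Synthetic cohort generator

No public recordings exist for this problem, so `generate_subject()` /
`generate_cohort()` stand in for the clinic. Each beat is the sum of
two log-normal-shaped lobes — a systolic wave peaking `rise_time` after
the foot and a dicrotic wave placed `1.5 * notch_delay` later at
`notch_depth` of the systolic amplitude — a shape chosen purely for
landmark identifiability: it is smooth, has one interior maximum, a
well-defined foot, and a local minimum (the notch) between the lobes.
It is *not* a hemodynamic model; no claim is made about waveform
physiology beyond those landmarks.

Degree of stenosis couples to inter-arm asymmetry through fixed
monotone maps (`asymmetry_from_dos()`):

| asymmetry | default coupling | units |
|---|---|---|
| foot delay (right − left) | `0.08 · DOS` | s |
| rise-time skew | `0.05 · DOS` | s |
| amplitude ratio (right/left) | `1 − 0.4 · DOS` | — |
| notch shift | `0.03 · DOS` | s |

The coefficients are invented effect sizes — the clinical literature
gives directions, not magnitudes — sized so that the three DOS bands
are separable but *overlapping* under jitter, which is what makes the
classification task non-trivial. They are exposed as arguments and are
deliberately not tuned: they define the study conditions, and every
end-to-end number in the package is conditional on them.

Per-subject physiologic variability (`jitter_params()`): beat-period
jitter 2% CV shared by both arms (one heart), landmark timing jitter
5 ms SD and amplitude jitter 3% CV drawn independently per channel and
beat, all zero-mean and seed-controlled. `jitter_off()` gives
deterministic waveforms for ground-truth tests. Cohorts draw DOS
uniformly within class bands [5, 30]%, (30, 50]% and (50, 85]%
(near-total occlusions, whose affected-arm pulse would be barely
recordable, are excluded), with metadata diameters fixed at $D = 1$,
$d = \sqrt{1 - \mathrm{DOS}}$ so the DOS formula inverts exactly.
Default records are 10 s (about 12 beats at the default 72 bpm), 22
subjects per class — the scale of the clinical cohort this design
mirrors and the scale at which all study-level tests run.

What the generator does **not** emulate: respiration and vasomotor
baseline modulation (only a small 0.25 Hz drift common to both arms),
motion artifacts, probe-coupling differences between arms, arrhythmia,
and any dependence of pulse *shape* (rather than timing/amplitude) on
stenosis. Passing tests on synthetic cohorts therefore demonstrate
internal consistency of the pipeline under its own assumptions — not
clinical performance.

## Preprocessing and landmark detection

Filtering is a digital 2nd-order Butterworth low-pass, 20 Hz cutoff at
1 kHz (bilinear transform with prewarping, via the `signal` package).
The default is forward-only (causal), matching a streaming acquisition
chain; its ~11 ms group delay cancels in all bilateral comparisons
because both channels incur it equally. A zero-phase (forward–backward)
mode exists for comparisons against absolute ground-truth times.

The beat detector is deliberately simple and dependency-free: maxima of
the 25 ms-smoothed first derivative above half the derivative's 90th
percentile mark systolic upstrokes; a 250 ms refractory period (a
240 bpm ceiling) deduplicates; the pulse foot is the signal minimum in
the 300 ms before each upstroke. Candidates closer to the record start
than the 300 ms search window are discarded — they have no context to
anchor a foot, and this also removes the causal filter's startup
transient, whose rise mimics an upstroke. Within a beat window the
systolic peak is the (necessarily interior) argmax, and the notch is
the most prominent interior local minimum between the peak and 80% of
the window, reported missing for damped pulses with no interior
minimum. All indices are 1-based R sample indices; landmark *times* in
seconds are the exchange format between modules.

## Features

Per matched beat pair (nearest feet across channels within half the
median beat period), the four absolute asymmetries: foot time (d1),
systolic-peak time (d2, the pulse-transit-time asymmetry), rise time
(d3) and amplitude (d4), aggregated across beats by the median (robust
to occasional misdetections; beats with missing landmarks are
excluded). The fact that the four features are *these* landmark
asymmetries is the largest interpretive decision in the package — the
motivating literature names rise time, amplitude and pulse transit time
as the discriminative bilateral quantities — and it is isolated behind
`extract_features()` so alternative definitions can be swapped.

d4 needs a scale convention. Normalizing each channel's amplitudes by
its own median would cancel exactly the amplitude damping the feature
is meant to measure, so both channels are put on one common scale: the
larger of the two channels' median pulse amplitudes. A pure amplitude
ratio $r$ then yields $d4 = 1 - r$, and multiplying both channels by a
common constant leaves d4 unchanged.

Min–max normalization $\hat x = (x - \min)/(\max - \min)$ is fitted on
training rows only and applied to test rows unclipped (values outside
$[0,1]$ are informative); degenerate columns ($\max = \min$) map to 0
with a warning. Fitting inside each cross-validation training fold
prevents leakage of test-subject ranges into the scaler.

## ECOC one-vs-rest SVM

Three binary soft-margin SVMs are trained on the code-matrix columns —
learner 1: class 1 vs rest; learner 2: classes {1,2} vs 3; learner 3:
classes {1,3} vs 2 — with codewords (1,1,1), (0,1,0), (0,0,1). Three
learners respects the $2^{n-1}-1$ bound for $n = 3$ classes. Output
bits are $f_k(x) \ge 0$ and decoding is minimum Hamming distance;
exhaustive enumeration of the 8 possible output codes shows two can
tie (e.g. (0,0,0) is at distance 1 from both class 2 and class 3), and
ties are resolved by margin-weighted decoding — minimize the summed
$|f_k|$ over mismatched bits, so bits the learners were confident about
cost more to flip — then by lowest class index.

The trainer is a self-contained SMO (sequential minimal optimization):
pairwise working sets with the max-$|E_1 - E_2|$ second-choice
heuristic, solving the standard dual with box constraint
$0 \le \alpha_i \le C$ and $\sum_i \alpha_i y_i = 0$. Numerical
choices: KKT tolerance $10^{-3}$, hard cap of 10 000 update steps,
degenerate (`eta <= 0`, duplicate-point) directions moved to the bound
the gradient points at. The bias is recomputed after convergence as the
mean of $y_i - g(x_i)$ over margin support vectors
($0 < \alpha_i < C$); when no margin SVs exist (small $C$), the KKT
conditions only bound $b$ to an interval — lower bounds from
$(y=+1, \alpha<C)$ and $(y=-1, \alpha>0)$ points, upper bounds from the
mirror set — and the midpoint is used. The contract the tests assert is
KKT satisfaction, dual feasibility and agreement with an independent QP
solver on binary problems, not any property of the optimization path.

Kernels: linear $x^\top z$, quadratic $(x^\top z + \gamma)^2$ (the
pipeline default, $\gamma = 1$) and RBF
$\exp(-\gamma\lVert x - z\rVert^2)$ ($\gamma = 1/p$ by default). The
quadratic default matters structurally: learner 3 must separate the
*middle* DOS class from both extremes, which is not linearly separable
when features grow monotonically with DOS — an interval needs a
quadratic boundary. This is why the quadratic kernel dominates the
linear one on this task by construction, and the end-to-end test
asserts exactly that ordering rather than a tuned number. A variant RBF
with $\lVert x + z\rVert^2$ (a plus sign, as sometimes printed) is
selectable behind `rbf_form = "sum"` for fidelity experiments only; it
is not a similarity kernel and is never a default. $C$ and $\gamma$
defaults ($C = 10$, quadratic $\gamma = 1$) are deliberately unstudied
round numbers; `svm_grid_search()` exists for users who want the
empirical-selection step.

## MLP baseline

The comparison network is a 4–36–3 multilayer perceptron: log-sigmoid
hidden layer, linear outputs, one-hot targets, trained by
Levenberg–Marquardt on the sum of squared errors. Choices the
architecture description leaves open: uniform
$\pm\sqrt{6/(\mathrm{fan\,in}+\mathrm{fan\,out})}$ seeded
initialization; damping $\mu_0 = 10^{-3}$, $\times 10$ on rejected
steps, $\div 10$ on accepted ones; stopping on gradient
$\infty$-norm $< 10^{-7}$, $\mu > 10^{10}$ or 200 accepted epochs;
prediction by argmax with ties to the lowest class. The accepted-step
error sequence is non-increasing by construction, training is
deterministic under a fixed seed, and the analytic Jacobian is verified
against central finite differences on a 4–3–3 network. LM is a local
optimizer, so distinct seeds may reach different optima;
`mlpn_train_multistart()` reports the best of $k$ starts.

## Evaluation and the noise protocol

Metrics are one-vs-rest per class — sensitivity, specificity, precision
(positive predictive value) — macro-averaged over classes with defined
denominators, plus overall accuracy, all in percent. Cross-validation
defaults to leave-one-subject-out (the natural scheme at a 22-per-class
cohort scale), pooling per-fold predictions into one confusion matrix;
per-class values are always reported alongside the macro means so any
averaging convention can be checked. CPU time is logged for information
and never asserted.

The noise-robustness protocol corrupts the *raw* two-channel signals of
the subjects the clean-trained model classifies 100% correctly, re-runs
preprocessing and feature extraction, and re-classifies with the
unchanged model at SNR 40/30/20 dB, averaging over noise seeds. SNR is
defined as $10\log_{10}(P_s/P_w)$ with $P_s$ the mean-squared
mean-removed signal and the noise rescaled to its realized power, so
the empirical SNR equals the target exactly.

The noise construction deserves its own paragraph, because it is the
one place where the obvious choice is the wrong one. White Gaussian
noise at 20 dB input SNR loses ~97% of its power to the pipeline's own
20 Hz low-pass (the filter's equivalent noise bandwidth is ~22 Hz of a
500 Hz band), leaving an in-band SNR near 35 dB — the protocol would
barely probe anything. The clinical protocol this mirrors constructs
its noise *from the raw PPG signals themselves*, i.e. spectrally
in-band noise. `add_noise()` therefore offers both: `type = "white"`
(the simple reading) and `type = "surrogate"` — a phase-randomized
surrogate sharing the signal's own amplitude spectrum, for which the
target SNR is also the in-band SNR. `noise_robustness()` defaults to
the surrogate, and the degradation ordering asserted by the study-scale
test (stable at 40–30 dB, sharp drop at 20 dB) is computed under it.

## Problem sizes and limitations

Study-scale computations use 66 subjects (22 per class), 10 s records
at 1 kHz, LOSO over 66 folds, and 10 noise seeds per SNR level — the
cohort scale of the clinical setting this package models, and
comfortably desk-sized (the full test suite runs in about a minute).

Known limitations: the d1–d4 definitions are an interpretation (see
above); the DOS→asymmetry couplings are invented effect sizes; the
generator omits the artifact classes listed earlier, so synthetic
accuracy should be read as an upper bound on what identical code would
achieve on clinical data; the bundled 22-subject diameter table is
largely self-inconsistent (see `dos_consistency_report()`) and only its
three formula-consistent rows serve as exact oracles; and no
probability calibration or alternative multiclass codings (one-vs-one,
random codes) are provided.
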