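# avfppg

Grading arteriovenous fistula (AVF) stenosis from bilateral
photoplethysmography (PPG).

Hemodialysis patients depend on a surgically created artery–vein
connection (the AVF) for vascular access. Repeated puncturing leads to
stenosis — progressive narrowing of the vessel — which is graded by the
**degree of stenosis**

```
DOS = 1 − (d / D)²
```

where *d* is the lesion diameter and *D* the normal vessel diameter
(DOS = 1 is total occlusion; DOS > 50% usually indicates surgery,
30–50% may impair dialysis efficiency). Measuring *d* and *D* requires
ultrasound or angiography; this package implements a noninvasive
screening pipeline instead: when one arm's access is obstructed, the
pulses recorded at the two thumbs become progressively **asynchronous**,
and the left–right asymmetry of pulse landmarks predicts the DOS class.

The pipeline, for two-channel 1 kHz thumb PPG:

1. **Preprocessing** — 2nd-order IIR Butterworth low-pass at 20 Hz;
   beat segmentation at pulse feet; per-beat landmarks (foot, systolic
   peak, dicrotic notch).
2. **Features** — per matched beat pair, the absolute bilateral
   differences of foot time (d1), systolic-peak time / pulse-transit
   time (d2), rise time (d3) and normalized amplitude (d4), aggregated
   by the median and min–max normalized over the training cohort
   (`x̂ = (x − min)/(max − min)`).
3. **Classifier** — an error-correcting output coding one-versus-rest
   SVM (ESVM-OVR): three soft-margin kernel SVMs
   `f(y) = sgn(Σᵢ αᵢ yᵢ K(xᵢ, y) + b)` trained on the code-matrix
   relabelings class 1 → (1,1,1), class 2 → (0,1,0), class 3 → (0,0,1),
   decoded by minimum Hamming distance (margin-weighted tie-break).
   Default kernel is quadratic, `K(x,z) = (xᵀz + γ)²`; linear and RBF
   are available, as is a 4–36–3 Levenberg–Marquardt MLP baseline.
4. **Evaluation** — one-vs-rest sensitivity / specificity / precision
   (PPV) / accuracy, leave-one-subject-out cross-validation, and an SNR
   noise-robustness protocol (40 / 30 / 20 dB) against a fixed
   clean-trained model.

The clinical recordings behind this design are not publicly available,
so the package includes a first-class **synthetic bilateral-PPG
generator**: quasi-periodic two-lobe pulses whose inter-arm foot delay,
rise-time skew, amplitude damping and notch shift grow monotonically
with DOS, plus physiologic beat-to-beat jitter and SNR-calibrated
noise. All end-to-end results below are computed on such synthetic
cohorts.

## Worked example

```r
library(avfppg)

cohort <- generate_cohort(n_per_class = 22, seed = 1, duration = 10)
#> Synthetic PPG cohort: 66 subjects (classes: 22/22/22)

feats  <- cohort_features(cohort)                     # d1..d4 per subject
report <- cross_validate(feats, spec = kernel_spec("quadratic", gamma = 1), C = 10)
report
#> n = 66  accuracy 95.45%  precision 96.00%  specificity 97.73%  sensitivity 95.45%
report$confusion
#>     predicted
#> true  1  2  3
#>    1 20  2  0
#>    2  0 22  0
#>    3  0  1 21

clf   <- train_classifier(feats)                      # clean-trained model
noise <- noise_robustness(cohort, clf, feats, snr_list = c(40, 30, 20),
                          n_seeds = 10, seed = 1)
noise
#> Noise robustness over 64 subjects, 10 seeds per SNR:
#>  snr_db accuracy precision specificity sensitivity
#>      40    98.91     98.99       99.44       98.89
#>      30    97.66     97.88       98.82       97.64
#>      20    75.94     78.37       88.00       76.19
```

Reading: leave-one-subject-out accuracy with the quadratic kernel is
95.5% on the 66-subject synthetic cohort (each held-out subject is
normalized with training-fold statistics only); the two errors in the
confusion matrix sit at the class-band boundaries, where beat-to-beat
jitter overlaps adjacent DOS classes. Under in-band noise the fixed
model is stable at 40–30 dB and degrades sharply at 20 dB — the
expected ordering for an asynchrony-timing classifier.

Grading utilities work directly on diameters:

```r
dos(1.52, 1.63)          # 0.130415
dos_to_class(0.130415)   # 1
```

A thin command-line front end over the same functions lives at
`inst/cli/avfppg.R` (subcommands `synth`, `features`, `train`,
`train-ann`, `predict`, `evaluate`, `noise-test`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","avfppg.R",package="avfppg"))')" \
    synth --n-per-class 22 --seed 1 --duration 10 --out cohort/
```

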