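---
title: "Simulating and analysing a tactile P300 BCI recorded with scalp and around-the-ear EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a tactile P300 BCI recorded with scalp and around-the-ear EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridtap)
```

## The problem

P300 brain-computer interfaces (BCIs) let a user select one of several
options by attending to rare "target" stimuli in an oddball stream: the
attended stimulus evokes a positive event-related potential (ERP) some
300--700 ms after onset, and a linear classifier detects which stimulus
stream carries it. Tactile variants deliver the oddball through vibrating
tactors on the body, which matters for users who cannot rely on gaze
control. A practical obstacle is the EEG cap itself; flex-printed
around-the-ear arrays (the cEEGrid, ten electrodes per ear) are far less
obtrusive, but their electrodes sit farther from the central scalp sites
where the tactile P300 is largest, and on the right ear two positions are
consumed by ground and reference.

`gridtap` implements the complete offline evaluation pipeline for such a
study -- a four-position vibrotactile oddball recorded simultaneously with a
12-channel scalp cap and two cEEGrids -- together with a calibrated
synthetic-data generator, so that every stage is exercisable end to end with
no access to raw recordings.

## The paradigm and its simulation

One session consists of 6 runs. Within a run the attended position (front,
back, left, right) switches pseudo-randomly after ten vibrations of each
tactor, forming a *target block* of 40 stimuli (10 per position); each
position is the target twice per run with no immediate repetitions, giving
8 blocks per run and, over the session, 480 target and 1,440 non-target
stimuli. Stimuli are 220 ms vibrations with a 400 ms inter-stimulus
interval (620 ms onset asynchrony). `schedule_session()` generates exactly
this event stream; the no-repeat target sequence is drawn by rejection
sampling, which is exact and uniform over admissible sequences. Gaps between
blocks (1.5 s) and runs (3 s) are scheduling conveniences for the continuous
synthetic recording, not task parameters.

`synthesize_recording()` renders a schedule into a continuous multi-channel
recording:

* **ERP model.** Each target stimulus adds a Gaussian-windowed positive
  deflection (SD 90 ms) on the configured channels, peaking 463 ms
  post-stimulus on scalp channels and 501 ms on the ear derivations. The
  template's *peak* is chosen so that its *mean over the analysis window*
  (350--650 ms scalp, 400--700 ms ear) equals the configured amplitude
  exactly -- the window mean is precisely the feature the analysis extracts,
  so the configured values (defaults: Cz 3.53, Fz 2.70, Pz 2.68 µV;
  R2-R7 1.87, R3-R6 1.69, L2-L7 1.58, L3-L6 1.63 µV) are recoverable by
  construction in the noise-free case. This makes the generator and the
  extractor mutually checkable to numerical precision.
* **Template support.** The template is truncated at ±310 ms around its
  peak. The truncation radius covers both analysis windows but is short
  enough that, at the 620 ms onset asynchrony, a stimulus's template cannot
  reach the *analysis window* of its neighbours -- overlapping templates add
  linearly (the standard ERP superposition assumption) without breaking the
  calibration identity. Neighbouring templates do reach the 100 ms
  *baseline* window, so the identity is exact pre-baseline-correction in
  dense streams and exact throughout for isolated stimuli.
* **Bipolar amplitudes.** An amplitude keyed by a bipolar label (e.g.
  R2-R7) is realized as +half the template on the minuend parent and −half
  on the subtrahend, so the derived difference carries the full calibrated
  amplitude while monopolar channels stay moderate.
* **Noise.** Per-channel Gaussian background with a 1/f power spectrum by
  default (a white option exists). The spectral choice is load-bearing:
  EEG background is temporally correlated, so its in-band power at the
  feature level is high relative to its peak amplitude. White noise strong
  enough to place classification accuracy in the realistic regime would
  trip the ±75 µV rejection criterion on most epochs; 1/f noise reaches
  the same discriminative difficulty at peak amplitudes the criterion
  rarely touches. The default SD of 16 µV was fixed once by a simulation
  grid as the level at which the default end-to-end pipeline yields
  cap-EEG group accuracies near 80% while keeping epoch rejection rare
  (&lt;5% on the analysis channels). It is a synthetic operating point,
  not a measured quantity.
* **Polarity and heterogeneity.** A subject-level sign flips all ERP
  deflections (a small minority of real subjects show inverted polarity);
  the study orchestrator additionally draws per-subject amplitude and noise
  scales (log-normal) and the inversion indicator (probability 2/37).
* **Artifacts.** With a configurable per-epoch probability, a 40 ms square
  excursion above the ±75 µV rejection threshold is added 200--450 ms
  post-onset. That placement window guarantees each excursion falls into
  exactly one stimulus epoch (epochs of neighbouring stimuli overlap in
  time), so rejection counts are exactly identifiable against the
  generator's bookkeeping.

What the generator deliberately does **not** model: spatially correlated
background (each channel's noise is independent), ocular/muscle artifact
morphology, non-stationarity, and volume-conduction topography. The
independence simplification has one visible consequence: a bipolar
derivation of two independent channels carries √2 times the single-channel
noise, whereas real EEG background is largely common-mode and cancels in
bipolar pairs. Ear-set accuracies in the default simulation are therefore
lower, relative to the cap, than the gap observed in real recordings.
Passing tests consequently validate the *pipeline* -- its arithmetic,
contracts and statistical calibration -- not biophysical realism.

## The signal path

The offline path is fixed: band-pass filter → epoch → baseline-correct →
reject artifacts → average, with the order enforced by the objects' types
and state flags (double baseline correction, or rejection before
correction, raise errors).

* **Filter.** Zero-phase (forward–backward) 4th-order Butterworth high-pass
  at 0.1 Hz followed by a 4th-order low-pass at 30 Hz. Zero-phase filtering
  preserves ERP latencies. The passes run in compiled code with
  even-reflection padding and steady-state initial conditions, so a
  constant signal passes without start-up transients — important at the
  very low high-pass corner. The 48–52 Hz notch the amplifiers applied at
  acquisition is a property of stored data and therefore belongs to the
  simulator, not this module (with white or 1/f synthetic noise it would be
  a no-op and is omitted).
* **Epochs.** Half-open window [−100, 800) ms around each onset: at 250 Hz,
  25 pre- plus 200 post-stimulus samples (225 in total). Events too close
  to the recording edge are dropped with a warning.
* **Baseline.** Per epoch and channel, the mean of the pre-stimulus samples
  is subtracted.
* **Rejection.** An epoch is rejected when any sample *strictly* exceeds
  75 µV in magnitude on any scanned channel; exactly 75.0 µV is kept. The
  scan is scoped to the channels entering the given analysis (scalp set or
  ear set), so one noisy unused channel cannot discard the session;
  thresholding is applied after baseline correction. Both choices are
  conventions where the procedure is underdetermined, and both are
  configurable. Rejection applies to the ERP analysis by default and to
  classification only on request (`reject_for_classification`).
* **Averaging.** Kept epochs are averaged per class (target / non-target).

ERP features are the window mean amplitude (closed interval on the sample
grid) and the peak latency (extremum of the requested polarity, ties to the
earliest sample, default search window 300–700 ms — the procedure reports a
peak without defining its search window, so the default brackets the
deflection on both systems).

## Classification

Features are per-channel means of consecutive 50 ms bins over 0–800 ms
(16 bins/channel: 12 × 16 = 192 features for the cap, (18 + 8) × 16 = 416
for the ear set with its eight bipolar derivations). Bin edges are laid on
the sample grid, so at 250 Hz bins alternate between 12 and 13 samples.

The classifier is stepwise linear discriminant analysis (SWLDA), the
long-standing P300 classifier: least-squares regression of ±1 class labels
on the features with forward–backward stepwise selection driven by
partial-F p-values (enter while min p < 0.10, remove while max p > 0.15,
at most 60 features). These thresholds are the P300-classifier convention —
the tool is named in the literature without its settings — and all are
configurable. The implementation uses the classical sweep-operator
formulation on the augmented cross-product matrix, which makes each
add/remove step O(p²) and allocation-free; the test suite verifies the
entire selection path and the final weights against an independent
`lm()`/`add1()`/`drop1()` stepwise walker, and that disabling selection
reproduces full OLS to 1e−8.

Selection accuracy is evaluated by leave-one-out cross-validation at the
level of *target blocks* (48 folds for a full session): leaving out single
epochs would leak the held-out block's other repetitions into training, so
the block is the defensible unit. Scores of the held-out block are averaged
per position and the arg-max is the selected target (ties resolve to the
first position in canonical order front, back, left, right). A fold whose
model is degenerate (no feature passes entry) counts as incorrect. The
cross-product matrix of the whole session is computed once; each fold
subtracts the held-out block's contribution, which keeps 48-fold CV cheap.

Chance calibration uses the exact binomial tail: the significance bound is
the smallest k with P(X ≥ k | n, 0.25) < 0.05 — for 48 selections k = 18,
i.e. 37.5% (floor-rounded to 37 when quoted as an integer) — and the 70%
usability convention is flagged alongside.

## Psychophysics

The somatosensory sensitivity task presents pairs of stimuli (reference at
100%, second stimulus lowered in 5% steps, grid down to 40%) and asks
whether they felt equal. The scheduler first sweeps the grid once in seeded
random order, then samples uniformly among intensities whose running
response ratio lies strictly inside (0.2, 0.8) — the ambiguous region —
falling back to the full grid when none qualify, with a 53-trial budget
(the largest session length observed in practice). Band and budget are
scheduler conventions; the adaptive idea (test inconsistent intensities
more often) is the specified behaviour.

Response ratios per intensity live on a 0 (always unequal) to 1 (always
equal) scale. A two-parameter logistic with asymptotes fixed at 0 and 1 is
fitted by least squares weighted by per-intensity trial counts — fitting
the ratio points directly, which is the most literal reading of fitting "to
these data"; a binomial-likelihood GLM route is available behind
`method = "binomial"`. The sensitivity threshold is the fitted midpoint
(ratio 0.5). One-sided response sets, fewer than three tested intensities,
or optimizer failure yield `converged = FALSE` and no threshold —
`estimate_threshold()` then raises rather than reporting a number,
mirroring the exclusion of undeterminable participants. Midpoints outside
the tested range are flagged as boundary fits. The logistic family itself
is an assumption (the procedure specifies only "a sigmoidal function") and
is documented as such.

## Group statistics

Paired t (two-tailed) and Pearson correlations delegate to base R's
`t.test()`/`cor.test()` behind a tidy result type. The one-way
within-subject ANOVA computes the sums of squares directly, with partial
η², Mauchly's sphericity test (delegated to `stats::mauchly.test`), and
Greenhouse–Geisser ε applied to both degrees of freedom when sphericity is
rejected at α = 0.05 (the trigger level is a convention; the correction
policy is specified). Post-hocs are all pairwise paired t tests with
Bonferroni multiplication capped at 1; the all-pairs family over the seven
channels of interest is an assumption, documented here. The suite checks
all three tests against independent implementations (closed-form formulas;
`car::Anova` for the ANOVA) on random datasets, and the two-condition
ANOVA against the squared paired t.

In the formatted per-subject overview table, accuracies below the 70%
usability criterion are marked `*`, accuracies below the binomial chance
bound are marked `+`, and missing cells are rendered as en-dashes.

## Numerical and design choices

* Onsets are stored in seconds and converted to 1-based sample indices by
  rounding to the nearest sample; epoching is pure index arithmetic
  afterwards.
* Montage: on the right ear R4a/R4b are ground and reference and are not
  data channels (18 recordable ear channels by default); whether the left
  ear mirrors the exclusion is hardware-ambiguous and is a flag
  (`mirror_ear_exclusions`).
* EDF (16-bit) is supported for interchange, with events in a companion
  `.tsv` since classic EDF carries no annotations; the package's own JSON +
  float64 container is lossless and dependency-free.
* Seeding: one master seed; every stochastic stage derives its own child
  stream via a fixed multiplicative hash (`derive_seed()`), so any single
  stage is reproducible in isolation and whole studies are bit-for-bit
  repeatable.
* Problem sizes in the test suite: the null-calibration study simulates 200
  signal-free full sessions through the complete pipeline on the
  12-channel cap montage, and the SNR sweep 5 amplitude levels × 20
  sessions; psychometric recovery uses 500 replicates of 40 trials. These
  sizes give the assertions comfortable statistical resolution (binomial
  bands over 9,600 selections) at desk-scale runtimes.

## Known limitations

* Channel noise is spatially independent (see above); ear-set accuracies
  are conservative relative to real recordings.
* The exact binomial chance bound treats a subject's 48 selections as
  independent. Under block-wise leave-one-out CV they are not: every fold's
  test block is training data for every other fold, and with stepwise
  models that select to the feature cap on signal-free data the fold
  outcomes are positively correlated. The group mean stays unbiased at 25%,
  but per-subject accuracies are overdispersed relative to
  Binomial(48, 0.25), so on signal-free data more subjects cross the 37.5%
  bound than the nominal 3.6% — the bound is anti-conservative as a
  per-subject false-positive control for this CV scheme. The
  null-calibration test quantifies this; interpret single-subject
  significance flags accordingly.
* The ERP template is unimodal and identical across channels of a class up
  to scale; real tactile ERPs have multi-component morphology.
* The generator's 48–52 Hz notch omission is correct for white/1-over-f
  synthetic noise but means mains interference is never simulated.
* Group results reported by the package on synthetic cohorts characterise
  the pipeline under the generator's assumptions only; none of them are
  estimates of any real cohort's values.
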