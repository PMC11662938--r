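---
title: "Methods: simulating and analyzing dPPR smFRET trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing dPPR smFRET trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprfret)
```

## The system and the measurement

Designer pentatricopeptide repeat (dPPR) proteins are modular α-solenoids in
which each ~35-residue repeat reads one ssRNA base. On binding its target,
the solenoid compacts: the superhelix tightens from roughly 10 repeats per
turn (pitch ~85 Å) to 9 per turn (pitch ~43 Å). A donor/acceptor pair placed
on repeats eight apart therefore moves from outside to inside the Förster
radius, and single-molecule FRET on surface-immobilized protein reports
binding of unlabeled RNA in real time: an unbound molecule sits near FRET
~0.4 and jumps to ~0.8 when RNA binds.

`pprfret` implements the full measurement chain as testable code: a
generative model of the traces, crosstalk calibration and FRET computation,
nonlinear trace denoising, hidden-Markov state finding, kinetic analysis
with explicit censoring rules, three-color (ALEX) coincidence analysis,
solenoid geometry, and titration fitting. Because real microscope data
carry unknowable ground truth, the package's guarantees are phrased as
recovery: every analysis-side estimate is validated against the known
parameters of its own generator, end to end.

## The trace generator

`simulate_state_path()` draws a continuous-time Markov jump process
(Gillespie algorithm) over the conformational states of a `kinetic_scheme`
and discretizes it to camera frames. A frame is assigned the state occupying
the majority of its 200 ms exposure — the camera integrates, and a
transition mid-frame is attributed to whichever state dominated. Exact jump
times are retained as ground truth.

`render_two_color()` converts the per-frame FRET efficiency `E` into
channel intensities: donor `I(1-E)`, acceptor `IE + gI(1-E)` where `g` is
the donor-to-acceptor spectral leakage, plus independent Gaussian noise per
channel. Each dye photobleaches once, irreversibly, after an exponential
time; after acceptor bleaching all emission returns to the donor while the
acceptor channel keeps only leakage, and after donor bleaching both
channels are dark. Defaults: total intensity 1000 a.u., `g = 0.07`, frame
interval 0.2 s (5 Hz acquisition), photobleach mean 600 s per dye — with an
oxygen-scavenging buffer, dyes routinely outlive multi-minute movies, and
the long default keeps censoring mild in kinetic cohorts. Injection-style
cohorts emulating a microfluidic experiment use 120 s per dye where the
study conditions call for it (see the acceptance script).

Noise is specified on the FRET scale: `channel_noise_for_fret_sd()` inverts
the delta-method propagation of channel noise through the FRET ratio, so "a
cohort at σ_FRET = 0.08" has a precise generative meaning. Two features of
real data are deliberately not modeled: EMCCD excess noise (the Gaussian
approximation is conservative at these intensities) and dye blinking
(suppressed experimentally by Trolox/oxygen-scavenger chemistry). Passing
tests therefore demonstrate correctness of the analysis chain under
well-behaved photophysics, not robustness to pathological dyes.

`simulate_injection_cohort()` starts every molecule unbound, injects ligand
at 10 s, draws an exponential wait to first binding, and then either holds
the molecule bound forever (the stable fraction, 80% by default) or lets it
toggle under a user-supplied post-binding scheme. Three-color rendering
(`render_three_color()`) interleaves 532 and 488 nm excitation
frame-by-frame (even frames 532, frame 0 first); on 488 frames a bound,
unbleached blue dye distributes a configured total across the three
channels, and an unbound molecule gives only background.

## Crosstalk, FRET, and molecule selection

The crosstalk constant is calibrated on donor-only molecules as the pooled
median of the acceptor/donor ratio over pre-bleach frames
(`estimate_crosstalk()`). The median is used rather than the mean because
residual undetected steps and near-zero donor frames produce heavy tails.
Background is taken from the post-donor-bleach segment when one exists and
zero otherwise — the generator's default background is zero, and on real
data the post-bleach segment is the only model-free background estimate
available per molecule.

`compute_fret()` applies the corrected-acceptor ratio
`(A - gD) / (A - gD + D)`. Values are reported unclamped; the correction is
approximate (no gamma or direct-excitation terms), so out-of-range values
are information, not errors. `truncate_at_photobleach()` cuts each
trajectory at the earlier of the donor and acceptor bleach frames, keeping
the truncation frame and imaging lifetime as metadata; trajectories with no
observed bleach are flagged censored.

Photobleach steps are found by penalized least-squares binary segmentation
(`detect_photobleach_steps()`): the split penalty is `2 σ² log n` with σ a
robust (median-absolute-difference) noise estimate, so a noiseless step of
any size is always found, and reported steps must exceed `sensitivity × σ`
(default 3). In `process_trace()` the donor bleach is located on the summed
donor + acceptor intensity — which is flat across FRET transitions and
collapses only when the donor dies — while the acceptor bleach must drop
the acceptor channel below 0.15 of the concurrent donor level persistently,
the signature of pure leakage. Molecule selection
(`select_molecules()`) keeps traces with exactly one donor and one acceptor
bleach event; extra downward steps not balanced by an anticorrelated step
on the partner channel (intensity conservation is the signature of a FRET
transition) mark multi-fluorophore molecules. The Pearson anticorrelation
criterion (ceiling 0) is applied only to molecules showing at least one
candidate transition, since a static molecule's channels are uncorrelated
noise.

## Denoising

`nl_filter()` implements a forward-backward predictor-weighted (nonlinear)
filter. At each frame, one-sided running means of the preceding and
following `N_FA·f^k` frames are combined with weights proportional to each
predictor's mean squared prediction error over the trailing/leading `m`
frames raised to the power `-p`. A window straddling a state transition
predicts badly and loses essentially all weight, so steps pass through
unsmoothed while plateau noise is averaged. Defaults follow the standard
settings `p = 5`, `N_FA = 1`, `f = 2`, with `m = 10` comparison frames.

The number of scales is the one genuinely open knob. With two scales
(windows 1 and 2) the filter averages too few samples to beat even a plain
5-frame moving average on plateaus (measured plateau RMSE 0.060 vs 0.045 at
σ = 0.1); four scales (windows 1, 2, 4, 8 per direction) reach 0.038 while
displacing step edges by at most one frame in 95% of replicates. The
package therefore defaults to `n_scales = 4`. Because the base window
`N_FA = 1` is what enters the minimum-residence rule below, the extra
scales do not change the dwell-time censoring.

## State finding

`fit_hmm()` fits Gaussian-emission hidden Markov models by maximum a
posteriori EM. The `mu` and `beta` hyperparameters (defaults 1.5 and 0.5)
parameterize a Normal–Gamma prior on each state's emission mean and
precision: `mu` is the pseudo-count strength pulling state means toward a
prior mean of 0.5 FRET, and `beta` scales the precision-prior rate
(`a0 = 2.5`, `b0 = 0.025 β`, i.e. a prior state width near 0.1 FRET).
These act as the over-fitting guard: spurious narrow states are penalized
through the precision prior, and thinly-populated states are pulled toward
the uninformative center. One visible consequence is a mild shrinkage of
MAP state means, `κ0/(κ0 + N)` toward 0.5 — about 10⁻³ for a
125-frame state — which is far below the reported tolerances.

Model selection runs over `k = 1…4` with 5 deterministic restarts per `k`
(restart seeds derive from `(seed, k, restart)`), scoring each converged
fit by the maximized log-likelihood minus `½ · npar · log T`. Ties break
toward fewer states, and the penalized objective (likelihood plus log
prior) is recorded per iteration; EM theory guarantees it never decreases,
and the test suite asserts this on every fit it makes. States are reported
sorted by ascending mean; decoding is by Viterbi path, and
`decode_posteriors()` provides forward–backward posteriors (validated in
the tests against exhaustive path enumeration at small T). Emission widths
are floored at 10⁻⁴ FRET so degenerate noiseless input remains numerically
decodable. The pipeline denoises before fitting, matching the standard
order of operations; the raw series is kept alongside for comparison.

## Kinetics and censoring

Transitions of the idealized (Viterbi state-mean) trajectory are classified
by which side of the 0.5 FRET threshold the departing and arriving state
means occupy: `T_low-high` is binding, `T_high-low` release, and changes
within one side are recorded but excluded from the two classes. A state
mean exactly at the threshold counts as high (a documented tie-break;
thresholds compare state means, not raw frames). Residence times are
cumulative per side — consecutive same-side states merge — and two
censoring rules apply: the final dwell of every molecule is deleted (its
true extent is cut off by photobleaching), and dwells shorter than
`2 · F · N_FA` (400 ms at 200 ms frames, `N_FA = 1`) are discarded because
the denoising filter cannot guarantee them. The per-molecule accounting
identity `kept + discarded + terminal = imaging lifetime` is asserted
exactly in the tests.

`binding_release_rate()` divides threshold crossings per direction by the
imaging lifetime. `time_to_first_binding()` reports the time from injection
to the first binding transition; molecules that never bind before
truncation are censored and excluded from the cohort mean (the mean of
observed events), with a Kaplan–Meier restricted-mean alternative
(`method = "km"`, via the survival package) that uses the censored
molecules. Note that the observed-event mean is biased low whenever
photobleaching competes with slow binding — with per-dye bleach means of
120 s, an exponential 10.6 s wait is recovered near 9–10 s — which is a
property of the estimator the measurement itself uses, not of the
implementation; the tests therefore compare at 3 standard errors.
`synchronized_transition_average()` aligns binding transitions whose
departing dwell exceeds 10 s and averages the FRET in a ±10 s window;
events nearer the record edge than the window are NA-padded and masked.
`collate_histogram()` pools per-frame FRET over [-0.2, 1.2] and normalizes
the density to unit integral.

## Three-color coincidence

`demultiplex_alex()` splits a trace by laser tag, preserving original frame
indices; FRET is computed on the 532 sub-trace with the identical machinery
(the HMM applies unchanged). `total_488_fluorescence()` sums the three
background-subtracted channels per 488 frame; when no explicit background
is given it is estimated per molecule and channel from the dark (at or
below median) frames. `correlate_binding()` measures, for each binding
transition, the lag to the nearest 488 onset. Because the two lasers never
share a frame under alternation, the minimal resolvable lag is one original
frame, and "same-frame" coincidence is operationalized as |lag| ≤ 1; this
is asserted in the summary metadata. The 488 profile around transitions is
max-normalized per molecule — the simplest normalization consistent with
comparing molecules of different brightness; it is a documented choice, not
the only one possible.

## Solenoid geometry

Per-repeat reference points are Cα centroids of the annotated 35-residue
repeats. `fit_superhelix()` estimates the axis direction from cross
products of second differences of consecutive centroids — for a regular
helix these lie exactly in the plane normal to the axis — refines it by
least squares, fits the in-plane circle (Kasa algebraic fit) for the radius
and center, and reads twist and rise as mean angular and axial increments.
Twist is right-handed about the axis oriented from the first to the last
repeat; `pitch = rise × 360 / twist` and `repeats_per_turn = 360 / twist`
hold by construction. At least four centroids are required (three points
always lie on a circle and carry no pitch information). Collinear centroids
raise a degenerate-geometry error.

`inter_repeat_transforms()` performs the hinge analysis: for each adjacent
repeat pair, repeat *i* of conformation A is superposed on repeat *i* of B
(Kabsch), and the residual rigid transform carrying repeat *i+1* along is
decomposed as a screw — rotation angle about and translation along a single
axis. The decomposition composes back to the original motion to 10⁻⁹ Å on
test points. `screen_fret_pairs()` evaluates all residue pairs at a given
repeat separation (same position within each repeat, Cα by default — the
atom choice for literature distances is not always stated, and Cα is the
convention adopted here), retains pairs whose apo distance exceeds the
Förster radius while the bound distance falls below it, and ranks by
predicted FRET change `E = 1/(1 + (r/R0)^6)`.

## Titration

`fit_kd()` fits the 1:1 ligand-depletion isotherm by Levenberg–Marquardt
least squares. The depletion (quadratic mass-balance) form rather than a
hyperbola is required because the sensor is assayed at 5 nM, comparable to
the ~1 nM dissociation constant, so free ligand is appreciably depleted at
the transition. Start values come from the curve extremes and the half-rise
point; Kd is bounded below by zero. A flat curve or a fitted Kd beyond ten
times the concentration range is flagged non-identifiable, and Kd ≤ 10⁻³ nM
is flagged near-stoichiometric; neither raises an error. Standard errors
derive from the Jacobian at the optimum, and first-order optimality
(residuals orthogonal to the Jacobian columns) is asserted in the tests.

## Orchestration and reproducibility

`run_pipeline()` chains simulate → calibrate → FRET/truncate → denoise →
HMM → kinetics from a single nested configuration (R list or YAML; full
defaults in `default_run_config()`, a demo in
`inst/extdata/demo_config.yaml`). Every output directory contains the
tables, a machine-readable `summary.json`, and a log recording package
version and seed; reruns with the same configuration are bit-identical.
All randomness in the package flows through explicit integer seeds —
cohort generators consume one seed per cohort, and HMM restarts derive
their streams from `(seed, k, restart)`. The command-line surface is the
package's function layer plus `scripts/acceptance.R`; the analyses are
meant to be driven from R.

## Problem sizes

The test suite and the acceptance script work at the cohort sizes the
study design calls for: 150–200 molecules per condition for state-mean and
classification checks, injection cohorts of 168 and 150 molecules at 5 Hz
for binding-time recovery (the faster cohort over 120 s records, the
slower over 240 s so that 41 s waits are observable), 10⁴ dwells for
distributional checks, and 100 noise replicates for the titration. These
sizes make every stochastic tolerance a 3-standard-error statement rather
than a hopeful margin.

## Known limitations

The generator's photophysics is deliberately minimal: no blinking, no
excess camera noise, no baseline drift, single-exponential bleaching. The
HMM assumes Gaussian emissions of per-state constant width and shares no
information across molecules. The observed-event binding-time estimator
inherits the censoring bias discussed above; use the Kaplan–Meier option
when bleaching is fast relative to binding. The geometry module fits
regular superhelices; strongly irregular solenoids violate its averaging
assumptions and show up as a large `rms_radius`.
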