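# pprfret

Single-molecule FRET analysis of designer pentatricopeptide repeat (dPPR)
protein–RNA binding, as a tested, reusable R pipeline.

## The problem

dPPR proteins are programmable α-solenoids: each ~35-residue repeat reads
one ssRNA base, so a designed repeat array binds a chosen RNA sequence. On
binding, the solenoid compacts — the superhelix tightens from ~10 repeats
per turn (pitch ~85 Å) to 9 per turn (pitch ~43 Å) — and a donor/acceptor
dye pair placed on repeats eight apart swings from outside to inside the
Förster radius (R0 = 54 Å for Cy3/AF647). Surface-immobilized, dye-labeled
dPPR therefore acts as a single-molecule FRET sensor for RNA binding: an
unbound molecule sits near FRET ~0.4 and steps to ~0.8 when RNA binds.

`pprfret` is for people who build or analyze such experiments. It provides
both sides of the measurement:

- **Simulation** — continuous-time Markov state paths rendered into
  two- or three-color (ALEX) intensity traces with donor→acceptor
  crosstalk, Gaussian detection noise, and single-step photobleaching;
  injection cohorts with exponential waits and a stable/dynamic split;
  titration curves under the ligand-depletion isotherm; ideal solenoid
  coordinate sets. All with stored ground truth.
- **Analysis** — crosstalk calibration on donor-only molecules and the
  corrected-acceptor FRET ratio `E = (A − gD)/(A − gD + D)`; photobleach
  step detection and molecule-selection QC; forward–backward nonlinear
  (predictor-weighted) denoising; MAP Gaussian hidden-Markov state finding
  with model selection over 1–4 states; transition classification at the
  0.5 FRET threshold, residence times with last-dwell deletion and the
  `2·F·N_FA` minimum-residence rule, binding/release rates, time to first
  binding, synchronized transition averages, FRET histograms; ALEX
  demultiplexing and binding-coincidence analysis; superhelical parameter
  fitting (radius, rise, twist, pitch), inter-repeat hinge screws, and
  Förster-based FRET-pair screening; and quadratic-depletion Kd fitting.

## A worked example

Simulate an injection experiment (RNA injected at 10 s, exponential wait
with mean 10.6 s, 80% of molecules binding irreversibly), then analyze it
back blind:

```r
library(pprfret)

phys <- photophysics_config(
  total_intensity = 1000, crosstalk_g = 0.07,
  noise_sd = channel_noise_for_fret_sd(0.08, 1000),
  donor_bleach_mean = 120, acceptor_bleach_mean = 120)
inj <- injection_config(injection_time = 10, wait_mean = 10.6,
                        fraction_stable = 0.8)
set <- simulate_injection_cohort(168, inj, phys, duration = 120, seed = 11)

g <- estimate_crosstalk(simulate_donor_only(20, phys, duration = 60,
                                            seed = 12))
trajs <- denoise_trajectories(lapply(set, process_trace, model = g))
fits  <- fit_hmm_cohort(trajs, hmm_priors(), seed = 13)

cfg <- analysis_config()
fb  <- cohort_first_binding(fits, cfg, injection_time = 10)
cat(sprintf("crosstalk g = %.3f\n", g$g))
cat(sprintf("mean time to first binding = %.2f +/- %.2f s (n = %d)\n",
            fb$mean, fb$sem, fb$n_observed))
```

```
crosstalk g = 0.068
mean time to first binding = 9.12 +/- 0.84 s (n = 120)
```

The calibration recovers the generative crosstalk (0.07), and the cohort
mean sits within three standard errors of the generative 10.6 s wait — the
small downward offset is the censoring bias of the observed-event
estimator when photobleaching (120 s per dye here) competes with binding,
a property of the estimator itself; `cohort_first_binding(..., method =
"km")` gives the censoring-aware alternative.

Geometry side, in one line each:

```r
fit_superhelix(generate_ideal_solenoid(solenoid_spec(4.8, 40, 25, 18)))$pitch
#> [1] 43.2
fit_superhelix(generate_ideal_solenoid(solenoid_spec(8.5, 36, 25, 18)))$pitch
#> [1] 85
predict_fret_from_distance(c(71, 40), r0 = 54)
#> [1] 0.1615747 0.8582175
```

A complete run (simulation → tables → summary JSON → log) from one config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "pprfret"),
             out_dir = "demo_run")
```

The methods vignette (`vignettes/pprfret-methods.Rmd`) documents the
models, the priors, every censoring rule, and the package's design
decisions.

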