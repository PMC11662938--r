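test_that("transitions are classified by threshold crossing", {
  cfg <- analysis_config()
  f1 <- make_fit(rep(c(0.4, 0.8), each = 20))
  tr1 <- classify_transitions(f1, cfg)
  expect_equal(tr1$class, "T_low-high")
  expect_equal(tr1$frame, 20L)
  expect_equal(tr1$time_s, 4)

  f2 <- make_fit(rep(c(0.4, 0.8, 0.4), each = 10))
  expect_equal(classify_transitions(f2, cfg)$class,
               c("T_low-high", "T_high-low"))

  # all states above threshold: no classified transitions
  f3 <- make_fit(rep(c(0.6, 0.9), each = 10))
  expect_equal(classify_transitions(f3, cfg)$class, c("within", "within")[1])

  # state mean exactly at the threshold counts as high
  f4 <- make_fit(rep(c(0.4, 0.5), each = 10))
  expect_equal(classify_transitions(f4, cfg)$class, "T_low-high")
})

test_that("residence times apply the minimum-time and last-state rules", {
  cfg <- analysis_config()   # min residence 2 * 200 ms * 1 = 0.4 s
  expect_equal(cfg$min_residence_s, 0.4)

  # a single-frame (200 ms) dwell is dropped
  f <- make_fit(c(rep(0.4, 10), 0.8, rep(0.4, 10), rep(0.8, 5)))
  d <- residence_times(f, cfg)
  acc <- attr(d, "accounting")
  expect_equal(acc$discarded_s, 0.2)
  # terminal high dwell deleted
  expect_equal(acc$terminal_s, 1.0)
  expect_true(all(d$duration >= 0.4))

  # low(10)-high(5)-end: one low dwell of 2.0 s, terminal deleted
  f2 <- make_fit(c(rep(0.4, 10), rep(0.8, 5)))
  d2 <- residence_times(f2, cfg)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$duration, 2.0)
  expect_equal(d2$class, "T_low-high")
})

test_that("dwell accounting conserves the imaging lifetime", {
  cfg <- analysis_config()
  set.seed(21)
  for (r in 1:20) {
    ide <- 0.4 + 0.4 * (cumsum(rbinom(100, 1, 0.2)) %% 2)
    f <- make_fit(ide)
    d <- residence_times(f, cfg)
    acc <- attr(d, "accounting")
    expect_equal(acc$kept_s + acc$discarded_s + acc$terminal_s,
                 acc$lifetime_s, tolerance = 1e-12)
    expect_equal(acc$lifetime_s, length(ide) * 0.2)
  }
})

test_that("censoring-free dwell means match the generative rate", {
  # k_off = 0.2/s bound dwells: mean 5 s, checked on ground-truth paths
  set.seed(31)
  dwells <- numeric(0)
  while (length(dwells) < 1e4) {
    p <- simulate_state_path(two_state_scheme(0.2, 0.2), 3000, 0.2)
    j <- p$jumps
    rel <- which(j$from == 2L)
    ent <- which(j$to == 2L)
    n <- min(length(rel), length(ent))
    if (n > 0) {
      dd <- j$time[rel[seq_len(n)]] - j$time[ent[seq_len(n)]]
      dwells <- c(dwells, dd[dd > 0])
    }
  }
  dwells <- dwells[seq_len(1e4)]
  expect_lt(abs(mean(dwells) - 5) , 3 * 5 / sqrt(length(dwells)))
})

test_that("alternation bounds the binding/release count difference", {
  set.seed(41)
  for (r in 1:20) {
    ide <- 0.4 + 0.4 * (cumsum(rbinom(80, 1, 0.3)) %% 2)
    f <- make_fit(ide)
    tr <- classify_transitions(f, analysis_config())
    expect_lte(abs(sum(tr$class == "T_low-high") -
                     sum(tr$class == "T_high-low")), 1L)
  }
})

test_that("binding-and-release rates are crossings per lifetime", {
  cfg <- analysis_config()
  # 3 binding events in 60 s
  ide <- rep(rep(c(0.4, 0.8), 3), each = 50)
  f <- make_fit(ide, lifetime = 60)
  r <- binding_release_rate(f, cfg)
  expect_equal(r$n_binding, 3L)
  expect_equal(r$binding_rate, 0.05)
  # no crossings
  f0 <- make_fit(rep(0.4, 100))
  expect_equal(binding_release_rate(f0, cfg)$total_rate, 0)
  # zero lifetime errors
  fz <- make_fit(rep(0.4, 100), lifetime = 0)
  expect_error(binding_release_rate(fz, cfg), "lifetime")

  # symmetric two-state chain: per-direction crossing rate ~ occupancy x rate
  set.seed(51)
  rates <- vapply(1:40, function(i) {
    p <- simulate_state_path(two_state_scheme(0.1, 0.1), 500, 0.2)
    f <- make_fit(p$fret, lifetime = 500)
    binding_release_rate(f, analysis_config())$binding_rate
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05) / 0.05, 0.1)
})

test_that("dynamic fraction counts molecules with both transition classes", {
  cfg <- analysis_config()
  stable <- make_fit(c(rep(0.4, 20), rep(0.8, 30)))
  toggler <- make_fit(rep(c(0.4, 0.8), each = 10, times = 3))
  silent <- make_fit(rep(0.4, 50))
  expect_equal(dynamic_fraction(list(stable, silent), cfg)$dynamic_fraction,
               0)
  expect_equal(dynamic_fraction(list(toggler, toggler),
                                cfg)$dynamic_fraction, 1)
  expect_equal(dynamic_fraction(list(stable, toggler, silent),
                                cfg)$dynamic_fraction, 1 / 3)
})

test_that("first-binding times subtract the injection time", {
  cfg <- analysis_config()
  # first T_low-high at 20.6 s with injection at 10 s: 10.6 s
  ide <- c(rep(0.4, 103), rep(0.8, 50))
  f <- make_fit(ide)
  tb <- time_to_first_binding(f, cfg, injection_time = 10)
  expect_equal(tb$t_bind, 20.6 - 10)
  expect_false(tb$censored)
  # no binding before truncation: censored
  f0 <- make_fit(rep(0.4, 100))
  expect_true(time_to_first_binding(f0, cfg, 10)$censored)
  # cohort mean over uncensored values only
  cs <- cohort_first_binding(list(f, f, f0), cfg, injection_time = 10)
  expect_equal(cs$mean, 10.6)
  expect_equal(cs$n_observed, 2L)
  expect_equal(cs$n_censored, 1L)
})

test_that("synchronized averages align clean steps at lag zero", {
  cfg <- analysis_config(sync_window = 4, sync_min_residence = 4)
  # one clean 0.4 -> 0.8 event with long flanks
  f <- make_fit(c(rep(0.4, 60), rep(0.8, 60)))
  sy <- synchronized_transition_average(list(f), cfg)
  expect_equal(sy$n_events, 1L)
  w <- (length(sy$lag_s) - 1L) / 2L
  expect_equal(sy$mean[seq_len(w)], rep(0.4, w))
  expect_equal(sy$mean[w + 1L], 0.8)
  expect_equal(sy$mean[(w + 2L):(2L * w + 1L)], rep(0.8, w))

  # no qualifying events (short pre-dwell)
  f2 <- make_fit(c(rep(0.4, 10), rep(0.8, 60)))
  sy2 <- synchronized_transition_average(list(f2), cfg)
  expect_equal(sy2$n_events, 0L)

  # memoryless generation: no anticipatory drift before binding
  set.seed(61)
  phys <- phys_noisy(fret_sd = 0.06)
  inj <- injection_config(injection_time = 2, wait_mean = 6,
                          fraction_stable = 1)
  set <- simulate_injection_cohort(40, inj, phys, duration = 60, seed = 62)
  g <- crosstalk_model(0.07)
  trajs <- denoise_trajectories(lapply(set, process_trace, model = g))
  fits <- fit_hmm_cohort(trajs, hmm_priors(), seed = 63)
  cfg2 <- analysis_config(sync_window = 5, sync_min_residence = 5)
  sy3 <- synchronized_transition_average(fits, cfg2)
  pre <- sy3$mean[seq_len(10)]
  expect_lt(max(abs(pre - 0.4), na.rm = TRUE), 0.02 + 3 * 0.06 /
              sqrt(max(sy3$n_events, 1)))
})

test_that("pooled histograms are normalized and faithful", {
  h1 <- collate_histogram(list(rep(0.4, 1000)))
  expect_equal(sum(h1$count > 0), 1L)
  binw <- diff(h1$bin_center[1:2])
  expect_equal(sum(h1$density) * binw, 1, tolerance = 1e-9)

  set.seed(71)
  two <- list(c(rnorm(5000, 0.4, 0.02), rnorm(5000, 0.8, 0.02)))
  h2 <- collate_histogram(two)
  lo <- sum(h2$count[h2$bin_center < 0.6])
  expect_lt(abs(lo - 5000), 3 * sqrt(10000 * 0.25))
  expect_equal(sum(h2$density) * binw, 1, tolerance = 1e-9)
})
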