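test_that("crosstalk estimation recovers the leakage ratio", {
  # exact proportionality
  tr <- make_trace(rep(c(1000, 800), 50), rep(c(100, 80), 50))
  g <- estimate_crosstalk(as_trace_set(list(tr)))
  expect_equal(g$g, 0.1, tolerance = 1e-12)
  # zero acceptor signal
  tr0 <- make_trace(rep(1000, 100), rep(0, 100))
  expect_equal(estimate_crosstalk(as_trace_set(list(tr0)))$g, 0)
  # generation-parameter recovery at 2% channel noise
  phys <- photophysics_config(total_intensity = 1000, crosstalk_g = 0.07,
                              noise_sd = 20, donor_bleach_mean = 200)
  don <- simulate_donor_only(20, phys, duration = 60, seed = 51)
  ghat <- estimate_crosstalk(don)$g
  expect_lt(abs(ghat - 0.07), 0.005)
  # invariance to uniform intensity rescaling
  tr2 <- make_trace(tr$ch_donor * 3.7, tr$ch_acceptor * 3.7)
  expect_equal(estimate_crosstalk(as_trace_set(list(tr2)))$g, 0.1,
               tolerance = 1e-12)
})

test_that("FRET computation implements the crosstalk correction", {
  tr <- make_trace(c(rep(100, 10), rep(200, 10)),
                   c(rep(100, 10), rep(120, 10)))
  tj0 <- compute_fret(tr, crosstalk_model(0))
  expect_equal(tj0$fret[1L], 0.5)
  tj <- compute_fret(tr, crosstalk_model(0.1))
  # donor 200, acceptor 120, g = 0.1: CI = 100, FRET = 100/300
  expect_equal(tj$fret[11L], 1 / 3, tolerance = 1e-12)
  # g = 0 reduces exactly to A / (A + D)
  expect_equal(tj0$fret, tr$ch_acceptor / (tr$ch_acceptor + tr$ch_donor))
  # strictly increasing in acceptor at fixed donor and g
  a <- seq(10, 500, by = 10)
  f <- vapply(a, function(ai) {
    compute_fret(make_trace(rep(200, 10), rep(ai, 10)),
                 crosstalk_model(0.07))$fret[1L]
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("calibrated pipeline recovers a 0.4 generation cohort", {
  phys <- phys_noisy(fret_sd = 0.08, g = 0.07, donor_bleach = Inf,
                     acceptor_bleach = Inf)
  don <- simulate_donor_only(15, phys, duration = 60, seed = 61)
  g <- estimate_crosstalk(don)
  coh <- simulate_cohort(25, one_state_scheme(0.4), phys, duration = 60,
                         seed = 62)
  fret <- unlist(lapply(coh, function(tr) compute_fret(tr, g)$fret))
  expect_lt(abs(mean(fret) - 0.40), 0.01)
})

test_that("step detection finds photobleach events", {
  # noiseless step at frame 150: exactly one event at frame 150
  x <- c(rep(1000, 150), rep(0, 150))
  ev <- detect_photobleach_steps(x)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$frame, 150L)
  expect_equal(ev$magnitude, -1000)
  # two sequential drops: two events in order
  x2 <- c(rep(1000, 100), rep(500, 100), rep(0, 100))
  ev2 <- detect_photobleach_steps(x2)
  expect_equal(ev2$frame, c(100L, 200L))
  # SNR-5 single step localized within 1 frame in >= 95% of replicates
  set.seed(77)
  hits <- vapply(seq_len(500), function(r) {
    y <- c(rep(500, 150), rep(0, 150)) + rnorm(300, 0, 100)
    e <- detect_photobleach_steps(y)
    nrow(e) >= 1L && min(abs(e$frame - 150L)) <= 1L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # pure noise: no events
  set.seed(78)
  expect_equal(nrow(detect_photobleach_steps(rnorm(200, 500, 30))), 0L)
})

test_that("molecule selection keeps single-pair anticorrelated traces", {
  phys <- phys_noisy(fret_sd = 0.06, donor_bleach = 300,
                     acceptor_bleach = 60)
  set <- simulate_cohort(6, two_state_scheme(0.1, 0.1), phys,
                         duration = 80, seed = 91)
  sel <- select_molecules(set)
  expect_equal(nrow(sel$report), 6L)
  # molecules whose acceptor bleached before the donor, with both events in
  # the record, must be accepted
  for (i in seq_along(set)) {
    tt <- attr(set[[i]], "truth")
    observable <- !is.na(tt$acceptor_bleach_frame) &&
      (is.na(tt$donor_bleach_frame) ||
         tt$acceptor_bleach_frame < tt$donor_bleach_frame - 5) &&
      tt$acceptor_bleach_frame > 10
    if (observable && !is.na(tt$donor_bleach_frame)) {
      expect_true(sel$report$pass[i],
                  label = sprintf("molecule %d accepted", i))
    }
  }

  # two acceptor bleach steps with an unresponsive donor: multi-acceptor
  tr2 <- make_trace(rep(200, 300),
                    c(rep(800, 100), rep(400, 100), rep(20, 100)))
  # give the trace a terminal donor bleach so the donor count is provable
  tr2$ch_donor[251:300] <- 0
  tr2$ch_acceptor[251:300] <- 0
  r2 <- select_molecules(as_trace_set(list(tr2)))$report
  expect_false(r2$pass)
  expect_equal(r2$reason, "multi-acceptor")

  # pure-noise trace rejected
  set.seed(5)
  trn <- make_trace(rnorm(200, 300, 20), rnorm(200, 300, 20))
  rn <- select_molecules(as_trace_set(list(trn)))$report
  expect_false(rn$pass)
})

test_that("photobleach truncation applies the min rule and censoring", {
  tr <- make_trace(rep(500, 400), rep(500, 400))
  tj <- compute_fret(tr, crosstalk_model(0))
  # donor bleach frame 300, acceptor 200: truncation at 200
  cut <- truncate_at_photobleach(tj, donor_bleach = 300,
                                 acceptor_bleach = 200)
  expect_equal(cut$truncation_frame, 200L)
  expect_equal(length(cut$fret), 200L)
  expect_false(cut$censored)
  # lifetime: 200 frames x 0.2 s = 40 s
  expect_equal(cut$imaging_lifetime, 40)
  # no bleach: full length, censored
  full <- truncate_at_photobleach(tj)
  expect_equal(length(full$fret), 400L)
  expect_true(full$censored)
  # bleach at frame 0 is an error
  expect_error(truncate_at_photobleach(tj, donor_bleach = 0), "frame 0")
})
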