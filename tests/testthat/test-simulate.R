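test_that("state-path simulation matches continuous-time Markov theory", {
  # one state or all-zero rates: constant path, no jumps
  p1 <- simulate_state_path(one_state_scheme(0.4), 10, 0.2, seed = 1)
  expect_equal(unique(p1$states), 1L)
  expect_equal(nrow(p1$jumps), 0L)
  p0 <- simulate_state_path(
    kinetic_scheme(c("a", "b"), c(0.4, 0.8), matrix(0, 2, 2)), 10, 0.2,
    seed = 1)
  expect_equal(unique(p0$states), 1L)

  # symmetric two-state at 0.5/s: dwell mean 2 s within 3 SE, and the
  # dwell distribution is exponential (KS test at alpha = 0.01)
  set.seed(42)
  dwells <- numeric(0)
  while (length(dwells) < 1e4) {
    p <- simulate_state_path(two_state_scheme(0.5, 0.5), 4000, 0.2)
    dwells <- c(dwells, diff(c(0, p$jumps$time)))
  }
  dwells <- dwells[seq_len(1e4)]
  se <- 2 / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 2), 3 * se)
  ks <- suppressWarnings(ks.test(dwells, "pexp", 0.5))
  expect_gt(ks$p.value, 0.01)

  # invalid scheme rejected
  expect_error(
    kinetic_scheme(c("a", "b"), c(0.4, 0.8),
                   matrix(c(0, -1, 1, 0), 2, 2)),
    "negative")
})

test_that("two-color rendering follows the crosstalk forward model", {
  path <- simulate_state_path(one_state_scheme(0.5), 10, 0.2, seed = 1)
  tr <- render_two_color(path, phys_clean(g = 0), seed = 1)
  expect_equal(tr$ch_donor, rep(500, 50))
  expect_equal(tr$ch_acceptor, rep(500, 50))

  path0 <- simulate_state_path(one_state_scheme(0), 10, 0.2, seed = 1)
  tr0 <- render_two_color(path0, phys_clean(g = 0.1), seed = 1)
  expect_equal(tr0$ch_donor, rep(1000, 50))
  expect_equal(tr0$ch_acceptor, rep(100, 50))
})

test_that("render -> calibrate -> FRET round trip recovers the input", {
  phys <- phys_noisy(fret_sd = 0.05, g = 0.07, donor_bleach = Inf,
                     acceptor_bleach = Inf)
  don <- simulate_donor_only(15, phys, duration = 60, seed = 21)
  g <- estimate_crosstalk(don)
  coh <- simulate_cohort(20, one_state_scheme(0.8), phys, duration = 60,
                         seed = 22)
  fret <- unlist(lapply(coh, function(tr) compute_fret(tr, g)$fret))
  expect_lt(abs(mean(fret) - 0.80), 0.01)
})

test_that("trace sets are reproducible and physically consistent", {
  phys <- phys_noisy()
  a <- simulate_cohort(4, two_state_scheme(), phys, duration = 30, seed = 9)
  b <- simulate_cohort(4, two_state_scheme(), phys, duration = 30, seed = 9)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))

  # finiteness and post-donor-bleach darkness
  phys_fast <- phys_noisy(donor_bleach = 10, acceptor_bleach = 1e6)
  set.seed(5)
  coh <- simulate_cohort(20, two_state_scheme(), phys_fast, duration = 60,
                         seed = 31)
  for (tr in coh) {
    expect_true(all(is.finite(tr$ch_donor) & is.finite(tr$ch_acceptor)))
    db <- attr(tr, "truth")$donor_bleach_frame
    if (!is.na(db)) {
      post <- tr$frame >= db
      expect_lt(mean(tr$ch_acceptor[post]), 5 * phys_fast$noise_sd)
    }
  }
})

test_that("injection cohorts honor injection time and stability split", {
  phys <- phys_noisy()
  inj <- injection_config(injection_time = 10, wait_mean = 10.6,
                          fraction_stable = 0.8)
  set <- simulate_injection_cohort(168, inj, phys, duration = 120, seed = 3)
  truth <- attr(set, "truth")
  expect_equal(nrow(truth), 168L)
  # CLT on the exponential wait mean
  expect_lt(abs(mean(truth$wait) - 10.6), 3 * 10.6 / sqrt(168))
  # no binding precedes the injection
  expect_true(all(truth$bind_time >= 10))
  for (tr in set) {
    j <- attr(tr, "truth")$jumps
    if (nrow(j) > 0L) expect_gte(min(j$time), 10)
  }

  # fully stable cohort: no release (2 -> 1) jumps in any ground truth
  inj1 <- injection_config(fraction_stable = 1)
  set1 <- simulate_injection_cohort(30, inj1, phys, duration = 80, seed = 4)
  for (tr in set1) {
    j <- attr(tr, "truth")$jumps
    expect_equal(sum(j$from == 2L & j$to == 1L), 0L)
  }
})

test_that("three-color rendering gives frame-exact binding coincidence", {
  sch <- two_state_scheme(0, 0)
  # unbound throughout: all 488-frame totals ~ 0
  p_un <- simulate_state_path(sch, 20, 0.2, seed = 1, initial_state = 1L)
  tr_un <- render_three_color(p_un, phys_clean(), seed = 1)
  b <- tr_un[tr_un$laser == 488L, ]
  expect_equal(max(abs(b$ch_blue + b$ch_donor + b$ch_acceptor)), 0)

  # bound throughout, noise free: constant configured 488 total
  p_b <- simulate_state_path(sch, 20, 0.2, seed = 1, initial_state = 2L)
  tr_b <- render_three_color(p_b, phys_clean(), seed = 1)
  bb <- tr_b[tr_b$laser == 488L, ]
  tot <- bb$ch_blue + bb$ch_donor + bb$ch_acceptor
  expect_equal(unique(round(tot, 9)), 1000)

  # binding at a known frame: first lit 488 frame is the first 488 frame
  # at/after the binding frame
  jumps <- data.frame(time = 8.05, from = 1L, to = 2L)
  path <- pprfret:::path_from_jumps(jumps, 20, 0.2, 1L, sch)
  tr <- render_three_color(path, phys_clean(), seed = 1)
  b3 <- tr[tr$laser == 488L, ]
  lit <- b3$frame[(b3$ch_blue + b3$ch_donor + b3$ch_acceptor) > 500]
  bind_frame <- min(which(path$fret >= 0.5)) - 1L
  expect_equal(min(lit), min(b3$frame[b3$frame >= bind_frame]))
})

test_that("titration simulation evaluates the depletion isotherm", {
  # stoichiometric and saturation limits
  expect_equal(bound_fraction_depletion(1e9, 1.2, 5), 1, tolerance = 1e-4)
  expect_equal(bound_fraction_depletion(2, 0, 5), 2 / 5)
  expect_equal(bound_fraction_depletion(7, 0, 5), 1)
  # direct quadratic evaluation at Kd = S = L = 5 nM
  expect_equal(bound_fraction_depletion(5, 5, 5), (15 - sqrt(125)) / 10,
               tolerance = 1e-12)
  # noiseless curve reproduces the model
  tm <- titration_model(kd = 1.2, noise_sd = 0)
  cv <- simulate_titration(tm, seed = 1)
  expect_equal(cv$fret, attr(cv, "truth")$fret_true)
  expect_equal(length(cv$ligand_conc), 12L)
})

test_that("trace tables round-trip through delimited text", {
  phys <- phys_noisy()
  set <- simulate_cohort(3, two_state_scheme(), phys, duration = 20,
                         seed = 8)
  f <- tempfile(fileext = ".csv")
  tf <- tempfile(fileext = ".json")
  write_traces(set, f, truth_file = tf)
  back <- read_traces(f, tf)
  expect_equal(length(back), 3L)
  expect_equal(back[[1L]]$ch_donor, set[[1L]]$ch_donor, tolerance = 1e-9)
  expect_equal(back[[2L]]$laser, set[[2L]]$laser)
  unlink(c(f, tf))
})
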