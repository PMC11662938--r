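# Shared fixtures, built in code at test time.

# Noise-free photophysics: deterministic rendering, no bleaching.
phys_clean <- function(g = 0, total = 1000) {
  photophysics_config(total_intensity = total, crosstalk_g = g,
                      noise_sd = 0, background = 0,
                      donor_bleach_mean = Inf, acceptor_bleach_mean = Inf,
                      blue_bleach_mean = Inf)
}

# Standard cohort photophysics at a FRET-scale noise level.
phys_noisy <- function(fret_sd = 0.08, g = 0.07, donor_bleach = 600,
                       acceptor_bleach = 600) {
  photophysics_config(
    total_intensity = 1000, crosstalk_g = g,
    noise_sd = channel_noise_for_fret_sd(fret_sd, 1000),
    donor_bleach_mean = donor_bleach, acceptor_bleach_mean = acceptor_bleach
  )
}

# A literal, loop-based reference implementation of the forward-backward
# nonlinear filter, kept deliberately independent of the package version.
nl_filter_reference <- function(x, p = 5, n_fa = 1, f = 2, n_scales = 4,
                                m = 10) {
  n <- length(x)
  wins <- n_fa * f^(0:(n_scales - 1))
  out <- numeric(n)
  for (t in 1:n) {
    preds <- c(); errs <- c()
    for (w in wins) {
      # forward predictor at position j: mean of x[j-w .. j-1]
      if (t - w >= 1) {
        preds <- c(preds, mean(x[(t - w):(t - 1)]))
        es <- c()
        for (j in max(w + 1, t - m + 1):t) {
          es <- c(es, (mean(x[(j - w):(j - 1)]) - x[j])^2)
        }
        errs <- c(errs, mean(es))
      }
      # backward predictor
      if (t + w <= n) {
        preds <- c(preds, mean(x[(t + 1):(t + w)]))
        es <- c()
        for (j in t:min(n - w, t + m - 1)) {
          es <- c(es, (mean(x[(j + 1):(j + w)]) - x[j])^2)
        }
        errs <- c(errs, mean(es))
      }
    }
    if (length(preds) == 0) { out[t] <- x[t]; next }
    if (any(errs <= 1e-12)) {
      wt <- as.numeric(errs <= 1e-12)
    } else {
      wt <- errs^(-p)
    }
    out[t] <- sum(wt * preds) / sum(wt)
  }
  out
}

# Deterministic staircase trace (no noise) as a raw fret_trace for QC tests.
make_trace <- function(donor, acceptor, dt = 0.2, id = "fix1") {
  n <- length(donor)
  tr <- data.frame(
    molecule_id = id, frame = 0:(n - 1), time_s = (0:(n - 1)) * dt,
    laser = 532L, ch_donor = donor, ch_acceptor = acceptor,
    ch_blue = NA_real_
  )
  attr(tr, "frame_interval") <- dt
  class(tr) <- c("fret_trace", "data.frame")
  tr
}

# Minimal hand-built hmm_fit for kinetics unit tests: an idealized
# two-level series with known frame interval and lifetime.
make_fit <- function(idealized, dt = 0.2, id = "fit1",
                     lifetime = length(idealized) * dt) {
  lv <- sort(unique(idealized))
  structure(
    list(k = length(lv), state_means = lv,
         state_sds = rep(0.05, length(lv)),
         transition_matrix = diag(length(lv)),
         initial_probs = rep(1 / length(lv), length(lv)),
         path = match(idealized, lv), idealized = idealized,
         series = idealized,
         molecule_id = id, frame_interval = dt,
         imaging_lifetime = lifetime, censored = FALSE),
    class = "hmm_fit"
  )
}
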