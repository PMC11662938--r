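#' Classify FRET transitions of an HMM fit
#'
#' Every change in the idealized (Viterbi state-mean) series produces one
#' transition record with the departing and arriving FRET levels. The
#' directional class is assigned from the side of the binding threshold each
#' level falls on: `T_low-high` (binding) when the departing mean is below
#' and the arriving mean at/above the threshold, `T_high-low` (release) for
#' the reverse; changes between states on the same side are recorded as
#' `within` and excluded from the two classes. State means exactly at the
#' threshold count as high.
#'
#' @param fit An `hmm_fit`.
#' @param cfg An [analysis_config].
#' @return Data frame with columns `frame` (0-based first frame of the
#'   arriving state), `time_s`, `f_before`, `f_after`, `class`
#'   (`"T_low-high"`, `"T_high-low"` or `"within"`).
#' @export
classify_transitions <- function(fit, cfg = analysis_config()) {
  stopifnot(inherits(fit, "hmm_fit"), inherits(cfg, "analysis_config"))
  ide <- fit$idealized
  ch <- which(diff(ide) != 0)
  if (length(ch) == 0L) {
    return(data.frame(frame = integer(), time_s = numeric(),
                      f_before = numeric(), f_after = numeric(),
                      class = character()))
  }
  f_before <- ide[ch]
  f_after <- ide[ch + 1L]
  hi_b <- f_before >= cfg$fret_threshold
  hi_a <- f_after >= cfg$fret_threshold
  cls <- ifelse(!hi_b & hi_a, "T_low-high",
                ifelse(hi_b & !hi_a, "T_high-low", "within"))
  data.frame(frame = ch,                      # 0-based: ch is 1-based index
             time_s = ch * fit$frame_interval,
             f_before = f_before, f_after = f_after, class = cls)
}

#' Cumulative residence times with censoring rules
#'
#' The idealized series is reduced to its side (low/high of the binding
#' threshold) per frame, and consecutive same-side states are merged so that
#' each dwell is the cumulative time spent on one side before a crossing.
#' The final dwell of every molecule — truncated by photobleaching, so its
#' true extent is unknowable — is deleted. Completed dwells shorter than the
#' minimum residence time `2 * F * N_FA` (the smoothing floor of the
#' denoising filter) are discarded.
#'
#' @param fit An `hmm_fit`.
#' @param cfg An [analysis_config].
#' @return Data frame of retained dwells (`molecule_id`, `class` of the
#'   terminating transition, `duration` in seconds, `side`), with attribute
#'   `accounting`: list of `kept_s`, `discarded_s`, `terminal_s`,
#'   `lifetime_s` satisfying
#'   `kept_s + discarded_s + terminal_s == lifetime_s`.
#' @export
residence_times <- function(fit, cfg = analysis_config()) {
  stopifnot(inherits(fit, "hmm_fit"), inherits(cfg, "analysis_config"))
  dt <- fit$frame_interval
  side <- ifelse(fit$idealized >= cfg$fret_threshold, "high", "low")
  r <- rle(side)
  durations <- r$lengths * dt
  n_dwell <- length(durations)
  terminal_s <- durations[n_dwell]
  completed <- seq_len(n_dwell - 1L)
  keep <- completed[durations[completed] >= cfg$min_residence_s]
  drop <- completed[durations[completed] < cfg$min_residence_s]
  out <- if (length(keep) > 0L) {
    data.frame(
      molecule_id = fit$molecule_id,
      class = ifelse(r$values[keep] == "low", "T_low-high", "T_high-low"),
      duration = durations[keep],
      side = r$values[keep]
    )
  } else {
    data.frame(molecule_id = character(), class = character(),
               duration = numeric(), side = character())
  }
  attr(out, "accounting") <- list(
    kept_s = sum(durations[keep]),
    discarded_s = sum(durations[drop]),
    terminal_s = terminal_s,
    lifetime_s = length(fit$idealized) * dt
  )
  out
}

#' Binding-and-release rate of a molecule
#'
#' Number of threshold crossings in each direction divided by the molecule's
#' imaging lifetime (time until photobleaching).
#'
#' @param fit An `hmm_fit`.
#' @param cfg An [analysis_config].
#' @return One-row data frame: `molecule_id`, `n_binding`, `n_release`,
#'   `lifetime_s`, `binding_rate`, `release_rate`, `total_rate` (all
#'   per second).
#' @export
binding_release_rate <- function(fit, cfg = analysis_config()) {
  lifetime <- fit$imaging_lifetime
  if (is.null(lifetime) || !is.finite(lifetime) || lifetime <= 0) {
    stop("imaging lifetime must be positive")
  }
  tr <- classify_transitions(fit, cfg)
  nb <- sum(tr$class == "T_low-high")
  nr <- sum(tr$class == "T_high-low")
  data.frame(molecule_id = fit$molecule_id, n_binding = nb, n_release = nr,
             lifetime_s = lifetime,
             binding_rate = nb / lifetime, release_rate = nr / lifetime,
             total_rate = (nb + nr) / lifetime)
}

#' Fraction of dynamic molecules in a cohort
#'
#' A molecule is dynamic when its classified transitions include both a
#' binding (`T_low-high`) and a release (`T_high-low`) event; molecules with
#' no transitions count as static.
#'
#' @param fits List of `hmm_fit` objects.
#' @param cfg An [analysis_config].
#' @return List with `dynamic_fraction`, `n_dynamic`, `n` and the logical
#'   per-molecule vector `dynamic`.
#' @export
dynamic_fraction <- function(fits, cfg = analysis_config()) {
  stopifnot(length(fits) >= 1)
  dyn <- vapply(fits, function(f) {
    tr <- classify_transitions(f, cfg)
    any(tr$class == "T_low-high") && any(tr$class == "T_high-low")
  }, logical(1))
  list(dynamic_fraction = mean(dyn), n_dynamic = sum(dyn), n = length(dyn),
       dynamic = dyn)
}

#' Time from injection to first binding
#'
#' Time from ligand injection to the first `T_low-high` transition of a
#' molecule. Molecules showing no binding before photobleach truncation are
#' censored at their imaging lifetime.
#'
#' @param fit An `hmm_fit`.
#' @param cfg An [analysis_config].
#' @param injection_time Injection time (s), within the record.
#' @return One-row data frame `molecule_id`, `t_bind` (NA when censored),
#'   `censored`, `observe_end` (last observed time after injection).
#' @export
time_to_first_binding <- function(fit, cfg = analysis_config(),
                                  injection_time = 10) {
  lifetime <- fit$imaging_lifetime
  if (injection_time >= lifetime + fit$frame_interval) {
    return(data.frame(molecule_id = fit$molecule_id, t_bind = NA_real_,
                      censored = TRUE,
                      observe_end = max(lifetime - injection_time, 0)))
  }
  tr <- classify_transitions(fit, cfg)
  tb <- tr$time_s[tr$class == "T_low-high"]
  tb <- tb[tb >= injection_time]
  if (length(tb) == 0L) {
    data.frame(molecule_id = fit$molecule_id, t_bind = NA_real_,
               censored = TRUE, observe_end = lifetime - injection_time)
  } else {
    data.frame(molecule_id = fit$molecule_id,
               t_bind = min(tb) - injection_time,
               censored = FALSE, observe_end = lifetime - injection_time)
  }
}

#' Cohort summary of first-binding times
#'
#' Mean and standard error over the uncensored binding times (censored
#' molecules are excluded from the mean, matching reporting of the time
#' until the first observed transition). A Kaplan-Meier restricted-mean
#' alternative that uses the censored molecules is available as
#' `method = "km"`.
#'
#' @param fits List of `hmm_fit` objects.
#' @param cfg An [analysis_config].
#' @param injection_time Injection time (s).
#' @param method `"observed"` (default) or `"km"`.
#' @return List with `mean`, `sem`, `n_observed`, `n_censored` and the
#'   per-molecule table `events`.
#' @export
cohort_first_binding <- function(fits, cfg = analysis_config(),
                                 injection_time = 10,
                                 method = c("observed", "km")) {
  method <- match.arg(method)
  ev <- do.call(rbind, lapply(fits, time_to_first_binding, cfg = cfg,
                              injection_time = injection_time))
  obs <- ev$t_bind[!ev$censored]
  if (method == "observed") {
    m <- mean(obs)
    s <- if (length(obs) > 1L) sd(obs) / sqrt(length(obs)) else NA_real_
  } else {
    tt <- ifelse(ev$censored, ev$observe_end, ev$t_bind)
    fitkm <- survival::survfit(
      survival::Surv(tt, !ev$censored) ~ 1
    )
    sm <- summary(fitkm, rmean = max(tt))$table
    m <- unname(sm["rmean"])
    s <- unname(sm["se(rmean)"])
  }
  list(mean = m, sem = s, n_observed = sum(!ev$censored),
       n_censored = sum(ev$censored), events = ev)
}

#' Synchronized average around binding transitions
#'
#' Aligns the FRET series of every qualifying binding transition (departing
#' low-state residence time greater than `sync_min_residence`) at the
#' transition frame and averages over events, giving the mean FRET profile
#' from `-sync_window` to `+sync_window` seconds. Events closer than the
#' window to the record edges are padded with NA and masked from the
#' average.
#'
#' @param fits List of `hmm_fit` objects.
#' @param cfg An [analysis_config].
#' @param use_raw Use the raw (pre-denoising) series when stored (default
#'   FALSE: the series the HMM saw).
#' @return List with `profiles` (events x lags matrix), `lag_s`, `mean`,
#'   `sd`, `n_events`.
#' @export
synchronized_transition_average <- function(fits, cfg = analysis_config(),
                                            use_raw = FALSE) {
  dt <- fits[[1L]]$frame_interval
  w <- as.integer(round(cfg$sync_window / dt))
  lag_s <- (-w:w) * dt
  rows <- list()
  for (fit in fits) {
    series <- fit$series
    tr <- classify_transitions(fit, cfg)
    dw <- residence_dwell_bounds(fit, cfg)
    for (i in seq_len(nrow(tr))) {
      if (tr$class[i] != "T_low-high") next
      # residence time of the departing (low) dwell
      f <- tr$frame[i]                     # 0-based first frame of new state
      pre <- dw$duration[dw$end_frame == f]
      if (length(pre) == 0L || pre[1L] <= cfg$sync_min_residence) next
      idx <- (f - w):(f + w) + 1L          # 1-based window, centered at f
      prof <- rep(NA_real_, length(idx))
      ok <- idx >= 1L & idx <= length(series)
      prof[ok] <- series[idx[ok]]
      rows[[length(rows) + 1L]] <- prof
    }
  }
  if (length(rows) == 0L) {
    return(list(profiles = matrix(numeric(), 0L, 2L * w + 1L),
                lag_s = lag_s, mean = rep(NA_real_, 2L * w + 1L),
                sd = rep(NA_real_, 2L * w + 1L), n_events = 0L))
  }
  profiles <- do.call(rbind, rows)
  list(profiles = profiles, lag_s = lag_s,
       mean = colMeans(profiles, na.rm = TRUE),
       sd = apply(profiles, 2L, sd, na.rm = TRUE),
       n_events = nrow(profiles))
}

# Side dwells with their terminating frame (0-based first frame of the next
# side), including dwells of any duration; helper for the synchronized
# average.
residence_dwell_bounds <- function(fit, cfg) {
  dt <- fit$frame_interval
  side <- ifelse(fit$idealized >= cfg$fret_threshold, "high", "low")
  r <- rle(side)
  ends <- cumsum(r$lengths)
  data.frame(side = r$values, duration = r$lengths * dt,
             end_frame = ends)   # 0-based frame where the NEXT dwell starts
}

#' Pooled FRET efficiency histogram
#'
#' Collates the per-frame FRET values of all trajectories into a histogram
#' over `[-0.2, 1.2]`, in both raw-count and density-normalized (unit
#' integral) form. Values outside the range are dropped.
#'
#' @param trajs List of `fret_trajectory` objects (or numeric series).
#' @param bins Number of bins (default 56, i.e. 0.025 FRET per bin).
#' @param range Histogram range (default `c(-0.2, 1.2)`).
#' @return Data frame `bin_center`, `count`, `density`.
#' @export
collate_histogram <- function(trajs, bins = 56L, range = c(-0.2, 1.2)) {
  stopifnot(length(trajs) >= 1)
  vals <- unlist(lapply(trajs, function(tj) {
    if (inherits(tj, "fret_trajectory")) tj$fret else as.numeric(tj)
  }))
  vals <- vals[is.finite(vals) & vals >= range[1L] & vals <= range[2L]]
  breaks <- seq(range[1L], range[2L], length.out = bins + 1L)
  h <- hist(vals, breaks = breaks, plot = FALSE)
  data.frame(bin_center = h$mids, count = h$counts, density = h$density)
}
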