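#' Demultiplex an ALEX trace by excitation laser
#'
#' Partitions the frames of an alternating-laser-excitation trace into the
#' 532 nm sub-trace (donor/acceptor FRET frames) and the 488 nm sub-trace
#' (direct blue-dye excitation), preserving the original frame indices.
#'
#' @param trace A `fret_trace` with a `laser` column tagging each frame.
#' @return An object of class `alex_trace`: list with `g532` and `b488`
#'   (data frames with original `frame` indices), `frame_interval`
#'   (original grid) and `molecule_id`.
#' @export
demultiplex_alex <- function(trace) {
  if (is.null(trace$laser) || anyNA(trace$laser)) {
    stop("laser tags are missing")
  }
  g532 <- trace[trace$laser == 532L, , drop = FALSE]
  b488 <- trace[trace$laser == 488L, , drop = FALSE]
  structure(
    list(g532 = g532, b488 = b488,
         frame_interval = attr(trace, "frame_interval") %||%
           (if (nrow(trace) > 1L) median(diff(trace$time_s)) else 0.2),
         molecule_id = trace$molecule_id[1L],
         truth = attr(trace, "truth")),
    class = "alex_trace"
  )
}

#' Reassemble a demultiplexed ALEX trace
#'
#' @param alex An `alex_trace`.
#' @return The original-order `fret_trace` data frame.
#' @export
reassemble_alex <- function(alex) {
  out <- rbind(as.data.frame(alex$g532), as.data.frame(alex$b488))
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval") <- alex$frame_interval
  attr(out, "truth") <- alex$truth
  class(out) <- c("fret_trace", "data.frame")
  out
}

#' Total fluorescence on 488 nm frames
#'
#' Per 488 nm frame, the sum of the three background-subtracted detection
#' channels — the direct readout of whether a blue-labeled RNA is bound
#' (total near zero when unbound; near the blue-excited total intensity when
#' bound and participating in FRET with the protein dyes). The per-channel
#' background is estimated per molecule from the dark (unbound) frames —
#' the frames at or below the channel median — unless given.
#'
#' @param alex An `alex_trace` with a non-empty 488 sub-trace.
#' @param background Optional length-3 numeric background (blue, donor,
#'   acceptor channels).
#' @return Data frame `frame` (original index), `time_s`, `total488`.
#' @export
total_488_fluorescence <- function(alex, background = NULL) {
  stopifnot(inherits(alex, "alex_trace"))
  b <- alex$b488
  if (nrow(b) == 0L) stop("488 sub-trace is empty")
  chans <- cbind(b$ch_blue, b$ch_donor, b$ch_acceptor)
  if (is.null(background)) {
    background <- apply(chans, 2L, function(v) median(v[v <= median(v)]))
  }
  tot <- as.numeric(chans %*% c(1, 1, 1)) - sum(background)
  data.frame(frame = b$frame, time_s = b$time_s, total488 = tot)
}

#' Correlate protein-FRET transitions with RNA (488) signal
#'
#' Binding-coincidence analysis of a three-color molecule: (i) the lag, in
#' original frames, from each binding (`T_low-high`) transition of the
#' protein FRET trajectory to the nearest onset of 488 nm total
#' fluorescence; (ii) the distribution of 488 totals split by whether the
#' protein resides below or at/above the FRET threshold; and (iii)
#' synchronized profiles of protein FRET and max-normalized 488 total around
#' each binding transition. Under frame alternation the 532 and 488
#' observations never share a frame, so the minimal resolvable lag is one
#' original frame; same-frame coincidence is operationalized as
#' `abs(lag) <= 1`.
#'
#' @param fit_ppr An `hmm_fit` of the 532-frame FRET trajectory, whose
#'   stored series is on the 532 sub-grid; the fit must carry the original
#'   frame indices via `frames532`.
#' @param total488 Data frame from [total_488_fluorescence].
#' @param frames532 Original 0-based frame indices of the fitted 532 series.
#' @param cfg An [analysis_config].
#' @param sync_window Half-width of the synchronized profiles (s).
#' @return List with `lags` (per binding event, original frames),
#'   `coincident_fraction` (lag magnitude <= 1), `split` (mean/sd/n of 488
#'   totals in the low and high FRET states), `profiles` (synchronized mean
#'   FRET and normalized 488), and `min_resolvable_lag_frames = 1`.
#' @export
correlate_binding <- function(fit_ppr, total488, frames532,
                              cfg = analysis_config(), sync_window = 10) {
  stopifnot(inherits(fit_ppr, "hmm_fit"))
  n532 <- length(fit_ppr$series)
  if (length(frames532) != n532) {
    stop("frames532 must match the fitted 532 series length")
  }
  # (i) lags from each T_low-high to the nearest 488 onset
  tr <- classify_transitions(fit_ppr, cfg)
  bind_idx <- which(tr$class == "T_low-high")
  onsets <- detect_photobleach_steps(total488$total488, sensitivity = 3,
                                     direction = "up")
  onset_frames <- total488$frame[onsets$frame + 1L]
  lags <- numeric(0)
  for (i in bind_idx) {
    # original frame of the first high frame
    f532 <- tr$frame[i]                  # 0-based index on the 532 sub-grid
    f_orig <- frames532[f532 + 1L]
    if (length(onset_frames) == 0L) next
    lags <- c(lags, onset_frames[which.min(abs(onset_frames - f_orig))] -
                f_orig)
  }
  # (ii) 488 totals split by FRET state
  ide_at <- approx(frames532, fit_ppr$idealized, xout = total488$frame,
                   method = "constant", rule = 2)$y
  hi <- ide_at >= cfg$fret_threshold
  split <- data.frame(
    state = c("low", "high"),
    mean_total488 = c(mean(total488$total488[!hi]),
                      mean(total488$total488[hi])),
    sd_total488 = c(sd(total488$total488[!hi]), sd(total488$total488[hi])),
    n = c(sum(!hi), sum(hi))
  )
  # (iii) synchronized profiles around binding transitions
  dt532 <- fit_ppr$frame_interval
  dt_orig <- dt532 / 2
  w <- as.integer(round(sync_window / dt532))
  norm488 <- total488$total488 / max(abs(total488$total488), 1e-12)
  prof_fret <- list(); prof_488 <- list()
  for (i in bind_idx) {
    f532 <- tr$frame[i]
    idx <- (f532 - w):(f532 + w) + 1L
    pf <- rep(NA_real_, length(idx))
    ok <- idx >= 1L & idx <= n532
    pf[ok] <- fit_ppr$series[idx[ok]]
    prof_fret[[length(prof_fret) + 1L]] <- pf
    f_orig <- frames532[f532 + 1L]
    tgt <- f_orig + 2L * ((-w):w)
    p4 <- rep(NA_real_, length(tgt))
    mt <- match(tgt, total488$frame)
    p4[!is.na(mt)] <- norm488[mt[!is.na(mt)]]
    prof_488[[length(prof_488) + 1L]] <- p4
  }
  profiles <- if (length(prof_fret) > 0L) {
    list(lag_s = (-w:w) * dt532,
         fret_mean = colMeans(do.call(rbind, prof_fret), na.rm = TRUE),
         total488_mean = colMeans(do.call(rbind, prof_488), na.rm = TRUE))
  } else NULL
  list(lags = lags,
       coincident_fraction = if (length(lags) > 0) mean(abs(lags) <= 1)
                             else NA_real_,
       split = split,
       profiles = profiles,
       min_resolvable_lag_frames = 1L,
       original_frame_interval = dt_orig)
}
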