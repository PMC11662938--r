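#' Detect intensity change-points / photobleach steps
#'
#' Fits a piecewise-constant model by penalized least-squares binary
#' segmentation and reports the steps. The robust noise scale is estimated
#' from the median absolute first difference; a split is accepted when it
#' reduces the residual sum of squares by more than
#' `penalty * sigma^2 * log(n)`. Downward steps larger than
#' `sensitivity * sigma` are reported ordered by frame; a noiseless step of
#' any size is always found (the penalty vanishes with the noise estimate).
#'
#' @param series Numeric intensity sequence (length >= 10).
#' @param sensitivity Minimum reported step size in robust-noise units
#'   (default 3).
#' @param penalty Penalty multiplier of the `sigma^2 log(n)` split cost
#'   (default 2).
#' @param direction `"down"` (photobleaching; default), `"up"`, or `"both"`.
#' @param min_seg Minimum segment length in frames (default 2).
#' @return Data frame with columns `frame` (0-based first frame of the new
#'   level), `magnitude` (signed level change) and `sign`; attribute
#'   `levels` holds the fitted piecewise-constant series and attribute
#'   `sigma` the noise estimate. Zero rows when no step qualifies.
#' @export
detect_photobleach_steps <- function(series, sensitivity = 3, penalty = 2,
                                     direction = c("down", "up", "both"),
                                     min_seg = 2L) {
  direction <- match.arg(direction)
  x <- as.numeric(series)
  n <- length(x)
  if (n < 10L) stop("series must have at least 10 frames")
  sigma <- median(abs(diff(x))) / (sqrt(2) * 0.6744898)
  floor_gain <- 1e-10 * max(1, max(abs(x))^2)
  pen <- max(penalty * sigma^2 * log(n), floor_gain)

  cps <- integer(0)
  segment <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_seg) return(invisible(NULL))
    xs <- x[lo:hi]
    cs <- cumsum(xs)
    tot <- cs[len]
    i <- seq_len(len - 1L)
    valid <- i >= min_seg & (len - i) >= min_seg
    if (!any(valid)) return(invisible(NULL))
    # RSS reduction of splitting after position i (within-segment index)
    gain <- cs[i]^2 / i + (tot - cs[i])^2 / (len - i) - tot^2 / len
    gain[!valid] <- -Inf
    best <- which.max(gain)
    if (gain[best] > pen) {
      cp <- lo + best - 1L   # last index of left part (global)
      cps <<- c(cps, cp)
      segment(lo, cp)
      segment(cp + 1L, hi)
    }
    invisible(NULL)
  }
  segment(1L, n)
  cps <- sort(cps)

  bounds <- c(0L, cps, n)
  levels_fit <- numeric(n)
  seg_means <- numeric(length(bounds) - 1L)
  for (s in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    seg_means[s] <- mean(x[idx])
    levels_fit[idx] <- seg_means[s]
  }
  if (length(cps) == 0L) {
    ev <- data.frame(frame = integer(), magnitude = numeric(),
                     sign = integer())
  } else {
    mag <- diff(seg_means)
    ev <- data.frame(frame = cps, magnitude = mag,
                     sign = ifelse(mag < 0, -1L, 1L))
    thr <- sensitivity * sigma
    keep <- abs(ev$magnitude) > max(thr, 0)
    if (sigma == 0) keep <- abs(ev$magnitude) > 0
    ev <- ev[keep, , drop = FALSE]
    ev <- switch(direction,
                 down = ev[ev$sign < 0, , drop = FALSE],
                 up = ev[ev$sign > 0, , drop = FALSE],
                 both = ev)
    rownames(ev) <- NULL
  }
  attr(ev, "levels") <- levels_fit
  attr(ev, "sigma") <- sigma
  ev
}

#' Estimate the donor-to-acceptor crosstalk constant
#'
#' The crosstalk constant `g` is the ratio of fluorescence in the acceptor
#' and donor detection channels for molecules carrying only a donor dye. The
#' estimate is the pooled median over all pre-bleach frames of
#' `(acceptor - background) / (donor - background)`; the donor bleach frame
#' of each trace is located by step detection, and the per-channel
#' background is taken as the post-donor-bleach segment mean when a bleach
#' is observed (else 0).
#'
#' @param donor_only_traces A `fret_trace_set` of donor-only molecules.
#' @return An object of class `crosstalk_model`: list with `g`, `n_frames`
#'   (frames pooled) and `per_trace` medians.
#' @export
estimate_crosstalk <- function(donor_only_traces) {
  stopifnot(inherits(donor_only_traces, "fret_trace_set"))
  ratios <- list()
  per_trace <- numeric(0)
  for (tr in donor_only_traces) {
    d <- tr$ch_donor[tr$laser == 532L]
    a <- tr$ch_acceptor[tr$laser == 532L]
    steps <- detect_photobleach_steps(d)
    bleach <- persistent_bleach_frame(d, steps)
    if (!is.na(bleach) && bleach > 5L) {
      pre <- seq_len(bleach)
      post <- (bleach + 1L):length(d)
      bg_d <- mean(d[post])
      bg_a <- mean(a[post])
    } else {
      pre <- seq_along(d)
      bg_d <- 0
      bg_a <- 0
    }
    dd <- d[pre] - bg_d
    ok <- dd > 0
    if (!any(ok)) next
    r <- (a[pre][ok] - bg_a) / dd[ok]
    ratios[[length(ratios) + 1L]] <- r
    per_trace <- c(per_trace, median(r))
  }
  pooled <- unlist(ratios)
  if (length(pooled) == 0L) stop("undefined crosstalk: donor channel empty")
  structure(
    list(g = max(0, median(pooled)), n_frames = length(pooled),
         per_trace = per_trace),
    class = "crosstalk_model"
  )
}

#' @rdname estimate_crosstalk
#' @param g A known crosstalk constant (>= 0).
#' @export
crosstalk_model <- function(g) {
  stopifnot(g >= 0)
  structure(list(g = g, n_frames = NA_integer_, per_trace = numeric(0)),
            class = "crosstalk_model")
}

# First 0-based frame of a step after which the fitted level stays near the
# terminal background; NA when the channel never bleaches within the record.
persistent_bleach_frame <- function(x, steps, ref = NULL) {
  if (nrow(steps) == 0L) return(NA_integer_)
  lv <- attr(steps, "levels")
  sigma <- attr(steps, "sigma")
  n <- length(x)
  span <- diff(range(lv))
  if (span <= 0) return(NA_integer_)
  for (i in seq_len(nrow(steps))) {
    f <- steps$frame[i]
    post <- lv[(f + 1L):n]
    dark <- min(lv) + max(3 * sigma, 0.1 * span)
    if (all(post <= dark)) return(f)
  }
  NA_integer_
}

#' Compute a crosstalk-corrected FRET trajectory
#'
#' Per frame, the corrected acceptor intensity is
#' `CI_acceptor = ch_acceptor - g * ch_donor` and the FRET efficiency
#' `CI_acceptor / (CI_acceptor + ch_donor)`. Values are not clamped to
#' `[0, 1]`; frames with a non-positive or zero denominator are flagged
#' non-finite. Only 532 nm frames enter (demultiplex ALEX traces first).
#'
#' @param trace A `fret_trace`.
#' @param model A `crosstalk_model` (or [estimate_crosstalk] result).
#' @return An object of class `fret_trajectory`: list with `molecule_id`,
#'   `fret`, `time_s`, `frame` (original 0-based frames), `frame_interval`,
#'   `truncation_frame` (NA until truncated), `censored`,
#'   `imaging_lifetime`, and `nonfinite` flags.
#' @export
compute_fret <- function(trace, model) {
  stopifnot(inherits(model, "crosstalk_model"))
  tr <- trace[trace$laser == 532L, , drop = FALSE]
  if (nrow(tr) == 0L) stop("trace has no 532 nm frames")
  if (nrow(tr) > 2L) {
    dts <- diff(tr$time_s)
    if (diff(range(dts)) > 1e-6) stop("non-uniform frame interval")
  }
  ci <- tr$ch_acceptor - model$g * tr$ch_donor
  denom <- ci + tr$ch_donor
  fret <- ci / denom
  structure(
    list(molecule_id = tr$molecule_id[1L],
         fret = fret,
         time_s = tr$time_s,
         frame = tr$frame,
         frame_interval = if (nrow(tr) > 1L) median(diff(tr$time_s))
                          else attr(trace, "frame_interval") %||% 0.2,
         truncation_frame = NA_integer_,
         censored = TRUE,
         imaging_lifetime = nrow(tr) *
           (if (nrow(tr) > 1L) median(diff(tr$time_s)) else 0.2),
         nonfinite = !is.finite(fret)),
    class = "fret_trajectory"
  )
}

#' Truncate a FRET trajectory at photobleaching
#'
#' Keeps only frames acquired before the earlier of the donor and acceptor
#' photobleach steps. When neither channel bleaches within the record the
#' full trajectory is retained and flagged censored.
#'
#' @param traj A `fret_trajectory` (from [compute_fret]).
#' @param donor_bleach,acceptor_bleach 0-based bleach frames on the
#'   trajectory's own frame grid (NA for none), e.g. from
#'   [detect_photobleach_steps] on each channel.
#' @return The truncated `fret_trajectory` with `truncation_frame`,
#'   `imaging_lifetime` and `censored` set.
#' @export
truncate_at_photobleach <- function(traj, donor_bleach = NA,
                                    acceptor_bleach = NA) {
  stopifnot(inherits(traj, "fret_trajectory"))
  cand <- c(donor_bleach, acceptor_bleach)
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0L) {
    traj$truncation_frame <- length(traj$fret)
    traj$censored <- TRUE
    traj$imaging_lifetime <- length(traj$fret) * traj$frame_interval
    return(traj)
  }
  cut <- min(cand)
  if (cut <= 0L) stop("photobleach at frame 0 leaves an empty trajectory")
  keep <- seq_len(cut)
  traj$fret <- traj$fret[keep]
  traj$time_s <- traj$time_s[keep]
  traj$frame <- traj$frame[keep]
  traj$nonfinite <- traj$nonfinite[keep]
  traj$truncation_frame <- as.integer(cut)
  traj$censored <- FALSE
  traj$imaging_lifetime <- cut * traj$frame_interval
  traj
}

#' Process a raw trace into a truncated FRET trajectory
#'
#' Convenience wrapper: locates the donor and acceptor photobleach steps,
#' computes crosstalk-corrected FRET, and truncates at the earlier bleach.
#' The donor bleach is found on the summed donor + acceptor intensity (which
#' is insensitive to FRET transitions) and the acceptor bleach on the
#' acceptor channel with a leakage-level persistence test.
#'
#' @inheritParams compute_fret
#' @param sensitivity Step-detection sensitivity.
#' @return A truncated `fret_trajectory`.
#' @export
process_trace <- function(trace, model, sensitivity = 3) {
  tr <- trace[trace$laser == 532L, , drop = FALSE]
  bl <- locate_bleach_frames(tr, sensitivity)
  traj <- compute_fret(trace, model)
  truncate_at_photobleach(traj, bl$donor, bl$acceptor)
}

# Donor bleach: persistent collapse of total (D + A) intensity to its dark
# level. Acceptor bleach: downward acceptor step, before the donor death,
# after which the acceptor level stays below a leakage ceiling relative to
# the donor level over the same frames.
locate_bleach_frames <- function(tr, sensitivity = 3,
                                 leak_ceiling = 0.15) {
  d <- tr$ch_donor
  a <- tr$ch_acceptor
  n <- length(d)
  tot <- d + a
  steps_t <- detect_photobleach_steps(tot, sensitivity)
  donor_bleach <- persistent_bleach_frame(tot, steps_t)
  alive_end <- if (is.na(donor_bleach)) n else donor_bleach
  acceptor_bleach <- NA_integer_
  if (alive_end > 10L) {
    steps_a <- detect_photobleach_steps(a[seq_len(alive_end)], sensitivity)
    if (nrow(steps_a) > 0L) {
      for (i in seq_len(nrow(steps_a))) {
        f <- steps_a$frame[i]
        post <- (f + 1L):alive_end
        if (length(post) < 3L) next
        if (mean(a[post]) <= leak_ceiling * max(mean(d[post]), 1e-12)) {
          acceptor_bleach <- f
          break
        }
      }
    }
  }
  list(donor = donor_bleach, acceptor = acceptor_bleach)
}

#' Molecule-selection quality control
#'
#' Keeps molecules showing exactly one donor and exactly one acceptor
#' photobleach event. The donor bleach is the persistent collapse of the
#' summed intensity; the acceptor bleach is the persistent drop of the
#' acceptor channel to its leakage level while the donor is alive. Extra
#' non-conserving downward steps on either channel (steps not balanced by an
#' anticorrelated change in the other channel, the signature of additional
#' fluorophores) disqualify a molecule as multi-donor / multi-acceptor. The
#' anticorrelation criterion (Pearson correlation of donor vs acceptor over
#' pre-bleach frames below `anticorrelation_ceiling`) is applied only to
#' molecules whose trajectory contains at least one candidate FRET
#' transition.
#'
#' @param traces A `fret_trace_set`.
#' @param sensitivity Step-detection sensitivity.
#' @param anticorrelation_ceiling Maximum allowed donor/acceptor Pearson
#'   correlation for dynamic molecules (default 0).
#' @param require_acceptor_bleach,require_donor_bleach Require the bleach
#'   event to occur within the record (default TRUE, matching selection of
#'   molecules whose fluorophore count is provable).
#' @return List with `accepted` (a `fret_trace_set`, possibly empty list)
#'   and `report` (data frame of per-molecule pass/fail and reason).
#' @export
select_molecules <- function(traces, sensitivity = 3,
                             anticorrelation_ceiling = 0,
                             require_donor_bleach = TRUE,
                             require_acceptor_bleach = TRUE) {
  stopifnot(inherits(traces, "fret_trace_set"))
  rows <- list()
  keep <- logical(length(traces))
  for (k in seq_along(traces)) {
    tr0 <- traces[[k]]
    tr <- tr0[tr0$laser == 532L, , drop = FALSE]
    id <- tr$molecule_id[1L]
    verdict <- qc_one_molecule(tr, sensitivity, anticorrelation_ceiling,
                               require_donor_bleach, require_acceptor_bleach)
    keep[k] <- verdict$pass
    rows[[k]] <- data.frame(molecule_id = id, pass = verdict$pass,
                            reason = verdict$reason)
  }
  accepted <- traces[keep]
  if (sum(keep) > 0L) accepted <- as_trace_set(accepted)
  list(accepted = accepted, report = do.call(rbind, rows))
}

qc_one_molecule <- function(tr, sensitivity, anticorrelation_ceiling,
                            require_donor_bleach, require_acceptor_bleach) {
  d <- tr$ch_donor
  a <- tr$ch_acceptor
  n <- length(d)
  bl <- locate_bleach_frames(tr, sensitivity)
  if (require_donor_bleach && is.na(bl$donor)) {
    return(list(pass = FALSE, reason = "no donor bleach"))
  }
  if (require_acceptor_bleach && is.na(bl$acceptor)) {
    return(list(pass = FALSE, reason = "no acceptor bleach"))
  }
  # classify steps: conserving (FRET transition) vs non-conserving
  steps_d <- detect_photobleach_steps(d, sensitivity, direction = "both")
  steps_a <- detect_photobleach_steps(a, sensitivity, direction = "both")
  extra_d <- count_nonconserving(steps_d, steps_a, bl$donor, bl$acceptor)
  extra_a <- count_nonconserving(steps_a, steps_d, bl$acceptor, bl$donor)
  if (extra_a > 0L) return(list(pass = FALSE, reason = "multi-acceptor"))
  if (extra_d > 0L) return(list(pass = FALSE, reason = "multi-donor"))
  # anticorrelation check only for molecules with candidate transitions
  trans <- conserving_transitions(steps_d, steps_a, bl$donor, bl$acceptor)
  if (trans > 0L) {
    end_alive <- min(c(bl$donor, bl$acceptor, n), na.rm = TRUE)
    if (end_alive > 5L) {
      rho <- suppressWarnings(cor(d[seq_len(end_alive)],
                                  a[seq_len(end_alive)]))
      if (is.finite(rho) && rho > anticorrelation_ceiling) {
        return(list(pass = FALSE, reason = "not anticorrelated"))
      }
    }
  }
  list(pass = TRUE, reason = "ok")
}

# Downward steps on a channel that are neither its own bleach event, nor a
# step at the partner's bleach frame, nor matched by an opposite-sign step of
# comparable size on the partner channel (intensity conservation under FRET).
count_nonconserving <- function(steps, partner_steps, own_bleach,
                                partner_bleach) {
  down <- steps[steps$sign < 0, , drop = FALSE]
  if (nrow(down) == 0L) return(0L)
  extra <- 0L
  for (i in seq_len(nrow(down))) {
    f <- down$frame[i]
    if (!is.na(own_bleach) && abs(f - own_bleach) <= 1L) next
    if (!is.na(partner_bleach) && abs(f - partner_bleach) <= 1L) next
    j <- which(abs(partner_steps$frame - f) <= 1L &
                 partner_steps$sign > 0)
    matched <- FALSE
    if (length(j) > 0L) {
      bal <- abs(down$magnitude[i] + partner_steps$magnitude[j])
      matched <- any(bal < 0.5 * abs(down$magnitude[i]))
    }
    if (!matched) extra <- extra + 1L
  }
  extra
}

conserving_transitions <- function(steps_d, steps_a, donor_bleach,
                                   acceptor_bleach) {
  if (nrow(steps_d) == 0L || nrow(steps_a) == 0L) return(0L)
  cnt <- 0L
  for (i in seq_len(nrow(steps_d))) {
    f <- steps_d$frame[i]
    if (!is.na(donor_bleach) && abs(f - donor_bleach) <= 1L) next
    if (!is.na(acceptor_bleach) && abs(f - acceptor_bleach) <= 1L) next
    j <- which(abs(steps_a$frame - f) <= 1L &
                 steps_a$sign == -steps_d$sign[i])
    if (length(j) == 0L) next
    bal <- abs(steps_d$magnitude[i] + steps_a$magnitude[j])
    if (any(bal < 0.5 * abs(steps_d$magnitude[i]))) cnt <- cnt + 1L
  }
  cnt
}
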