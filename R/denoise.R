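#' Nonlinear forward-backward trace filtering
#'
#' Edge-preserving denoising of FRET trajectories prior to state finding,
#' after the predictor-weighted forward-backward filter of Chung & Kennedy.
#' At each frame, running-mean predictors are formed from trailing (forward)
#' and leading (backward) windows of sizes `n_fa * f^k` frames
#' (`k = 0 .. n_scales - 1`), excluding the current frame. Each predictor is
#' weighted proportionally to its mean squared prediction error over the `m`
#' trailing (forward) or leading (backward) frames raised to `-exponent_p`,
#' with the weights normalized to sum to one. Because every predictor looks
#' only to one side of the current frame, a predictor whose window straddles
#' a state transition incurs a large prediction error and loses essentially
#' all weight, so genuine steps pass through unsmoothed while plateau noise
#' is averaged away.
#'
#' At the first and last frames, where one direction has no complete window,
#' the available direction's predictors take all the weight. The output is a
#' convex combination of running means of the input and is therefore bounded
#' by the input range; constant inputs are returned unchanged.
#'
#' @param series Numeric FRET sequence; length must exceed twice the largest
#'   predictor window.
#' @param params An [nl_filter_params].
#' @return Filtered numeric sequence of the same length.
#' @export
nl_filter <- function(series, params = nl_filter_params()) {
  stopifnot(inherits(params, "nl_filter_params"))
  x <- as.numeric(series)
  n <- length(x)
  windows <- as.integer(round(params$n_fa * params$f^(seq_len(params$n_scales) - 1L)))
  wmax <- max(windows)
  if (n <= 2L * wmax) stop("series too short for the requested windows")
  m <- params$m
  p <- params$exponent_p
  eps <- 1e-12

  n_pred <- 2L * length(windows)
  preds <- matrix(NA_real_, n, n_pred)
  errs <- matrix(NA_real_, n, n_pred)
  cs <- c(0, cumsum(x))

  for (j in seq_along(windows)) {
    w <- windows[j]
    # forward predictor: mean of the w frames preceding t
    fw <- rep(NA_real_, n)
    idx <- (w + 1L):n
    fw[idx] <- (cs[idx] - cs[idx - w]) / w
    # backward predictor: mean of the w frames following t
    bw <- rep(NA_real_, n)
    idx2 <- 1L:(n - w)
    bw[idx2] <- (cs[idx2 + w + 1L] - cs[idx2 + 1L]) / w
    preds[, j] <- fw
    preds[, length(windows) + j] <- bw

    # squared prediction errors, averaged over trailing / leading m frames
    se_f <- (fw - x)^2
    se_b <- (bw - x)^2
    errs[, j] <- trailing_mean(se_f, m)
    errs[, length(windows) + j] <- leading_mean(se_b, m)
  }

  out <- numeric(n)
  for (t in seq_len(n)) {
    ok <- !is.na(preds[t, ]) & !is.na(errs[t, ])
    if (!any(ok)) {
      # only at extreme edges: fall back to nearest available predictor
      ok <- !is.na(preds[t, ])
    }
    if (!any(ok)) {
      out[t] <- x[t]
      next
    }
    e <- errs[t, ok]
    e[is.na(e)] <- max(e, na.rm = TRUE)
    if (any(e <= eps)) {
      w_t <- as.numeric(e <= eps)
    } else {
      w_t <- e^(-p)
    }
    w_t <- w_t / sum(w_t)
    out[t] <- sum(w_t * preds[t, ok])
  }
  out
}

# Mean of the available values among the m entries ending at t (inclusive).
trailing_mean <- function(v, m) {
  n <- length(v)
  out <- rep(NA_real_, n)
  good <- !is.na(v)
  vv <- ifelse(good, v, 0)
  cv <- c(0, cumsum(vv))
  cg <- c(0, cumsum(good))
  lo <- pmax(seq_len(n) - m, 0L)
  cnt <- cg[seq_len(n) + 1L] - cg[lo + 1L]
  s <- cv[seq_len(n) + 1L] - cv[lo + 1L]
  out[cnt > 0] <- s[cnt > 0] / cnt[cnt > 0]
  out
}

leading_mean <- function(v, m) {
  rev(trailing_mean(rev(v), m))
}

#' Denoise every trajectory in a list
#'
#' Photobleach-truncated trajectories can be arbitrarily short; for series
#' too short for the largest predictor window the number of scales is
#' reduced to the largest that fits, and series too short for even the base
#' window are passed through unfiltered.
#'
#' @param trajs List of `fret_trajectory` objects.
#' @param params An [nl_filter_params].
#' @return The list with each `fret` series replaced by its filtered version
#'   (original kept as `fret_raw`).
#' @export
denoise_trajectories <- function(trajs, params = nl_filter_params()) {
  lapply(trajs, function(tj) {
    tj$fret_raw <- tj$fret
    p <- params
    while (p$n_scales > 1L &&
           length(tj$fret) <= 2L * p$n_fa * p$f^(p$n_scales - 1L)) {
      p$n_scales <- p$n_scales - 1L
    }
    if (length(tj$fret) > 2L * p$n_fa) {
      tj$fret <- nl_filter(tj$fret, p)
    }
    tj
  })
}
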