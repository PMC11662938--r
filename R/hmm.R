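#' Fit a Gaussian hidden Markov model to a FRET trajectory
#'
#' State finding by maximum a posteriori expectation-maximization with
#' Gaussian emissions, a Dirichlet prior on the transition rows, and a
#' Normal-Gamma prior on each state's emission mean and precision
#' parameterized by the `mu` (prior-mean pseudo-count strength) and `beta`
#' (precision-scale multiplier) hyperparameters of [hmm_priors]. For each
#' candidate state count in `k_range` and each restart, EM is run to
#' convergence of the penalized objective (log-likelihood plus log prior,
#' guaranteed non-decreasing across iterations); the model maximizing the
#' evidence score — the maximized log-likelihood minus half the parameter
#' count times `log(T)` — is returned, with ties broken toward fewer states.
#' States are reported sorted by ascending emission mean and the trajectory
#' is decoded by the most probable (Viterbi) path.
#'
#' @param traj A `fret_trajectory` (length >= 10) or numeric FRET series.
#' @param priors An [hmm_priors].
#' @param seed Integer seed; restarts are seeded deterministically from
#'   `(seed, k, restart)`.
#' @return An object of class `hmm_fit`: list with `k`, `state_means`,
#'   `state_sds`, `transition_matrix`, `initial_probs`, `path` (Viterbi,
#'   1-based), `idealized` (state mean at each frame), `evidence`,
#'   `evidence_by_k`, `objective_trace` (per-iteration penalized objective
#'   of the winning fit), `converged`, plus trajectory metadata
#'   (`molecule_id`, `frame_interval`, `imaging_lifetime`, `series`).
#' @export
fit_hmm <- function(traj, priors = hmm_priors(), seed = 1) {
  stopifnot(inherits(priors, "hmm_priors"))
  if (inherits(traj, "fret_trajectory")) {
    x <- traj$fret
    meta <- list(molecule_id = traj$molecule_id,
                 frame_interval = traj$frame_interval,
                 imaging_lifetime = traj$imaging_lifetime,
                 censored = traj$censored)
  } else {
    x <- as.numeric(traj)
    meta <- list(molecule_id = "series",
                 frame_interval = 0.2,
                 imaging_lifetime = length(x) * 0.2,
                 censored = NA)
  }
  x <- x[is.finite(x)]
  if (length(x) < 10L) stop("trajectory too short for HMM fitting (< 10)")
  T_len <- length(x)

  best <- NULL
  evidence_by_k <- setNames(rep(-Inf, length(priors$k_range)),
                            priors$k_range)
  for (k in priors$k_range) {
    if (k > T_len) next
    for (r in seq_len(priors$restarts)) {
      init <- hmm_init(x, k, seed, r)
      fit <- hmm_map_em(x, k, init, priors)
      npar <- (k * k - k) + 2 * k + (k - 1)
      fit$evidence <- fit$loglik - 0.5 * npar * log(T_len)
      if (fit$evidence > evidence_by_k[as.character(k)]) {
        evidence_by_k[as.character(k)] <- fit$evidence
      }
      if (is.null(best) || fit$evidence > best$evidence + 1e-9) {
        best <- fit
      }
    }
  }
  best <- hmm_sort_states(best)
  path <- as.integer(viterbi_gaussian(x, best$mu, best$sigma, best$A,
                                      best$pi0))
  structure(
    c(list(k = length(best$mu),
           state_means = best$mu,
           state_sds = best$sigma,
           transition_matrix = best$A,
           initial_probs = best$pi0,
           path = path,
           idealized = best$mu[path],
           evidence = best$evidence,
           evidence_by_k = evidence_by_k,
           objective_trace = best$objective_trace,
           loglik = best$loglik,
           converged = best$converged,
           series = x),
      meta),
    class = "hmm_fit"
  )
}

hmm_init <- function(x, k, seed, restart) {
  set.seed((seed * 1009L + k * 101L + restart) %% .Machine$integer.max)
  qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  jitter_sd <- max(sd(x), 1e-3) * 0.2 * (restart > 1)
  mu <- sort(qs + rnorm(k, 0, jitter_sd))
  sigma <- rep(max(mad(x), sd(x) / 2, 1e-3), k)
  A <- matrix(0.05 / max(k - 1, 1), k, k)
  diag(A) <- if (k > 1) 0.95 else 1
  list(mu = mu, sigma = sigma, A = A, pi0 = rep(1 / k, k))
}

# MAP EM with Normal-Gamma emission priors and Dirichlet transition priors.
hmm_map_em <- function(x, k, init, priors, max_iter = 200, tol = 1e-8) {
  m0 <- priors$prior_mean
  kappa0 <- priors$mu              # pseudo-count strength on the mean
  a0 <- 2.5                        # precision-prior shape
  b0 <- priors$beta * 0.025        # precision-prior rate (beta-scaled)
  alpha_tr <- priors$transition_concentration
  mu <- init$mu; sigma <- init$sigma; A <- init$A; pi0 <- init$pi0
  T_len <- length(x)
  obj_trace <- numeric(0)
  converged <- FALSE
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    e <- fb_gaussian(x, mu, sigma, A, pi0)
    ll <- e$loglik
    obj <- ll + hmm_log_prior(mu, sigma, A, m0, kappa0, a0, b0, alpha_tr)
    obj_trace <- c(obj_trace, obj)
    if (it > 1L &&
        abs(obj - obj_trace[it - 1L]) <
          tol * (abs(obj_trace[it - 1L]) + 1)) {
      converged <- TRUE
      break
    }
    g <- e$gamma
    xs <- e$xi_sum
    nk <- colSums(g)
    xbar <- as.numeric(crossprod(g, x)) / pmax(nk, 1e-12)
    mu_new <- (kappa0 * m0 + nk * xbar) / (kappa0 + nk)
    ssq <- vapply(seq_len(k), function(j) {
      sum(g[, j] * (x - mu_new[j])^2)
    }, numeric(1))
    lambda <- (nk / 2 + a0 - 0.5) /
      (b0 + 0.5 * ssq + 0.5 * kappa0 * (mu_new - m0)^2)
    sigma_new <- pmax(1 / sqrt(lambda), 1e-4)
    if (k > 1) {
      A_new <- xs + (alpha_tr - 1)
      A_new[A_new < 1e-12] <- 1e-12
      A_new <- A_new / rowSums(A_new)
    } else {
      A_new <- matrix(1, 1, 1)
    }
    pi_new <- g[1L, ] + 1e-12
    pi_new <- pi_new / sum(pi_new)
    mu <- mu_new; sigma <- sigma_new; A <- A_new; pi0 <- pi_new
  }
  list(mu = mu, sigma = sigma, A = A, pi0 = pi0, loglik = ll,
       objective_trace = obj_trace, converged = converged)
}

hmm_log_prior <- function(mu, sigma, A, m0, kappa0, a0, b0, alpha_tr) {
  lambda <- 1 / sigma^2
  lp <- sum(0.5 * log(kappa0 * lambda / (2 * pi)) -
              0.5 * kappa0 * lambda * (mu - m0)^2 +
              a0 * log(b0) - lgamma(a0) + (a0 - 1) * log(lambda) -
              b0 * lambda)
  if (nrow(A) > 1 && alpha_tr != 1) {
    lp <- lp + sum((alpha_tr - 1) * log(pmax(A, 1e-300)))
  }
  lp
}

hmm_sort_states <- function(fit) {
  o <- order(fit$mu)
  fit$mu <- fit$mu[o]
  fit$sigma <- fit$sigma[o]
  fit$A <- fit$A[o, o, drop = FALSE]
  fit$pi0 <- fit$pi0[o]
  fit
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit: k = %d, means = %s, evidence = %.2f>\n", x$k,
              paste(sprintf("%.3f", x$state_means), collapse = "/"),
              x$evidence))
  invisible(x)
}

#' Per-frame posterior state probabilities
#'
#' Forward-backward smoothing posteriors of the fitted model on its
#' trajectory; each row sums to one.
#'
#' @param fit An `hmm_fit`.
#' @param traj The trajectory the fit was produced from (a
#'   `fret_trajectory` or numeric series); defaults to the series stored in
#'   the fit.
#' @return Numeric matrix `T x k` of posteriors.
#' @export
decode_posteriors <- function(fit, traj = NULL) {
  stopifnot(inherits(fit, "hmm_fit"))
  x <- if (is.null(traj)) fit$series else {
    v <- if (inherits(traj, "fret_trajectory")) traj$fret else
      as.numeric(traj)
    v[is.finite(v)]
  }
  if (length(x) != length(fit$series)) {
    stop("trajectory length does not match the fitted series")
  }
  e <- fb_gaussian(x, fit$state_means, fit$state_sds,
                   fit$transition_matrix, fit$initial_probs)
  e$gamma
}

#' Fit a cohort of trajectories
#'
#' Trajectories with fewer than `min_length` finite frames (too short after
#' photobleach truncation) are skipped.
#'
#' @param trajs List of `fret_trajectory` objects (or numeric series).
#' @param priors An [hmm_priors].
#' @param seed Integer seed; trajectory `i` uses `seed + i`.
#' @param min_length Minimum trajectory length (default 10).
#' @return List of `hmm_fit` objects (skipped trajectories omitted).
#' @export
fit_hmm_cohort <- function(trajs, priors = hmm_priors(), seed = 1,
                           min_length = 10L) {
  fits <- lapply(seq_along(trajs), function(i) {
    x <- if (inherits(trajs[[i]], "fret_trajectory")) trajs[[i]]$fret else
      as.numeric(trajs[[i]])
    if (sum(is.finite(x)) < min_length) return(NULL)
    fit_hmm(trajs[[i]], priors, seed = seed + i)
  })
  fits[!vapply(fits, is.null, logical(1))]
}
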