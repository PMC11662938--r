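#' Kinetic scheme for conformational switching
#'
#' Defines a continuous-time Markov model of the conformational states of a
#' surface-immobilized sensor protein. The canonical model for a designer PPR
#' protein has two states: unbound (FRET ~0.4, expanded solenoid) and
#' RNA-bound (FRET ~0.8, compacted solenoid).
#'
#' @param state_labels Character vector of state names.
#' @param fret_means Numeric vector of per-state FRET efficiencies in `[0, 1]`.
#' @param rates Square matrix of transition rates (per second); `rates[i, j]`
#'   is the rate from state `i` to state `j`. The diagonal is ignored.
#' @return An object of class `kinetic_scheme`.
#' @examples
#' two_state_scheme(k_on = 0.1, k_off = 0.1)
#' @export
kinetic_scheme <- function(state_labels, fret_means, rates) {
  n <- length(state_labels)
  if (n < 1L) stop("at least one state is required")
  if (length(fret_means) != n) stop("fret_means must match state_labels")
  if (any(fret_means < 0 | fret_means > 1)) {
    stop("fret_means must lie in [0, 1]")
  }
  rates <- as.matrix(rates)
  if (!all(dim(rates) == c(n, n))) stop("rates must be an n x n matrix")
  diag(rates) <- 0
  if (any(rates < 0)) stop("invalid scheme: negative transition rate")
  structure(
    list(state_labels = as.character(state_labels),
         fret_means = as.numeric(fret_means),
         rates = rates),
    class = "kinetic_scheme"
  )
}

#' @rdname kinetic_scheme
#' @param fret_unbound,fret_bound FRET efficiencies of the unbound and bound
#'   conformations.
#' @param k_on,k_off Binding and release rates (per second).
#' @export
two_state_scheme <- function(k_on = 0.1, k_off = 0.1,
                             fret_unbound = 0.4, fret_bound = 0.8) {
  kinetic_scheme(
    state_labels = c("unbound", "bound"),
    fret_means = c(fret_unbound, fret_bound),
    rates = matrix(c(0, k_on, k_off, 0), 2, 2, byrow = TRUE)
  )
}

#' @rdname kinetic_scheme
#' @param fret Constant FRET efficiency of the single state.
#' @param label State name.
#' @export
one_state_scheme <- function(fret, label = "state") {
  kinetic_scheme(label, fret, matrix(0, 1, 1))
}

#' Photophysics configuration for trace rendering
#'
#' Detection-model parameters shared by the two- and three-color trace
#' renderers: summed dye emission, donor-to-acceptor spectral crosstalk,
#' additive Gaussian detection noise, channel background, and single-step
#' exponential photobleaching lifetimes for each dye.
#'
#' @param total_intensity Summed donor + acceptor emission per frame (a.u.).
#' @param crosstalk_g Fraction of donor emission leaking into the acceptor
#'   detection channel (dimensionless, >= 0).
#' @param noise_sd Per-channel Gaussian noise standard deviation (a.u.).
#' @param background Per-channel dark offset (a.u.).
#' @param donor_bleach_mean,acceptor_bleach_mean,blue_bleach_mean Mean of the
#'   exponential photobleach time for each dye, in seconds (`Inf` disables
#'   bleaching of that dye).
#' @param blue_total_intensity Summed three-channel emission under 488 nm
#'   excitation when the blue-labeled ligand is bound (a.u.).
#' @param blue_fractions Length-3 fractions of `blue_total_intensity` detected
#'   in the (blue, donor, acceptor) channels; must sum to 1.
#' @return An object of class `photophysics_config`.
#' @export
photophysics_config <- function(total_intensity = 1000,
                                crosstalk_g = 0.07,
                                noise_sd = 60,
                                background = 0,
                                donor_bleach_mean = 600,
                                acceptor_bleach_mean = 600,
                                blue_bleach_mean = 600,
                                blue_total_intensity = 1000,
                                blue_fractions = c(0.4, 0.25, 0.35)) {
  stopifnot(total_intensity > 0, crosstalk_g >= 0, noise_sd >= 0,
            donor_bleach_mean > 0, acceptor_bleach_mean > 0,
            blue_bleach_mean > 0, blue_total_intensity > 0,
            length(blue_fractions) == 3, all(blue_fractions >= 0))
  blue_fractions <- blue_fractions / sum(blue_fractions)
  structure(
    list(total_intensity = total_intensity, crosstalk_g = crosstalk_g,
         noise_sd = noise_sd, background = background,
         donor_bleach_mean = donor_bleach_mean,
         acceptor_bleach_mean = acceptor_bleach_mean,
         blue_bleach_mean = blue_bleach_mean,
         blue_total_intensity = blue_total_intensity,
         blue_fractions = blue_fractions),
    class = "photophysics_config"
  )
}

#' Per-channel noise for a target FRET standard deviation
#'
#' Inverts the first-order (delta-method) propagation of additive channel
#' noise through the crosstalk-corrected FRET ratio, so that cohorts can be
#' generated at a stated FRET-scale noise level. At FRET efficiency `E` with
#' total intensity `I` and crosstalk `g`, independent channel noise of
#' standard deviation `s` gives
#' `Var(FRET) ~ s^2 * ((1 + g^2) (1 - E)^2 + E^2 + 2 g E (1 - E)) / I^2`.
#'
#' @param fret_sd Target FRET-scale standard deviation.
#' @param total_intensity Summed emission per frame (a.u.).
#' @param fret FRET efficiency at which to match (default 0.5).
#' @param crosstalk_g Crosstalk constant used at generation.
#' @return Per-channel noise standard deviation in a.u.
#' @export
channel_noise_for_fret_sd <- function(fret_sd, total_intensity,
                                      fret = 0.5, crosstalk_g = 0) {
  stopifnot(fret_sd >= 0, total_intensity > 0)
  e <- fret; g <- crosstalk_g
  k <- (1 + g^2) * (1 - e)^2 + e^2 + 2 * g * e * (1 - e)
  fret_sd * total_intensity / sqrt(k)
}

#' Injection experiment configuration
#'
#' Describes a solution-injection experiment: molecules start unbound, ligand
#' is injected at `injection_time`, each molecule waits an exponential time
#' with mean `wait_mean` before its first binding event, and a fraction
#' `fraction_stable` of molecules then remains bound irreversibly while the
#' rest follow `post_binding_scheme`.
#'
#' @param injection_time Time of ligand injection (s, >= 0).
#' @param wait_mean Mean exponential wait from injection to first binding (s).
#' @param post_binding_scheme [kinetic_scheme] followed by the dynamic
#'   (non-stable) subpopulation after first binding, starting in its bound
#'   (highest-FRET) state.
#' @param fraction_stable Proportion of molecules binding irreversibly.
#' @param fret_unbound,fret_bound FRET efficiencies before/after binding for
#'   the stable subpopulation (defaults 0.4 / 0.8).
#' @return An object of class `injection_config`.
#' @export
injection_config <- function(injection_time = 10, wait_mean = 10.6,
                             post_binding_scheme = two_state_scheme(),
                             fraction_stable = 0.8,
                             fret_unbound = 0.4, fret_bound = 0.8) {
  stopifnot(injection_time >= 0, wait_mean > 0,
            fraction_stable >= 0, fraction_stable <= 1,
            inherits(post_binding_scheme, "kinetic_scheme"))
  structure(
    list(injection_time = injection_time, wait_mean = wait_mean,
         post_binding_scheme = post_binding_scheme,
         fraction_stable = fraction_stable,
         fret_unbound = fret_unbound, fret_bound = fret_bound),
    class = "injection_config"
  )
}

#' Titration generative model
#'
#' 1:1 binding of ligand to a FRET sensor at fixed concentration, with ligand
#' depletion (the quadratic mass-balance solution), observed as ensemble FRET.
#'
#' @param kd Dissociation constant (nM, >= 0).
#' @param sensor_conc Sensor concentration (nM, > 0).
#' @param ligand_concs Ligand concentrations (nM, > 0). Default: 12 points
#'   log-spaced from 1000 nM down to 0.01 nM.
#' @param fret_free,fret_bound Ensemble FRET of free and saturated sensor.
#' @param noise_sd Additive Gaussian noise on observed FRET.
#' @return An object of class `titration_model`.
#' @export
titration_model <- function(kd = 1.2, sensor_conc = 5,
                            ligand_concs = 10^seq(3, -2, length.out = 12),
                            fret_free = 0.3, fret_bound = 0.7,
                            noise_sd = 0.02) {
  stopifnot(kd >= 0, sensor_conc > 0, all(ligand_concs > 0),
            fret_free < fret_bound, noise_sd >= 0)
  structure(
    list(kd = kd, sensor_conc = sensor_conc,
         ligand_concs = as.numeric(ligand_concs),
         fret_free = fret_free, fret_bound = fret_bound,
         noise_sd = noise_sd),
    class = "titration_model"
  )
}

#' Ideal alpha-solenoid specification
#'
#' Geometric parameters of an idealized superhelical repeat protein: each
#' repeat advances `rise` angstrom along and rotates `twist` degrees about the
#' superhelical axis at radius `radius`.
#'
#' @param rise Axial advance per repeat (angstrom).
#' @param twist Rotation per repeat (degrees, in (0, 180)).
#' @param radius Superhelical radius (angstrom, > 0).
#' @param n_repeats Number of repeats (>= 3).
#' @return An object of class `solenoid_spec`.
#' @export
solenoid_spec <- function(rise = 4.8, twist = 40, radius = 25,
                          n_repeats = 18) {
  stopifnot(twist > 0, twist < 180, radius > 0, n_repeats >= 3)
  structure(
    list(rise = rise, twist = twist, radius = radius,
         n_repeats = as.integer(n_repeats)),
    class = "solenoid_spec"
  )
}

#' Nonlinear forward-backward filter parameters
#'
#' Settings of the forward-backward nonlinear (predictor-weighted) filter used
#' to denoise FRET trajectories before state finding. Predictor running-mean
#' windows are `n_fa * f^k` frames for `k = 0 .. n_scales - 1`, in both the
#' forward (trailing) and backward (leading) directions; each predictor is
#' weighted by its mean squared prediction error over the last/next `m` frames
#' raised to the power `-exponent_p`.
#'
#' @param exponent_p Predictor-weight exponent (> 0, default 5).
#' @param n_fa Base running-average window, frames (>= 1, default 1). This is
#'   the `N_FA` that also sets the minimum-residence cutoff `2 * F * N_FA`.
#' @param f Window growth factor between scales (>= 1, default 2).
#' @param n_scales Number of window scales per direction (default 4).
#' @param m Prediction-error comparison window, frames (default 10).
#' @return An object of class `nl_filter_params`.
#' @export
nl_filter_params <- function(exponent_p = 5, n_fa = 1, f = 2,
                             n_scales = 4, m = 10) {
  stopifnot(exponent_p > 0, n_fa >= 1, f >= 1, n_scales >= 1, m >= 1)
  structure(
    list(exponent_p = exponent_p, n_fa = as.integer(n_fa), f = f,
         n_scales = as.integer(n_scales), m = as.integer(m)),
    class = "nl_filter_params"
  )
}

#' HMM prior hyperparameters
#'
#' Priors and search settings for Gaussian hidden Markov model fitting of
#' FRET trajectories. `mu` and `beta` parameterize a Normal-Gamma prior on
#' each state's emission mean and precision: `mu` is the pseudo-count strength
#' pulling state means toward `prior_mean` (0.5 FRET by default), and `beta`
#' multiplies the precision-prior scale (larger `beta` means broader expected
#' state widths). These act as mild regularizers that discourage over-fitting
#' of spurious narrow states.
#'
#' @param mu Strength (pseudo-counts) of the emission-mean prior (default 1.5).
#' @param beta Precision-prior scale multiplier (> 0, default 0.5).
#' @param prior_mean Prior emission mean (FRET, default 0.5).
#' @param transition_concentration Dirichlet concentration of the transition
#'   prior (default 1, i.e. flat).
#' @param k_range Candidate numbers of states (default 1:4).
#' @param restarts Random restarts per candidate `k` (default 5).
#' @return An object of class `hmm_priors`.
#' @export
hmm_priors <- function(mu = 1.5, beta = 0.5, prior_mean = 0.5,
                       transition_concentration = 1, k_range = 1:4,
                       restarts = 5) {
  stopifnot(beta > 0, restarts >= 1, length(k_range) >= 1,
            all(k_range >= 1), transition_concentration > 0)
  structure(
    list(mu = mu, beta = beta, prior_mean = prior_mean,
         transition_concentration = transition_concentration,
         k_range = sort(unique(as.integer(k_range))),
         restarts = as.integer(restarts)),
    class = "hmm_priors"
  )
}

#' Kinetic analysis configuration
#'
#' Settings for transition classification and residence-time extraction.
#' Transitions are classed by whether the departing/arriving HMM state means
#' fall below (`low`) or at/above (`high`) `fret_threshold`. Residence times
#' shorter than the minimum `2 * frame_ms * n_fa` milliseconds (the smoothing
#' floor of the denoising filter) are discarded.
#'
#' @param fret_threshold Binding threshold on FRET (default 0.5). State means
#'   exactly at the threshold count as high.
#' @param frame_ms Frame interval `F` in milliseconds (default 200).
#' @param n_fa Denoising base window `N_FA` in frames (default 1).
#' @param sync_window Half-width of synchronized transition averages (s).
#' @param sync_min_residence Minimum pre-transition residence time for a
#'   transition to enter the synchronized average (s).
#' @return An object of class `analysis_config` with derived element
#'   `min_residence_s = 2 * frame_ms * n_fa / 1000`.
#' @export
analysis_config <- function(fret_threshold = 0.5, frame_ms = 200, n_fa = 1,
                            sync_window = 10, sync_min_residence = 10) {
  stopifnot(fret_threshold > 0, fret_threshold < 1, frame_ms > 0, n_fa >= 1,
            sync_window > 0, sync_min_residence >= 0)
  structure(
    list(fret_threshold = fret_threshold, frame_ms = frame_ms,
         n_fa = as.integer(n_fa),
         min_residence_s = 2 * frame_ms * n_fa / 1000,
         sync_window = sync_window,
         sync_min_residence = sync_min_residence),
    class = "analysis_config"
  )
}
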