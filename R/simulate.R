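#' Simulate a continuous-time state path
#'
#' Draws a continuous-time Markov jump process from a [kinetic_scheme] and
#' discretizes it to camera frames, assigning each frame the state that
#' occupies the majority of the frame. Exact jump times are retained as
#' ground truth.
#'
#' @param scheme A [kinetic_scheme].
#' @param duration Total simulated time (s, > 0).
#' @param frame_interval Camera frame interval (s, > 0; default 0.2 s, i.e.
#'   5 Hz acquisition).
#' @param seed Integer seed.
#' @param initial_state Starting state index (default 1).
#' @return An object of class `state_path`: list with `states` (integer per
#'   frame), `fret` (per-frame generative FRET), `time_s`, `frame_interval`,
#'   `jumps` (data frame of exact jump `time`, `from`, `to`), and `scheme`.
#' @export
simulate_state_path <- function(scheme, duration, frame_interval = 0.2,
                                seed = NULL, initial_state = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"), duration > 0,
            frame_interval > 0)
  if (!is.null(seed)) set.seed(seed)
  n_states <- length(scheme$state_labels)
  stopifnot(initial_state >= 1L, initial_state <= n_states)

  # Gillespie jump chain
  t_now <- 0
  s_now <- as.integer(initial_state)
  jump_time <- numeric(0)
  jump_from <- integer(0)
  jump_to <- integer(0)
  repeat {
    exit <- sum(scheme$rates[s_now, ])
    if (exit <= 0) break
    dt <- rexp(1L, exit)
    t_now <- t_now + dt
    if (t_now >= duration) break
    s_next <- sample.int(n_states, 1L, prob = scheme$rates[s_now, ])
    jump_time <- c(jump_time, t_now)
    jump_from <- c(jump_from, s_now)
    jump_to <- c(jump_to, s_next)
    s_now <- s_next
  }
  jumps <- data.frame(time = jump_time, from = jump_from, to = jump_to)
  path_from_jumps(jumps, duration, frame_interval, initial_state, scheme)
}

# Discretize a jump sequence to frames by majority occupancy within each
# frame. Linear in frames + jumps: only segments overlapping a frame are
# visited.
path_from_jumps <- function(jumps, duration, frame_interval, initial_state,
                            scheme) {
  n_frames <- floor(duration / frame_interval + 1e-9)
  states <- integer(n_frames)
  n_states <- length(scheme$state_labels)
  bounds <- c(0, jumps$time, Inf)
  seq_states <- c(as.integer(initial_state), jumps$to)
  seg <- 1L
  n_seg <- length(seq_states)
  occ <- numeric(n_states)
  for (i in seq_len(n_frames)) {
    t0 <- (i - 1L) * frame_interval
    t1 <- i * frame_interval
    if (bounds[seg + 1L] >= t1) {
      # single segment spans the whole frame
      states[i] <- seq_states[seg]
      next
    }
    occ[] <- 0
    j <- seg
    while (j <= n_seg && bounds[j] < t1) {
      lo <- max(bounds[j], t0)
      hi <- min(bounds[j + 1L], t1)
      if (hi > lo) occ[seq_states[j]] <- occ[seq_states[j]] + (hi - lo)
      j <- j + 1L
    }
    states[i] <- which.max(occ)
    # advance to the segment containing t1 for the next frame
    while (seg < n_seg && bounds[seg + 1L] <= t1) seg <- seg + 1L
  }
  structure(
    list(states = states,
         fret = scheme$fret_means[states],
         time_s = (seq_len(n_frames) - 1L) * frame_interval,
         frame_interval = frame_interval,
         duration = duration,
         jumps = jumps,
         scheme = scheme),
    class = "state_path"
  )
}

#' Render a two-color smFRET intensity trace
#'
#' Forward model of the detection system: with per-frame generative FRET `E`
#' and summed emission `I`, the donor channel records `I * (1 - E)` and the
#' acceptor channel `I * E + g * I * (1 - E)` (donor leakage), each plus
#' Gaussian noise. After single-step acceptor photobleaching all emission
#' returns to the donor (`I + noise`) while the acceptor channel retains only
#' leakage (`g * I + background + noise`); after donor photobleaching both
#' channels fall to `background + noise`. Bleach frames are kept as ground
#' truth.
#'
#' @param path A [simulate_state_path] result.
#' @param phys A [photophysics_config].
#' @param seed Integer seed.
#' @param molecule_id Identifier stored in the trace.
#' @return An object of class `fret_trace`: data frame with columns
#'   `molecule_id`, `frame` (0-based), `time_s`, `laser`, `ch_donor`,
#'   `ch_acceptor`, `ch_blue` (NA for two-color), and attribute `truth`.
#' @export
render_two_color <- function(path, phys, seed = NULL, molecule_id = "mol1") {
  stopifnot(inherits(path, "state_path"), inherits(phys, "photophysics_config"))
  if (length(path$states) == 0L) stop("state path is empty")
  if (!is.null(seed)) set.seed(seed)
  n <- length(path$states)
  dt <- path$frame_interval

  t_donor <- rexp_or_inf(phys$donor_bleach_mean)
  t_acceptor <- rexp_or_inf(phys$acceptor_bleach_mean)
  donor_bleach_frame <- bleach_frame(t_donor, dt, n)
  acceptor_bleach_frame <- bleach_frame(t_acceptor, dt, n)

  ch <- render_channels(path$fret, phys, donor_bleach_frame,
                        acceptor_bleach_frame)
  trace <- data.frame(
    molecule_id = molecule_id,
    frame = seq_len(n) - 1L,
    time_s = path$time_s,
    laser = 532L,
    ch_donor = ch$donor,
    ch_acceptor = ch$acceptor,
    ch_blue = NA_real_
  )
  attr(trace, "truth") <- list(
    jumps = path$jumps,
    states = path$states,
    fret = path$fret,
    donor_bleach_frame = donor_bleach_frame,
    acceptor_bleach_frame = acceptor_bleach_frame
  )
  attr(trace, "frame_interval") <- dt
  class(trace) <- c("fret_trace", "data.frame")
  trace
}

rexp_or_inf <- function(mean_s) {
  if (is.infinite(mean_s)) Inf else rexp(1L, 1 / mean_s)
}

# First 0-based frame whose start time is at/after the bleach event;
# NA when the dye outlives the record.
bleach_frame <- function(t_bleach, dt, n_frames) {
  if (is.infinite(t_bleach)) return(NA_integer_)
  f <- as.integer(ceiling(t_bleach / dt - 1e-12))
  if (f >= n_frames) NA_integer_ else f
}

render_channels <- function(fret, phys, donor_bleach_frame,
                            acceptor_bleach_frame) {
  n <- length(fret)
  I <- phys$total_intensity
  g <- phys$crosstalk_g
  bg <- phys$background
  donor <- I * (1 - fret)
  acceptor <- I * fret + g * I * (1 - fret)
  frames0 <- seq_len(n) - 1L
  if (!is.na(acceptor_bleach_frame)) {
    post_a <- frames0 >= acceptor_bleach_frame
    donor[post_a] <- I
    acceptor[post_a] <- g * I + bg
  }
  if (!is.na(donor_bleach_frame)) {
    post_d <- frames0 >= donor_bleach_frame
    donor[post_d] <- bg
    acceptor[post_d] <- bg
  }
  list(donor = donor + rnorm(n, 0, phys$noise_sd),
       acceptor = acceptor + rnorm(n, 0, phys$noise_sd))
}

#' Simulate a cohort of identically-generated two-color traces
#'
#' @param n Number of molecules.
#' @param scheme [kinetic_scheme] shared by all molecules.
#' @param phys [photophysics_config].
#' @param duration Trace duration (s).
#' @param frame_interval Frame interval (s).
#' @param seed Integer seed (one stream for the whole cohort).
#' @param id_prefix Molecule identifier prefix.
#' @return A `fret_trace_set`: list of `fret_trace` objects.
#' @export
simulate_cohort <- function(n, scheme, phys, duration = 60,
                            frame_interval = 0.2, seed = 1,
                            id_prefix = "mol") {
  stopifnot(n >= 1)
  set.seed(seed)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    path <- simulate_state_path(scheme, duration, frame_interval, seed = NULL)
    traces[[i]] <- render_two_color(path, phys, seed = NULL,
                                    molecule_id = sprintf("%s%03d", id_prefix, i))
  }
  as_trace_set(traces)
}

#' Simulate donor-only calibration traces
#'
#' Molecules carrying only a donor dye: the acceptor channel records pure
#' donor leakage (`g * I`), which is the calibration signal for the crosstalk
#' constant. Acceptor photobleaching is disabled (there is no acceptor dye).
#'
#' @inheritParams simulate_cohort
#' @return A `fret_trace_set`.
#' @export
simulate_donor_only <- function(n, phys, duration = 60, frame_interval = 0.2,
                                seed = 1) {
  phys$acceptor_bleach_mean <- Inf
  simulate_cohort(n, one_state_scheme(0, "donor_only"), phys, duration,
                  frame_interval, seed, id_prefix = "donly")
}

#' Simulate a solution-injection cohort
#'
#' Each molecule is unbound until `injection_time` plus an exponential wait,
#' then binds. A `fraction_stable` subset stays bound irreversibly; the rest
#' follow the post-binding kinetic scheme starting from its bound state.
#' Ground-truth wait times and the stable/dynamic assignment are stored per
#' trace and on the returned set.
#'
#' @param n Number of molecules (>= 1).
#' @param inj An [injection_config].
#' @param phys A [photophysics_config].
#' @param duration Trace duration (s).
#' @param frame_interval Frame interval (s).
#' @param seed Integer seed.
#' @return A `fret_trace_set` with attribute `truth` (data frame of
#'   `molecule_id`, `wait`, `bind_time`, `stable`).
#' @export
simulate_injection_cohort <- function(n, inj, phys, duration = 120,
                                      frame_interval = 0.2, seed = 1) {
  stopifnot(n >= 1, inherits(inj, "injection_config"),
            inherits(phys, "photophysics_config"))
  set.seed(seed)
  post <- inj$post_binding_scheme
  bound_state <- which.max(post$fret_means)
  two <- kinetic_scheme(
    c("unbound", "bound"),
    c(inj$fret_unbound, inj$fret_bound),
    matrix(0, 2, 2)
  )
  traces <- vector("list", n)
  waits <- numeric(n)
  stable <- logical(n)
  for (i in seq_len(n)) {
    waits[i] <- rexp(1L, 1 / inj$wait_mean)
    stable[i] <- runif(1L) < inj$fraction_stable
    t_bind <- inj$injection_time + waits[i]
    if (t_bind >= duration) {
      path <- simulate_state_path(two, duration, frame_interval, seed = NULL)
    } else if (stable[i]) {
      jumps <- data.frame(time = t_bind, from = 1L, to = 2L)
      path <- path_from_jumps(jumps, duration, frame_interval, 1L, two)
    } else {
      # post-binding dynamics simulated on the residual record
      sub <- simulate_state_path(post, duration - t_bind, frame_interval,
                                 seed = NULL, initial_state = bound_state)
      # express the whole record in the two-state unbound/bound frame
      side <- ifelse(post$fret_means >= 0.5, 2L, 1L)
      sub_jumps <- sub$jumps
      side_seq <- side[c(bound_state, sub_jumps$to)]
      changed <- which(side_seq[-1L] != side_seq[-length(side_seq)])
      jumps <- data.frame(
        time = c(t_bind, t_bind + sub_jumps$time[changed]),
        from = c(1L, side_seq[changed]),
        to = c(2L, side_seq[changed + 1L])
      )
      path <- path_from_jumps(jumps, duration, frame_interval, 1L, two)
    }
    tr <- render_two_color(path, phys, seed = NULL,
                           molecule_id = sprintf("inj%03d", i))
    truth <- attr(tr, "truth")
    truth$wait <- waits[i]
    truth$bind_time <- t_bind
    truth$stable <- stable[i]
    attr(tr, "truth") <- truth
    traces[[i]] <- tr
  }
  set <- as_trace_set(traces)
  attr(set, "truth") <- data.frame(
    molecule_id = vapply(traces, function(x) x$molecule_id[1L], ""),
    wait = waits,
    bind_time = inj$injection_time + waits,
    stable = stable
  )
  set
}

#' Render a three-color ALEX trace
#'
#' Alternating laser excitation: even frames (0-based, starting at frame 0)
#' are excited at 532 nm and rendered exactly as in [render_two_color]; odd
#' frames are excited at 488 nm. On 488 frames, while the blue-labeled RNA is
#' bound (generative FRET at/above 0.5) and the blue dye unbleached, the
#' three channels receive the configured fractions of the blue-excited total
#' intensity; while unbound, all three channels record only background plus
#' noise.
#'
#' @inheritParams render_two_color
#' @param alex_scheme `"even532"` (default; frame 0 excited at 532 nm) or
#'   `"even488"`.
#' @return A `fret_trace` whose `laser` column alternates 532/488 and whose
#'   `ch_blue` column is filled on 488 frames.
#' @export
render_three_color <- function(path, phys, seed = NULL,
                               molecule_id = "mol1",
                               alex_scheme = c("even532", "even488")) {
  stopifnot(inherits(path, "state_path"), inherits(phys, "photophysics_config"))
  alex_scheme <- match.arg(alex_scheme)
  if (length(path$states) == 0L) stop("state path is empty")
  if (!is.null(seed)) set.seed(seed)
  n <- length(path$states)
  dt <- path$frame_interval
  frames0 <- seq_len(n) - 1L
  is532 <- if (alex_scheme == "even532") frames0 %% 2L == 0L else
    frames0 %% 2L == 1L

  t_donor <- rexp_or_inf(phys$donor_bleach_mean)
  t_acceptor <- rexp_or_inf(phys$acceptor_bleach_mean)
  t_blue <- rexp_or_inf(phys$blue_bleach_mean)
  donor_bleach_frame <- bleach_frame(t_donor, dt, n)
  acceptor_bleach_frame <- bleach_frame(t_acceptor, dt, n)
  blue_bleach_frame <- bleach_frame(t_blue, dt, n)

  ch <- render_channels(path$fret, phys, donor_bleach_frame,
                        acceptor_bleach_frame)
  donor <- ch$donor
  acceptor <- ch$acceptor
  blue <- phys$background + rnorm(n, 0, phys$noise_sd)

  bound <- path$fret >= 0.5
  blue_alive <- if (is.na(blue_bleach_frame)) rep(TRUE, n) else
    frames0 < blue_bleach_frame
  lit <- !is532 & bound & blue_alive
  bf <- phys$blue_fractions * phys$blue_total_intensity
  blue[!is532] <- phys$background + rnorm(sum(!is532), 0, phys$noise_sd)
  donor[!is532] <- phys$background + rnorm(sum(!is532), 0, phys$noise_sd)
  acceptor[!is532] <- phys$background + rnorm(sum(!is532), 0, phys$noise_sd)
  blue[lit] <- blue[lit] + bf[1L]
  donor[lit] <- donor[lit] + bf[2L]
  acceptor[lit] <- acceptor[lit] + bf[3L]

  trace <- data.frame(
    molecule_id = molecule_id,
    frame = frames0,
    time_s = path$time_s,
    laser = ifelse(is532, 532L, 488L),
    ch_donor = donor,
    ch_acceptor = acceptor,
    ch_blue = blue
  )
  attr(trace, "truth") <- list(
    jumps = path$jumps, states = path$states, fret = path$fret,
    donor_bleach_frame = donor_bleach_frame,
    acceptor_bleach_frame = acceptor_bleach_frame,
    blue_bleach_frame = blue_bleach_frame
  )
  attr(trace, "frame_interval") <- dt
  class(trace) <- c("fret_trace", "data.frame")
  trace
}

#' Simulate an ensemble FRET titration curve
#'
#' Bound sensor fraction at total ligand `L` and total sensor `S` under 1:1
#' binding with ligand depletion:
#' `fb = ((Kd + S + L) - sqrt((Kd + S + L)^2 - 4 S L)) / (2 S)`.
#' Observed FRET is `fret_free + fb * (fret_bound - fret_free)` plus Gaussian
#' noise.
#'
#' @param model A [titration_model].
#' @param seed Integer seed.
#' @return An object of class `titration_curve`: data frame with columns
#'   `ligand_conc`, `fret`, plus attributes `sensor_conc` and `truth`.
#' @export
simulate_titration <- function(model, seed = NULL) {
  stopifnot(inherits(model, "titration_model"))
  if (!is.null(seed)) set.seed(seed)
  fb <- bound_fraction_depletion(model$ligand_concs, model$kd,
                                 model$sensor_conc)
  fret_true <- model$fret_free + fb * (model$fret_bound - model$fret_free)
  curve <- data.frame(
    ligand_conc = model$ligand_concs,
    fret = fret_true + rnorm(length(fb), 0, model$noise_sd)
  )
  attr(curve, "sensor_conc") <- model$sensor_conc
  attr(curve, "truth") <- list(fb = fb, fret_true = fret_true, model = model)
  class(curve) <- c("titration_curve", "data.frame")
  curve
}

#' Bound fraction under the ligand-depletion (quadratic) isotherm
#'
#' @param ligand_conc Total ligand concentration(s), nM.
#' @param kd Dissociation constant, nM.
#' @param sensor_conc Total sensor concentration, nM.
#' @return Bound sensor fraction in `[0, 1]`.
#' @export
bound_fraction_depletion <- function(ligand_conc, kd, sensor_conc) {
  stopifnot(kd >= 0, sensor_conc > 0, all(ligand_conc >= 0))
  a <- kd + sensor_conc + ligand_conc
  disc <- a^2 - 4 * sensor_conc * ligand_conc
  if (any(disc < -1e-9 * a^2)) stop("negative discriminant; invalid inputs")
  disc <- pmax(disc, 0)
  (a - sqrt(disc)) / (2 * sensor_conc)
}
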