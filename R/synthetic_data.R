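# Synthetic-data generators. Every generator takes one integer seed, draws
# all randomness inside a withr::with_seed() scope (so the caller's RNG
# state is untouched and a fixed seed gives bit-identical output), and
# returns its ground truth alongside the data.

.ground_truth <- function(generator, params, seed) {
  list(generator = generator, params = params, seed = seed)
}

#' Generate noisy Q(V) replicates from a two-state Boltzmann
#'
#' Draws replicate charge-voltage curves from the ascending Boltzmann with
#' multiplicative Gaussian noise (noise scales with the charge, mimicking
#' amplitude-proportional measurement error after filtering). Intended for
#' round-trip parameter-recovery studies against [fit_boltzmann()].
#'
#' @param v_half,z_delta,q_max Generator Boltzmann parameters (mV, e0,
#'   charge units).
#' @param voltages Voltages at which to sample (mV).
#' @param n_replicates Number of replicate curves (separate patches).
#' @param relative_sigma Noise standard deviation as a fraction of each
#'   point's charge.
#' @param seed Integer seed.
#' @param temperature Kelvin.
#' @return List with `data` (data frame: `replicate`, `voltage_mV`,
#'   `charge`) and `ground_truth`.
#' @export
gen_qv_points <- function(v_half, z_delta, q_max = 1, voltages,
                          n_replicates = 1, relative_sigma = 0.02, seed = 1,
                          temperature = 295.15) {
  stopifnot(relative_sigma >= 0, n_replicates >= 1)
  mu <- boltzmann_qv(voltages, v_half, z_delta, q_max, temperature)
  data <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(replicate = r, voltage_mV = voltages,
                 charge = mu * (1 + stats::rnorm(length(mu), 0, relative_sigma)))
    }))
  })
  list(data = data,
       ground_truth = .ground_truth("gen_qv_points",
         list(v_half = v_half, z_delta = z_delta, q_max = q_max,
              relative_sigma = relative_sigma, n_replicates = n_replicates,
              temperature = temperature), seed))
}

#' Generate noisy gating-current sweep families
#'
#' Simulates a kinetic scheme through one of two protocol families and adds
#' Gaussian noise with standard deviation `relative_sigma` times the peak
#' current of each sweep:
#' * `"duration_series"` - hold, depolarising step of each requested
#'   duration, repolarisation to `repol_mV` (default 0 mV, the proton
#'   reversal potential at symmetric pH); the classic trapping time-course
#'   protocol with default durations 2-52 ms in 5 ms steps.
#' * `"double_pulse"` - two fixed-length depolarisations to `step_mV`
#'   separated by a recovery interval at the holding potential, one sweep
#'   per interval; used to measure recovery from trapping.
#'
#' @param scheme A [kinetic_scheme].
#' @param family `"duration_series"` or `"double_pulse"`.
#' @param durations Depolarisation durations (ms) for the duration series.
#' @param intervals Interpulse intervals (ms) for the double-pulse family.
#' @param hold_mV,step_mV,repol_mV Protocol voltages.
#' @param hold_ms Pre-step holding time (ms).
#' @param off_ms Repolarisation window simulated after the (last) step.
#' @param pulse_ms Pulse length for the double-pulse family.
#' @param sample_interval Sampling interval (ms).
#' @param relative_sigma Noise sd as a fraction of each sweep's peak |I|.
#' @param seed Integer seed.
#' @return List with `sweeps` (list of `gating_sweep`; for the double-pulse
#'   family annotated with `pulse2_start`/`pulse2_end`) and `ground_truth`.
#' @export
gen_gating_sweeps <- function(scheme,
                              family = c("duration_series", "double_pulse"),
                              durations = seq(2, 52, by = 5),
                              intervals = seq(5, 150, by = 5),
                              hold_mV = -90, step_mV = 200, repol_mV = 0,
                              hold_ms = 5, off_ms = 60, pulse_ms = 25,
                              sample_interval = 0.05,
                              relative_sigma = 0, seed = 1) {
  stopifnot(inherits(scheme, "kinetic_scheme"), relative_sigma >= 0)
  family <- match.arg(family)
  sweeps <- if (family == "duration_series") {
    lapply(durations, function(d) {
      simulate_protocol(scheme, voltage_protocol(
        c(hold_ms, d, off_ms), c(hold_mV, step_mV, repol_mV),
        sample_interval))
    })
  } else {
    lapply(intervals, function(gap) {
      sw <- simulate_protocol(scheme, voltage_protocol(
        c(hold_ms, pulse_ms, gap, pulse_ms, off_ms),
        c(hold_mV, step_mV, hold_mV, step_mV, repol_mV),
        sample_interval))
      p2 <- hold_ms + pulse_ms + gap
      sw$annotations <- list(depol_start = hold_ms,
                             depol_end = hold_ms + pulse_ms,
                             repol_start = hold_ms + pulse_ms,
                             duration = pulse_ms,
                             interval = gap,
                             pulse2_start = p2,
                             pulse2_end = p2 + pulse_ms)
      sw
    })
  }
  if (relative_sigma > 0) {
    sweeps <- withr::with_seed(seed, {
      lapply(sweeps, function(sw) {
        sw$current <- sw$current +
          stats::rnorm(length(sw$current), 0,
                       relative_sigma * max(abs(sw$current)))
        sw
      })
    })
  }
  list(sweeps = sweeps,
       ground_truth = .ground_truth("gen_gating_sweeps",
         list(family = family, durations = durations, intervals = intervals,
              hold_mV = hold_mV, step_mV = step_mV, repol_mV = repol_mV,
              relative_sigma = relative_sigma), seed))
}

#' Generate a noisy exponential time course
#'
#' Evaluates one of the [fit_exponential_model()] model forms at given
#' abscissae and adds Gaussian noise with standard deviation
#' `relative_sigma` times the peak |y| (amplitude-referenced, so the noise
#' level does not vanish where the curve does).
#'
#' @param model_id Model identifier (see [fit_exponential_model()]).
#' @param params Named list with `A`, `tau1` and for double models `B`,
#'   `tau2`.
#' @param x Abscissae (ms).
#' @param relative_sigma Noise sd as a fraction of peak |y|.
#' @param seed Integer seed.
#' @return List with `data` (data frame `x`, `y`) and `ground_truth`.
#' @export
gen_timecourse_series <- function(model_id, params, x, relative_sigma = 0,
                                  seed = 1) {
  model_id <- match.arg(model_id, names(.exp_models))
  stopifnot(relative_sigma >= 0)
  p <- unlist(params)
  missing <- setdiff(.exp_models[[model_id]]$pars, names(p))
  if (length(missing)) {
    stop(sprintf("params missing for %s: %s", model_id,
                 paste(missing, collapse = ", ")))
  }
  y <- .exp_models[[model_id]]$fn(x, p)
  if (relative_sigma > 0) {
    y <- withr::with_seed(seed,
      y + stats::rnorm(length(y), 0, relative_sigma * max(abs(y))))
  }
  list(data = data.frame(x = x, y = y),
       ground_truth = .ground_truth("gen_timecourse_series",
         c(list(model_id = model_id, relative_sigma = relative_sigma),
           as.list(p)), seed))
}

# Rigid side-chain group templates (Angstrom, centred so the unit-mass COM
# is at the origin). Deliberately schematic: only COM geometry matters for
# the analytics these toys feed.
.group_templates <- list(
  ASP = data.frame(elety = c("CG", "OD1", "OD2"),
                   x = c(0, 0, 0), y = c(0, 0.8, -0.8),
                   z = c(-0.8, 0.4, 0.4)),
  ARG = data.frame(elety = c("NE", "CZ", "NH1", "NH2"),
                   x = c(-0.7, -0.7, 0.7, 0.7), y = c(0.7, -0.7, 0.7, -0.7),
                   z = c(0, 0, 0, 0))
)

#' Generate a synthetic salt-bridge trajectory
#'
#' Builds a toy multi-frame structure containing schematic D160
#' (carboxylate) and R255/R258/R261 (guanidinium) side-chain groups whose
#' center-of-mass distances to D160 follow prescribed stochastic processes:
#' either a single Gaussian state (`mean`, `sigma`) or a two-state mixture
#' (`state_means`, `dwell_below`, `sigma`) in which each frame is
#' independently in the bridged state with probability `dwell_below`. D160
#' sits at the origin, R258 displaces along x, R261 along y, and R255 is
#' held at a fixed offset, so every pair distance is controlled or derived
#' analytically. The geometry is synthetic - a scaffold for exercising the
#' trajectory analytics, not a structural model.
#'
#' @param pairs List with elements `d160_r258` and `d160_r261`, each a list
#'   with either `mean` or `state_means` (length 2, bridged state first),
#'   plus `sigma` and optionally `dwell_below`.
#' @param n_frames Number of frames (>= 100).
#' @param seed Integer seed.
#' @param frame_interval Frame spacing in ns (metadata).
#' @return List with `traj` (a [frame_series]), `states` (per-frame,
#'   per-pair bridged indicator) and `ground_truth`.
#' @export
gen_toy_trajectory <- function(pairs, n_frames = 500, seed = 1,
                               frame_interval = 0.1) {
  stopifnot(n_frames >= 100,
            all(c("d160_r258", "d160_r261") %in% names(pairs)))
  draw_series <- function(spec) {
    sigma <- if (is.null(spec$sigma)) 0 else spec$sigma
    if (!is.null(spec$state_means)) {
      stopifnot(length(spec$state_means) == 2, !is.null(spec$dwell_below))
      st <- stats::rbinom(n_frames, 1, spec$dwell_below)  # 1 = bridged
      mu <- ifelse(st == 1, spec$state_means[1], spec$state_means[2])
    } else {
      st <- rep(NA_integer_, n_frames)
      mu <- rep(spec$mean, n_frames)
    }
    d <- mu + stats::rnorm(n_frames, 0, sigma)
    list(d = pmax(d, 0.5), state = st)
  }
  sim <- withr::with_seed(seed, {
    list(r258 = draw_series(pairs$d160_r258),
         r261 = draw_series(pairs$d160_r261))
  })

  residues <- list(
    list(resno = 160, resname = "ASP", template = .group_templates$ASP),
    list(resno = 258, resname = "ARG", template = .group_templates$ARG),
    list(resno = 261, resname = "ARG", template = .group_templates$ARG),
    list(resno = 255, resname = "ARG", template = .group_templates$ARG)
  )
  atoms <- do.call(rbind, lapply(residues, function(r) {
    data.frame(resno = r$resno, resid = r$resname, elety = r$template$elety,
               chain = "A")
  }))
  centers <- function(k) {
    rbind(c(0, 0, 0),                      # D160
          c(sim$r258$d[k], 0, 0),          # R258 along x
          c(0, sim$r261$d[k], 0),          # R261 along y
          c(0, -8, -4))                    # R255 fixed spectator
  }
  coords <- lapply(seq_len(n_frames), function(k) {
    ctr <- centers(k)
    do.call(rbind, lapply(seq_along(residues), function(i) {
      tpl <- as.matrix(residues[[i]]$template[, c("x", "y", "z")])
      sweep(tpl, 2, ctr[i, ], "+")
    }))
  })
  traj <- frame_series(coords, atoms, frame_interval)
  list(traj = traj,
       states = data.frame(d160_r258 = sim$r258$state,
                           d160_r261 = sim$r261$state),
       ground_truth = .ground_truth("gen_toy_trajectory",
         list(pairs = pairs, n_frames = n_frames), seed))
}
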