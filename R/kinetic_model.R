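#' Per-transition rate parameters of a voltage-dependent gating step
#'
#' One step of a linear activation chain is parameterised by its forward and
#' backward rates at 0 mV and by the gating charge it moves. The voltage
#' dependence follows the usual Eyring-type rate laws
#' \deqn{\alpha(V) = \alpha_0 \exp(x z\delta e_0 V / kT), \quad
#'       \beta(V) = \beta_0 \exp((x-1) z\delta e_0 V / kT)}
#' where `x` splits the charge `z_delta` between the forward and backward
#' barriers so that the equilibrium constant always moves the full `z_delta`.
#'
#' @param alpha0 Forward rate at 0 mV (1/ms), positive.
#' @param beta0 Backward rate at 0 mV (1/ms), positive.
#' @param x Forward charge fraction in \[0, 1\].
#' @param z_delta Total gating charge moved across the transition
#'   (elementary charges), non-negative.
#' @return An object of class `transition_params`.
#' @export
transition_params <- function(alpha0, beta0, x = 0.5, z_delta = 1) {
  stopifnot(is.numeric(alpha0), length(alpha0) == 1, is.finite(alpha0), alpha0 > 0,
            is.numeric(beta0), length(beta0) == 1, is.finite(beta0), beta0 > 0,
            is.numeric(x), length(x) == 1, x >= 0, x <= 1,
            is.numeric(z_delta), length(z_delta) == 1, z_delta >= 0)
  structure(list(alpha0 = alpha0, beta0 = beta0, x = x, z_delta = z_delta),
            class = "transition_params")
}

#' Voltage-dependent transition rates
#'
#' Evaluates the forward and backward rates of one gating transition at a
#' membrane voltage. Satisfies detailed balance:
#' `alpha/beta = (alpha0/beta0) * exp(z_delta * V / (kT/e0))`.
#'
#' @param params A [transition_params] object.
#' @param V Membrane voltage in mV (vectorised).
#' @param temperature Temperature in Kelvin.
#' @return A list with numeric components `alpha` and `beta` (1/ms).
#' @examples
#' p <- transition_params(alpha0 = 0.1, beta0 = 0.2, x = 0.5, z_delta = 1)
#' transition_rates(p, V = 0, temperature = 295.15)
#' @export
transition_rates <- function(params, V, temperature = 295.15) {
  stopifnot(inherits(params, "transition_params"),
            is.numeric(V), all(is.finite(V)))
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive finite value (Kelvin)")
  }
  vt <- thermal_voltage_mV(temperature)
  list(alpha = params$alpha0 * exp(params$x * params$z_delta * V / vt),
       beta  = params$beta0 * exp((params$x - 1) * params$z_delta * V / vt))
}

#' Linear-chain kinetic scheme for voltage-sensor gating
#'
#' Defines an N-state sequential activation scheme (default topology of the
#' five-state Hv1 gating model: three resting/intermediate states feeding two
#' active states). Consecutive states are connected by voltage-dependent
#' transitions; charge trapping corresponds to a slow backward rate out of
#' the last (deep active) state.
#'
#' @param transitions List of [transition_params], one per consecutive pair
#'   of states (`n_states - 1` entries).
#' @param state_names Character labels, default `A1..`/`B..` style labels.
#' @param n_channels Number of channels contributing to the macroscopic
#'   gating current.
#' @param temperature Temperature in Kelvin; defaults to 295.15 K (22 C).
#' @return An object of class `kinetic_scheme`.
#' @seealso [example_scheme()] for ready-made illustrative schemes.
#' @export
kinetic_scheme <- function(transitions, state_names = NULL,
                           n_channels = 1e7, temperature = 295.15) {
  stopifnot(is.list(transitions), length(transitions) >= 1)
  if (!all(vapply(transitions, inherits, logical(1), "transition_params"))) {
    stop("`transitions` must be a list of transition_params objects")
  }
  n_states <- length(transitions) + 1
  if (is.null(state_names)) {
    state_names <- paste0("S", seq_len(n_states))
  }
  stopifnot(length(state_names) == n_states,
            is.numeric(n_channels), n_channels > 0,
            is.numeric(temperature), temperature > 0)
  structure(list(state_names = as.character(state_names),
                 transitions = transitions,
                 n_channels = n_channels,
                 temperature = temperature),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  n <- length(x$state_names)
  cat(sprintf("Linear %d-state gating scheme: %s\n", n,
              paste(x$state_names, collapse = " <-> ")))
  tr <- do.call(rbind, lapply(x$transitions, function(p) {
    data.frame(alpha0 = p$alpha0, beta0 = p$beta0, x = p$x,
               z_delta = p$z_delta)
  }))
  print(tr, row.names = FALSE)
  cat(sprintf("n_channels = %.3g, T = %.2f K, total charge = %.3g e0\n",
              x$n_channels, x$temperature,
              sum(vapply(x$transitions, `[[`, numeric(1), "z_delta"))))
  invisible(x)
}

#' Cumulative gating charge of each state
#'
#' State charges are referenced to the first (fully resting) state:
#' `z_1 = 0`, `z_i = sum of z_delta over the first i-1 transitions`. The
#' population-weighted mean of this vector is the displaced gating charge
#' per channel.
#'
#' @param scheme A [kinetic_scheme].
#' @return Numeric vector of per-state charges (e0), non-decreasing.
#' @export
state_charges <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  zd <- vapply(scheme$transitions, `[[`, numeric(1), "z_delta")
  c(0, cumsum(zd))
}

#' Master-equation generator matrix at a fixed voltage
#'
#' Builds the n x n rate matrix G of the continuous-time Markov chain in the
#' row-vector convention `dp/dt = p G`: `G[i, i+1]` is the forward rate out
#' of state i, `G[i+1, i]` the backward rate, rows sum to zero.
#'
#' @param scheme A [kinetic_scheme].
#' @param V Membrane voltage in mV.
#' @return n x n numeric matrix (1/ms) with zero row sums.
#' @export
build_generator <- function(scheme, V) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            is.numeric(V), length(V) == 1, is.finite(V))
  n <- length(scheme$state_names)
  G <- matrix(0, n, n, dimnames = list(scheme$state_names, scheme$state_names))
  for (i in seq_len(n - 1)) {
    r <- transition_rates(scheme$transitions[[i]], V, scheme$temperature)
    G[i, i + 1] <- r$alpha
    G[i + 1, i] <- r$beta
  }
  diag(G) <- -rowSums(G)
  G
}

#' Equilibrium state occupancy at a fixed voltage
#'
#' Stationary distribution of the gating chain, computed from the left null
#' space of the generator. For the reversible linear chain this equals the
#' normalised product of Boltzmann factors `prod(alpha_j / beta_j)` along the
#' chain, which is used as an independent oracle in the tests.
#'
#' @param scheme A [kinetic_scheme].
#' @param V Membrane voltage in mV.
#' @return Probability vector over states (sums to 1).
#' @export
equilibrium_occupancy <- function(scheme, V) {
  G <- build_generator(scheme, V)
  n <- nrow(G)
  sv <- svd(G)
  # left null vector: column of U with (numerically) zero singular value
  if (n > 1 && sv$d[n - 1] < 1e-9 * max(sv$d)) {
    stop("degenerate scheme: generator has a multidimensional null space")
  }
  p <- sv$u[, n]
  p <- p / sum(p)
  if (any(p < -1e-12)) {
    stop("degenerate scheme: stationary vector is not a distribution")
  }
  p <- pmax(p, 0)
  stats::setNames(p / sum(p), scheme$state_names)
}

#' Solve the gating master equation by spectral decomposition
#'
#' Propagates the state occupancy exactly, `p(t) = p0 exp(G t)`, by
#' eigendecomposition of the generator. If the eigenvector matrix is close
#' to singular (defective generator) the solver falls back to a
#' scaling-and-squaring matrix exponential with a warning.
#'
#' @param scheme A [kinetic_scheme].
#' @param V Membrane voltage in mV (constant over `times`).
#' @param p0 Initial occupancy (sums to 1).
#' @param times Sample times in ms (non-negative, increasing).
#' @return An `occupancy_trajectory`: list with `times`, `occupancy`
#'   (length(times) x n matrix), and `voltage` per sample.
#' @export
solve_occupancies <- function(scheme, V, p0, times) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            is.numeric(p0), is.numeric(times), all(times >= 0),
            !is.unsorted(times))
  n <- length(scheme$state_names)
  if (length(p0) != n) stop("`p0` length must match the number of states")
  if (abs(sum(p0) - 1) > 1e-8) stop("`p0` must sum to 1")
  G <- build_generator(scheme, V)
  P <- .propagate(G, p0, times)
  structure(list(times = times,
                 occupancy = P,
                 voltage = rep(V, length(times)),
                 state_names = scheme$state_names),
            class = "occupancy_trajectory")
}

# Exact propagation of p(t) = p0 expm(G t) at the requested times.
.propagate <- function(G, p0, times) {
  n <- nrow(G)
  eg <- eigen(G)
  R <- eg$vectors
  lam <- eg$values
  use_spectral <- TRUE
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv)) {
    use_spectral <- FALSE
  } else {
    kappa <- norm(R, "2") * norm(Rinv, "2")
    if (!is.finite(kappa) || kappa > 1e10) use_spectral <- FALSE
  }
  if (use_spectral) {
    c0 <- as.vector(p0 %*% R)  # possibly complex
    P <- t(vapply(times, function(tt) {
      row <- (c0 * exp(lam * tt)) %*% Rinv
      Re(as.vector(row))
    }, numeric(n)))
  } else {
    warning("generator is numerically defective; using matrix-exponential fallback")
    P <- matrix(NA_real_, length(times), n)
    p <- p0
    tprev <- 0
    for (k in seq_along(times)) {
      dt <- times[k] - tprev
      if (dt > 0) p <- as.vector(p %*% as.matrix(Matrix::expm(G * dt)))
      P[k, ] <- p
      tprev <- times[k]
    }
  }
  # clip tiny negative round-off and renormalise
  P[P < 0 & P > -1e-10] <- 0
  P / rowSums(P)
}

#' Macroscopic gating current from an occupancy trajectory
#'
#' The gating current is the rate of change of the mean displaced charge,
#' \deqn{I_g(t) = N e_0 \sum_i z_i \, dp_i/dt,}
#' so that its time integral over a full relaxation equals
#' `N e0 (<z>_final - <z>_initial)`. With `scheme` supplied the derivative is
#' evaluated exactly as `p(t) G z`; otherwise central finite differences on
#' the sampled occupancy are used.
#'
#' @param traj An `occupancy_trajectory` from [solve_occupancies()].
#' @param z Per-state charges (e0), e.g. [state_charges()].
#' @param n_channels Channel count N.
#' @param scheme Optional [kinetic_scheme] for exact derivatives (the
#'   trajectory voltage must be constant in that case).
#' @return Numeric current trace in fC/ms, positive for outward (ON) charge
#'   movement.
#' @export
gating_current <- function(traj, z, n_channels, scheme = NULL) {
  stopifnot(inherits(traj, "occupancy_trajectory"))
  P <- traj$occupancy
  if (length(z) != ncol(P)) {
    stop("length of `z` must match the number of states in the trajectory")
  }
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "kinetic_scheme"))
    if (length(unique(traj$voltage)) != 1) {
      stop("exact derivative requires a constant-voltage trajectory")
    }
    G <- build_generator(scheme, traj$voltage[1])
    dz <- as.vector(P %*% G %*% z)
  } else {
    t <- traj$times
    mz <- as.vector(P %*% z)
    dz <- numeric(length(t))
    if (length(t) >= 3) {
      dz[-c(1, length(t))] <- (mz[-(1:2)] - mz[-((length(t) - 1):length(t))]) /
        (t[-(1:2)] - t[-((length(t) - 1):length(t))])
      dz[1] <- (mz[2] - mz[1]) / (t[2] - t[1])
      dz[length(t)] <- (mz[length(t)] - mz[length(t) - 1]) /
        (t[length(t)] - t[length(t) - 1])
    } else if (length(t) == 2) {
      dz[] <- (mz[2] - mz[1]) / (t[2] - t[1])
    }
  }
  n_channels * .e0_fC * dz
}

#' Voltage-step protocol
#'
#' A piecewise-constant voltage-clamp protocol: an ordered set of segments,
#' each holding one voltage for a duration, sampled on a uniform grid.
#'
#' @param durations Segment durations in ms (all positive).
#' @param voltages Segment voltages in mV (same length).
#' @param sample_interval Sampling interval in ms.
#' @return An object of class `voltage_protocol`.
#' @examples
#' # hold / depolarising step / repolarisation, as in a gating-current sweep
#' voltage_protocol(c(5, 20, 50), c(-90, 150, 0), sample_interval = 0.05)
#' @export
voltage_protocol <- function(durations, voltages, sample_interval = 0.05) {
  stopifnot(length(durations) >= 1, length(durations) == length(voltages),
            all(is.finite(durations)), all(durations > 0),
            all(is.finite(voltages)),
            is.numeric(sample_interval), sample_interval > 0)
  structure(list(durations = as.numeric(durations),
                 voltages = as.numeric(voltages),
                 sample_interval = sample_interval),
            class = "voltage_protocol")
}

#' Simulate a gating-current sweep under a step protocol
#'
#' Runs the kinetic scheme through a [voltage_protocol], starting from
#' equilibrium at the first segment's voltage (the holding potential) and
#' propagating occupancies exactly within each segment with continuity
#' across boundaries. For the canonical hold-step-hold protocol the sweep is
#' annotated with the depolarisation window and repolarisation start so the
#' trace-analysis functions can locate ON and OFF charge without guessing.
#'
#' @param scheme A [kinetic_scheme].
#' @param protocol A [voltage_protocol].
#' @return A `gating_sweep`: list with `times` (ms), `current` (fC/ms),
#'   `voltage` (mV per sample), `occupancy`, and `annotations`.
#' @export
simulate_protocol <- function(scheme, protocol) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "voltage_protocol"))
  if (length(protocol$durations) == 0) stop("empty protocol")
  z <- state_charges(scheme)
  dt <- protocol$sample_interval
  p <- equilibrium_occupancy(scheme, protocol$voltages[1])

  times <- numeric(0); volts <- numeric(0); curr <- numeric(0)
  occ <- NULL
  t0 <- 0
  nseg <- length(protocol$durations)
  for (s in seq_len(nseg)) {
    dur <- protocol$durations[s]
    V <- protocol$voltages[s]
    # segment-local sample times; the boundary sample belongs to the new segment
    tl <- seq(0, dur, by = dt)
    if (s == nseg && tl[length(tl)] < dur) tl <- c(tl, dur)
    G <- build_generator(scheme, V)
    P <- .propagate(G, p, tl)
    I <- scheme$n_channels * .e0_fC * as.vector(P %*% G %*% z)
    keep <- if (s < nseg) seq_len(length(tl) - 1) else seq_along(tl)
    times <- c(times, t0 + tl[keep])
    volts <- c(volts, rep(V, length(keep)))
    curr <- c(curr, I[keep])
    occ <- rbind(occ, P[keep, , drop = FALSE])
    p <- P[length(tl), ]
    t0 <- t0 + dur
  }

  ann <- list()
  if (nseg == 3) {
    ann <- list(depol_start = protocol$durations[1],
                depol_end = protocol$durations[1] + protocol$durations[2],
                repol_start = protocol$durations[1] + protocol$durations[2],
                duration = protocol$durations[2])
  }
  structure(list(times = times, current = curr, voltage = volts,
                 occupancy = occ, annotations = ann),
            class = "gating_sweep")
}

#' @export
print.gating_sweep <- function(x, ...) {
  cat(sprintf("Gating-current sweep: %d samples, %.3g-%.3g ms, peak |I| = %.4g fC/ms\n",
              length(x$times), min(x$times), max(x$times),
              max(abs(x$current))))
  if (length(x$annotations)) {
    cat(sprintf("  depolarisation %.3g-%.3g ms, repolarisation from %.3g ms\n",
                x$annotations$depol_start, x$annotations$depol_end,
                x$annotations$repol_start))
  }
  invisible(x)
}

#' Construct a gating sweep from raw samples
#'
#' @param times Sample times in ms, strictly increasing.
#' @param current Current samples (fC/ms).
#' @param voltage Voltage per sample (mV); scalar is recycled.
#' @param annotations Optional list with `depol_start`, `depol_end`,
#'   `repol_start`, `duration` (ms).
#' @return A `gating_sweep` object.
#' @export
gating_sweep <- function(times, current, voltage = NA_real_,
                         annotations = list()) {
  stopifnot(is.numeric(times), is.numeric(current),
            length(times) == length(current), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (length(voltage) == 1) voltage <- rep(voltage, length(times))
  stopifnot(length(voltage) == length(times))
  for (f in intersect(names(annotations),
                      c("depol_start", "depol_end", "repol_start"))) {
    v <- annotations[[f]]
    if (v < times[1] || v > times[length(times)]) {
      stop(sprintf("annotation `%s` lies outside the sweep time range", f))
    }
  }
  structure(list(times = times, current = current, voltage = voltage,
                 annotations = annotations),
            class = "gating_sweep")
}

#' Illustrative five-state gating schemes
#'
#' Ready-made parameterisations of the five-state linear gating chain
#' (A1-A2-A3-B1-B2) used throughout the documentation and tests. These are
#' documented example configurations with qualitatively correct behaviour,
#' not fitted channel parameters:
#' * `"conservative"` - all backward rates fast enough that the OFF charge
#'   fully recovers the ON charge (Q_OFF/Q_ON = 1).
#' * `"trapping"` - the A3 <-> B1 step has a deep active-side well (slow
#'   backward rate at the 0 mV repolarisation potential, large step charge),
#'   so on repolarisation to the proton reversal potential the sensor stalls
#'   behind the B1 -> A3 barrier and Q_OFF over a short window is much
#'   smaller than Q_ON, while the resting state is still favoured at the
#'   -90 mV holding potential.
#'
#' @param type `"conservative"` or `"trapping"`.
#' @param n_channels Channel count; default 2.4e7 gives a few nC of total
#'   gating charge, the order seen in giant-patch recordings.
#' @return A [kinetic_scheme].
#' @export
example_scheme <- function(type = c("conservative", "trapping"),
                           n_channels = 2.4e7) {
  type <- match.arg(type)
  step3 <- if (type == "trapping") {
    # slow entry into the deep B1 well (tau ~ 20 ms at +200 mV) and a
    # backward barrier high enough that escape at 0 mV takes minutes
    transition_params(alpha0 = 1.4e-4, beta0 = 7e-6, x = 0.5, z_delta = 1.5)
  } else {
    transition_params(alpha0 = 0.4, beta0 = 8.0, x = 0.5, z_delta = 0.8)
  }
  # per-step equilibrium constants of 0.05 at 0 mV keep the chain fully
  # resting at the 0 mV repolarisation potential (proton reversal), like
  # the real sensor whose Q(V) midpoint sits above +100 mV; full
  # activation then needs steps towards +200 mV, as in the published
  # double-pulse protocol
  kinetic_scheme(
    transitions = list(
      transition_params(alpha0 = 0.6, beta0 = 12.0, x = 0.5, z_delta = 0.5),
      transition_params(alpha0 = 0.5, beta0 = 10.0, x = 0.5, z_delta = 0.5),
      step3,
      transition_params(alpha0 = 0.3, beta0 = 6.0, x = 0.5, z_delta = 0.4)
    ),
    state_names = c("A1", "A2", "A3", "B1", "B2"),
    n_channels = n_channels,
    temperature = 295.15
  )
}
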