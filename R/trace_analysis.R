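#' Integrate gating charge over a time window
#'
#' Trapezoidal integral of the baseline-subtracted current over a window,
#' returned as a magnitude so that ON (outward, positive) and OFF (inward,
#' negative) charges can be compared directly. With `baseline = NULL` the
#' baseline is the mean current over the last 10% of the window, which
#' removes any residual steady current (e.g. the small macroscopic proton
#' current some selectivity-filter mutants carry).
#'
#' @param sweep A `gating_sweep`.
#' @param window Numeric length-2 vector `(start, end)` in ms.
#' @param baseline Baseline current (fC/ms), `NULL` for the tail-mean
#'   estimate, or `0` to integrate the raw current.
#' @param signed If `TRUE`, return the signed integral instead of the
#'   magnitude.
#' @return Charge in fC (non-negative unless `signed = TRUE`).
#' @export
integrate_charge <- function(sweep, window, baseline = 0, signed = FALSE) {
  stopifnot(inherits(sweep, "gating_sweep"),
            is.numeric(window), length(window) == 2, window[1] < window[2])
  t <- sweep$times
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9) {
    stop("integration window lies outside the sweep time range")
  }
  sel <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
  if (sum(sel) < 2) stop("integration window contains fewer than 2 samples")
  tw <- t[sel]; iw <- sweep$current[sel]
  if (is.null(baseline)) {
    tail_sel <- tw >= window[2] - 0.1 * diff(window)
    baseline <- mean(iw[tail_sel])
  }
  if (!is.finite(baseline)) stop("baseline must be finite")
  q <- pracma::trapz(tw, iw - baseline)
  if (signed) q else abs(q)
}

#' Peak amplitude of the fast OFF-gating current transient
#'
#' Magnitude of the extremum of the baseline-subtracted current within a
#' short search window after repolarisation. The OFF transient decays from
#' its peak essentially instantaneously on the sweep time base, so a 5 ms
#' window captures it for all the kinetics considered here; the window is
#' configurable.
#'
#' @param sweep A `gating_sweep` whose annotations include `repol_start`.
#' @param search_window Length of the post-repolarisation search window (ms).
#' @param baseline Baseline current; `NULL` estimates it as the mean over
#'   the final 10% of the repolarisation segment.
#' @return Peak magnitude in fC/ms.
#' @export
off_peak_amplitude <- function(sweep, search_window = 5, baseline = NULL) {
  stopifnot(inherits(sweep, "gating_sweep"))
  rs <- sweep$annotations$repol_start
  if (is.null(rs)) stop("sweep has no `repol_start` annotation")
  t <- sweep$times
  t_end <- t[length(t)]
  sel <- t >= rs & t <= min(rs + search_window, t_end)
  if (sum(sel) < 1) stop("empty repolarisation search window")
  if (is.null(baseline)) {
    off_len <- t_end - rs
    tail_sel <- t >= t_end - 0.1 * off_len
    baseline <- mean(sweep$current[tail_sel])
  }
  max(abs(sweep$current[sel] - baseline))
}

# Exponential model catalogue. Each entry: parameter names (taus last),
# prediction function, and number of time constants.
.exp_models <- list(
  single_decay = list(
    pars = c("A", "tau1"),
    fn = function(t, p) p[["A"]] * exp(-t / p[["tau1"]])
  ),
  single_saturating = list(
    pars = c("A", "tau1"),
    fn = function(t, p) p[["A"]] * (1 - exp(-t / p[["tau1"]]))
  ),
  double_decay = list(
    pars = c("A", "tau1", "B", "tau2"),
    fn = function(t, p) p[["A"]] * exp(-t / p[["tau1"]]) +
      p[["B"]] * exp(-t / p[["tau2"]])
  ),
  double_saturating = list(
    pars = c("A", "tau1", "B", "tau2"),
    fn = function(t, p) p[["A"]] * (1 - exp(-t / p[["tau1"]])) +
      p[["B"]] * (1 - exp(-t / p[["tau2"]]))
  )
)

# Crude log-linear tail estimate of a decay time constant; NA on failure.
.tail_tau <- function(t, y) {
  y0 <- y - min(y) * (min(y) < 0)
  pos <- which(abs(y0) > 0.05 * max(abs(y0)))
  if (length(pos) < 3) return(NA_real_)
  fit <- tryCatch(stats::lm(log(abs(y0[pos])) ~ t[pos]), error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  sl <- unname(stats::coef(fit)[2])
  if (!is.finite(sl) || sl >= 0) NA_real_ else -1 / sl
}

#' Fit single/double exponential kinetics to a time course
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of one of four
#' exponential models to `(t, y)` data:
#' * `single_decay`: `A exp(-t/tau1)`
#' * `single_saturating`: `A (1 - exp(-t/tau1))`
#' * `double_decay`: `A exp(-t/tau1) + B exp(-t/tau2)`
#' * `double_saturating`: `A (1 - exp(-t/tau1)) + B (1 - exp(-t/tau2))`
#' each optionally plus a constant offset. Because the amplitudes enter
#' linearly, the fit uses variable projection: for every candidate set of
#' time constants the optimal amplitudes are solved by linear least
#' squares, the profiled residual is minimised over a log-spaced grid of
#' time constants (seeded additionally by a log-linear tail regression and
#' any user `init`), and the best candidate is polished by full
#' Levenberg-Marquardt. Time constants are returned in canonical order
#' `tau1 <= tau2` (amplitudes permuted accordingly). Amplitude signs are
#' unconstrained, so mixed rising/decaying double fits are allowed.
#'
#' @param t Time points (ms), increasing.
#' @param y Observations.
#' @param model_id One of `"single_decay"`, `"single_saturating"`,
#'   `"double_decay"`, `"double_saturating"`.
#' @param init Optional named list of starting values (`A`, `tau1`, `B`,
#'   `tau2`, `offset`).
#' @param fit_offset If `TRUE`, estimate an additive offset; otherwise the
#'   offset is fixed at 0.
#' @return An object of class `exponential_fit`: list with `model_id`,
#'   `A`, `B`, `tau1`, `tau2` (NA for single models), `offset`, `rss`,
#'   `fitted`, `converged`.
#' @examples
#' t <- seq(0, 60, by = 2)
#' y <- 5 * exp(-t / 10)
#' fit_exponential_model(t, y, "single_decay")
#' @export
fit_exponential_model <- function(t, y, model_id, init = NULL,
                                  fit_offset = FALSE) {
  model_id <- match.arg(model_id, names(.exp_models))
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  if (is.unsorted(t, strictly = TRUE)) stop("`t` must be strictly increasing")
  mod <- .exp_models[[model_id]]
  npar <- length(mod$pars) + as.integer(fit_offset)
  if (length(t) <= npar) {
    stop(sprintf("need more than %d points to fit %s", npar, model_id))
  }

  span <- diff(range(t))
  saturating <- grepl("saturating", model_id)
  n_tau <- length(mod$pars) / 2
  tau_seed <- .tail_tau(t, if (saturating) max(y) - y else y)

  # profiled (variable-projection) residual: amplitudes are linear given taus
  basis_col <- function(tau) {
    if (saturating) 1 - exp(-t / tau) else exp(-t / tau)
  }
  amp_solve <- function(taus) {
    X <- vapply(taus, basis_col, numeric(length(t)))
    if (fit_offset) X <- cbind(X, 1)
    f <- stats::lm.fit(X, y)
    list(coef = f$coefficients, rss = sum(f$residuals^2))
  }

  tau_grid <- exp(seq(log(max(min(diff(t)) / 4, span * 5e-4)),
                      log(span * 25), length.out = 30))
  extra <- c(tau_seed, unlist(init)[grepl("^tau", names(unlist(init)))])
  tau_grid <- sort(unique(c(tau_grid, extra[is.finite(extra) & extra > 0])))
  cand <- if (n_tau == 1) {
    lapply(tau_grid, function(x) x)
  } else {
    pairs <- expand.grid(tau1 = tau_grid, tau2 = tau_grid)
    pairs <- pairs[pairs$tau1 < pairs$tau2, , drop = FALSE]
    lapply(seq_len(nrow(pairs)), function(k) as.numeric(pairs[k, ]))
  }
  best <- NULL
  for (taus in cand) {
    sol <- tryCatch(amp_solve(taus), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol$coef)) next
    if (is.null(best) || sol$rss < best$rss) {
      best <- list(taus = taus, coef = sol$coef, rss = sol$rss)
    }
  }
  if (is.null(best)) stop("exponential fit failed: no admissible time constants")

  st <- if (n_tau == 1) {
    c(A = unname(best$coef[1]), tau1 = best$taus[1])
  } else {
    c(A = unname(best$coef[1]), tau1 = best$taus[1],
      B = unname(best$coef[2]), tau2 = best$taus[2])
  }
  if (!is.null(init)) {
    ini <- unlist(init)
    st[intersect(names(st), names(ini))] <- ini[intersect(names(st), names(ini))]
  }
  lower <- ifelse(grepl("^tau", mod$pars), 1e-6, -Inf)
  if (fit_offset) {
    st <- c(st, offset = unname(best$coef[length(best$coef)]))
    lower <- c(lower, -Inf)
  }
  predict_fn <- function(p) {
    base <- mod$fn(t, p)
    if (fit_offset) base + p[["offset"]] else base
  }
  polish <- tryCatch(
    minpack.lm::nls.lm(
      par = as.list(st),
      fn = function(par) y - predict_fn(unlist(par)),
      lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (!is.null(polish) && sum(polish$fvec^2) <= best$rss + 1e-12) {
    best <- list(par = unlist(polish$par), rss = sum(polish$fvec^2),
                 converged = polish$info %in% 1:4)
  } else {
    best <- list(par = st, rss = best$rss, converged = TRUE)
  }

  p <- best$par
  A <- p[["A"]]; tau1 <- p[["tau1"]]
  B <- if ("B" %in% names(p)) p[["B"]] else NA_real_
  tau2 <- if ("tau2" %in% names(p)) p[["tau2"]] else NA_real_
  if (!is.na(tau2) && tau2 < tau1) {  # canonical order: tau1 <= tau2
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- A; A <- B; B <- tmp
  }
  offset <- if (fit_offset) p[["offset"]] else 0
  pars_out <- c(A = A, tau1 = tau1, B = B, tau2 = tau2)
  structure(list(model_id = model_id, A = A, B = B, tau1 = tau1, tau2 = tau2,
                 offset = offset, rss = best$rss,
                 fitted = {
                   pf <- pars_out[!is.na(pars_out)]
                   if (fit_offset) pf <- c(pf, offset = offset)
                   predict_fn(pf)
                 },
                 converged = best$converged),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Exponential fit (%s): A = %.6g, tau1 = %.6g ms", x$model_id,
              x$A, x$tau1))
  if (!is.na(x$tau2)) cat(sprintf(", B = %.6g, tau2 = %.6g ms", x$B, x$tau2))
  if (x$offset != 0) cat(sprintf(", offset = %.6g", x$offset))
  cat(sprintf("; RSS = %.4g\n", x$rss))
  invisible(x)
}

#' Q_OFF/Q_ON charge-ratio time course across depolarisation durations
#'
#' For each sweep of a variable-duration family, integrates the ON charge
#' over the depolarisation window (baseline: mean current over its final
#' 10%, removing residual steady current) and the OFF charge over the
#' first `off_window` ms of repolarisation (baseline: mean over the final
#' 10% of the repolarisation segment), and returns the Q_OFF/Q_ON ratio
#' per duration. A ratio staying at 1 indicates charge conservation; a
#' ratio decaying with duration is the signature of voltage-sensor
#' trapping.
#'
#' @param sweeps List of `gating_sweep` objects annotated with
#'   `depol_start`, `depol_end`, `repol_start`, `duration`.
#' @param off_window OFF integration window length in ms (default 20).
#' @param noise_floor Minimum Q_ON (fC) below which the ratio is flagged
#'   undefined (NA).
#' @param on_baseline ON-window baseline: `NULL` (default) estimates it as
#'   the mean current over the final 10% of the depolarisation, which
#'   removes a residual steady (macroscopic) current but clips genuine
#'   gating current when the pulse is shorter than the ON relaxation; pass
#'   `0` for leak-free simulated sweeps.
#' @return Data frame with columns `duration_ms`, `q_on_fC`, `q_off_fC`,
#'   `ratio`.
#' @export
charge_ratio_timecourse <- function(sweeps, off_window = 20,
                                    noise_floor = 0, on_baseline = NULL) {
  stopifnot(is.list(sweeps), length(sweeps) >= 1)
  rows <- lapply(sweeps, function(sw) {
    ann <- sw$annotations
    if (is.null(ann$depol_start) || is.null(ann$repol_start)) {
      stop("sweep lacks depolarisation/repolarisation annotations")
    }
    t_end <- sw$times[length(sw$times)]
    # the sample at repol_start already carries the OFF transient; end the
    # ON window at the last sample of the depolarising segment
    on_end <- max(sw$times[sw$times < ann$repol_start])
    q_on <- integrate_charge(sw, c(ann$depol_start, on_end),
                             baseline = on_baseline)
    off_end <- min(ann$repol_start + off_window, t_end)
    off_tail <- t_end - ann$repol_start
    base_sel <- sw$times >= t_end - 0.1 * off_tail
    off_base <- mean(sw$current[base_sel])
    q_off <- integrate_charge(sw, c(ann$repol_start, off_end),
                              baseline = off_base)
    data.frame(duration_ms = ann$duration, q_on_fC = q_on, q_off_fC = q_off,
               ratio = if (q_on > noise_floor) q_off / q_on else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[order(out$duration_ms), , drop = FALSE]
}

#' Double-pulse recovery-from-trapping analysis
#'
#' Fits the recovered second-pulse charge as a saturating exponential of
#' the interpulse interval, `Q(t) = Q_max (1 - exp(-t/tau))`, and returns
#' the recovery amplitude and time constant. This quantifies how long the
#' voltage sensor needs at the holding potential to escape the trapped
#' active configuration.
#'
#' @param intervals Interpulse intervals in ms (>= 4 points).
#' @param charges Second-pulse ON charge per interval (fC).
#' @return List with `q_max` (fC), `tau` (ms) and the underlying
#'   `exponential_fit`.
#' @export
recovery_analysis <- function(intervals, charges) {
  stopifnot(is.numeric(intervals), is.numeric(charges),
            length(intervals) == length(charges))
  if (length(intervals) < 4) stop("need at least 4 interval points")
  o <- order(intervals)
  intervals <- intervals[o]; charges <- charges[o]
  dif <- diff(charges)
  if (any(dif < -0.05 * max(abs(charges)))) {
    warning("recovery data are non-monotone beyond noise; fitting anyway")
  }
  fit <- fit_exponential_model(intervals, charges, "single_saturating")
  list(q_max = fit$A, tau = fit$tau1, fit = fit)
}
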