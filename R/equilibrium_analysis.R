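#' Assemble a Q(V) curve from charge-by-voltage measurements
#'
#' Sorts by voltage, averages duplicate voltages (with a warning), and, when
#' several replicates are supplied, pools them into per-voltage mean and
#' SEM. One Q(V) curve is measured per patch, so replicates are across
#' patches.
#'
#' @param voltages Step voltages in mV.
#' @param charges Gating charges in fC (or any consistent unit).
#' @param replicate Optional replicate identifier per point.
#' @param normalize If `TRUE`, scale charges to a maximum of 1.
#' @return An object of class `qv_curve`: data frame with columns
#'   `voltage_mV`, `charge`, and (when replicates are pooled) `sem`, `n`.
#' @export
build_qv <- function(voltages, charges, replicate = NULL, normalize = FALSE) {
  stopifnot(is.numeric(voltages), is.numeric(charges),
            length(voltages) == length(charges),
            all(is.finite(voltages)), all(is.finite(charges)))
  df <- data.frame(voltage_mV = voltages, charge = charges)
  if (!is.null(replicate)) {
    stopifnot(length(replicate) == length(voltages))
    df$replicate <- replicate
    agg_m <- stats::aggregate(charge ~ voltage_mV, df, mean)
    agg_s <- stats::aggregate(charge ~ voltage_mV, df,
                              function(x) stats::sd(x) / sqrt(length(x)))
    agg_n <- stats::aggregate(charge ~ voltage_mV, df, length)
    df <- data.frame(voltage_mV = agg_m$voltage_mV, charge = agg_m$charge,
                     sem = agg_s$charge, n = agg_n$charge)
  } else if (anyDuplicated(df$voltage_mV)) {
    warning("duplicate voltages averaged")
    df <- stats::aggregate(charge ~ voltage_mV, df, mean)
  }
  df <- df[order(df$voltage_mV), , drop = FALSE]
  if (length(unique(df$voltage_mV)) < 5) {
    stop("a Q(V) curve needs at least 5 distinct voltages")
  }
  if (normalize) df$charge <- df$charge / max(df$charge)
  rownames(df) <- NULL
  structure(df, class = c("qv_curve", "data.frame"))
}

#' Two-state Boltzmann charge-voltage relation
#'
#' Evaluates `Q(V) = q_max / (1 + exp(-z_delta * F * (V - v_half) / (R T)))`
#' (ascending in V: depolarisation moves gating charge outward). The
#' descending orientation, with a plus sign in the exponent, is available
#' via `descending = TRUE`.
#'
#' @param V Voltage in mV.
#' @param v_half Half-activation voltage in mV.
#' @param z_delta Effective gating charge (e0).
#' @param q_max Maximal charge.
#' @param temperature Kelvin.
#' @param descending Use the descending orientation.
#' @return Charge at each voltage.
#' @export
boltzmann_qv <- function(V, v_half, z_delta, q_max = 1, temperature = 295.15,
                         descending = FALSE) {
  s <- if (descending) 1 else -1
  vt <- thermal_voltage_mV(temperature)  # kT/e0 = RT/F in mV
  q_max / (1 + exp(s * z_delta * (V - v_half) / vt))
}

#' Fit a two-state Boltzmann to a Q(V) curve
#'
#' Least-squares estimates of `v_half` (mV), `z_delta` (e0) and `q_max`
#' from charge-voltage data. The midpoint satisfies Q(v_half) = q_max/2 and
#' the slope of the normalised curve at the midpoint is
#' `z_delta * F / (4 R T)` per mV. Standard errors come from the local
#' linearisation of the fit.
#'
#' @param curve A `qv_curve` from [build_qv()], or any data frame with
#'   columns `voltage_mV` and `charge`.
#' @param temperature Kelvin.
#' @param descending Fit the descending orientation instead.
#' @return An object of class `boltzmann_fit`: list with `v_half`,
#'   `z_delta`, `q_max`, their standard errors, `rss` and `fitted`.
#' @export
fit_boltzmann <- function(curve, temperature = 295.15, descending = FALSE) {
  stopifnot(is.data.frame(curve),
            all(c("voltage_mV", "charge") %in% names(curve)))
  V <- curve$voltage_mV; Q <- curve$charge
  if (length(V) < 4) stop("too few points for a 3-parameter Boltzmann fit")
  rngQ <- diff(range(Q))
  if (rngQ <= 0 || rngQ < 1e-12 * max(abs(Q))) {
    stop("charge data are flat; Boltzmann fit is unidentifiable")
  }
  qm0 <- max(Q)
  qn <- Q / qm0
  v0 <- V[which.min(abs(qn - 0.5))]
  vt <- thermal_voltage_mV(temperature)
  # slope-based z seed from the central part of the curve
  mid <- qn > 0.2 & qn < 0.8
  z0 <- if (sum(mid) >= 2) {
    sl <- stats::coef(stats::lm(qn[mid] ~ V[mid]))[2]
    max(abs(sl) * 4 * vt, 0.1)
  } else 1
  fit <- minpack.lm::nlsLM(
    charge ~ boltzmann_qv(voltage_mV, v_half, z_delta, q_max,
                          temperature = temperature,
                          descending = descending),
    data = data.frame(voltage_mV = V, charge = Q),
    start = list(v_half = v0, z_delta = z0, q_max = qm0),
    lower = c(-Inf, 1e-4, 1e-12),
    control = stats::nls.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(v_half = unname(cf["v_half"]),
                 z_delta = unname(cf["z_delta"]),
                 q_max = unname(cf["q_max"]),
                 se = stats::setNames(unname(se), names(cf)),
                 temperature = temperature,
                 descending = descending,
                 rss = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Two-state Boltzmann fit: V0.5 = %.4g mV, z-delta = %.4g e0, Qmax = %.5g\n",
              x$v_half, x$z_delta, x$q_max))
  invisible(x)
}

#' Activation free energy of the voltage sensor
#'
#' Chemical free-energy cost of the resting-to-active transition at 0 mV
#' under the two-state model: `delta_G = z_delta * F * V0.5`, converted to
#' kcal/mol. Differences between mutants (`delta_delta_G`) isolate the
#' effect of a perturbation on the sensor's energy landscape.
#'
#' @param fit A `boltzmann_fit`, or a list with `v_half` (mV) and
#'   `z_delta` (e0).
#' @return Free energy in kcal/mol.
#' @examples
#' activation_free_energy(list(v_half = 124.1, z_delta = 1.14))  # ~3.26
#' @export
activation_free_energy <- function(fit) {
  stopifnot(is.list(fit), !is.null(fit$v_half), !is.null(fit$z_delta))
  fit$z_delta * .faraday_C_per_mol * (fit$v_half / 1000) / .joule_per_kcal
}

#' Correlate mutant activation energies with selectivity-filter
#' hydrophobicity
#'
#' Ordinary least-squares regression of per-mutant `ddG` (activation
#' free-energy difference vs a reference construct, kcal/mol) on the
#' hydrophobicity of the residue substituted at the selectivity filter.
#' Returns the fitted line and Pearson correlation.
#'
#' @param ddg Free-energy differences (kcal/mol), one per mutant.
#' @param hydrophobicity Hydrophobicity scale value per mutant (kcal/mol).
#' @return List with `slope`, `intercept`, `r`, and the underlying `lm`
#'   fit.
#' @export
ddg_hydrophobicity_correlation <- function(ddg, hydrophobicity) {
  stopifnot(is.numeric(ddg), is.numeric(hydrophobicity),
            length(ddg) == length(hydrophobicity))
  if (length(ddg) < 3) stop("need at least 3 mutants for a correlation")
  fit <- stats::lm(ddg ~ hydrophobicity)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r = stats::cor(hydrophobicity, ddg), fit = fit)
}

#' Residue hydrophobicity scales
#'
#' Two standard residue-level hydrophobicity tables, in kcal/mol, for use
#' with [ddg_hydrophobicity_correlation()]: the Wimley-White interface
#' scale (free energy of transfer from water to the POPC interface;
#' negative = favourable for hydrophobic residues under the sign convention
#' used here) and the Kyte-Doolittle hydropathy index (dimensionless but
#' conventionally quoted as-is). Neither scale is privileged; any
#' user-supplied residue-to-value table can be used instead.
#'
#' @param scale `"wimley_white"` or `"kyte_doolittle"`.
#' @return Named numeric vector keyed by one-letter residue code.
#' @export
hydrophobicity_scale <- function(scale = c("wimley_white", "kyte_doolittle")) {
  scale <- match.arg(scale)
  if (scale == "wimley_white") {
    c(A = 0.17, R = 0.81, N = 0.42, D = 1.23, C = -0.24, E = 2.02,
      Q = 0.58, G = 0.01, H = 0.17, I = -0.31, L = -0.56, K = 0.99,
      M = -0.23, F = -1.13, P = 0.45, S = 0.13, T = 0.14, W = -1.85,
      Y = -0.94, V = 0.07)
  } else {
    c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5,
      Q = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
      M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
      Y = -1.3, V = 4.2)
  }
}
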