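---
title: "Modelling and quantifying voltage-sensor charge trapping in Hv1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying voltage-sensor charge trapping in Hv1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvgating)
```

## The problem

The voltage-gated proton channel Hv1 is unusual in that voltage sensing,
proton permeation and pH sensing all live in one structural domain. In
low-conductance mutants the movement of the S4 voltage sensor can be
observed directly as a *gating current*: a transient, capacitive-like
current carried by the sensor's charged arginines. On depolarisation an
outward ON transient moves charge `Q_ON`; on repolarisation an inward OFF
transient should return the same charge, `Q_OFF = Q_ON`. When a positive
charge sits near position 264 on the intracellular side — an introduced
arginine, the guanidinium-bearing blocker 2GBI, or simply a high local
proton concentration — the sensor stalls in its active configuration:
`Q_OFF` falls well below `Q_ON` on the tens-of-milliseconds time scale.
This is *charge trapping*. hvgating provides the quantitative machinery
for studying it: a kinetic simulator, sweep analytics, equilibrium
(Boltzmann) analysis, trajectory post-processing for the structural
(salt-bridge) interpretation, and synthetic-data generators with known
ground truth.

## The kinetic model

Gating is modelled as a continuous-time Markov chain on a linear sequence
of states (by default five, `A1-A2-A3-B1-B2`: resting and intermediate
states feeding two active states). Each step carries rates

$$\alpha(V) = \alpha_0\, e^{x\, z\delta\, e_0 V / kT}, \qquad
  \beta(V) = \beta_0\, e^{(x-1)\, z\delta\, e_0 V / kT},$$

so the fraction $x$ splits the step charge $z\delta$ between the forward
and backward activation barriers while the equilibrium constant always
moves the full $z\delta$. Units are 1/ms, mV and elementary charges; the
conversion constant $kT/e_0$ is computed from the temperature
(`thermal_voltage_mV()`, about 25.4 mV at the 295.15 K default, i.e.
22 °C room temperature), never hard-coded.

Occupancies obey the master equation in row-vector convention,
$\mathrm{d}p/\mathrm{d}t = p\,G$, with $G$ the tridiagonal generator
built by `build_generator()`. `solve_occupancies()` propagates this
*exactly* by eigendecomposition, $p(t) = p_0 R\, e^{\Lambda t} R^{-1}$;
if the eigenvector matrix is ill-conditioned beyond 1e10 the solver falls
back to a scaling-and-squaring matrix exponential with a warning. The
current readout is

$$I_g(t) = N e_0 \sum_i z_i \frac{\mathrm{d}p_i}{\mathrm{d}t},$$

with $z_i$ the cumulative charge of state $i$ relative to the first state
(`state_charges()`), so the time integral of a full relaxation is exactly
$N e_0 \Delta\langle z\rangle$. ON currents are positive (outward),
OFF currents negative. Note the separation: the master equation governs
probabilities only; the charge vector enters through the readout, not
the dynamics.

`simulate_protocol()` runs piecewise-constant voltage protocols starting
from equilibrium at the holding potential. At a voltage step the boundary
sample belongs to the *new* segment, so the instantaneous OFF peak is
sampled at the moment of repolarisation; analyses that integrate the ON
window must therefore stop one sample earlier, which
`charge_ratio_timecourse()` does automatically.

The five-state parameterisations shipped as `example_scheme()` are
documented illustrations, not fitted channel constants (no such constants
are tabulated in the available literature for these mutants). They were
chosen once, on physical grounds: per-step equilibrium constants of 0.05
at 0 mV keep the chain fully resting at the proton reversal potential —
as for the real channel, whose Q(V) midpoint lies above +100 mV so that
essentially no charge is displaced at 0 mV — and depolarising steps to
+200 mV (the published double-pulse protocol voltage) achieve full
activation. The `"trapping"` variant deepens the `B1` well at the
`A3 <-> B1` step (entry τ ≈ 20 ms at +200 mV, escape at 0 mV of order
minutes, step charge 1.5 e0 so the resting state still wins at −90 mV),
reproducing the phenomenology: fast ON charge movement, an OFF deficit
that grows with depolarisation duration, and slow recovery at negative
potentials.

## Trace analysis

`integrate_charge()` uses trapezoidal quadrature of the
baseline-subtracted current, with magnitudes returned so ON and OFF
charges compare directly. Two baseline conventions matter:

* For recordings, the ON baseline is the mean current over the final 10%
  of the depolarisation, which removes the small residual macroscopic
  current some selectivity-filter mutants carry. For pulses shorter than
  the ON relaxation this clips genuine gating charge, so
  `charge_ratio_timecourse(on_baseline = 0)` should be used for
  simulated, leak-free sweeps.
* The OFF baseline is the mean over the final 10% of the repolarisation
  segment; the OFF integration window is 20 ms by default (configurable),
  matching the published convention.

`off_peak_amplitude()` searches the first 5 ms after repolarisation; the
window length is a package choice (the source protocols do not state
one) and is configurable.

`fit_exponential_model()` fits four model families (single/double,
decaying/saturating, optional offset) by variable projection: amplitudes
are linear given the time constants, so the profiled residual is
minimised over a log-spaced grid of time constants (augmented by a
log-linear tail estimate and any user initialisation) and the best
candidate is polished by Levenberg-Marquardt. This makes the fit
essentially immune to local minima; on noiseless data all shipped model
forms are recovered to at least 1e-4. Time constants are reported in
canonical order `tau1 <= tau2`, and amplitude signs are unconstrained
(mixed rising/decaying behaviour occurs in real Q_OFF/Q_ON series).

`recovery_analysis()` fits the double-pulse recovery as
$Q(t) = Q_{max}(1 - e^{-t/\tau})$. The saturating form is used because
recovered charge *increases* with the interpulse interval; the amplitude
is the fully recovered charge and $\tau$ the escape time from the
trapped state.

### Statistical identifiability of slow time constants

A caveat that the synthetic studies make explicit: when the slow time
constant of a double-exponential exceeds the sampled span (e.g.
τ ≈ 185 ms estimated from 11 points over 2–52 ms), the least-squares
estimator — although exact in the noiseless limit and essentially at the
Cramér–Rao bound under noise — has an irreducible sampling error of
order 10–30% per series at 1–2% measurement noise. The same holds for a
slow saturating component underneath an already-saturated fast one. The
package reports the least-squares value as is; in practice such
constants should be estimated from pooled replicates (as is done for
multi-patch recordings), and single-series values beyond the span should
be quoted with generous uncertainties.

## Equilibrium analysis

`fit_boltzmann()` fits the two-state relation in ascending orientation,

$$\frac{Q}{Q_{max}} = \frac{1}{1 + e^{-z\delta F (V - V_{0.5}) / RT}},$$

because depolarisation moves gating charge outward and measured Q(V)
curves rise with V; the mirrored (descending) form is available behind
`descending = TRUE` for comparison with sources that print it that way.
The fit estimates $V_{0.5}$ (mV), $z\delta$ (e0) and $Q_{max}$ with
standard errors from the local linearisation; `build_qv()` pools
replicates (one Q(V) per patch) into per-voltage mean and SEM first.

`activation_free_energy()` converts a fit to the chemical free energy of
the resting-to-active transition at 0 mV,
$\Delta G = z\delta\, F\, V_{0.5}$, in kcal/mol — the standard two-state
convention (for example, $z\delta = 1.14$ and $V_{0.5} = 124.1$ mV give
3.26 kcal/mol). Differences between mutants ($\Delta\Delta G$) feed
`ddg_hydrophobicity_correlation()`, an ordinary least-squares regression
against a residue hydrophobicity scale. Two standard tables ship
(Wimley–White interface, Kyte–Doolittle); neither is privileged and any
residue-to-kcal/mol table can be supplied, since which index a given
study used is often not recoverable.

## Trajectory analytics

The structural interpretation of trapping is the formation of persistent
salt bridges between the selectivity-filter aspartate (D160) and the S4
arginines R258/R261 in an intermediate-active state. The module works on
`frame_series` objects (multi-model PDB via `read_structure_frames()`,
or built in code) with a small selection language
(`"resid 160 and name OD1 OD2 CG"`). Design choices:

* Charged groups are the side-chain moieties — carboxylate
  (OD1, OD2, CG) for Asp, guanidinium (NH1, NH2, NE, CZ) for Arg — and
  distances are between centres of mass with unit masses unless masses
  are given.
* A salt bridge is counted as formed at group–group distance ≤ 4 Å
  (`salt_bridge_occupancy()`, threshold configurable).
* `coulomb_energy()` is the deliberately simple screened point-charge
  estimate $k_C q_a q_b / (\varepsilon_r r)$ averaged over frames, with
  $k_C = 332.0637$ kcal·Å/mol. The relative dielectric
  $\varepsilon_r$ is a **required** argument — there is no defensible
  silent default for a protein/water interface, and reported cycle
  energies are only interpretable alongside the $\varepsilon_r$ used.
* `cycle_energy()` closes the thermodynamic cycle: transition energies
  $\Delta E = E(A_I) - E(A_F)$ per construct, and the variant-minus-
  reference difference $\Delta\Delta E$; it is antisymmetric under
  exchanging the state labels.
* `cluster_frames()` superposes every frame onto the first over the
  C-alpha atoms (own Kabsch implementation, SVD-based, proper rotations
  only) and runs k-means on the flattened coordinates — Euclidean
  distance there is proportional to C-alpha RMSD — with k-means++-style
  restarts under a fixed seed; each cluster is represented by the frame
  nearest its mean. `discard_equilibration()` drops the leading fraction
  of frames (default 1/7, e.g. 50 ns of a 350 ns replicate) before such
  analyses.

## Synthetic data and what the tests do (and do not) show

Every generator takes one integer seed, draws all randomness in an
isolated RNG scope (bit-identical output under a fixed seed, caller's
RNG untouched), and returns its ground truth beside the data.

* `gen_qv_points()`: ascending Boltzmann with **multiplicative** Gaussian
  noise — measurement error on integrated charge scales with the charge.
* `gen_gating_sweeps()` and `gen_timecourse_series()`: exact model output
  plus **additive** Gaussian noise scaled to the peak amplitude —
  instrument noise after filtering is amplitude-independent, and
  peak-referencing keeps it from vanishing where the signal does.
* `gen_toy_trajectory()`: schematic D160/R255/R258/R261 side-chain
  groups whose COM distances follow prescribed single-state or two-state
  (independent Bernoulli dwell) processes; it writes valid, byte-stable
  multi-model PDB. The geometry is synthetic scaffolding for the
  analytics, not a structural model.

The generators emulate the *functional forms and noise levels* of
patch-clamp and MD observables, not their physics: no capacitive/leak
transients, no 1/f noise, no series-resistance artefacts, no solvent or
force-field detail, and two-state dwell sequences are uncorrelated
between frames. Parameter-recovery tests passing on these data therefore
validate the estimators and the pipeline plumbing — integration windows,
baselines, units, orientation conventions — under honest noise; they do
not certify performance against instrumentation artefacts absent from
the generators.

## Numerical choices and problem sizes

* Probability conservation is enforced to 1e-9 per sample; equilibrium
  distributions are validated against the detailed-balance product along
  the chain to 1e-10.
* The spectral propagator is cross-checked against a dense matrix
  exponential on 100 random five-state schemes (and 10–15 against a
  fourth-order Runge–Kutta oracle at dt = 1e-4 ms) to 1e-7 — sizes chosen
  to exercise the rate ranges two decades wide while keeping the suite
  brisk.
* Charge-conservation checks integrate trapezoidally at 0.02–0.05 ms
  sampling; the fast post-step transient limits ON/OFF cancellation to
  about 0.1–0.2%, which the tolerances reflect.
* Recovery/bias studies use 60 seeds per condition; fitter bias is held
  under 2% at 1% noise with 200 samples for all four model families.
* Default protocol family: hold −90 mV, step to +200 mV for 2–52 ms in
  5 ms increments, repolarise to 0 mV with a 20 ms OFF integration
  window — the published trapping time-course design.

## Known limitations

Linear chains only (no branched or cyclic schemes), deterministic
macroscopic currents only (no Gillespie single-channel noise), no proton
conduction coupled to gating, no binary trajectory formats (multi-model
PDB or in-code frames; an adapter to other readers is a one-function
shim), and no periodic-boundary unwrapping (inputs are assumed whole).
These follow the package's scope: the quantitative analysis layer, not
data acquisition or MD itself.
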