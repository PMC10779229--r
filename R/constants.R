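# Physical constants (CODATA 2018). Charge unit throughout is the elementary
# charge e0; macroscopic charge is reported in fC, time in ms, voltage in mV.

.kB_J_per_K <- 1.380649e-23
.e0_C <- 1.602176634e-19
.e0_fC <- 1.602176634e-4     # elementary charge in femtocoulombs
.faraday_C_per_mol <- 96485.33212
.gas_const_J_per_molK <- 8.31446261815324
.joule_per_kcal <- 4184
.coulomb_const_kcalA <- 332.0637  # kcal*Angstrom/(mol*e0^2)

#' Thermal voltage kT/e0
#'
#' The thermal voltage sets the voltage scale of every exponential rate law
#' and of the two-state Boltzmann: at 295.15 K (22 degrees C, the standard
#' recording temperature for patch-clamp work on Hv1) it is about 25.4 mV.
#'
#' @param temperature Absolute temperature in Kelvin.
#' @return Thermal voltage in mV.
#' @examples
#' thermal_voltage_mV(295.15)
#' @export
thermal_voltage_mV <- function(temperature) {
  stopifnot(is.numeric(temperature), all(is.finite(temperature)),
            all(temperature > 0))
  1000 * .kB_J_per_K * temperature / .e0_C
}
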