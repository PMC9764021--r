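## Physical constants and unit conversions used throughout.
## Internal units: length A (angstrom), time us (microsecond), voltage mV,
## energy kcal/mol, rates us^-1.

## 1 kcal/mol per elementary charge = 43.3641 mV (1 kcal/mol = 0.0433641 eV)
.KCALMOL_PER_E_TO_MV <- 43.3641

## Elementary charge, coulomb
.E_CHARGE <- 1.602176634e-19

## Gas constant, kcal mol^-1 K^-1
.R_KCAL <- 1.987204258640832e-3

#' Convert an applied constant electric field to a transmembrane voltage
#'
#' A constant electric field `E_field` (kcal mol^-1 A^-1 e^-1) applied across
#' a periodic box of z-extent `box_length_z` (A) imposes a transmembrane
#' voltage `E_field * box_length_z * 43.3641` mV, using the exact conversion
#' 1 kcal/mol = 0.0433641 eV.
#'
#' @param E_field applied field, kcal mol^-1 A^-1 e^-1 (sign preserved).
#' @param box_length_z box z-length, A; must be > 0.
#' @return voltage in mV.
#' @examples
#' field_to_voltage(0.05, 140)  # ~303.5 mV
#' @export
field_to_voltage <- function(E_field, box_length_z) {
  if (!is.numeric(E_field) || !is.numeric(box_length_z))
    stop("'E_field' and 'box_length_z' must be numeric")
  if (any(box_length_z <= 0))
    stop("'box_length_z' must be positive")
  E_field * box_length_z * .KCALMOL_PER_E_TO_MV
}

#' Voltage protocol descriptor
#'
#' Bundles an applied field, box length, and the implied voltage. If all of
#' `E_field`, `box_length_z` and `voltage` are given they must be mutually
#' consistent (voltage = E_field * box_length_z * 43.3641 mV).
#'
#' @param E_field applied field, kcal mol^-1 A^-1 e^-1 (optional if `voltage`
#'   given).
#' @param box_length_z box z-length, A.
#' @param voltage transmembrane voltage, mV (optional; derived from the field
#'   if missing).
#' @param temperature temperature, K.
#' @return object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(E_field = NULL, box_length_z = NULL,
                             voltage = NULL, temperature = 310) {
  if (is.null(voltage)) {
    if (is.null(E_field) || is.null(box_length_z))
      stop("provide 'voltage' or both 'E_field' and 'box_length_z'")
    voltage <- field_to_voltage(E_field, box_length_z)
  } else if (!is.null(E_field) && !is.null(box_length_z)) {
    expect <- field_to_voltage(E_field, box_length_z)
    if (abs(expect - voltage) > 1e-6 * max(1, abs(expect)))
      stop(sprintf("inconsistent protocol: field implies %.4f mV, got %.4f mV",
                   expect, voltage))
  }
  if (temperature <= 0) stop("'temperature' must be positive (K)")
  structure(list(E_field = E_field, box_length_z = box_length_z,
                 voltage = voltage, temperature = temperature),
            class = "voltage_protocol")
}

## Dimensionless bias exponent helper: full-drop Eyring factor.
## A charge z_q crossing an edge over which a fraction delta of the membrane
## voltage V (mV) drops experiences forward/backward rate factors
## exp(+-z_q*delta*u/2) with u = (V/43.3641)/(R*T) in units of kT.
.bias_exponent <- function(z_q, delta, voltage_mv, temperature = 310) {
  u <- (voltage_mv / .KCALMOL_PER_E_TO_MV) / (.R_KCAL * temperature)
  z_q * delta * u / 2
}
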