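## Internal unit system: mass in g/mol (= amu), length in nm, time in ps,
## temperature in K.  With these units 1 amu nm^2/ps^2 = 1 kJ/mol exactly,
## so kB in kJ/(mol K) makes kB*T directly an energy in internal units.

#' Physical constants and unit conversions
#'
#' `gleml` works internally in MD-native units (g/mol, nm, ps, K), in which
#' energies in kJ/mol coincide with amu nm^2/ps^2.  Conversions to the units
#' in which membrane frictions and diffusion coefficients are conventionally
#' quoted (Pa s um and um^2/s) happen only at the API boundary.
#'
#' @format `kB` is the Boltzmann constant in kJ/(mol K).
#' @keywords internal
#' @name gleml-units
NULL

## Boltzmann constant, kJ mol^-1 K^-1
.kB <- 0.00831446

## amu/ps (internal friction unit, = g mol^-1 ps^-1) -> Pa s um
## 1 amu/ps = 1e-3/NA kg * 1e12 s^-1 = 1.66053906660e-15 kg/s = Pa s m,
## and 1 Pa s m = 1e6 Pa s um.
.friction_to_Pa_s_um <- 1.66053906660e-9

## nm^2/ps -> um^2/s
.D_to_um2_s <- 1e6

kBT <- function(temperature) .kB * temperature
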