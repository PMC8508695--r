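## Physical constants and unit conversions.
##
## All matrix algebra is carried out in SI units (kg, m, s, N, N/m);
## user-facing interfaces speak Angstrom, amu, ps, THz and A^2.

#' @keywords internal
.const <- list(
  kB       = 1.380649e-23,      # Boltzmann constant, J/K
  amu_kg   = 1.66053906660e-27, # unified atomic mass unit, kg
  ang_m    = 1e-10,             # Angstrom, m
  ps_s     = 1e-12,             # picosecond, s
  thz_hz   = 1e12               # THz, Hz
)

## rad/s -> THz
.omega_to_thz <- function(omega) omega / (2 * pi) / .const$thz_hz
## THz -> rad/s
.thz_to_omega <- function(f_thz) 2 * pi * f_thz * .const$thz_hz
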