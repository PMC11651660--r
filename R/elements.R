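# Atomic mass tables. Monoisotopic values are the masses of the most
# abundant isotope (CODATA/AME); average values are IUPAC conventional
# standard atomic weights. Both in Da.

.monoisotopic <- c(
  H  = 1.0078250319,
  C  = 12,
  N  = 14.0030740052,
  O  = 15.9949146221,
  F  = 18.99840320,
  Na = 22.98976928,
  P  = 30.97376199,
  S  = 31.97207069,
  Cl = 34.96885268,
  K  = 38.96370649,
  Br = 78.9183376,
  I  = 126.9044719
)

.atomic_weight <- c(
  H  = 1.008,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  F  = 18.998403163,
  Na = 22.98976928,
  P  = 30.973761998,
  S  = 32.06,
  Cl = 35.45,
  K  = 39.0983,
  Br = 79.904,
  I  = 126.90447
)

# Singly-charged adduct mass offsets, electron mass included:
# proton 1.00728 Da, sodium cation 22.98922 Da.
.ion_offsets <- c("M+H" = 1.00728, "M-H" = -1.00728, "M+Na" = 22.98922,
                  "neutral" = 0)
.ion_charges <- c("M+H" = 1L, "M-H" = -1L, "M+Na" = 1L, "neutral" = 0L)

#' Gas constant in J/(mol K)
#' @keywords internal
.RGAS <- 8.314
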