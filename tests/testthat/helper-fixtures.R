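# Shared fixtures: default instrument, the reference medium used by the
# displacement tables, and small utilities used across test files.

INST <- fd_instrument() # 100 MHz, n = 1.4
MED_REF <- ds_medium(0.010, 1.0)

RHO_SHORT_LONG <- c(25, 25, 37, 37) # LINR / TRAP / DRCT distances
RHO_ALIN <- c(20, 30, 32, 42)

# A reflectance set with prescribed complex values at prescribed distances
# (e.g. data synthesized from an idealized or inversion-side model).
set_from_values <- function(R, rho, inst = INST) {
  arr <- ds_arrangement("LINR")
  set <- reflectance_set(arr, MED_REF, inst)
  set$R[] <- R
  set$rho[] <- rho
  set
}

# Multiply the four pairs (1A, 2B, 1B, 2A) by per-optode complex coupling
# factors: sources s1, s2 and detectors dA, dB.
apply_coupling <- function(set, s1, s2, dA, dB) {
  set$R <- set$R * c(s1 * dA, s2 * dB, s1 * dB, s2 * dA)
  set
}

# Relative error (%) of a recovery against the true medium.
rec_error_pct <- function(fit, medium) {
  c(mua = 100 * (fit$mua - medium$mua) / medium$mua,
    musp = 100 * (fit$musp - medium$musp) / medium$musp)
}
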