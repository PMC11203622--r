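# One-exciton propagation utilities shared by the linear and 2D-IR engines.
# All propagation is done in a rotating frame at `omega_ref` (cm^-1) so that
# the phase per step stays far from the Nyquist limit at typical frame
# spacings.

# per-frame step propagators exp(-i (H - omega_ref) * 2*pi*c * dt)
frame_propagators <- function(hs, omega_ref, dt_ps = hs$dt_ps) {
  nf <- dim(hs$hamiltonians)[3]
  rate <- 2 * pi * C_CMPS * dt_ps
  lapply(seq_len(nf), function(f) {
    h <- hs$hamiltonians[, , f]
    e <- eigen(h, symmetric = TRUE)
    ph <- exp(-1i * rate * (e$values - omega_ref))
    e$vectors %*% (ph * t(e$vectors))
  })
}

# frame index for absolute step `k` (0-based), recycling the trajectory
# periodically when the propagation window outruns it
frame_at <- function(k, nf) ((k) %% nf) + 1L

# unitarity defect of a propagator (max |U U^H - I|); used by tests and
# invariant checks
unitarity_defect <- function(u) {
  max(abs(u %*% Conj(t(u)) - diag(nrow(u))))
}
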