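# Shared fixtures, built in code.

relay_spec <- relay_helix_peptide()

# a random symmetric amide I-like Hamiltonian with dipoles
random_exciton <- function(n = 36, seed = 1, spread = 8, coupling_sd = 3) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * n, sd = coupling_sd), n)
    m <- (m + t(m)) / 2
    diag(m) <- 1650 + rnorm(n, sd = spread)
    mu <- matrix(rnorm(n * 3, sd = 0.2), n)
    hamiltonian_series(m, mu, dt_ps = 0.01)
  })
}

# analytic lifetime-broadened stick spectrum: the exact Fourier transform of
# sum_n mu_n^2 exp(-i w_n t - t/2T), evaluated on `grid`
broadened_sticks <- function(sticks, grid, lifetime_ps) {
  gamma <- 1 / (2 * lifetime_ps) # ps^-1
  sapply(grid, function(w) {
    a <- 2 * pi * 2.99792458e-2 * (w - sticks$energy) # rad/ps
    sum(sticks$intensity * gamma / (gamma^2 + a^2))
  })
}

# O...H i -> i+4 distances of one frame
frame_oh <- function(traj, frame = 1) {
  hb <- hbond_series(traj)
  hb[hb$frame == frame, ]
}
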