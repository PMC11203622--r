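test_that("a single static oscillator gives the analytic Lorentzian", {
  h <- hamiltonian_series(matrix(1650), matrix(c(0.37, 0, 0), 1), dt_ps = 0.01)
  s <- linear_spectrum_td(h, lifetime_ps = 1, grid = seq(1620, 1680, 0.05))
  expect_equal(s$frequency[which.max(s$intensity)], 1650, tolerance = 0.06)
  # interpolated half-maximum width against 1/(4 pi c T)
  half <- max(s$intensity) / 2
  xs <- s$frequency
  ys <- s$intensity
  left <- approx(ys[xs < 1650], xs[xs < 1650], xout = half)$y
  right <- approx(ys[xs > 1650], xs[xs > 1650], xout = half)$y
  hwhm_theory <- 1 / (4 * pi * 2.99792458e10 * 1e-12) # cm^-1 for T = 1 ps
  expect_equal((right - left) / 2, hwhm_theory, tolerance = 0.01)
})

test_that("a degenerate parallel-dipole dimer is one line shifted by J", {
  j <- 6
  st <- stick_spectrum(matrix(c(1650, j, j, 1650), 2),
                       dipoles = rbind(c(0.4, 0, 0), c(0.4, 0, 0)))
  expect_equal(st$energy, c(1650 - j, 1650 + j))
  expect_equal(st$intensity, c(0, 2 * 0.4^2), tolerance = 1e-12)
  h <- hamiltonian_series(matrix(c(1650, j, j, 1650), 2),
                          rbind(c(0.4, 0, 0), c(0.4, 0, 0)), dt_ps = 0.01)
  s <- linear_spectrum_td(h, grid = seq(1600, 1700, 0.25))
  expect_equal(s$frequency[which.max(s$intensity)], 1650 + j, tolerance = 0.3)
})

test_that("time-domain and stick routes agree for static Hamiltonians", {
  hs <- random_exciton(seed = 3)
  grid <- seq(1550, 1750, 0.5)
  s <- linear_spectrum_td(hs, lifetime_ps = 1, grid = grid)
  st <- stick_spectrum(hs)
  oracle <- broadened_sticks(st, grid, 1)
  scale <- sum(s$intensity) / sum(oracle)
  expect_lt(max(abs(s$intensity - oracle * scale)) / max(oracle * scale), 1e-3)
})

test_that("dipole strength is conserved under diagonalization", {
  for (seed in 1:5) {
    hs <- random_exciton(seed = seed)
    st <- stick_spectrum(hs)
    site_sum <- sum(hs$dipoles[, , 1]^2)
    expect_equal(sum(st$intensity), site_sum, tolerance = 1e-9)
  }
})

test_that("IPR spans [1, N] with the defining limits", {
  expect_equal(ipr(c(1, rep(0, 35))), 1)
  expect_equal(ipr(rep(1 / 6, 36)), 36)
  phi4 <- rep(0, 36); phi4[c(2, 9, 17, 30)] <- 1 / 2
  expect_equal(ipr(phi4), 4)
  # property: all eigenvectors of random Hamiltonians stay in bounds,
  # normalized to 1e-12
  hs <- random_exciton(seed = 7)
  e <- eigen(hs$hamiltonians[, , 1], symmetric = TRUE)
  for (m in 1:36) {
    expect_equal(sum(e$vectors[, m]^2), 1, tolerance = 1e-12)
    v <- ipr(e$vectors[, m])
    expect_gte(v, 1)
    expect_lte(v, 36)
  }
})

test_that("eigenmode binning conserves the density of states", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, 4, noise_nm = 0.003, seed = 2)
  hs <- build_hamiltonian_series(traj)
  es <- eigen_summary(hs, bins = seq(1550, 1750, 2))
  expect_equal(sum(es$by_bin$dos), 36, tolerance = 1e-12)
  ok <- !is.na(es$by_bin$ipr)
  expect_true(all(es$by_bin$ipr[ok] >= 1 & es$by_bin$ipr[ok] <= 36))
  expect_equal(dim(es$site_components), c(36, 100))
})

test_that("second derivatives locate band centres as minima", {
  grid <- seq(1600, 1700, 0.25)
  one <- new_spectrum1d(grid, 5 * exp(-(grid - 1654)^2 / (2 * 8^2)))
  d2 <- second_derivative(one, window = 15, polyorder = 3)
  expect_equal(grid[which.min(d2$intensity)], 1654, tolerance = 0.25)

  # two Gaussians 1.5 widths apart: the filter must match the analytic second
  # derivative of the sum, including the positions of its local minima
  g2 <- function(x, c0, s0) {
    ((x - c0)^2 / s0^4 - 1 / s0^2) * exp(-(x - c0)^2 / (2 * s0^2))
  }
  two <- new_spectrum1d(grid, exp(-(grid - 1650)^2 / (2 * 8^2)) +
                          exp(-(grid - 1662)^2 / (2 * 8^2)))
  d2b <- second_derivative(two, window = 15, polyorder = 3)
  analytic <- g2(grid, 1650, 8) + g2(grid, 1662, 8)
  interior <- seq(20, length(grid) - 20)
  expect_lt(max(abs(d2b$intensity[interior] - analytic[interior])), 1e-4)
  find_min <- function(y) {
    idx <- which(y < dplyr::lag(y, default = Inf) &
                   y < dplyr::lead(y, default = Inf) & y < 0)
    idx[idx %in% interior]
  }
  expect_equal(length(find_min(analytic)), 2)
  expect_equal(grid[find_min(d2b$intensity)], grid[find_min(analytic)],
               tolerance = 0.3)

  flat <- new_spectrum1d(grid, rep(3, length(grid)))
  expect_lt(max(abs(second_derivative(flat)$intensity)), 1e-10)
  expect_error(second_derivative(one, window = 10), "odd")
  expect_error(second_derivative(one, window = 1001), "larger")
})

test_that("band ratios read constructed intensities back", {
  grid <- seq(1600, 1720, 0.2)
  spec <- new_spectrum1d(grid, 2.31 * exp(-(grid - 1654)^2 / (2 * 7^2)) +
                           1.0 * exp(-(grid - 1683)^2 / (2 * 6^2)))
  r <- band_ratio(spec, 1654, 1683)
  expect_equal(r, 2.31 / (1 + 2.31 * exp(-(1683 - 1654)^2 / (2 * 7^2))),
               tolerance = 0.01)
  expect_equal(band_ratio(spec, 1654, 1654), 1.0)
  zero <- new_spectrum1d(grid, rep(0, length(grid)))
  expect_error(band_ratio(zero, 1654, 1683), "zero denominator")
  expect_error(band_ratio(spec, 1500, 1683), "within")
})
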