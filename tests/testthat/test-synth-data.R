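test_that("noise- and switch-free trajectories replicate the base frame", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, n_frames = 5, noise_nm = 0, switch_prob = 0,
                          seed = 3)
  for (f in 1:5) {
    expect_identical(frame_coords(traj, f), frame_coords(helix, 1))
  }
})

test_that("trajectories are bit-reproducible from the seed", {
  helix <- make_ideal_helix(relay_spec)
  t1 <- make_trajectory(helix, 20, noise_nm = 0.01, switch_prob = 0.2,
                        seed = 42, switch_pairs = list(c(22, 26)))
  t2 <- make_trajectory(helix, 20, noise_nm = 0.01, switch_prob = 0.2,
                        seed = 42, switch_pairs = list(c(22, 26)))
  expect_identical(t1$xyz, t2$xyz)
  t3 <- make_trajectory(helix, 20, noise_nm = 0.01, switch_prob = 0.2,
                        seed = 43, switch_pairs = list(c(22, 26)))
  expect_false(identical(t1$xyz, t3$xyz))
})

test_that("hydrogen-bond switching follows the two-state Markov statistics", {
  helix <- make_ideal_helix(relay_spec)
  p <- 0.1
  n <- 10000
  traj <- make_trajectory(helix, n, noise_nm = 0, switch_prob = p, seed = 11,
                          switch_pairs = list(c(22, 26)))
  states <- attr(traj, "hbond_states")[, 1]
  # symmetric two-state chain: stationary broken fraction 1/2; variance of
  # the mean inflated by the chain autocorrelation rho = 1 - 2p
  rho <- 1 - 2 * p
  se <- sqrt(0.25 * (1 + rho) / (1 - rho) / n)
  expect_lt(abs(mean(states) - 0.5), 3 * se)
  # and the broken-state geometry actually breaks the bond
  f_broken <- which(states)[1]
  f_formed <- which(!states)[1]
  hb <- hbond_series(traj, pairs = 22)
  expect_gt(hb$distance_nm[hb$frame == f_broken], 0.35)
  expect_lt(hb$distance_nm[hb$frame == f_formed], 0.35)
})

test_that("trajectory generator validates its arguments", {
  helix <- make_ideal_helix(relay_spec)
  expect_error(make_trajectory(helix, 0, seed = 1), "n_frames")
  expect_error(make_trajectory(helix, 5, noise_nm = -1, seed = 1), "noise_nm")
  expect_error(make_trajectory(helix, 5, switch_prob = 2, seed = 1), "switch_prob")
})

test_that("synthetic 2D surfaces carry exact analytic lobe volumes", {
  ax <- seq(1600, 1720, 0.5)
  pk <- tibble::tibble(center_tau = 1660, center_m = 1660, width_tau = 6,
                       width_m = 5, amplitude = 7, tilt_deg = 0,
                       anharmonicity = 200) # negative lobe far off-grid
  s <- make_synthetic_2dir(pk, ax, ax)
  vol_exact <- 2 * pi * 7 * 6 * 5
  expect_equal(s$meta$components$volume[1], vol_exact, tolerance = 1e-9)
  # grid integral over the positive half-plane matches to < 1%
  num <- sum(s$intensity[s$intensity > 0]) * 0.5^2
  expect_equal(num, vol_exact, tolerance = 0.01)
})

test_that("two separated tilted peaks integrate to their stated volumes", {
  ax <- seq(1580, 1760, 0.5)
  pk <- tibble::tibble(
    center_tau = c(1630, 1700), center_m = c(1630, 1700),
    width_tau = c(6, 5), width_m = c(5, 4), amplitude = c(10, 4),
    tilt_deg = c(30, 30), anharmonicity = c(500, 500)
  )
  s <- make_synthetic_2dir(pk, ax, ax)
  mid_t <- s$omega_tau < 1665
  for (k in 1:2) {
    sel <- if (k == 1) mid_t else !mid_t
    num <- sum(pmax(s$intensity[sel, ], 0)) * 0.5^2
    truth <- s$meta$components$volume[s$meta$components$peak == k][1]
    expect_equal(num, truth, tolerance = 0.01)
  }
})

test_that("an empty peak list gives an all-zero surface", {
  ax <- seq(1600, 1700, 1)
  s <- make_synthetic_2dir(tibble::tibble(), ax, ax)
  expect_true(all(s$intensity == 0))
})

test_that("bi-exponential generator matches its closed form", {
  d <- make_biexp_decay(1, 1.38, 0.3, 0.2, c(0, 0.5, 1, 2), noise_sd = 0)
  expect_equal(d$signal[2], 1 * exp(-1.38 * 0.5) + 0.3 * exp(-0.2 * 0.5),
               tolerance = 1e-12)
  # A2 = 0: log-linear decay
  d1 <- make_biexp_decay(2, 0.7, 0, 1, seq(0.1, 5, 0.1))
  slopes <- diff(log(d1$signal)) / diff(d1$time_ps)
  expect_equal(max(abs(slopes + 0.7)), 0, tolerance = 1e-9)
  expect_identical(make_biexp_decay(1, 1, 0.1, 0.2, 0:10, 0.05, seed = 5),
                   make_biexp_decay(1, 1, 0.1, 0.2, 0:10, 0.05, seed = 5))
})

test_that("CD curves invert the Baldwin relation exactly", {
  # boundary cases: pure coil / pure helix recover the baselines
  tc <- c(10, 40, 70)
  coil <- make_cd_curve(tibble::tibble(temperature_c = tc, fh = 0), nr = 35)
  expect_equal(coil$theta_222, 2220 - 53 * tc, tolerance = 1e-12)
  full <- make_cd_curve(tibble::tibble(temperature_c = tc, fh = 1), nr = 35)
  expect_equal(full$theta_222, (-44000 + 250 * tc) * (1 - 3 / 35),
               tolerance = 1e-12)
  # round trip through helical_fraction
  curve <- make_cd_curve(tibble::tibble(temperature_c = 70, fh = 0.56), nr = 35)
  back <- helical_fraction(curve$theta_222, 70, 35)
  expect_equal(back$fh, 0.56, tolerance = 1e-12)
  expect_error(make_cd_curve(tibble::tibble(temperature_c = 1, fh = 1.2), 35),
               "\\[0, 1\\]")
})

test_that("double-well landscapes hit the requested energetics on a grid", {
  w <- make_double_well(3.36, 6, list(c(0.47, 0.34), c(0.48, 0.64)))
  gx <- seq(w$domain[1, 1], w$domain[2, 1], length.out = 241)
  gy <- seq(w$domain[1, 2], w$domain[2, 2], length.out = 241)
  z <- matrix(w$fn(as.matrix(expand.grid(gx, gy))), 241, 241)
  an <- fes_analyze(new_fes_grid(gx, gy, z - min(z)))
  expect_equal(nrow(an$minima), 2)
  expect_equal(an$minima$delta_kjmol[2], 3.36, tolerance = 0.01)
  # barrier via independent grid search: max-over-min on the straight path
  expect_equal(an$barriers$barrier_kjmol[1], 6, tolerance = 0.05)
})

test_that("symmetric double wells have equal depths", {
  w <- make_double_well(0, 5, list(c(0, 0), c(0.4, 0)))
  v <- w$fn(rbind(c(0, 0), c(0.4, 0)))
  expect_equal(v[1], v[2], tolerance = 1e-6)
  expect_equal(w$fn(rbind(c(0.2, 0))) - min(v), 5, tolerance = 1e-3)
})

test_that("malformed landscapes are rejected", {
  expect_error(make_double_well(4, 3, list(c(0, 0), c(0.4, 0))), "exceed")
  expect_error(make_double_well(0, 5, list(c(0, 0), c(0, 0))), "distinct")
})
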