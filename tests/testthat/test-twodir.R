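single_osc <- hamiltonian_series(matrix(1650), matrix(c(0.37, 0, 0), 1),
                                 dt_ps = 0.02)
gx <- seq(1600, 1700, 0.5)

test_that("a single anharmonic oscillator gives the three-level pattern", {
  r <- response_functions(single_osc, t_w = 0.2, t1_max = 2.5, t3_max = 2.5,
                          anharmonicity = 16)
  s <- absorptive(r, gx, gx)
  ipos <- which(s$intensity == max(s$intensity), arr.ind = TRUE)
  ineg <- which(s$intensity == min(s$intensity), arr.ind = TRUE)
  expect_equal(c(s$omega_tau[ipos[1]], s$omega_m[ipos[2]]), c(1650, 1650))
  expect_equal(c(s$omega_tau[ineg[1]], s$omega_m[ineg[2]]), c(1650, 1634))
  # harmonic dipole scaling: the two lobes carry equal integrated magnitude
  pos <- sum(s$intensity[s$intensity > 0])
  neg <- -sum(s$intensity[s$intensity < 0])
  expect_equal(pos, neg, tolerance = 0.02)
  # the absorptive fundamental lineshape is symmetric about the diagonal
  # through (w0, w0); isolate it by pushing the overtone lobe off-window
  s_iso <- absorptive(response_functions(single_osc, t_w = 0.2, t1_max = 2.5,
                                         t3_max = 2.5, anharmonicity = 300),
                      gx, gx)
  iw <- which(abs(s_iso$omega_tau - 1650) <= 8)
  block <- s_iso$intensity[iw, iw]
  expect_lt(max(abs(block - t(block))) / max(abs(block)), 0.01)
})

test_that("the harmonic limit cancels exactly", {
  r <- response_functions(single_osc, t_w = 0.2, t1_max = 2, t3_max = 2,
                          anharmonicity = 0)
  s <- absorptive(r, gx, gx)
  ref <- absorptive(response_functions(single_osc, t_w = 0.2, t1_max = 2,
                                       t3_max = 2, anharmonicity = 16), gx, gx)
  expect_lt(max(abs(s$intensity)), 1e-10 * max(abs(ref$intensity)))
})

test_that("uncoupled oscillators factorize: no cross-peak pathways", {
  mk <- function(h, mu) hamiltonian_series(h, mu, dt_ps = 0.02)
  args <- list(t_w = 0, t1_max = 2, t3_max = 2, anharmonicity = 16)
  sA <- absorptive(do.call(response_functions,
                           c(list(mk(matrix(1640), matrix(c(0.37, 0, 0), 1))), args)),
                   gx, gx)
  sB <- absorptive(do.call(response_functions,
                           c(list(mk(matrix(1670), matrix(c(0.37, 0, 0), 1))), args)),
                   gx, gx)
  sAB <- absorptive(do.call(response_functions,
                            c(list(mk(diag(c(1640, 1670)),
                                      rbind(c(0.37, 0, 0), c(0.37, 0, 0)))), args)),
                    gx, gx)
  expect_lt(max(abs(sAB$intensity - sA$intensity - sB$intensity)),
            1e-10 * max(abs(sAB$intensity)))
})

test_that("a coupled dimer shows cross-peaks at eigenfrequency pairs", {
  hj <- matrix(c(1645, 8, 8, 1665), 2)
  ev <- eigen(hj, symmetric = TRUE)$values
  h <- hamiltonian_series(hj, rbind(c(0.37, 0, 0), c(0, 0.37, 0)), dt_ps = 0.02)
  s <- absorptive(response_functions(h, t_w = 0, t1_max = 2, t3_max = 2,
                                     anharmonicity = 16), gx, gx)
  ia <- which.min(abs(s$omega_tau - min(ev)))
  ib <- which.min(abs(s$omega_m - max(ev)))
  expect_gt(abs(s$intensity[ia, ib]), 0.05 * max(abs(s$intensity)))
})

test_that("one-exciton propagators are unitary to 1e-9 per step", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, 5, noise_nm = 0.005, seed = 6)
  hs <- build_hamiltonian_series(traj)
  for (u in helixspec:::frame_propagators(hs, 1650)) {
    expect_lt(helixspec:::unitarity_defect(u), 1e-9)
  }
})

test_that("static-Hamiltonian signals decay monotonically with wait time", {
  mags <- vapply(c(0.2, 0.5, 1, 2, 4), function(tw) {
    s <- absorptive(response_functions(single_osc, t_w = tw, t1_max = 1.5,
                                       t3_max = 1.5, anharmonicity = 16), gx, gx)
    max(abs(s$intensity))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("wait-time sweeps record their wait times and handle empty lists", {
  out <- sweep_waittimes(single_osc, list(0.2, 0.5), omega_tau = gx,
                         omega_m = gx, t1_max = 1, t3_max = 1,
                         anharmonicity = 16)
  expect_length(out, 2)
  expect_equal(vapply(out, function(s) s$t_w, numeric(1)),
               c(`0.2` = 0.2, `0.5` = 0.5))
  expect_length(sweep_waittimes(single_osc, list(), t1_max = 1, t3_max = 1), 0)
})

test_that("too-short trajectories are refused when recycling is disabled", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, 10, noise_nm = 0.002, seed = 3)
  hs <- build_hamiltonian_series(traj)
  expect_error(
    response_functions(hs, t_w = 1, t1_max = 2, t3_max = 2, recycle = FALSE),
    "shorter"
  )
  expect_error(response_functions(single_osc, anharmonicity = -1), ">= 0")
})
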