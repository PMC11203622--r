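test_that("hydrogen-bond classification matches the geometry and cutoff", {
  ideal <- make_ideal_helix(relay_spec)
  hb <- hbond_series(ideal)
  expect_true(all(hb$formed))
  bent <- make_bent_helix(relay_spec, list(c(22, 26), c(23, 27)))
  hbb <- hbond_series(bent)
  expect_setequal(hbb$acceptor[!hbb$formed], c(22, 23))
  # an effectively infinite cutoff classifies nothing as broken
  expect_true(all(hbond_series(bent, cutoff_nm = 1e6)$formed))
})

test_that("hbond_series is a pure per-frame function", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, 6, noise_nm = 0.01, seed = 14)
  rev_traj <- traj
  rev_traj$xyz <- traj$xyz[, , 6:1]
  a <- hbond_series(traj)
  b <- hbond_series(rev_traj)
  for (f in 1:6) {
    expect_equal(a$distance_nm[a$frame == f], b$distance_nm[b$frame == 7 - f])
  }
})

test_that("rank-one rigid motion loads entirely on the first component", {
  helix <- make_ideal_helix(relay_spec)
  base <- frame_coords(helix)
  xyz <- array(0, dim = c(nrow(base), 3, 10))
  for (f in 1:10) xyz[, , f] <- base + cbind(0.01 * f, 0, 0)[rep(1, nrow(base)), ]
  traj <- new_trajectory(xyz, helix$atoms)
  p <- pca_trajectory(traj, align = FALSE)
  expect_gt(p$eigenvalues[1] / sum(p$eigenvalues), 0.999)
})

test_that("PCA eigenvectors are orthonormal and variance is conserved", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, 25, noise_nm = 0.01, seed = 5)
  p <- pca_trajectory(traj)
  v <- p$eigenvectors
  expect_lt(max(abs(crossprod(v) - diag(ncol(v)))), 1e-10)
  x <- helixspec:::traj_flat(traj, p$atom_rows)
  # total variance equals the covariance trace of the aligned coordinates
  expect_equal(sum(p$eigenvalues), sum(apply(p$projections, 2, stats::var)),
               tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
})

test_that("isotropic noise eigenvalues stay near the Marchenko-Pastur band", {
  helix <- make_ideal_helix(peptide_spec(strrep("A", 8)))
  sigma <- 0.01
  n <- 400
  traj <- make_trajectory(helix, n, noise_nm = sigma, seed = 9)
  p <- pca_trajectory(traj, align = FALSE)
  d <- length(p$eigenvalues)
  edge <- sigma^2 * (1 + sqrt(d / n))^2
  expect_lt(p$eigenvalues[1], 1.2 * edge)
  expect_gt(p$eigenvalues[1], sigma^2)
})

test_that("pseudo-trajectories span the projection extrema", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, 20, noise_nm = 0.008, seed = 12)
  p <- pca_trajectory(traj)
  ps <- pseudo_trajectory(p, component = 1, n_frames = 2)
  ex_min <- matrix(p$mean + min(p$projections[, 1]) * p$eigenvectors[, 1],
                   ncol = 3, byrow = TRUE)
  expect_equal(frame_coords(ps, 1), ex_min, tolerance = 1e-12)
  # midpoint frame equals the mean structure for symmetric projections
  p_sym <- p
  p_sym$projections[, 1] <- c(-1, 1, rep(0, nrow(p$projections) - 2))
  mid <- pseudo_trajectory(p_sym, 1, n_frames = 3)
  expect_equal(frame_coords(mid, 2),
               matrix(p$mean, ncol = 3, byrow = TRUE), tolerance = 1e-12)
  expect_error(pseudo_trajectory(p, component = 10000), "rank")
})

test_that("identical frames yield a flagged degenerate PCA", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, 5, noise_nm = 0, seed = 1)
  expect_warning(p <- pca_trajectory(traj), "identical frames")
  expect_true(p$degenerate)
  expect_equal(sum(p$eigenvalues), 0)
})

test_that("a constructed bend motion is recovered by its pseudo-trajectory", {
  ideal <- make_ideal_helix(relay_spec)
  bent <- make_bent_helix(relay_spec, list(c(22, 26)))
  # interpolate linearly between straight and bent conformers
  nfr <- 11
  na <- nrow(ideal$atoms)
  xyz <- array(0, dim = c(na, 3, nfr))
  for (f in seq_len(nfr)) {
    lam <- (f - 1) / (nfr - 1)
    xyz[, , f] <- (1 - lam) * frame_coords(ideal) + lam * frame_coords(bent)
  }
  traj <- new_trajectory(xyz, ideal$atoms)
  p <- pca_trajectory(traj, align = FALSE)
  expect_gt(p$eigenvalues[1] / sum(p$eigenvalues), 0.999)
  ps <- pseudo_trajectory(p, 1, n_frames = 2)
  # end-to-end bend angle range of the pseudo-trajectory matches construction
  bend_angle <- function(coords, atoms) {
    ca <- coords[atoms$atom == "CA", ]
    a <- ca[8, ] - ca[1, ]
    b <- ca[35, ] - ca[28, ]
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  }
  ang_true <- c(bend_angle(frame_coords(ideal), ideal$atoms),
                bend_angle(frame_coords(bent), bent$atoms))
  sel_atoms <- p$atoms
  ang_ps <- c(bend_angle(frame_coords(ps, 1), sel_atoms),
              bend_angle(frame_coords(ps, 2), sel_atoms))
  expect_equal(diff(range(ang_ps)), diff(range(ang_true)),
               tolerance = 0.05 * diff(range(ang_true)))
})

test_that("well-tempered metadynamics recovers a known free-energy gap", {
  w <- make_double_well(3.36, 6, list(c(0.47, 0.34), c(0.48, 0.64)))
  fes <- wtmetad(w, steps = 300000, seed = 7)
  an <- fes_analyze(fes)
  expect_gte(nrow(an$minima), 2)
  expect_equal(an$minima$delta_kjmol[2], 3.36, tolerance = 0.5)
})

test_that("metadynamics recovers harmonic curvature", {
  kw <- 300 # kJ/mol/nm^2
  well <- list(
    fn = function(p) 0.5 * kw * ((p[, 1] - 0.5)^2 + (p[, 2] - 0.5)^2),
    grad = function(p) kw * cbind(p[, 1] - 0.5, p[, 2] - 0.5),
    domain = rbind(c(0.2, 0.2), c(0.8, 0.8)),
    centers = list(c(0.5, 0.5))
  )
  fes <- wtmetad(well, steps = 200000, seed = 3)
  # quadratic fit of the recovered FES along x through the centre
  iy <- which.min(abs(fes$d2 - 0.5))
  sel <- abs(fes$d1 - 0.5) < 0.12
  fitq <- stats::lm(fes$free_energy[sel, iy] ~ I((fes$d1[sel] - 0.5)^2))
  expect_equal(unname(stats::coef(fitq)[2]), kw / 2, tolerance = 0.1 * kw / 2)
})

test_that("runs shorter than one pace leave a flagged flat surface", {
  w <- make_double_well(2, 5, list(c(0.3, 0.3), c(0.6, 0.6)))
  expect_warning(fes <- wtmetad(w, steps = 100, pace = 500, seed = 1),
                 "no hills")
  expect_true(all(fes$free_energy == 0))
})

test_that("FES analysis converts to kT exactly and finds barriers on grids", {
  kt <- helixspec:::R_KJMOL * 298.15
  expect_equal(round(free_energy_in_kt(4.67), 1), 1.9)
  expect_equal(round(free_energy_in_kt(3.36), 1), 1.4)
  expect_equal(free_energy_in_kt(4.67) * kt, 4.67, tolerance = 1e-12)
  # flat grid: no minima
  flat <- new_fes_grid(seq(0, 1, 0.1), seq(0, 1, 0.1), matrix(1, 11, 11))
  expect_equal(nrow(fes_analyze(flat)$minima), 0)
  # constructed two-minimum surface with a 5 kJ/mol saddle
  w <- make_double_well(2, 5, list(c(0.3, 0.5), c(0.7, 0.5)))
  gx <- seq(0.05, 0.95, 0.005)
  z <- matrix(w$fn(as.matrix(expand.grid(gx, gx))), length(gx))
  an <- fes_analyze(new_fes_grid(gx, gx, z - min(z)))
  expect_equal(an$barriers$barrier_kjmol[1], 5, tolerance = 0.05)
})
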