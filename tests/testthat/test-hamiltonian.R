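test_that("oscillator enumeration matches the carbonyl-counting rule", {
  expect_equal(nrow(enumerate_oscillators(relay_spec)), 36)
  expect_equal(nrow(enumerate_oscillators(
    peptide_spec("GA", n_terminal_cap = "none"))), 2)
  expect_equal(nrow(enumerate_oscillators(
    peptide_spec(strrep("A", 10)))), 11)
  # cross-check: carbonyl oxygens present in the built coordinates
  helix <- make_ideal_helix(relay_spec)
  expect_equal(sum(helix$atoms$atom == "O"), 36)
})

test_that("site frequencies reduce to the base frequency without charges", {
  helix <- make_ideal_helix(relay_spec)
  chromo <- enumerate_oscillators(relay_spec)
  freq <- site_frequencies(frame_coords(helix), helix, chromo, site_map())
  expect_equal(freq, rep(1650, 36), tolerance = 1e-12)
})

test_that("the electrostatic map is linear and matches brute force", {
  helix <- make_ideal_helix(relay_spec)
  chromo <- enumerate_oscillators(relay_spec)
  coords <- frame_coords(helix)
  q <- tibble::tibble(x = 1, y = 0.5, z = 0.2, q = 0.5)
  m1 <- site_map(point_charges = q)
  f1 <- site_frequencies(coords, helix, chromo, m1)
  # doubling the charge doubles the shift
  m2 <- site_map(point_charges = dplyr::mutate(q, q = 1))
  f2 <- site_frequencies(coords, helix, chromo, m2)
  expect_equal(f2 - 1650, 2 * (f1 - 1650), tolerance = 1e-10)
  # brute-force evaluation of the documented formula for site 5
  geo <- helixspec:::chromophore_geometry(coords, helix, chromo, m1)
  pot <- function(p) 0.5 / sqrt(sum((p - c(1, 0.5, 0.2))^2))
  shift5 <- m1$potential_coefficient * (pot(geo$opos[5, ]) - pot(geo$cpos[5, ]))
  expect_equal(f1[5] - 1650, shift5, tolerance = 1e-10)
})

test_that("couplings use the vacuum TDC constant and decay as 1/r^3", {
  # the prefactor, rederived from SI constants independently of the package
  debye <- 3.33564e-30
  k_oracle <- debye^2 / (1.112650056e-10 * 1e-30) / 1.98644586e-23
  expect_equal(helixspec:::TDC_PREFACTOR_CM_A3_D2, k_oracle, tolerance = 1e-6)

  helix <- make_ideal_helix(relay_spec)
  chromo <- enumerate_oscillators(relay_spec)
  coords <- frame_coords(helix)
  map <- site_map()
  j <- couplings(coords, helix, chromo, map)
  expect_equal(j, t(j), tolerance = 1e-12)
  expect_true(all(diag(j) == 0))
  expect_true(all(j[cbind(1:35, 2:36)] == map$nn_coupling))
  # brute-force one non-adjacent pair from the geometry
  geo <- helixspec:::chromophore_geometry(coords, helix, chromo, map)
  a <- 3; b <- 9
  rv <- geo$pos[b, ] - geo$pos[a, ]
  r <- sqrt(sum(rv^2)); rh <- rv / r
  orient <- sum(geo$dir[a, ] * geo$dir[b, ]) -
    3 * sum(geo$dir[a, ] * rh) * sum(geo$dir[b, ] * rh)
  expect_equal(j[a, b], k_oracle * orient * 0.37^2 / (10 * r)^3,
               tolerance = 1e-9)
  # 1/r^3 decay along the chain for same-phase pairs
  js <- abs(j[cbind(1:20, 1:20 + 7)])
  expect_true(all(diff(js) < 1e-9 | js[-1] < 1e-6))
})

test_that("coupling symmetry holds on noisy geometries", {
  helix <- make_ideal_helix(relay_spec)
  traj <- make_trajectory(helix, 5, noise_nm = 0.01, seed = 8)
  chromo <- enumerate_oscillators(relay_spec)
  for (f in 1:5) {
    j <- couplings(frame_coords(traj, f), traj, chromo, site_map())
    expect_lt(max(abs(j - t(j))), 1e-12)
  }
})

test_that("hamiltonian series are symmetric, deterministic and frame-wise", {
  helix <- make_ideal_helix(relay_spec)
  hs <- build_hamiltonian_series(helix)
  expect_equal(dim(hs$hamiltonians), c(36, 36, 1))
  h <- hs$hamiltonians[, , 1]
  expect_lt(max(abs(h - t(h))), 1e-9)
  # repeated identical frames give identical matrices
  traj <- make_trajectory(helix, 3, noise_nm = 0, seed = 1)
  hs3 <- build_hamiltonian_series(traj)
  expect_identical(hs3$hamiltonians[, , 1], hs3$hamiltonians[, , 3])
})

test_that("a local break perturbs couplings mostly near the break", {
  ideal <- make_ideal_helix(relay_spec)
  bent <- make_bent_helix(relay_spec, list(c(22, 26)))
  hi <- build_hamiltonian_series(ideal)$hamiltonians[, , 1]
  hb <- build_hamiltonian_series(bent)$hamiltonians[, , 1]
  dmat <- abs(hi - hb)
  big <- which(dmat > 0.5, arr.ind = TRUE)
  # chromophore indices are resno + 1 (acetyl first); the hinge sits at
  # residues 22-26, so large changes must touch that neighbourhood
  expect_true(all(big[, 1] >= 20 | big[, 2] >= 20))
  # sites far upstream of the break are untouched at the 1e-6 level
  expect_lt(max(dmat[1:15, 1:15]), 1e-6)
})

test_that("coincident chromophores raise a geometry error", {
  helix <- make_ideal_helix(peptide_spec("AAAAAA"))
  squashed <- helix
  squashed$xyz[, , 1] <- squashed$xyz[, , 1] * 1e-3
  chromo <- enumerate_oscillators(squashed$spec)
  expect_error(
    couplings(frame_coords(squashed), squashed, chromo, site_map()),
    "0.05 nm"
  )
})
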