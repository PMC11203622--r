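#' Linear amide I spectrum by time-domain propagation
#'
#' Computes `I(w) = Re Int dt e^{-iwt} sum_nm sum_j mu_n^j(0) F_nm(t)
#' mu_m^j(t) e^{-t/2T}`, where `F(t)` is the time-ordered one-exciton
#' propagator built from per-frame matrix exponentials over the stored frame
#' spacing, and the `j` sum runs over the three lab axes. The trajectory is
#' recycled periodically if the propagation window outruns it, and the
#' correlation function is averaged over `n_starts` evenly spaced start
#' frames.
#'
#' @param hs A `hamiltonian_series`.
#' @param lifetime_ps Amide I lifetime `T` (> 0); default 1 ps.
#' @param grid Frequency axis for the output (cm^-1).
#' @param t_max_ps Length of the propagated correlation function (ps).
#' @param apodization `"none"` (default) or `"cos"` (half-cosine window).
#' @param n_starts Number of trajectory start frames averaged over.
#'
#' @return A [new_spectrum1d()] with metadata `lifetime_ps`.
#' @examples
#' h <- hamiltonian_series(matrix(1650), matrix(c(1, 0, 0), 1), dt_ps = 0.01)
#' s <- linear_spectrum_td(h, lifetime_ps = 1)
#' @export
linear_spectrum_td <- function(hs, lifetime_ps = 1,
                               grid = seq(1500, 1800, 0.5),
                               t_max_ps = 16, apodization = c("none", "cos"),
                               n_starts = 1L) {
  apodization <- match.arg(apodization)
  if (lifetime_ps <= 0) abort("`lifetime_ps` must be > 0")
  dt <- hs$dt_ps
  if (dt > 0.05) {
    warn("frame spacing above 0.05 ps; propagation may be inaccurate")
  }
  nf <- dim(hs$hamiltonians)[3]
  n_t <- ceiling(t_max_ps / dt) + 1L
  omega_ref <- mean(apply(hs$hamiltonians, 3, function(m) mean(diag(m))))
  props <- frame_propagators(hs, omega_ref)

  starts <- unique(floor(seq(0, max(0, nf - 1), length.out = n_starts)))
  ct <- complex(length.out = n_t)
  for (s0 in starts) {
    psi <- hs$dipoles[, , frame_at(s0, nf), drop = TRUE]
    psi <- matrix(as.complex(psi), nrow = dim(hs$dipoles)[1])
    mu0_frame <- frame_at(s0, nf)
    for (k in seq_len(n_t)) {
      f <- frame_at(s0 + k - 1L, nf)
      mu_t <- matrix(hs$dipoles[, , f], ncol = 3L)
      ct[k] <- ct[k] + sum(mu_t * psi)
      psi <- props[[frame_at(s0 + k - 1L, nf)]] %*% psi
    }
  }
  ct <- ct / length(starts)

  t_ps <- (seq_len(n_t) - 1) * dt
  damp <- exp(-t_ps / (2 * lifetime_ps))
  w <- rep(1, n_t)
  w[1] <- 0.5
  if (apodization == "cos") w <- w * cos(pi * t_ps / (2 * max(t_ps)))
  # direct half-sided Fourier transform onto the requested grid
  phase <- 2 * pi * C_CMPS * outer(grid - omega_ref, t_ps)
  intensity <- as.numeric(Re(exp(1i * phase) %*% (ct * damp * w))) * dt
  new_spectrum1d(grid, intensity,
                 meta = list(lifetime_ps = lifetime_ps, source = "nise",
                             omega_ref = omega_ref))
}

#' Stick spectrum of a single Hamiltonian frame
#'
#' Diagonalizes one exciton Hamiltonian and returns eigenstate energies with
#' squared eigen-basis transition dipoles. The summed dipole strength equals
#' the site-basis sum exactly (orthogonal transform).
#'
#' @param hs A `hamiltonian_series` (or a plain symmetric matrix).
#' @param frame Frame index when `hs` is a series.
#' @param dipoles `N x 3` site dipoles, required when `hs` is a matrix.
#' @return Tibble with columns `energy` (cm^-1) and `intensity` (D^2),
#'   ascending in energy.
#' @examples
#' stick_spectrum(hamiltonian_series(diag(c(1640, 1660)),
#'                                   rbind(c(1, 0, 0), c(1, 0, 0))))
#' @export
stick_spectrum <- function(hs, frame = 1L, dipoles = NULL) {
  if (inherits(hs, "hamiltonian_series")) {
    h <- hs$hamiltonians[, , frame]
    mu <- matrix(hs$dipoles[, , frame], ncol = 3L)
  } else {
    h <- hs
    if (is.null(dipoles)) abort("`dipoles` required with a plain matrix")
    mu <- matrix(dipoles, ncol = 3L)
  }
  if (max(abs(h - t(h))) > 1e-9) abort("Hamiltonian must be symmetric")
  e <- eigen(h, symmetric = TRUE)
  mu_eig <- t(e$vectors) %*% mu
  tibble(
    energy = rev(e$values),
    intensity = rev(rowSums(mu_eig^2))
  ) |> arrange(.data$energy)
}

#' Inverse participation ratio of one eigenmode
#'
#' `IPR = 1 / sum_n phi_n^4` for a normalized eigenvector: 1 when the
#' excitation is localized on a single oscillator, N when spread uniformly
#' over all N oscillators.
#'
#' @param phi Eigenvector (normalized to unit length; renormalized if not).
#' @return The IPR, in `[1, length(phi)]`.
#' @examples
#' ipr(rep(1 / 6, 36)) # 36
#' @export
ipr <- function(phi) {
  phi <- phi / sqrt(sum(phi^2))
  1 / sum(phi^4)
}

#' Frequency-binned eigenmode diagnostics
#'
#' Diagonalizes every frame of a Hamiltonian series, bins the eigenmodes by
#' frequency, and accumulates per-bin time-averaged inverse participation
#' ratios, oscillator strengths, densities of states and mean squared site
#' components. The per-frame DOS sums to the oscillator count N.
#'
#' @param hs A `hamiltonian_series`.
#' @param bins Increasing bin-edge vector (cm^-1).
#' @return An object of class `eigen_summary`: `$by_bin` tibble
#'   (`bin_center`, `dos`, `ipr`, `mu2`, `n_modes`) and `$site_components`
#'   (`n_sites x n_bins` matrix of mean squared components).
#' @examples
#' h <- build_hamiltonian_series(make_ideal_helix(relay_helix_peptide()))
#' eigen_summary(h, seq(1600, 1700, 5))
#' @export
eigen_summary <- function(hs, bins = seq(1550, 1750, 2)) {
  if (any(diff(bins) <= 0)) abort("bin edges must be increasing")
  nf <- dim(hs$hamiltonians)[3]
  n <- dim(hs$hamiltonians)[1]
  nb <- length(bins) - 1L
  dos <- ipr_sum <- mu2 <- counts <- numeric(nb)
  site_comp <- matrix(0, n, nb)
  for (f in seq_len(nf)) {
    e <- eigen(hs$hamiltonians[, , f], symmetric = TRUE)
    mu_eig <- t(e$vectors) %*% matrix(hs$dipoles[, , f], ncol = 3L)
    strengths <- rowSums(mu_eig^2)
    for (m in seq_len(n)) {
      b <- findInterval(e$values[m], bins, rightmost.closed = TRUE)
      if (b < 1L || b > nb) next
      phi <- e$vectors[, m]
      dos[b] <- dos[b] + 1
      ipr_sum[b] <- ipr_sum[b] + 1 / sum(phi^4)
      mu2[b] <- mu2[b] + strengths[m]
      counts[b] <- counts[b] + 1
      site_comp[, b] <- site_comp[, b] + phi^2
    }
  }
  by_bin <- tibble(
    bin_center = (bins[-1] + bins[-length(bins)]) / 2,
    dos = dos / nf,
    ipr = ifelse(counts > 0, ipr_sum / pmax(counts, 1), NA_real_),
    mu2 = mu2 / nf,
    n_modes = counts
  )
  site_comp <- sweep(site_comp, 2, pmax(counts, 1), "/")
  structure(
    list(by_bin = by_bin, site_components = site_comp, n_sites = n,
         n_frames = nf, bins = bins),
    class = "eigen_summary"
  )
}

#' @export
print.eigen_summary <- function(x, ...) {
  cat("<eigen_summary> ", x$n_sites, " oscillators, ", x$n_frames,
      " frame(s), ", nrow(x$by_bin), " bins\n", sep = "")
  print(x$by_bin)
  invisible(x)
}

#' @rdname eigen_summary
#' @param x,object An `eigen_summary`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eigen_summary <- function(x, ...) x$by_bin

#' @rdname eigen_summary
#' @exportS3Method ggplot2::autoplot
autoplot.eigen_summary <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$by_bin, c("dos", "ipr", "mu2"),
                             names_to = "quantity")
  ggplot(dat, aes(x = .data$bin_center, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    labs(x = expression(omega ~ (cm^-1)), y = NULL) +
    theme_minimal()
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Useful for resolving overlapping amide I bands: band centres appear as
#' local minima of the second derivative.
#'
#' @param s A [new_spectrum1d()] on a uniform grid.
#' @param window Odd filter window length (points), greater than `polyorder`.
#' @param polyorder Fitting polynomial order.
#' @return A [new_spectrum1d()] holding the second derivative.
#' @export
second_derivative <- function(s, window = 11L, polyorder = 3L) {
  if (window %% 2L == 0L || window <= polyorder) {
    abort("`window` must be odd and greater than `polyorder`")
  }
  if (window > length(s$frequency)) abort("`window` larger than the spectrum")
  h <- diff(s$frequency)
  if (max(abs(h - h[1])) > 1e-6) abort("second_derivative needs a uniform grid")
  d2 <- signal::sgolayfilt(s$intensity, p = polyorder, n = window, m = 2L,
                           ts = h[1])
  new_spectrum1d(s$frequency, d2, meta = c(s$meta, list(derivative = 2L)))
}

#' Ratio of band intensities at two frequencies
#'
#' By default each band height is the local maximum within +/- `window_cm`
#' of the requested position; set `local_max = FALSE` to read the nearest
#' grid point instead.
#'
#' @param s A [new_spectrum1d()].
#' @param omega_a,omega_b Band positions (cm^-1), inside the axis range.
#' @param local_max Use the local maximum within the window?
#' @param window_cm Search half-window (cm^-1).
#' @return `intensity(omega_a) / intensity(omega_b)`.
#' @examples
#' s <- new_spectrum1d(1600:1700, dnorm(1600:1700, 1654, 8))
#' band_ratio(s, 1654, 1683)
#' @export
band_ratio <- function(s, omega_a, omega_b, local_max = TRUE, window_cm = 3) {
  rng <- range(s$frequency)
  if (omega_a < rng[1] || omega_a > rng[2] || omega_b < rng[1] || omega_b > rng[2]) {
    abort("both frequencies must lie within the spectrum axis")
  }
  pick <- function(w) {
    if (local_max) {
      sel <- which(abs(s$frequency - w) <= window_cm)
      max(s$intensity[sel])
    } else {
      s$intensity[nearest_index(s$frequency, w)]
    }
  }
  a <- pick(omega_a)
  b <- pick(omega_b)
  if (abs(b) < .Machine$double.eps) abort("band ratio undefined: zero denominator")
  a / b
}
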