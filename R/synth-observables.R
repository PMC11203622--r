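# rotated-Gaussian surface on a grid; center (cx, cy), widths (sx, sy),
# tilt in degrees measured from the omega_tau axis
rotated_gaussian <- function(xg, yg, a, cx, cy, sx, sy, tilt_deg) {
  th <- deg2rad(tilt_deg)
  dx <- outer(xg - cx, rep(1, length(yg)))
  dy <- outer(rep(1, length(xg)), yg - cy)
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  a * exp(-u^2 / (2 * sx^2) - v^2 / (2 * sy^2))
}

#' Compose a synthetic 2D-IR surface from known tilted Gaussian peak pairs
#'
#' Each peak is a positive rotated Gaussian (the fundamental) plus an
#' equal-magnitude negative lobe displaced by the peak's anharmonicity along
#' omega_m. The exact analytic volume of every lobe (2*pi*A*sigma_tau*sigma_m,
#' sign carried by the lobe) is returned alongside the surface so fitters can
#' be validated against ground truth.
#'
#' @param peaks Tibble/data frame with columns `center_tau`, `center_m`,
#'   `width_tau`, `width_m`, `amplitude`, `tilt_deg`, `anharmonicity` (cm^-1
#'   and degrees). Zero rows give an all-zero surface.
#' @param omega_tau,omega_m Strictly increasing grid axes (cm^-1).
#' @param t_w Wait time stamped on the result (ps).
#'
#' @return A [new_spectrum2d()] whose `meta$components` tibble lists each
#'   lobe's analytic volume.
#' @examples
#' pk <- tibble::tibble(center_tau = 1660, center_m = 1660, width_tau = 6,
#'                      width_m = 6, amplitude = 10, tilt_deg = 30,
#'                      anharmonicity = 15)
#' s <- make_synthetic_2dir(pk, seq(1600, 1720, 0.5), seq(1600, 1720, 0.5))
#' s$meta$components
#' @export
make_synthetic_2dir <- function(peaks, omega_tau, omega_m, t_w = 0) {
  if (any(diff(omega_tau) <= 0) || any(diff(omega_m) <= 0)) {
    abort("grid axes must be strictly increasing")
  }
  peaks <- as_tibble(peaks)
  z <- matrix(0, length(omega_tau), length(omega_m))
  comps <- list()
  for (k in seq_len(nrow(peaks))) {
    p <- peaks[k, ]
    if (p$width_tau <= 0 || p$width_m <= 0) abort("peak widths must be > 0")
    if (p$anharmonicity < 0) abort("anharmonicity must be >= 0")
    vol <- 2 * pi * p$amplitude * p$width_tau * p$width_m
    z <- z + rotated_gaussian(omega_tau, omega_m, p$amplitude, p$center_tau,
                              p$center_m, p$width_tau, p$width_m, p$tilt_deg)
    z <- z - rotated_gaussian(omega_tau, omega_m, p$amplitude, p$center_tau,
                              p$center_m - p$anharmonicity,
                              p$width_tau, p$width_m, p$tilt_deg)
    comps[[length(comps) + 1]] <- tibble(
      peak = k, lobe = c("fundamental", "anharmonic"),
      center_tau = p$center_tau,
      center_m = c(p$center_m, p$center_m - p$anharmonicity),
      volume = c(vol, -vol)
    )
  }
  new_spectrum2d(
    omega_tau, omega_m, z, t_w = t_w, component = "absorptive",
    meta = list(components = if (length(comps)) bind_rows(comps) else
      tibble(peak = integer(), lobe = character(), center_tau = numeric(),
             center_m = numeric(), volume = numeric()))
  )
}

#' Generate a bi-exponential decay table
#'
#' `P(t) = A1 exp(-B1 t) + A2 exp(-B2 t)` plus optional Gaussian noise,
#' reproducible from `seed`. The decay-rate scale of the defaults matches
#' amide I population relaxation (order 1 ps^-1).
#'
#' @param a1,b1,a2,b2 Amplitudes and decay rates (rates in ps^-1, > 0).
#' @param t_grid Increasing time axis (ps).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Tibble with columns `time_ps`, `signal`.
#' @examples
#' make_biexp_decay(1, 1.38, 0.3, 0.2, seq(0, 10, 0.1))
#' @export
make_biexp_decay <- function(a1, b1, a2, b2, t_grid, noise_sd = 0, seed = 1L) {
  if (b1 <= 0 || b2 <= 0) abort("decay rates must be > 0")
  if (any(diff(t_grid) <= 0)) abort("`t_grid` must be increasing")
  p <- a1 * exp(-b1 * t_grid) + a2 * exp(-b2 * t_grid)
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      p <- p + rnorm(length(t_grid), sd = noise_sd)
    })
  }
  tibble(time_ps = as.numeric(t_grid), signal = p)
}

#' Generate a molar-ellipticity curve from target helical fractions
#'
#' Inverts the Baldwin helicity relation so that [helical_fraction()] applied
#' to the generated theta_222 values recovers the requested fractions exactly:
#' `theta_222 = theta_C + f_H (theta_H - theta_C)` with
#' `theta_C = 2220 - 53 T` and `theta_H = (-44000 + 250 T)(1 - 3/Nr)`.
#'
#' @param fh_by_t Tibble/data frame with columns `temperature_c` and `fh`
#'   (fractions in `[0, 1]`).
#' @param nr Residue count.
#' @return Tibble with columns `temperature_c`, `theta_222` (deg cm^2 dmol^-1
#'   per residue) and the input `fh`.
#' @examples
#' make_cd_curve(tibble::tibble(temperature_c = c(25, 70), fh = c(0.87, 0.56)), 35)
#' @export
make_cd_curve <- function(fh_by_t, nr) {
  fh_by_t <- as_tibble(fh_by_t)
  if (any(fh_by_t$fh < 0 | fh_by_t$fh > 1)) abort("`fh` must lie in [0, 1]")
  tc <- fh_by_t$temperature_c
  theta_c <- 2220 - 53 * tc
  theta_h <- (-44000 + 250 * tc) * (1 - 3 / nr)
  tibble(
    temperature_c = tc,
    theta_222 = theta_c + fh_by_t$fh * (theta_h - theta_c),
    fh = fh_by_t$fh
  )
}
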