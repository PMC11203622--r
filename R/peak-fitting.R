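# Tilted-2D-Gaussian peak-volume fitting for absorptive 2D-IR snapshots.
# Model convention (fixed): each peak is a positive rotated Gaussian plus an
# equal-magnitude negative lobe displaced by its anharmonicity along omega_m;
# tilt is 30 deg for diagonal peaks and 0 deg for cross-peaks; reported peak
# volumes are positive-lobe magnitudes 2*pi*A*sigma_tau*sigma_m.

PEAK_ROLES <- c("diagonal_low", "diagonal_high", "cross_lowhigh", "cross_highlow")

#' Bounded-search presets for the 2D peak fitter
#'
#' Two presets mirror the search spaces used for experimental and computed
#' relay-helix spectra: box constraints plus fixed starting values for peak
#' amplitudes, centres, widths and anharmonicities. Tilts are fixed at 30 deg
#' (diagonal) and 0 deg (cross).
#'
#' @param preset `"experimental"` or `"computational"`.
#' @return A named list of per-parameter `c(start, lower, upper)` triples by
#'   role.
#' @export
fit2d_preset <- function(preset = c("experimental", "computational")) {
  preset <- match.arg(preset)
  tri <- function(start, lower, upper) c(start = start, lower = lower, upper = upper)
  if (preset == "experimental") {
    list(
      diagonal_low = list(
        amplitude = tri(10, 0, 50), center_tau = tri(1660, 1655, 1670),
        center_m = tri(1660, 1655, 1670), width_tau = tri(6, 0.5, 20),
        width_m = tri(6, 0.5, 20), anharmonicity = tri(15, 10, 20),
        tilt_deg = 30
      ),
      diagonal_high = list(
        amplitude = tri(10, 0, 50), center_tau = tri(1680, 1670, 1690),
        center_m = tri(1680, 1670, 1690), width_tau = tri(5, 0.5, 13),
        width_m = tri(5, 0.5, 13), anharmonicity = tri(15, 10, 20),
        tilt_deg = 30
      ),
      cross = list(
        amplitude = tri(2, 0, 6), width_tau = tri(5, 0.5, 13),
        width_m = tri(5, 0.5, 13), anharmonicity = tri(15, 10, 20),
        tilt_deg = 0
      )
    )
  } else {
    list(
      diagonal_low = list(
        amplitude = tri(5, 0, 20), center_tau = tri(1655, 1650, 1660),
        center_m = tri(1655, 1650, 1660), width_tau = tri(6, 2, 20),
        width_m = tri(6, 2, 20), anharmonicity = tri(10, 8, 15),
        tilt_deg = 30
      ),
      diagonal_high = list(
        amplitude = tri(2, 0, 10), center_tau = tri(1675, 1670, 1680),
        center_m = tri(1675, 1670, 1680), width_tau = tri(5, 0.5, 10),
        width_m = tri(5, 0.5, 10), anharmonicity = tri(10, 8, 15),
        tilt_deg = 30
      ),
      cross = list(
        amplitude = tri(2, 0, 6), width_tau = tri(5, 0.5, 10),
        width_m = tri(5, 0.5, 10), anharmonicity = tri(10, 8, 15),
        tilt_deg = 0
      )
    )
  }
}

#' Evaluate a peak model on a grid
#'
#' @param model Tibble with one row per peak: `role`, `amplitude`,
#'   `center_tau`, `center_m`, `width_tau`, `width_m`, `tilt_deg`,
#'   `anharmonicity`.
#' @param omega_tau,omega_m Grid axes (cm^-1).
#' @return A [new_spectrum2d()] of the model surface.
#' @export
eval_peak_model <- function(model, omega_tau, omega_m) {
  model <- as_tibble(model)
  z <- matrix(0, length(omega_tau), length(omega_m))
  for (k in seq_len(nrow(model))) {
    p <- model[k, ]
    if (p$width_tau <= 0 || p$width_m <= 0) abort("widths must be > 0")
    z <- z + rotated_gaussian(omega_tau, omega_m, p$amplitude, p$center_tau,
                              p$center_m, p$width_tau, p$width_m, p$tilt_deg)
    z <- z - rotated_gaussian(omega_tau, omega_m, p$amplitude, p$center_tau,
                              p$center_m - p$anharmonicity,
                              p$width_tau, p$width_m, p$tilt_deg)
  }
  new_spectrum2d(omega_tau, omega_m, z, component = "absorptive",
                 meta = list(model = model))
}

# pack/unpack fitter parameters <-> model tibble
fit2d_pack <- function(cfg, with_cross) {
  par <- c(
    dl_a = cfg$diagonal_low$amplitude[["start"]],
    dl_ct = cfg$diagonal_low$center_tau[["start"]],
    dl_cm = cfg$diagonal_low$center_m[["start"]],
    dl_wt = cfg$diagonal_low$width_tau[["start"]],
    dl_wm = cfg$diagonal_low$width_m[["start"]],
    dl_anh = cfg$diagonal_low$anharmonicity[["start"]],
    dh_a = cfg$diagonal_high$amplitude[["start"]],
    dh_ct = cfg$diagonal_high$center_tau[["start"]],
    dh_cm = cfg$diagonal_high$center_m[["start"]],
    dh_wt = cfg$diagonal_high$width_tau[["start"]],
    dh_wm = cfg$diagonal_high$width_m[["start"]],
    dh_anh = cfg$diagonal_high$anharmonicity[["start"]]
  )
  lower <- c(
    cfg$diagonal_low$amplitude[["lower"]], cfg$diagonal_low$center_tau[["lower"]],
    cfg$diagonal_low$center_m[["lower"]], cfg$diagonal_low$width_tau[["lower"]],
    cfg$diagonal_low$width_m[["lower"]], cfg$diagonal_low$anharmonicity[["lower"]],
    cfg$diagonal_high$amplitude[["lower"]], cfg$diagonal_high$center_tau[["lower"]],
    cfg$diagonal_high$center_m[["lower"]], cfg$diagonal_high$width_tau[["lower"]],
    cfg$diagonal_high$width_m[["lower"]], cfg$diagonal_high$anharmonicity[["lower"]]
  )
  upper <- c(
    cfg$diagonal_low$amplitude[["upper"]], cfg$diagonal_low$center_tau[["upper"]],
    cfg$diagonal_low$center_m[["upper"]], cfg$diagonal_low$width_tau[["upper"]],
    cfg$diagonal_low$width_m[["upper"]], cfg$diagonal_low$anharmonicity[["upper"]],
    cfg$diagonal_high$amplitude[["upper"]], cfg$diagonal_high$center_tau[["upper"]],
    cfg$diagonal_high$center_m[["upper"]], cfg$diagonal_high$width_tau[["upper"]],
    cfg$diagonal_high$width_m[["upper"]], cfg$diagonal_high$anharmonicity[["upper"]]
  )
  if (with_cross) {
    for (cp in c("clh", "chl")) {
      par <- c(par, setNames(c(
        cfg$cross$amplitude[["start"]], cfg$cross$width_tau[["start"]],
        cfg$cross$width_m[["start"]], cfg$cross$anharmonicity[["start"]]
      ), paste0(cp, c("_a", "_wt", "_wm", "_anh"))))
      lower <- c(lower, cfg$cross$amplitude[["lower"]], cfg$cross$width_tau[["lower"]],
                 cfg$cross$width_m[["lower"]], cfg$cross$anharmonicity[["lower"]])
      upper <- c(upper, cfg$cross$amplitude[["upper"]], cfg$cross$width_tau[["upper"]],
                 cfg$cross$width_m[["upper"]], cfg$cross$anharmonicity[["upper"]])
    }
  }
  list(par = par, lower = lower, upper = upper)
}

fit2d_unpack <- function(par, cfg, with_cross) {
  model <- tibble(
    role = c("diagonal_low", "diagonal_high"),
    amplitude = c(par[["dl_a"]], par[["dh_a"]]),
    center_tau = c(par[["dl_ct"]], par[["dh_ct"]]),
    center_m = c(par[["dl_cm"]], par[["dh_cm"]]),
    width_tau = c(par[["dl_wt"]], par[["dh_wt"]]),
    width_m = c(par[["dl_wm"]], par[["dh_wm"]]),
    tilt_deg = c(cfg$diagonal_low$tilt_deg, cfg$diagonal_high$tilt_deg),
    anharmonicity = c(par[["dl_anh"]], par[["dh_anh"]])
  )
  if (with_cross) {
    # cross-peak centres tied to the fitted diagonal centres
    model <- bind_rows(model, tibble(
      role = c("cross_lowhigh", "cross_highlow"),
      amplitude = c(par[["clh_a"]], par[["chl_a"]]),
      center_tau = c(par[["dl_ct"]], par[["dh_ct"]]),
      center_m = c(par[["dh_cm"]], par[["dl_cm"]]),
      width_tau = c(par[["clh_wt"]], par[["chl_wt"]]),
      width_m = c(par[["clh_wm"]], par[["chl_wm"]]),
      tilt_deg = cfg$cross$tilt_deg,
      anharmonicity = c(par[["clh_anh"]], par[["chl_anh"]])
    ))
  }
  model
}

#' Fit tilted 2D Gaussian peaks to an absorptive 2D-IR snapshot
#'
#' Deterministic bounded least squares (Levenberg-Marquardt with box
#' constraints) from the preset starting point. The model always contains the
#' two diagonal fundamental/anharmonic peak pairs; `with_cross = TRUE` adds
#' the two cross-peak pairs, whose centres follow the fitted diagonal
#' centres. The residual is the sum of squared differences over the grid.
#'
#' @param spectrum A [new_spectrum2d()] (finite intensities).
#' @param config Preset name or a [fit2d_preset()]-shaped list.
#' @param with_cross Include cross-peaks?
#' @return An object of class `fit2d_result`: `model` (fitted peak tibble
#'   with per-peak `volume`), `residual`, `residual_map`, `converged`, and
#'   the input axes.
#' @examples
#' truth <- tibble::tibble(
#'   role = c("diagonal_low", "diagonal_high"),
#'   amplitude = c(12, 8), center_tau = c(1660, 1680), center_m = c(1660, 1680),
#'   width_tau = c(6, 5), width_m = c(6, 5), tilt_deg = 30, anharmonicity = 15
#' )
#' ax <- seq(1620, 1710, 1)
#' fit <- fit_peaks2d(eval_peak_model(truth, ax, ax), with_cross = FALSE)
#' fit$model$volume
#' @export
fit_peaks2d <- function(spectrum, config = "experimental", with_cross = TRUE) {
  if (!inherits(spectrum, "spectrum2d")) abort("`spectrum` must be a spectrum2d")
  if (!all(is.finite(spectrum$intensity))) abort("spectrum intensities must be finite")
  cfg <- if (is.character(config)) fit2d_preset(config) else config
  pk <- fit2d_pack(cfg, with_cross)
  target <- as.numeric(spectrum$intensity)

  resid_fn <- function(par) {
    names(par) <- names(pk$par)
    m <- fit2d_unpack(par, cfg, with_cross)
    as.numeric(eval_peak_model(m, spectrum$omega_tau, spectrum$omega_m)$intensity) -
      target
  }
  fit <- minpack.lm::nls.lm(
    par = pk$par, lower = pk$lower, upper = pk$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  converged <- fit$info %in% 1:4
  if (!converged) {
    warn(paste0("peak fit did not fully converge (info = ", fit$info,
                "); returning best-so-far"))
  }
  par <- fit$par
  names(par) <- names(pk$par)
  model <- fit2d_unpack(par, cfg, with_cross) |>
    mutate(volume = 2 * pi * .data$amplitude * .data$width_tau * .data$width_m)
  rmap <- matrix(resid_fn(fit$par), length(spectrum$omega_tau))
  structure(
    list(
      model = model,
      residual = sum(rmap^2),
      residual_map = new_spectrum2d(spectrum$omega_tau, spectrum$omega_m, rmap,
                                    t_w = spectrum$t_w, component = "absorptive"),
      converged = converged,
      t_w = spectrum$t_w,
      with_cross = with_cross
    ),
    class = "fit2d_result"
  )
}

#' @export
print.fit2d_result <- function(x, ...) {
  cat("<fit2d_result> T_w = ", x$t_w, " ps, residual = ",
      signif(x$residual, 4), if (!x$converged) " (not converged)", "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @rdname fit_peaks2d
#' @param x,object A `fit2d_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fit2d_result <- function(x, ...) x$model

#' @rdname fit_peaks2d
#' @exportS3Method generics::glance
glance.fit2d_result <- function(x, ...) {
  tibble(residual = x$residual, converged = x$converged, t_w = x$t_w,
         n_peaks = nrow(x$model))
}

#' Diagonal-volume ratio series across wait times
#'
#' For each wait time, the ratio of the high-frequency to the low-frequency
#' diagonal peak volume. Accepts either a list of [fit_peaks2d()] results or
#' a ready-made tibble of volumes with columns `t_w`, `diag_low`, `diag_high`
#' (useful for tabulated volumes).
#'
#' @param fits List of `fit2d_result` objects, or a volumes tibble.
#' @return Tibble with `t_w`, `diag_low`, `diag_high`, `ratio` (and a
#'   `defined` flag; the ratio of a zero low-diagonal volume is `NA`).
#' @examples
#' ratio_series(tibble::tibble(t_w = 0.7, diag_low = 6010, diag_high = 3582))
#' @export
ratio_series <- function(fits) {
  tbl <- if (is.data.frame(fits)) {
    as_tibble(fits)
  } else {
    purrr::map_dfr(fits, function(f) {
      m <- f$model
      tibble(
        t_w = f$t_w,
        diag_low = m$volume[m$role == "diagonal_low"],
        diag_high = m$volume[m$role == "diagonal_high"]
      )
    })
  }
  if (!all(c("t_w", "diag_low", "diag_high") %in% names(tbl))) {
    abort("need columns t_w, diag_low, diag_high")
  }
  tbl |>
    mutate(
      defined = abs(.data$diag_low) > .Machine$double.eps,
      ratio = ifelse(.data$defined, .data$diag_high / .data$diag_low, NA_real_)
    )
}
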