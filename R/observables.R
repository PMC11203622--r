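#' Isotropic pump-probe signal from parallel and perpendicular components
#'
#' `P(t) = (S_par + 2 S_perp) / 3`, pointwise on a shared time grid. This is
#' the magic-angle combination that isolates population relaxation from
#' orientational dynamics.
#'
#' @param s_par,s_perp Tibbles with columns `time_ps`, `signal` on identical
#'   time grids.
#' @return Tibble with columns `time_ps`, `signal`.
#' @examples
#' t <- seq(0, 5, 0.1)
#' isotropic_signal(tibble::tibble(time_ps = t, signal = exp(-t)),
#'                  tibble::tibble(time_ps = t, signal = 0.5 * exp(-t)))
#' @export
isotropic_signal <- function(s_par, s_perp) {
  s_par <- as_tibble(s_par)
  s_perp <- as_tibble(s_perp)
  if (nrow(s_par) != nrow(s_perp) ||
      max(abs(s_par$time_ps - s_perp$time_ps)) > 1e-9) {
    abort("parallel and perpendicular signals must share one time grid")
  }
  tibble(time_ps = s_par$time_ps,
         signal = (s_par$signal + 2 * s_perp$signal) / 3)
}

#' Bi-exponential fit of an isotropic decay
#'
#' Nonlinear least squares of `P(t) = A1 exp(-B1 t) + A2 exp(-B2 t)` using
#' all points with `t > t_min_ps`. Initialization is deterministic:
#' `A1 = P(t_min)`, `B1 = 1 ps^-1`, `A2 = 0.1 A1`, `B2 = 0.1 ps^-1`; the
#' result is reported with the faster rate first (`b1 >= b2`).
#'
#' @param p Tibble with columns `time_ps`, `signal`.
#' @param t_min_ps Fit-window start (ps); at least 6 points must lie beyond.
#' @return An object of class `biexp_fit`: `a1`, `b1`, `a2`, `b2`,
#'   `t_min_ps`, `residual`, `reduced` (TRUE when one amplitude vanished
#'   within tolerance), `null_fit` (TRUE for degenerate all-zero data).
#' @examples
#' d <- make_biexp_decay(1, 1.38, 0.2, 0.15, seq(0, 10, 0.1))
#' biexp_fit(d)
#' @export
biexp_fit <- function(p, t_min_ps = 0.5) {
  p <- as_tibble(p)
  sel <- p$time_ps > t_min_ps
  if (sum(sel) < 6L) abort("need at least 6 points beyond `t_min_ps`")
  t <- p$time_ps[sel]
  y <- p$signal[sel]
  out <- function(a1, b1, a2, b2, residual, reduced, null_fit) {
    structure(
      list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, t_min_ps = t_min_ps,
           residual = residual, reduced = reduced, null_fit = null_fit),
      class = "biexp_fit"
    )
  }
  if (all(abs(y) < .Machine$double.eps)) {
    warn("degenerate all-zero decay; returning null fit")
    return(out(0, NA_real_, 0, NA_real_, 0, FALSE, TRUE))
  }
  a10 <- y[1]
  start <- c(a1 = a10, b1 = 1, a2 = 0.1 * a10, b2 = 0.1)
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(-Inf, 1e-6, -Inf, 1e-6), upper = rep(Inf, 4),
    fn = function(par) par[1] * exp(-par[2] * t) + par[3] * exp(-par[4] * t) - y,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  par <- fit$par
  if (par[["b1"]] < par[["b2"]]) {
    par <- c(a1 = par[["a2"]], b1 = par[["b2"]], a2 = par[["a1"]], b2 = par[["b1"]])
  }
  scale <- max(abs(y))
  reduced <- min(abs(par[["a1"]]), abs(par[["a2"]])) < 1e-6 * scale
  out(par[["a1"]], par[["b1"]], par[["a2"]], par[["b2"]],
      sum(fit$fvec^2), reduced, FALSE)
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (x$null_fit) {
    cat("<biexp_fit> null fit (degenerate data)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<biexp_fit> A1 = %.4g, B1 = %.4g ps^-1, A2 = %.4g, B2 = %.4g ps^-1 (t > %g ps)\n",
    x$a1, x$b1, x$a2, x$b2, x$t_min_ps
  ))
  invisible(x)
}

#' @rdname biexp_fit
#' @param x,object A `biexp_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.biexp_fit <- function(x, ...) {
  tibble(
    term = c("a1", "b1", "a2", "b2"),
    estimate = c(x$a1, x$b1, x$a2, x$b2),
    unit = c("signal", "ps^-1", "signal", "ps^-1")
  )
}

#' @rdname biexp_fit
#' @exportS3Method generics::glance
glance.biexp_fit <- function(x, ...) {
  tibble(residual = x$residual, reduced = x$reduced, null_fit = x$null_fit,
         t_min_ps = x$t_min_ps)
}

#' @rdname biexp_fit
#' @param newdata Optional tibble with a `time_ps` column.
#' @exportS3Method generics::augment
augment.biexp_fit <- function(x, newdata, ...) {
  newdata <- as_tibble(newdata)
  mutate(newdata, .fitted = x$a1 * exp(-x$b1 * .data$time_ps) +
           x$a2 * exp(-x$b2 * .data$time_ps))
}

#' Peak-height ratio of a pump-probe surface across delays
#'
#' Peak heights are local maxima within +/- `window_cm` of the requested
#' frequencies (robust to small peak drifts, matching "peak height" usage),
#' ratioed per delay.
#'
#' @param surface Long tibble with columns `delay_ps`, `frequency`, `signal`.
#' @param omega_a,omega_b Peak positions (cm^-1).
#' @param delays Delays to evaluate (default: all present).
#' @param window_cm Search half-window (cm^-1).
#' @return Tibble with `delay_ps`, `height_a`, `height_b`, `ratio`,
#'   `defined`.
#' @export
peak_ratio_series <- function(surface, omega_a, omega_b, delays = NULL,
                              window_cm = 3) {
  surface <- as_tibble(surface)
  delays <- delays %||% sort(unique(surface$delay_ps))
  purrr::map_dfr(delays, function(d) {
    sl <- filter(surface, abs(.data$delay_ps - d) < 1e-9)
    if (nrow(sl) == 0L) abort(paste0("delay ", d, " not present in the surface"))
    pick <- function(w) {
      sel <- abs(sl$frequency - w) <= window_cm
      if (!any(sel)) abort("requested frequency outside the surface grid")
      max(sl$signal[sel])
    }
    ha <- pick(omega_a)
    hb <- pick(omega_b)
    tibble(
      delay_ps = d, height_a = ha, height_b = hb,
      defined = abs(hb) > .Machine$double.eps,
      ratio = ifelse(abs(hb) > .Machine$double.eps, ha / hb, NA_real_)
    )
  })
}

#' Predicted pump-probe peak ratio from a linear-spectrum ratio
#'
#' Pump-probe absorbance scales as the fourth power of the transition dipole
#' while linear absorbance scales as the square, so a linear band ratio `r`
#' driven purely by oscillator strength predicts a pump-probe ratio of `r^2`.
#'
#' @param linear_ratio Positive band ratio from a linear spectrum.
#' @return `linear_ratio^2`.
#' @examples
#' mu4_consistency(1.75) # 3.0625, i.e. ~3.1
#' @export
mu4_consistency <- function(linear_ratio) {
  if (any(linear_ratio <= 0)) abort("`linear_ratio` must be > 0")
  linear_ratio^2
}

#' Fractional helicity from molar ellipticity at 222 nm
#'
#' Baldwin relation: `f_H = (theta_222 - theta_C) / (theta_H - theta_C)` with
#' the random-coil and perfect-helix baselines `theta_C = 2220 - 53 T` and
#' `theta_H = (-44000 + 250 T)(1 - 3/Nr)` (T in Celsius, per-residue molar
#' ellipticities). Values outside `[0, 1]` are clamped and flagged. The
#' finite-length correction multiplies the full helix baseline; set
#' `alt_grouping = TRUE` for the alternative reading in which only the
#' -44000 term is corrected.
#'
#' @param theta_222 Molar ellipticity per residue at 222 nm
#'   (deg cm^2 dmol^-1).
#' @param temperature_c Temperature (Celsius).
#' @param nr Residue count (>= 4).
#' @param alt_grouping Use the alternative finite-length grouping?
#' @return Tibble with `theta_222`, `temperature_c`, `fh`, `clamped`.
#' @examples
#' helical_fraction(-14223.6, 70, 35) # fh = 0.56
#' @export
helical_fraction <- function(theta_222, temperature_c, nr,
                             alt_grouping = FALSE) {
  if (nr < 4) abort("`nr` must be at least 4")
  theta_c <- 2220 - 53 * temperature_c
  theta_h <- if (alt_grouping) {
    -44000 * (1 - 3 / nr) + 250 * temperature_c
  } else {
    (-44000 + 250 * temperature_c) * (1 - 3 / nr)
  }
  if (any(abs(theta_h - theta_c) < 1e-9)) {
    abort("non-physical baselines: theta_H equals theta_C")
  }
  fh_raw <- (theta_222 - theta_c) / (theta_h - theta_c)
  tibble(
    theta_222 = theta_222,
    temperature_c = temperature_c,
    fh = pmin(pmax(fh_raw, 0), 1),
    clamped = fh_raw < 0 | fh_raw > 1
  )
}
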