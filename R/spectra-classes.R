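#' One-dimensional spectrum container
#'
#' @param frequency Strictly increasing frequency axis (cm^-1).
#' @param intensity Intensity vector of the same length.
#' @param meta Named list of metadata (e.g. `lifetime_ps`, `source`).
#' @return An object of class `spectrum1d`.
#' @export
new_spectrum1d <- function(frequency, intensity, meta = list()) {
  if (length(frequency) != length(intensity)) {
    abort("`frequency` and `intensity` must have the same length")
  }
  if (any(diff(frequency) <= 0)) abort("`frequency` must be strictly increasing")
  if (!all(is.finite(intensity))) abort("intensities must be finite")
  structure(
    list(frequency = as.numeric(frequency), intensity = as.numeric(intensity),
         meta = meta),
    class = "spectrum1d"
  )
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat("<spectrum1d> ", length(x$frequency), " points, ",
      min(x$frequency), "-", max(x$frequency), " cm^-1\n", sep = "")
  invisible(x)
}

#' @rdname new_spectrum1d
#' @param x,object A `spectrum1d`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spectrum1d <- function(x, ...) {
  tibble(frequency = x$frequency, intensity = x$intensity)
}

#' @rdname new_spectrum1d
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum1d <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$frequency, y = .data$intensity)) +
    geom_line() +
    labs(x = expression(omega ~ (cm^-1)), y = "intensity") +
    theme_minimal()
}

#' Two-dimensional spectrum container
#'
#' Signed intensity on an (omega_tau, omega_m) grid at one wait time.
#'
#' @param omega_tau,omega_m Strictly increasing axes (cm^-1).
#' @param intensity Matrix `length(omega_tau) x length(omega_m)`.
#' @param t_w Wait time in ps.
#' @param component `"absorptive"`, `"rephasing"` or `"nonrephasing"`.
#' @param meta Named metadata list.
#' @return An object of class `spectrum2d`.
#' @export
new_spectrum2d <- function(omega_tau, omega_m, intensity, t_w = 0,
                           component = c("absorptive", "rephasing", "nonrephasing"),
                           meta = list()) {
  component <- match.arg(component)
  if (any(diff(omega_tau) <= 0) || any(diff(omega_m) <= 0)) {
    abort("axes must be strictly increasing")
  }
  if (!is.matrix(intensity) ||
      nrow(intensity) != length(omega_tau) ||
      ncol(intensity) != length(omega_m)) {
    abort("`intensity` must be a length(omega_tau) x length(omega_m) matrix")
  }
  structure(
    list(omega_tau = as.numeric(omega_tau), omega_m = as.numeric(omega_m),
         intensity = intensity, t_w = t_w, component = component, meta = meta),
    class = "spectrum2d"
  )
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat("<spectrum2d> ", x$component, ", ", length(x$omega_tau), " x ",
      length(x$omega_m), " grid, T_w = ", x$t_w, " ps\n", sep = "")
  invisible(x)
}

#' @rdname new_spectrum2d
#' @param x,object A `spectrum2d`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.spectrum2d <- function(x, ...) {
  tibble(
    omega_tau = rep(x$omega_tau, times = length(x$omega_m)),
    omega_m = rep(x$omega_m, each = length(x$omega_tau)),
    intensity = as.numeric(x$intensity),
    t_w = x$t_w
  )
}

#' @rdname new_spectrum2d
#' @exportS3Method ggplot2::autoplot
autoplot.spectrum2d <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$omega_tau, y = .data$omega_m,
                           fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = expression(omega[tau] ~ (cm^-1)), y = expression(omega[m] ~ (cm^-1)),
         title = paste0("T_w = ", object$t_w, " ps (", object$component, ")")) +
    theme_minimal()
}

# nearest grid index
nearest_index <- function(axis, value) which.min(abs(axis - value))
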