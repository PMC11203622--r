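#' Construct an analytic 2D double-well potential with prescribed energetics
#'
#' Builds a smooth potential as the sum of two isotropic Gaussian wells and
#' calibrates the well depths by Newton iteration so that, measured on the
#' actual surface, the two local minima differ by `dg_kjmol` and the saddle
#' between them sits `barrier_kjmol` above the global minimum. The second
#' listed position becomes the global minimum when `dg_kjmol > 0`.
#'
#' @param dg_kjmol Free-energy difference between the two minima (kJ/mol,
#'   may be negative to deepen the first well instead).
#' @param barrier_kjmol Saddle height above the global minimum (kJ/mol);
#'   must exceed `abs(dg_kjmol)` for a saddle to exist between two minima.
#' @param minima_positions List of two numeric `c(x, y)` well centres (nm).
#' @param sigma_nm Gaussian well width; default a quarter of the
#'   centre-to-centre distance.
#'
#' @return An object of class `double_well`: `fn(p)` and `grad(p)` operating
#'   on `n x 2` matrices, the calibrated depths, and a `domain` bounding box.
#' @examples
#' w <- make_double_well(3.36, 6, list(c(0.47, 0.34), c(0.48, 0.64)))
#' w$fn(rbind(c(0.48, 0.64)))
#' @export
make_double_well <- function(dg_kjmol, barrier_kjmol, minima_positions,
                             sigma_nm = NULL) {
  if (length(minima_positions) != 2L) {
    abort("`minima_positions` must list exactly two well centres")
  }
  c1 <- as.numeric(minima_positions[[1]])
  c2 <- as.numeric(minima_positions[[2]])
  d <- dist3(c(c1, 0), c(c2, 0))
  if (d < 1e-6) abort("well centres must be distinct")
  if (barrier_kjmol <= abs(dg_kjmol)) {
    abort("`barrier_kjmol` must exceed |dg_kjmol| for a well-formed landscape")
  }
  sigma <- sigma_nm %||% (d / 4)

  make_fn <- function(d1, d2) {
    force(d1); force(d2)
    function(p) {
      p <- matrix(p, ncol = 2)
      r1 <- (p[, 1] - c1[1])^2 + (p[, 2] - c1[2])^2
      r2 <- (p[, 1] - c2[1])^2 + (p[, 2] - c2[2])^2
      -d1 * exp(-r1 / (2 * sigma^2)) - d2 * exp(-r2 / (2 * sigma^2))
    }
  }
  make_grad <- function(d1, d2) {
    force(d1); force(d2)
    function(p) {
      p <- matrix(p, ncol = 2)
      g1 <- exp(-((p[, 1] - c1[1])^2 + (p[, 2] - c1[2])^2) / (2 * sigma^2))
      g2 <- exp(-((p[, 1] - c2[1])^2 + (p[, 2] - c2[2])^2) / (2 * sigma^2))
      cbind(
        d1 * (p[, 1] - c1[1]) / sigma^2 * g1 + d2 * (p[, 1] - c2[1]) / sigma^2 * g2,
        d1 * (p[, 2] - c1[2]) / sigma^2 * g1 + d2 * (p[, 2] - c2[2]) / sigma^2 * g2
      )
    }
  }

  # measure (min1, min2, saddle) on the current surface
  measure <- function(d1, d2) {
    fn <- make_fn(d1, d2)
    m1 <- stats::optim(c1, function(p) fn(rbind(p)), method = "BFGS")
    m2 <- stats::optim(c2, function(p) fn(rbind(p)), method = "BFGS")
    sad <- stats::optimize(
      function(t) fn(rbind(m1$par + t * (m2$par - m1$par))),
      interval = c(0.05, 0.95), maximum = TRUE
    )
    c(v1 = m1$value, v2 = m2$value, vs = sad$objective)
  }

  # Newton iteration on depths: targets are v1 - v2 = dg, vs - v2 = barrier
  # (with well 2 global for dg > 0; symmetric otherwise)
  dep <- c(barrier_kjmol - min(dg_kjmol, 0), barrier_kjmol + max(dg_kjmol, 0))
  resid <- function(dep) {
    m <- measure(dep[1], dep[2])
    gm <- min(m["v1"], m["v2"])
    c(
      (m[["v1"]] - m[["v2"]]) - dg_kjmol,
      (m[["vs"]] - gm) - barrier_kjmol
    )
  }
  for (it in 1:60) {
    r0 <- resid(dep)
    if (max(abs(r0)) < 1e-6) break
    eps <- 1e-4
    j <- cbind(
      (resid(dep + c(eps, 0)) - r0) / eps,
      (resid(dep + c(0, eps)) - r0) / eps
    )
    step <- tryCatch(solve(j, r0), error = function(e) NULL)
    if (is.null(step)) abort("double-well calibration failed (singular Jacobian)")
    dep <- dep - step
    if (any(dep <= 0)) abort("double-well calibration failed (non-physical depths)")
  }
  if (max(abs(resid(dep))) > 1e-4) {
    abort("double-well calibration did not converge; adjust sigma_nm or barrier")
  }

  margin <- max(4 * sigma, 0.15)
  domain <- rbind(
    pmin(c1, c2) - margin,
    pmax(c1, c2) + margin
  )
  structure(
    list(
      fn = make_fn(dep[1], dep[2]),
      grad = make_grad(dep[1], dep[2]),
      centers = list(c1, c2), depths = dep, sigma_nm = sigma,
      dg_kjmol = dg_kjmol, barrier_kjmol = barrier_kjmol,
      domain = domain
    ),
    class = "double_well"
  )
}

#' @export
print.double_well <- function(x, ...) {
  cat("<double_well> dG = ", x$dg_kjmol, " kJ/mol, barrier = ",
      x$barrier_kjmol, " kJ/mol, sigma = ", round(x$sigma_nm, 4), " nm\n",
      sep = "")
  invisible(x)
}
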