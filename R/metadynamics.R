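#' Free-energy-surface grid container
#'
#' @param d1,d2 Strictly increasing collective-variable axes (nm).
#' @param free_energy Matrix `length(d1) x length(d2)` (kJ/mol).
#' @param temperature_k Temperature used for kT conversions.
#' @param meta Metadata list.
#' @return An object of class `fes_grid`.
#' @export
new_fes_grid <- function(d1, d2, free_energy, temperature_k = 298.15,
                         meta = list()) {
  if (any(diff(d1) <= 0) || any(diff(d2) <= 0)) {
    abort("axes must be strictly increasing")
  }
  if (!is.matrix(free_energy) || nrow(free_energy) != length(d1) ||
      ncol(free_energy) != length(d2)) {
    abort("`free_energy` must be a length(d1) x length(d2) matrix")
  }
  structure(
    list(d1 = as.numeric(d1), d2 = as.numeric(d2), free_energy = free_energy,
         temperature_k = temperature_k, meta = meta),
    class = "fes_grid"
  )
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid> ", length(x$d1), " x ", length(x$d2), " grid, range ",
      round(min(x$free_energy), 2), "-", round(max(x$free_energy), 2),
      " kJ/mol\n", sep = "")
  invisible(x)
}

#' @rdname new_fes_grid
#' @param x,object An `fes_grid`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fes_grid <- function(x, ...) {
  tibble(
    d1 = rep(x$d1, times = length(x$d2)),
    d2 = rep(x$d2, each = length(x$d1)),
    free_energy = as.numeric(x$free_energy)
  )
}

#' @rdname new_fes_grid
#' @exportS3Method ggplot2::autoplot
autoplot.fes_grid <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$d1, y = .data$d2, z = .data$free_energy)) +
    geom_raster(aes(fill = .data$free_energy)) +
    geom_contour(colour = "grey30", binwidth = 2.5) +
    scale_fill_gradient2(low = "darkblue", mid = "steelblue", high = "white",
                         midpoint = max(object$free_energy) / 2) +
    labs(x = "d1 (nm)", y = "d2 (nm)", fill = "G (kJ/mol)") +
    theme_minimal()
}

#' Well-tempered metadynamics on an analytic 2D potential
#'
#' Runs an overdamped Langevin walker on a smooth 2D potential while
#' depositing progressively shrinking Gaussian hills along the two collective
#' variables, and reconstructs the free-energy surface as
#' `-(gamma/(gamma-1)) * V_bias` on a grid, shifted so its minimum is zero.
#' The bias schedule follows the standard well-tempered protocol: a hill of
#' height `height * exp(-V_bias(s)/((gamma-1) kT))` every `pace` steps.
#'
#' @param potential A [make_double_well()] object, or any list with `fn`,
#'   `grad` and `domain` fields of the same shapes.
#' @param steps Number of Langevin steps (>= `pace`).
#' @param height Initial hill height (kJ/mol).
#' @param pace Steps between hill depositions.
#' @param width Hill width (nm).
#' @param biasfactor Well-tempered bias factor gamma (> 1).
#' @param dt_ps Integration step (ps).
#' @param diffusion Walker diffusion constant (nm^2/ps).
#' @param temperature_k Temperature (K).
#' @param seed Integer seed.
#' @param grid_n Bias/FES grid points per axis.
#'
#' @return An [new_fes_grid()]; `meta` keeps the hill log and walker start.
#' @examples
#' w <- make_double_well(3.36, 6, list(c(0.47, 0.34), c(0.48, 0.64)))
#' fes <- wtmetad(w, steps = 20000, seed = 1)
#' @export
wtmetad <- function(potential, steps, height = 1.2, pace = 500L, width = 0.05,
                    biasfactor = 6.0, dt_ps = 0.01, diffusion = 0.01,
                    temperature_k = 298.15, seed = 1L, grid_n = 81L) {
  if (steps < 0) abort("`steps` must be non-negative")
  if (biasfactor <= 1) abort("`biasfactor` must be > 1")
  # runs shorter than one deposition pace produce a flat FES (warned below)
  kt <- R_KJMOL * temperature_k
  dom <- potential$domain
  gx <- seq(dom[1, 1], dom[2, 1], length.out = grid_n)
  gy <- seq(dom[1, 2], dom[2, 2], length.out = grid_n)
  hx <- gx[2] - gx[1]
  hy <- gy[2] - gy[1]

  vb <- matrix(0, grid_n, grid_n)   # bias on grid
  gbx <- matrix(0, grid_n, grid_n)  # bias gradient on grid
  gby <- matrix(0, grid_n, grid_n)

  # bilinear interpolation of a grid field at (x, y)
  interp <- function(m, x, y) {
    ix <- min(max(1L, floor((x - gx[1]) / hx) + 1L), grid_n - 1L)
    iy <- min(max(1L, floor((y - gy[1]) / hy) + 1L), grid_n - 1L)
    tx <- (x - gx[ix]) / hx
    ty <- (y - gy[iy]) / hy
    (1 - tx) * (1 - ty) * m[ix, iy] + tx * (1 - ty) * m[ix + 1L, iy] +
      (1 - tx) * ty * m[ix, iy + 1L] + tx * ty * m[ix + 1L, iy + 1L]
  }

  hills <- list()
  n_escape <- 0L
  withr::with_seed(as.integer(seed), {
    p <- if (is.null(potential$centers)) {
      as.numeric(colMeans(dom))
    } else {
      as.numeric(potential$centers[[1]])
    }
    mob <- diffusion / kt * dt_ps
    noise_sd <- sqrt(2 * diffusion * dt_ps)
    for (s in seq_len(steps)) {
      g <- as.numeric(potential$grad(rbind(p)))
      g[1] <- g[1] + interp(gbx, p[1], p[2])
      g[2] <- g[2] + interp(gby, p[1], p[2])
      p <- p - mob * g + rnorm(2, sd = noise_sd)
      # reflective walls
      for (k in 1:2) {
        if (p[k] < dom[1, k]) { p[k] <- 2 * dom[1, k] - p[k]; n_escape <- n_escape + 1L }
        if (p[k] > dom[2, k]) { p[k] <- 2 * dom[2, k] - p[k]; n_escape <- n_escape + 1L }
        p[k] <- min(max(p[k], dom[1, k]), dom[2, k])
      }
      if (s %% pace == 0L) {
        w <- height * exp(-interp(vb, p[1], p[2]) / ((biasfactor - 1) * kt))
        ex <- exp(-(gx - p[1])^2 / (2 * width^2))
        ey <- exp(-(gy - p[2])^2 / (2 * width^2))
        hill <- w * outer(ex, ey)
        vb <- vb + hill
        gbx <- gbx + hill * outer(-(gx - p[1]) / width^2, rep(1, grid_n))
        gby <- gby + hill * outer(rep(1, grid_n), -(gy - p[2]) / width^2)
        hills[[length(hills) + 1]] <- c(p, w)
      }
    }
  })

  fes <- -(biasfactor / (biasfactor - 1)) * vb
  fes <- fes - min(fes)
  hill_log <- if (length(hills)) {
    m <- do.call(rbind, hills)
    tibble(d1 = m[, 1], d2 = m[, 2], height = m[, 3])
  } else {
    tibble(d1 = numeric(), d2 = numeric(), height = numeric())
  }
  if (nrow(hill_log) == 0L) warn("no hills deposited; FES is flat")
  new_fes_grid(
    gx, gy, fes, temperature_k = temperature_k,
    meta = list(hills = hill_log, boundary_reflections = n_escape,
                height = height, pace = pace, width = width,
                biasfactor = biasfactor, steps = steps, seed = seed)
  )
}

#' Locate minima, free-energy differences and barriers on an FES grid
#'
#' Minima are strict 8-neighbour local minima of the gridded surface. Pairwise
#' free-energy differences are reported relative to the global minimum in both
#' kJ/mol and kT (`kT = R * temperature_k`). The barrier between the global
#' minimum and each other minimum is the bottleneck (max-over-min) level at
#' which the two basins connect on the 8-connected grid, found by a
#' union-find flood in order of increasing energy.
#'
#' @param fes An [new_fes_grid()].
#' @param temperature_k Temperature for the kT conversion (K); defaults to the
#'   grid's stored temperature.
#'
#' @return A list with `minima` (tibble: `d1`, `d2`, `free_energy`,
#'   `delta_kjmol`, `delta_kt`, sorted by depth), `barriers` (tibble:
#'   `to_minimum`, `barrier_kjmol`, `barrier_kt`, measured from the global
#'   minimum), and `kt_kjmol`.
#' @examples
#' w <- make_double_well(3.36, 6, list(c(0.47, 0.34), c(0.48, 0.64)))
#' g <- expand.grid(x = seq(0.2, 0.8, 0.005), y = seq(0.1, 0.9, 0.005))
#' z <- matrix(w$fn(as.matrix(g)), 121, 161)
#' fes_analyze(new_fes_grid(seq(0.2, 0.8, 0.005), seq(0.1, 0.9, 0.005),
#'                          z - min(z)))
#' @export
fes_analyze <- function(fes, temperature_k = NULL) {
  temperature_k <- temperature_k %||% fes$temperature_k
  kt <- R_KJMOL * temperature_k
  g <- fes$free_energy
  if (!all(is.finite(g))) abort("FES grid must be finite")
  nx <- nrow(g)
  ny <- ncol(g)

  is_min <- matrix(FALSE, nx, ny)
  for (i in 2:(nx - 1)) {
    for (j in 2:(ny - 1)) {
      nb <- g[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (g[i, j] < min(nb[-5])) is_min[i, j] <- TRUE
    }
  }
  mins <- which(is_min, arr.ind = TRUE)
  if (nrow(mins) == 0L) {
    return(list(
      minima = tibble(d1 = numeric(), d2 = numeric(), free_energy = numeric(),
                      delta_kjmol = numeric(), delta_kt = numeric()),
      barriers = tibble(to_minimum = integer(), barrier_kjmol = numeric(),
                        barrier_kt = numeric()),
      kt_kjmol = kt
    ))
  }
  gv <- g[mins]
  ord <- order(gv)
  mins <- mins[ord, , drop = FALSE]
  gv <- gv[ord]
  minima <- tibble(
    d1 = fes$d1[mins[, 1]], d2 = fes$d2[mins[, 2]], free_energy = gv,
    delta_kjmol = gv - gv[1], delta_kt = (gv - gv[1]) / kt
  )

  barriers <- tibble(to_minimum = integer(), barrier_kjmol = numeric(),
                     barrier_kt = numeric())
  if (nrow(mins) > 1L) {
    # union-find flood by increasing energy level
    parent <- seq_len(nx * ny)
    find <- function(a) {
      while (parent[a] != a) {
        parent[a] <<- parent[parent[a]]
        a <- parent[a]
      }
      a
    }
    cell <- function(i, j) (j - 1L) * nx + i
    ordc <- order(g)
    active <- logical(nx * ny)
    min_cells <- cell(mins[, 1], mins[, 2])
    connected_at <- rep(NA_real_, nrow(mins))
    remaining <- nrow(mins) - 1L
    for (c0 in ordc) {
      i <- ((c0 - 1L) %% nx) + 1L
      j <- ((c0 - 1L) %/% nx) + 1L
      active[c0] <- TRUE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0L && dj == 0L) next
          i2 <- i + di
          j2 <- j + dj
          if (i2 < 1L || i2 > nx || j2 < 1L || j2 > ny) next
          c2 <- cell(i2, j2)
          if (!active[c2]) next
          r1 <- find(c0)
          r2 <- find(c2)
          if (r1 != r2) parent[r1] <- r2
        }
      }
      if (remaining > 0L) {
        root0 <- find(min_cells[1])
        for (k in seq_len(nrow(mins))[-1]) {
          if (is.na(connected_at[k]) && active[min_cells[k]] &&
              find(min_cells[k]) == root0) {
            connected_at[k] <- g[c0]
            remaining <- remaining - 1L
          }
        }
        if (remaining == 0L) break
      }
    }
    barriers <- tibble(
      to_minimum = seq_len(nrow(mins))[-1],
      barrier_kjmol = connected_at[-1] - gv[1],
      barrier_kt = (connected_at[-1] - gv[1]) / kt
    )
  }
  list(minima = minima, barriers = barriers, kt_kjmol = kt)
}

#' Convert a free-energy difference to units of kT
#'
#' @param dg_kjmol Free-energy difference (kJ/mol).
#' @param temperature_k Temperature (K).
#' @return `dg_kjmol / (R * temperature_k)`, dimensionless.
#' @examples
#' free_energy_in_kt(4.67) # ~1.9 at 298.15 K
#' @export
free_energy_in_kt <- function(dg_kjmol, temperature_k = 298.15) {
  dg_kjmol / (R_KJMOL * temperature_k)
}
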