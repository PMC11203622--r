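#' Define the amide I site map
#'
#' The site map fixes how local amide I frequencies, transition dipoles and
#' couplings are computed from coordinates. The default is a self-contained
#' electrostatic map: every site starts from `base_frequency` and is shifted
#' by `potential_coefficient * (phi_O - phi_C)`, where `phi_X` is the Coulomb
#' potential (units e/nm) of the supplied point charges at the carbonyl C and
#' O atoms. Transition dipoles sit on the C=O bond (displaced toward the
#' amide N where one exists), tilted `dipole_tilt_deg` from the C=O axis in
#' the O-C-N plane, with magnitude `dipole_debye`. Couplings are
#' transition-dipole couplings for non-adjacent sites and a constant for
#' nearest neighbours. Externally parameterized maps drop in by overriding
#' these fields.
#'
#' @param base_frequency Unperturbed site frequency (cm^-1).
#' @param potential_coefficient Linear response of the site frequency to the
#'   O-minus-C potential difference (cm^-1 per e/nm).
#' @param point_charges Optional tibble with columns `x`, `y`, `z` (nm), `q`
#'   (elementary charges) describing a fixed external electrostatic
#'   environment; `NULL` means no electrostatic shift.
#' @param dipole_debye Transition-dipole magnitude (D).
#' @param dipole_tilt_deg In-plane tilt of the dipole away from C=O, toward
#'   the amide N (degrees).
#' @param dipole_offset_nm Dipole origin: displacement from C along C=O (nm).
#' @param nn_coupling Nearest-neighbour coupling constant (cm^-1); a helical
#'   default replaces the dihedral-indexed lookup of published maps.
#' @param frequency_window Physical window for diagonal entries; values
#'   outside it trigger a warning.
#'
#' @return An object of class `site_map`.
#' @export
site_map <- function(base_frequency = 1650,
                     potential_coefficient = -400,
                     point_charges = NULL,
                     dipole_debye = 0.37,
                     dipole_tilt_deg = 20,
                     dipole_offset_nm = 0.0868,
                     nn_coupling = -7,
                     frequency_window = c(1550, 1750)) {
  if (!is.null(point_charges)) {
    point_charges <- as_tibble(point_charges)
    stopifnot(all(c("x", "y", "z", "q") %in% names(point_charges)))
  }
  structure(
    list(
      base_frequency = base_frequency,
      potential_coefficient = potential_coefficient,
      point_charges = point_charges,
      dipole_debye = dipole_debye,
      dipole_tilt_deg = dipole_tilt_deg,
      dipole_offset_nm = dipole_offset_nm,
      nn_coupling = nn_coupling,
      frequency_window = frequency_window
    ),
    class = "site_map"
  )
}

#' Enumerate the amide I chromophores of a peptide
#'
#' One oscillator per backbone carbonyl, ordered N- to C-terminal: the
#' acetyl cap carbonyl (when present), each peptide-bond carbonyl, and the
#' C-terminal acid (or amide) carbonyl. The relay helix peptide
#' (35 residues, acetyl cap, acid terminus) therefore carries 36.
#'
#' @param spec A [peptide_spec()].
#' @return Tibble with one row per chromophore: `site`, `label`, `resno`
#'   (residue owning the C=O; 0 for the acetyl cap) and `next_resno` (residue
#'   providing the amide N-H, `NA` for the terminal carbonyl).
#' @examples
#' nrow(enumerate_oscillators(relay_helix_peptide())) # 36
#' @export
enumerate_oscillators <- function(spec) {
  if (!inherits(spec, "peptide_spec")) abort("`spec` must be a peptide_spec")
  res <- c(if (spec$n_terminal_cap == "acetyl") 0L, seq_len(spec$n_residues))
  tibble(
    site = seq_along(res),
    label = ifelse(
      res == 0L, "acetyl",
      ifelse(res == spec$n_residues,
             if (spec$c_terminal == "carboxylic_acid") "c_term_acid" else "c_term_amide",
             "backbone")
    ),
    resno = res,
    next_resno = c(res[-1], NA_integer_)
  )
}

# Per-site geometry for one frame: dipole position (nm), unit direction,
# C and O coordinates. Returns list(pos, dir, cpos, opos) matrices.
chromophore_geometry <- function(coords, traj, chromo, map) {
  n <- nrow(chromo)
  pos <- dirm <- cpos <- opos <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    r <- chromo$resno[k]
    ci <- atom_index(traj, r, if (r == 0L) "C" else "C", must = FALSE)
    oi <- atom_index(traj, r, "O", must = FALSE)
    if (is.na(ci) || is.na(oi)) {
      abort(paste0("chromophore ", k, " (residue ", r,
                   "): missing backbone C/O atom"))
    }
    cxyz <- coords[ci, ]
    oxyz <- coords[oi, ]
    u_co <- unit(oxyz - cxyz)
    nr <- chromo$next_resno[k]
    ni <- if (!is.na(nr)) atom_index(traj, nr, "N", must = FALSE) else NA_integer_
    if (!is.na(ni)) {
      u_cn <- unit(coords[ni, ] - cxyz)
      # rotate u_co toward the amide N within the O-C-N plane
      ax <- cross3(u_co, u_cn)
      dirv <- if (vec_norm(ax) < 1e-9) u_co else {
        as.numeric(rotation_about_axis(ax, deg2rad(map$dipole_tilt_deg)) %*% u_co)
      }
    } else {
      dirv <- u_co
    }
    cpos[k, ] <- cxyz
    opos[k, ] <- oxyz
    pos[k, ] <- cxyz + map$dipole_offset_nm * u_co
    dirm[k, ] <- dirv
  }
  list(pos = pos, dir = dirm, cpos = cpos, opos = opos)
}

coulomb_potential <- function(points, charges) {
  # potential in e/nm at each row of `points` from charges (x, y, z, q in nm, e)
  if (is.null(charges) || nrow(charges) == 0L) {
    return(rep(0, nrow(points)))
  }
  vapply(seq_len(nrow(points)), function(i) {
    r <- sqrt((charges$x - points[i, 1])^2 + (charges$y - points[i, 2])^2 +
                (charges$z - points[i, 3])^2)
    sum(charges$q / pmax(r, 1e-6))
  }, numeric(1))
}

#' Site frequencies for one frame
#'
#' @param coords `n_atoms x 3` coordinate matrix (nm) of one frame.
#' @param traj The trajectory the coordinates belong to (for atom lookup).
#' @param chromo Chromophore table from [enumerate_oscillators()].
#' @param map A [site_map()].
#' @return Numeric vector of site frequencies (cm^-1).
#' @export
site_frequencies <- function(coords, traj, chromo, map = site_map()) {
  geo <- chromophore_geometry(coords, traj, chromo, map)
  shift <- map$potential_coefficient *
    (coulomb_potential(geo$opos, map$point_charges) -
       coulomb_potential(geo$cpos, map$point_charges))
  freq <- map$base_frequency + shift
  win <- map$frequency_window
  if (any(freq < win[1] | freq > win[2])) {
    warn(paste0("site frequencies outside the physical window [", win[1], ", ",
                win[2], "] cm^-1"))
  }
  freq
}

#' Inter-site couplings for one frame
#'
#' Transition-dipole coupling
#' `J = k (u_n.u_m - 3 (u_n.r)(u_m.r)) |mu_n||mu_m| / r^3` with
#' `k = 5034.1 cm^-1 A^3 D^-2` (the vacuum electrostatic constant in these
#' units) for non-adjacent pairs; adjacent sites use the map's constant
#' nearest-neighbour coupling.
#'
#' @inheritParams site_frequencies
#' @return Symmetric `N x N` matrix with zero diagonal (cm^-1).
#' @export
couplings <- function(coords, traj, chromo, map = site_map()) {
  geo <- chromophore_geometry(coords, traj, chromo, map)
  n <- nrow(chromo)
  j <- matrix(0, n, n)
  mu <- map$dipole_debye
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (b == a + 1L) {
        j[a, b] <- j[b, a] <- map$nn_coupling
        next
      }
      rvec <- geo$pos[b, ] - geo$pos[a, ]
      r_nm <- vec_norm(rvec)
      if (r_nm < 0.05) {
        abort(paste0("chromophores ", a, " and ", b,
                     " are closer than 0.05 nm; geometry invalid"))
      }
      rhat <- rvec / r_nm
      ua <- geo$dir[a, ]
      ub <- geo$dir[b, ]
      orient <- sum(ua * ub) - 3 * sum(ua * rhat) * sum(ub * rhat)
      r_a <- r_nm * 10 # Angstrom
      j[a, b] <- j[b, a] <- TDC_PREFACTOR_CM_A3_D2 * orient * mu * mu / r_a^3
    }
  }
  j
}

#' Build the per-frame exciton Hamiltonian series for a trajectory
#'
#' For every frame: site frequencies on the diagonal, couplings off-diagonal
#' (both in cm^-1), plus per-site transition-dipole 3-vectors (Debye).
#'
#' @param traj A [new_trajectory()].
#' @param spec A [peptide_spec()]; defaults to the trajectory's stored spec.
#' @param map A [site_map()].
#' @return An object of class `hamiltonian_series`: `hamiltonians`
#'   (`N x N x n_frames` array), `dipoles` (`N x 3 x n_frames`), `dt_ps`,
#'   and the chromophore table.
#' @examples
#' h <- build_hamiltonian_series(make_ideal_helix(relay_helix_peptide()))
#' dim(h$hamiltonians) # 36 x 36 x 1
#' @export
build_hamiltonian_series <- function(traj, spec = NULL, map = site_map()) {
  spec <- spec %||% traj$spec
  if (is.null(spec)) abort("no peptide_spec available")
  chromo <- enumerate_oscillators(spec)
  n <- nrow(chromo)
  nf <- n_frames(traj)
  h <- array(0, dim = c(n, n, nf))
  mu <- array(0, dim = c(n, 3L, nf))
  for (f in seq_len(nf)) {
    coords <- frame_coords(traj, f)
    jm <- couplings(coords, traj, chromo, map)
    diag(jm) <- site_frequencies(coords, traj, chromo, map)
    h[, , f] <- jm
    geo <- chromophore_geometry(coords, traj, chromo, map)
    mu[, , f] <- geo$dir * map$dipole_debye
  }
  structure(
    list(hamiltonians = h, dipoles = mu, dt_ps = traj$timestep_ps,
         chromophores = chromo, map = map),
    class = "hamiltonian_series"
  )
}

#' @export
print.hamiltonian_series <- function(x, ...) {
  cat("<hamiltonian_series> ", dim(x$hamiltonians)[1], " sites x ",
      dim(x$hamiltonians)[3], " frame(s), dt = ", x$dt_ps, " ps\n", sep = "")
  invisible(x)
}

#' Build a hamiltonian_series directly from matrices
#'
#' Escape hatch for externally computed or hand-made Hamiltonians (model
#' systems, map tables from other programs).
#'
#' @param hamiltonians `N x N x F` array or a single `N x N` matrix (cm^-1).
#' @param dipoles `N x 3 x F` array or `N x 3` matrix (Debye).
#' @param dt_ps Frame spacing (ps).
#' @return A `hamiltonian_series`.
#' @export
hamiltonian_series <- function(hamiltonians, dipoles, dt_ps = 0.02) {
  if (is.matrix(hamiltonians)) {
    hamiltonians <- array(hamiltonians, dim = c(dim(hamiltonians), 1L))
  }
  if (is.matrix(dipoles)) dipoles <- array(dipoles, dim = c(dim(dipoles), 1L))
  for (f in seq_len(dim(hamiltonians)[3])) {
    m <- hamiltonians[, , f]
    if (max(abs(m - t(m))) > 1e-9) abort("Hamiltonians must be symmetric")
  }
  structure(
    list(hamiltonians = hamiltonians, dipoles = dipoles, dt_ps = dt_ps,
         chromophores = tibble(site = seq_len(dim(hamiltonians)[1])),
         map = NULL),
    class = "hamiltonian_series"
  )
}
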