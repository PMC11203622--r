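# Backbone geometry constants (nm / degrees). Fixed standard values for the
# internal-coordinate chain builder; the amide H sits in the peptide plane,
# trans to the preceding carbonyl oxygen.
BB <- list(
  b_n_ca  = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329,
  b_c_o   = 0.1229, b_n_h  = 0.1010, b_ch3_c = 0.1507, b_c_oxt = 0.1310,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_n_h = 119.5, a_ca_c_oxt = 118.0,
  omega = 180
)

# Build a single backbone frame from per-residue phi/psi (degrees).
# Returns list(coords = n x 3 matrix (nm), atoms = tibble).
build_backbone <- function(spec, phi, psi) {
  n <- spec$n_residues
  stopifnot(length(phi) == n, length(psi) == n)
  acetyl <- spec$n_terminal_cap == "acetyl"

  pos <- list() # named "resno.atom"
  put <- function(resno, atom, xyz) pos[[paste0(resno, ".", atom)]] <<- xyz
  get_ <- function(resno, atom) pos[[paste0(resno, ".", atom)]]

  dummy <- c(0, 0, 0.1)
  if (acetyl) {
    put(0, "CH3", c(0, 0, 0))
    put(0, "C", c(BB$b_ch3_c, 0, 0))
    put(1, "N", place_atom(dummy, get_(0, "CH3"), get_(0, "C"),
                           BB$b_c_n, BB$a_ca_c_n, 0))
    put(1, "CA", place_atom(get_(0, "CH3"), get_(0, "C"), get_(1, "N"),
                            BB$b_n_ca, BB$a_c_n_ca, BB$omega))
    put(1, "C", place_atom(get_(0, "C"), get_(1, "N"), get_(1, "CA"),
                           BB$b_ca_c, BB$a_n_ca_c, phi[1]))
  } else {
    put(1, "N", c(0, 0, 0))
    put(1, "CA", c(BB$b_n_ca, 0, 0))
    put(1, "C", place_atom(dummy, get_(1, "N"), get_(1, "CA"),
                           BB$b_ca_c, BB$a_n_ca_c, 0))
  }

  for (i in seq_len(n - 1)) {
    put(i + 1, "N", place_atom(get_(i, "N"), get_(i, "CA"), get_(i, "C"),
                               BB$b_c_n, BB$a_ca_c_n, psi[i]))
    put(i + 1, "CA", place_atom(get_(i, "CA"), get_(i, "C"), get_(i + 1, "N"),
                                BB$b_n_ca, BB$a_c_n_ca, BB$omega))
    put(i + 1, "C", place_atom(get_(i, "C"), get_(i + 1, "N"), get_(i + 1, "CA"),
                               BB$b_ca_c, BB$a_n_ca_c, phi[i + 1]))
  }

  # carbonyl oxygens: planar sp2, trans to the following amide nitrogen
  if (acetyl) {
    put(0, "O", place_atom(get_(1, "N"), get_(0, "CH3"), get_(0, "C"),
                           BB$b_c_o, BB$a_ca_c_o, 180))
  }
  for (i in seq_len(n - 1)) {
    put(i, "O", place_atom(get_(i + 1, "N"), get_(i, "CA"), get_(i, "C"),
                           BB$b_c_o, BB$a_ca_c_o, 180))
  }
  # C-terminal carbonyl + terminal group, oriented by psi of the last residue
  put(n, "O", place_atom(get_(n, "N"), get_(n, "CA"), get_(n, "C"),
                         BB$b_c_o, BB$a_ca_c_o, psi[n] + 180))
  if (spec$c_terminal == "carboxylic_acid") {
    put(n, "OXT", place_atom(get_(n, "N"), get_(n, "CA"), get_(n, "C"),
                             BB$b_c_oxt, BB$a_ca_c_oxt, psi[n]))
  } else {
    put(n, "NT", place_atom(get_(n, "N"), get_(n, "CA"), get_(n, "C"),
                            BB$b_c_n, BB$a_ca_c_n, psi[n]))
    put(n, "HT", place_atom(get_(n, "O"), get_(n, "C"), get_(n, "NT"),
                            BB$b_n_h, BB$a_c_n_h, 180))
  }

  # amide hydrogens: trans to the preceding carbonyl O across the C-N bond
  h_first <- if (acetyl) 1L else 2L
  for (i in seq(h_first, n)) {
    if (spec$residues[i] == "P") next
    prev <- i - 1L
    put(i, "H", place_atom(get_(prev, "O"), get_(prev, "C"), get_(i, "N"),
                           BB$b_n_h, BB$a_c_n_h, 180))
  }

  order_tbl <- list()
  if (acetyl) {
    order_tbl[[1]] <- tibble(resno = 0L, resid = "ACE", atom = c("CH3", "C", "O"))
  }
  for (i in seq_len(n)) {
    ats <- c("N", if (!is.null(get_(i, "H"))) "H", "CA", "C", "O")
    if (i == n) {
      ats <- c(ats, if (spec$c_terminal == "carboxylic_acid") "OXT" else c("NT", "HT"))
    }
    order_tbl[[length(order_tbl) + 1]] <-
      tibble(resno = i, resid = unname(AA3[spec$residues[i]]), atom = ats)
  }
  atoms <- bind_rows(order_tbl)
  coords <- t(vapply(
    seq_len(nrow(atoms)),
    function(k) get_(atoms$resno[k], atoms$atom[k]),
    numeric(3)
  ))
  list(coords = coords, atoms = atoms)
}

#' Build an ideal helical (or other uniform-dihedral) peptide conformation
#'
#' Constructs a single-frame backbone by internal-coordinate chain building
#' with fixed standard bond lengths and angles, all residues sharing the same
#' phi/psi pair. The alpha-helical defaults place every interior i -> i+4
#' O...H hydrogen bond near 0.2 nm.
#'
#' @param spec A [peptide_spec()].
#' @param phi_deg,psi_deg Backbone dihedrals in degrees, in (-180, 180].
#' @param timestep_ps Nominal frame spacing recorded on the trajectory (ps).
#'
#' @return A single-frame [new_trajectory()].
#' @examples
#' helix <- make_ideal_helix(relay_helix_peptide())
#' hbond_series(helix)
#' @export
make_ideal_helix <- function(spec, phi_deg = -57.8, psi_deg = -47.0,
                             timestep_ps = 0.02) {
  if (!inherits(spec, "peptide_spec")) abort("`spec` must be a peptide_spec")
  for (a in c(phi_deg, psi_deg)) {
    if (!is.finite(a) || a <= -180 || a > 180) {
      abort("dihedral angles must lie in (-180, 180]")
    }
  }
  n <- spec$n_residues
  bb <- build_backbone(spec, rep(phi_deg, n), rep(psi_deg, n))
  new_trajectory(
    bb$coords, bb$atoms,
    timestep_ps = timestep_ps, spec = spec,
    dihedrals = tibble(resno = seq_len(n), phi = phi_deg, psi = psi_deg)
  )
}

# Indices needed for i -> i+4 O...H distances. Returns tibble(pair = i,
# o_idx, h_idx) for all pairs whose donor H exists.
hbond_pair_index <- function(traj, pairs = NULL) {
  n <- traj$spec$n_residues %||% max(traj$atoms$resno)
  if (is.null(pairs)) pairs <- seq_len(max(0L, n - 4L))
  tibble(
    pair = pairs,
    o_idx = vapply(pairs, function(i) atom_index(traj, i, "O"), integer(1)),
    h_idx = vapply(pairs, function(i) atom_index(traj, i + 4L, "H", must = FALSE),
                   integer(1))
  )
}

oh_distances <- function(coords, idx) {
  vapply(seq_len(nrow(idx)), function(k) {
    if (is.na(idx$h_idx[k])) return(NA_real_)
    dist3(coords[idx$o_idx[k], ], coords[idx$h_idx[k], ])
  }, numeric(1))
}

#' Build a bent helix with designated broken i -> i+4 hydrogen bonds
#'
#' Starts from [make_ideal_helix()] and applies, for each requested break
#' `(i, i+4)`, a rigid hinge rotation of all atoms downstream of the CA of
#' residue `i+1` about an axis through that CA. The hinge direction and bend
#' angle are found by a bounded backtracking search so that exactly the
#' targeted O(i)...H(i+4) distances exceed the 0.35 nm hydrogen-bond cutoff
#' while every other measurable pair stays bonded. Because each hinge is a
#' rigid-body motion, the helix segments between breaks remain exactly ideal
#' internally.
#'
#' @param spec A [peptide_spec()].
#' @param break_positions List of integer pairs `c(i, i + 4)` (or an empty
#'   list for no breaks); a two-column matrix is also accepted.
#' @param phi_deg,psi_deg Dihedrals of the underlying ideal helix.
#' @param timestep_ps Frame spacing recorded on the trajectory (ps).
#' @param cutoff_nm Hydrogen-bond cutoff; broken pairs are pushed beyond
#'   `cutoff_nm + 0.01`, intact pairs kept below `cutoff_nm - 0.01`.
#'
#' @return A single-frame [new_trajectory()] with attribute-stored break set.
#' @examples
#' bent <- make_bent_helix(relay_helix_peptide(), list(c(22, 26), c(23, 27)))
#' dplyr::filter(hbond_series(bent), !formed)
#' @export
make_bent_helix <- function(spec, break_positions,
                            phi_deg = -57.8, psi_deg = -47.0,
                            timestep_ps = 0.02, cutoff_nm = 0.35) {
  ideal <- make_ideal_helix(spec, phi_deg, psi_deg, timestep_ps)
  if (is.matrix(break_positions)) {
    break_positions <- split(break_positions, seq_len(nrow(break_positions)))
  }
  if (length(break_positions) == 0L) {
    attr(ideal, "broken_pairs") <- integer(0)
    return(ideal)
  }
  n <- spec$n_residues
  br <- sort(vapply(break_positions, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L || p[2] != p[1] + 4L || p[1] < 1L || p[2] > n) {
      abort("each break must be a pair c(i, i + 4) within the sequence")
    }
    p[1]
  }, integer(1)))
  if (anyDuplicated(br)) abort("duplicate break positions")

  idx <- hbond_pair_index(ideal)
  measurable <- which(!is.na(idx$h_idx))
  coords0 <- frame_coords(ideal, 1)
  lo <- cutoff_nm - 0.01
  hi <- cutoff_nm + 0.01

  # atoms rotating for a hinge at residue i+1: C/O of i+1 and everything after
  moving_rows <- function(i) {
    which(ideal$atoms$resno > i + 1L |
            (ideal$atoms$resno == i + 1L & ideal$atoms$atom %in% c("C", "O")))
  }
  # local helix axis near the hinge, from flanking CA atoms
  local_axis <- function(coords, i) {
    lo_r <- max(1L, i - 1L)
    hi_r <- min(n, i + 3L)
    unit(coords[atom_index(ideal, hi_r, "CA"), ] -
           coords[atom_index(ideal, lo_r, "CA"), ])
  }

  candidates <- expand.grid(
    beta = seq(8, 72, by = 4), theta = seq(0, 345, by = 15)
  )

  check <- function(coords, upto) {
    d <- oh_distances(coords, idx)
    for (k in measurable) {
      j <- idx$pair[k]
      if (j > upto) next
      if (j %in% br) {
        if (!(d[k] > hi)) return(FALSE)
      } else if (!(d[k] < lo)) {
        return(FALSE)
      }
    }
    TRUE
  }

  budget <- 20000L
  solve_from <- function(coords, depth) {
    if (depth > length(br)) {
      return(if (check(coords, n)) coords else NULL)
    }
    i <- br[depth]
    rows <- moving_rows(i)
    pivot <- coords[atom_index(ideal, i + 1L, "CA"), ]
    ax <- local_axis(coords, i)
    ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p1 <- unit(cross3(ax, ref))
    p2 <- cross3(ax, p1)
    for (k in seq_len(nrow(candidates))) {
      if (budget <= 0L) return(NULL)
      budget <<- budget - 1L
      th <- deg2rad(candidates$theta[k])
      axis <- cos(th) * p1 + sin(th) * p2
      rot <- rotation_about_axis(axis, deg2rad(candidates$beta[k]))
      trial <- coords
      trial[rows, ] <- sweep(sweep(trial[rows, , drop = FALSE], 2, pivot) %*%
                               t(rot), 2, pivot, "+")
      if (!check(trial, i)) next
      res <- solve_from(trial, depth + 1L)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  out <- solve_from(coords0, 1L)
  if (is.null(out)) {
    abort("could not construct the requested hydrogen-bond breaks (bounded hinge search exhausted)")
  }
  res <- new_trajectory(out, ideal$atoms, timestep_ps = timestep_ps,
                        spec = spec, dihedrals = ideal$dihedrals)
  attr(res, "broken_pairs") <- br
  res
}
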