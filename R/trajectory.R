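#' Trajectory container
#'
#' Ordered frames of labelled backbone coordinates in nm. Internally a
#' `helix_trajectory` holds an `n_atoms x 3 x n_frames` array plus an atom
#' table (residue number, residue name, atom name) shared by all frames.
#'
#' @param xyz Numeric array `n_atoms x 3 x n_frames` (nm), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param atoms Tibble with columns `resno`, `resid`, `atom` describing each
#'   row of `xyz` (1-based residue numbering; cap atoms use `resno = 0` for an
#'   N-terminal acetyl).
#' @param timestep_ps Frame spacing in ps.
#' @param spec Optional [peptide_spec()] the coordinates were built from.
#' @param dihedrals Optional per-residue phi/psi table kept by the builders.
#'
#' @return An object of class `helix_trajectory`.
#' @export
new_trajectory <- function(xyz, atoms, timestep_ps = 0.02, spec = NULL,
                           dihedrals = NULL) {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  if (!all(is.finite(xyz))) abort("trajectory coordinates must be finite")
  if (nrow(atoms) != dim(xyz)[1]) abort("`atoms` must match the first dim of `xyz`")
  if (!is.numeric(timestep_ps) || timestep_ps <= 0) {
    abort("`timestep_ps` must be a positive number")
  }
  structure(
    list(
      xyz = xyz,
      atoms = as_tibble(atoms),
      timestep_ps = timestep_ps,
      spec = spec,
      dihedrals = dihedrals
    ),
    class = "helix_trajectory"
  )
}

#' @export
print.helix_trajectory <- function(x, ...) {
  cat(
    "<helix_trajectory> ", n_frames(x), " frame(s), ", nrow(x$atoms),
    " atoms, dt = ", x$timestep_ps, " ps\n",
    sep = ""
  )
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `helix_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract one frame as an n x 3 coordinate matrix (nm)
#' @param traj A `helix_trajectory`.
#' @param i Frame index.
#' @return Numeric matrix `n_atoms x 3`.
#' @export
frame_coords <- function(traj, i = 1L) {
  traj$xyz[, , i, drop = TRUE]
}

# Row index of a named atom; errors if absent unless must = FALSE.
atom_index <- function(traj, resno, atom, must = TRUE) {
  i <- which(traj$atoms$resno == resno & traj$atoms$atom == atom)
  if (length(i) == 0L) {
    if (must) {
      abort(paste0("atom ", atom, " of residue ", resno, " not present"))
    }
    return(NA_integer_)
  }
  i[1]
}

#' Tidy a trajectory into a long tibble
#'
#' @param x A `helix_trajectory`.
#' @param ... Unused.
#' @return Tibble with one row per atom per frame: `frame`, `time_ps`,
#'   `resno`, `resid`, `atom`, `x`, `y`, `z` (nm).
#' @exportS3Method generics::tidy
tidy.helix_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- nrow(x$atoms)
  out <- tibble(
    frame = rep(seq_len(nf), each = na),
    time_ps = rep((seq_len(nf) - 1) * x$timestep_ps, each = na),
    resno = rep(x$atoms$resno, nf),
    resid = rep(x$atoms$resid, nf),
    atom = rep(x$atoms$atom, nf),
    x = as.numeric(x$xyz[, 1, ]),
    y = as.numeric(x$xyz[, 2, ]),
    z = as.numeric(x$xyz[, 3, ])
  )
  out
}

#' Plot the backbone trace of selected frames
#'
#' Projects CA positions onto the first two principal axes of the first frame
#' and draws the chain trace, one panel per frame.
#'
#' @param object A `helix_trajectory`.
#' @param frames Frame indices to draw (default: first frame).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.helix_trajectory <- function(object, frames = 1L, ...) {
  ca <- which(object$atoms$atom == "CA")
  ref <- object$xyz[ca, , frames[1], drop = TRUE]
  pr <- svd(sweep(ref, 2, colMeans(ref)))$v[, 1:2]
  dat <- purrr::map_dfr(frames, function(f) {
    xy <- sweep(object$xyz[ca, , f, drop = TRUE], 2, colMeans(ref)) %*% pr
    tibble(frame = f, resno = object$atoms$resno[ca], u = xy[, 1], v = xy[, 2])
  })
  ggplot(dat, aes(x = .data$u, y = .data$v)) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~frame) +
    labs(x = "principal axis 1 (nm)", y = "principal axis 2 (nm)") +
    theme_minimal()
}
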