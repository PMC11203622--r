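#' i -> i+4 backbone hydrogen-bond distance series
#'
#' Measures, per frame, the O(i)...H(i+4) distance between each residue's
#' carbonyl oxygen and the amide hydrogen four residues ahead, and classifies
#' the bond as formed when the distance is below the cutoff. Pairs whose
#' donor amide hydrogen does not exist (e.g. proline at i+4) are flagged
#' absent rather than dropped.
#'
#' @param traj A [new_trajectory()].
#' @param pairs Acceptor residue indices `i` to measure (default: all with
#'   `i + 4` in the chain).
#' @param cutoff_nm Hydrogen-bond cutoff; the conventional 0.35 nm default.
#' @return Tibble with `frame`, `acceptor` (i), `donor` (i+4),
#'   `distance_nm`, `formed`, `measurable`.
#' @examples
#' hbond_series(make_ideal_helix(relay_helix_peptide()))
#' @export
hbond_series <- function(traj, pairs = NULL, cutoff_nm = 0.35) {
  idx <- hbond_pair_index(traj, pairs)
  nf <- n_frames(traj)
  purrr::map_dfr(seq_len(nf), function(f) {
    d <- oh_distances(frame_coords(traj, f), idx)
    tibble(
      frame = f,
      acceptor = idx$pair,
      donor = idx$pair + 4L,
      distance_nm = d,
      measurable = !is.na(d),
      formed = ifelse(is.na(d), NA, d <= cutoff_nm)
    )
  })
}

#' Plot hydrogen-bond distance traces
#'
#' @param object Output of [hbond_series()].
#' @param cutoff_nm Cutoff line to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_hbond_series <- function(object, cutoff_nm = 0.35, ...) {
  ggplot(filter(object, .data$measurable),
         aes(x = .data$frame, y = .data$distance_nm,
             colour = factor(.data$acceptor))) +
    geom_line() +
    ggplot2::geom_hline(yintercept = cutoff_nm, linetype = 2) +
    labs(x = "frame", y = "O...H distance (nm)", colour = "pair i") +
    theme_minimal()
}

# frames x (3 * n_sel) coordinate matrix of selected atoms
traj_flat <- function(traj, sel) {
  nf <- n_frames(traj)
  t(vapply(seq_len(nf), function(f) {
    as.numeric(t(traj$xyz[sel, , f]))
  }, numeric(3 * length(sel))))
}

#' Principal component analysis of trajectory coordinates
#'
#' Two-pass alignment in the standard essential-dynamics protocol: heavy
#' atoms of every frame are superposed on the first frame, an average
#' structure is formed, frames are re-superposed on that average, and the
#' covariance matrix of the aligned coordinates is diagonalized.
#'
#' @param traj A [new_trajectory()] with at least 3 frames.
#' @param atom_selection `"heavy"` (default, all non-hydrogen atoms) or
#'   `"ca"`.
#' @param align Perform the superpositions? Disable for trajectories that are
#'   already aligned or for rigid-motion diagnostics.
#' @return An object of class `pca_result`: `eigenvalues` (descending),
#'   `eigenvectors` (columns, orthonormal), `projections`
#'   (frames x components), `mean` coordinates, the atom subset table, and a
#'   `degenerate` flag for identical-frame input.
#' @examples
#' helix <- make_ideal_helix(relay_helix_peptide())
#' traj <- make_trajectory(helix, 30, noise_nm = 0.01, seed = 4)
#' p <- pca_trajectory(traj)
#' head(p$eigenvalues)
#' @export
pca_trajectory <- function(traj, atom_selection = c("heavy", "ca"),
                           align = TRUE) {
  atom_selection <- match.arg(atom_selection)
  if (n_frames(traj) < 3L) abort("PCA needs at least 3 frames")
  sel <- switch(
    atom_selection,
    heavy = which(!traj$atoms$atom %in% c("H", "HT")),
    ca = which(traj$atoms$atom == "CA")
  )
  x <- traj_flat(traj, sel)
  if (align) {
    x <- bio3d::fit.xyz(fixed = x[1, ], mobile = x,
                        fixed.inds = seq_len(ncol(x)),
                        mobile.inds = seq_len(ncol(x)))
    avg <- colMeans(x)
    x <- bio3d::fit.xyz(fixed = avg, mobile = x,
                        fixed.inds = seq_len(ncol(x)),
                        mobile.inds = seq_len(ncol(x)))
  }
  mu <- colMeans(x)
  cv <- stats::cov(x)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  degenerate <- sum(vals) < 1e-20
  if (degenerate) warn("identical frames: all PCA eigenvalues are zero")
  proj <- sweep(x, 2, mu) %*% e$vectors
  structure(
    list(
      eigenvalues = vals,
      eigenvectors = e$vectors,
      projections = proj,
      mean = mu,
      atoms = traj$atoms[sel, ],
      atom_rows = sel,
      timestep_ps = traj$timestep_ps,
      degenerate = degenerate
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  v <- x$eigenvalues
  cat("<pca_result> ", length(v), " modes; leading variance fractions: ",
      paste(round(head(v, 3) / max(sum(v), 1e-300), 3), collapse = ", "),
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' @rdname pca_trajectory
#' @param x,object A `pca_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pca_result <- function(x, ...) {
  tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$eigenvalues / max(sum(x$eigenvalues), 1e-300)
  )
}

#' @rdname pca_trajectory
#' @exportS3Method ggplot2::autoplot
autoplot.pca_result <- function(object, ...) {
  dat <- tibble(frame = seq_len(nrow(object$projections)),
                pc1 = object$projections[, 1],
                pc2 = object$projections[, 2])
  ggplot(dat, aes(x = .data$pc1, y = .data$pc2, colour = .data$frame)) +
    geom_point() +
    labs(x = "projection on PC1 (nm)", y = "projection on PC2 (nm)") +
    theme_minimal()
}

#' Pseudo-trajectory along one principal component
#'
#' Sweeps the mean structure along an eigenvector between the minimum and
#' maximum projections observed in the trajectory, in `n_frames` linear
#' steps; with `n_frames = 2` exactly the two extreme structures result.
#'
#' @param p A [pca_trajectory()] result.
#' @param component Principal-component index.
#' @param n_frames Number of frames to generate (>= 2).
#' @return A [new_trajectory()] over the PCA atom subset.
#' @export
pseudo_trajectory <- function(p, component = 1L, n_frames = 20L) {
  if (component < 1L || component > ncol(p$eigenvectors)) {
    abort("`component` outside the available rank")
  }
  if (n_frames < 2L) abort("`n_frames` must be >= 2")
  pr <- p$projections[, component]
  lambda <- seq(min(pr), max(pr), length.out = n_frames)
  ev <- p$eigenvectors[, component]
  na <- nrow(p$atoms)
  xyz <- array(0, dim = c(na, 3L, n_frames))
  for (k in seq_len(n_frames)) {
    xyz[, , k] <- matrix(p$mean + lambda[k] * ev, ncol = 3L, byrow = TRUE)
  }
  new_trajectory(xyz, p$atoms, timestep_ps = p$timestep_ps)
}
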