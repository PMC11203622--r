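#' Generate a noisy multi-frame trajectory with switchable hydrogen bonds
#'
#' Emulates picosecond break/re-form dynamics of designated i -> i+4 hydrogen
#' bonds with a two-state (formed/broken) symmetric Markov chain per frame,
#' superimposed with isotropic Gaussian coordinate noise. The broken-state
#' geometry of each switching-pair combination is the hinge construction of
#' [make_bent_helix()], so the switching is statistical, not mechanical.
#' Everything is a pure function of the arguments and `seed`.
#'
#' @param base Single-frame trajectory from [make_ideal_helix()] or
#'   [make_bent_helix()] (its stored [peptide_spec()] is required when
#'   `switch_pairs` is used).
#' @param n_frames Number of frames (>= 1).
#' @param noise_nm Standard deviation of per-atom isotropic Gaussian noise (nm).
#' @param switch_prob Per-frame probability of toggling each switching pair
#'   between formed and broken.
#' @param seed Integer seed; identical calls are bit-identical.
#' @param switch_pairs Optional list of `c(i, i + 4)` pairs that toggle. All
#'   pairs share one state ensemble but switch independently.
#'
#' @return A [new_trajectory()] with `n_frames` frames; the per-frame broken
#'   state of each switching pair is stored in attribute `"hbond_states"`
#'   (frames x pairs logical matrix, TRUE = broken).
#' @examples
#' helix <- make_ideal_helix(relay_helix_peptide())
#' traj <- make_trajectory(helix, n_frames = 50, noise_nm = 0.002,
#'                         switch_prob = 0.1, seed = 1,
#'                         switch_pairs = list(c(22, 26)))
#' @export
make_trajectory <- function(base, n_frames, noise_nm = 0, switch_prob = 0,
                            seed = 1L, switch_pairs = NULL) {
  if (!inherits(base, "helix_trajectory")) abort("`base` must be a helix_trajectory")
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  if (noise_nm < 0) abort("`noise_nm` must be >= 0")
  if (switch_prob < 0 || switch_prob > 1) abort("`switch_prob` must be in [0, 1]")
  n_frames <- as.integer(n_frames)
  base_xyz <- frame_coords(base, 1)
  na <- nrow(base_xyz)

  n_pairs <- length(switch_pairs)
  if (n_pairs > 0 && is.null(base$spec)) {
    abort("hydrogen-bond switching needs a trajectory with a stored peptide_spec")
  }
  base_broken <- attr(base, "broken_pairs") %||% integer(0)

  withr::with_seed(as.integer(seed), {
    states <- matrix(FALSE, n_frames, max(1L, n_pairs))
    if (n_pairs > 0) {
      switch_pairs <- lapply(switch_pairs, as.integer)
      st <- vapply(seq_len(n_pairs), function(p) {
        switch_pairs[[p]][1] %in% base_broken
      }, logical(1))
      for (f in seq_len(n_frames)) {
        if (f > 1L && switch_prob > 0) {
          flip <- runif(n_pairs) < switch_prob
          st <- xor(st, flip)
        }
        states[f, ] <- st
      }
    }

    # geometry per distinct state combination, cached
    geom_cache <- list()
    frame_geom <- function(st) {
      key <- paste(as.integer(st), collapse = "")
      if (!is.null(geom_cache[[key]])) return(geom_cache[[key]])
      broken_idx <- sort(unique(c(
        setdiff(base_broken, vapply(switch_pairs, `[`, integer(1), 1)),
        vapply(switch_pairs[st], `[`, integer(1), 1)
      )))
      g <- if (length(broken_idx) == 0L && length(base_broken) == 0L) {
        base_xyz
      } else {
        frame_coords(make_bent_helix(
          base$spec, lapply(broken_idx, function(i) c(i, i + 4L)),
          phi_deg = base$dihedrals$phi[1] %||% -57.8,
          psi_deg = base$dihedrals$psi[1] %||% -47.0
        ), 1)
      }
      geom_cache[[key]] <<- g
      g
    }

    xyz <- array(0, dim = c(na, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      g <- if (n_pairs > 0) frame_geom(states[f, ]) else base_xyz
      noise <- if (noise_nm > 0) {
        matrix(rnorm(na * 3L, sd = noise_nm), na, 3L)
      } else {
        0
      }
      xyz[, , f] <- g + noise
    }
  })

  out <- new_trajectory(xyz, base$atoms, timestep_ps = base$timestep_ps,
                        spec = base$spec, dihedrals = base$dihedrals)
  if (n_pairs > 0) {
    colnames(states) <- vapply(switch_pairs, function(p) {
      paste0(p[1], "-", p[2])
    }, character(1))
    attr(out, "hbond_states") <- states
  }
  out
}
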