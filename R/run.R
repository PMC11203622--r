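# Config-driven pipeline runner. Every stage validates its parameter schema
# (unknown keys rejected, stochastic stages require an explicit seed), writes
# its artifact, and drops a provenance sidecar (<out>.meta.json with config
# hash, seed and package version) next to every output file.

STAGE_SCHEMAS <- list(
  synth_helix = list(
    required = c("sequence", "out"),
    optional = c("n_terminal_cap", "c_terminal", "phi_deg", "psi_deg", "breaks"),
    stochastic = FALSE
  ),
  synth_traj = list(
    required = c("sequence", "n_frames", "out", "seed"),
    optional = c("n_terminal_cap", "c_terminal", "phi_deg", "psi_deg",
                 "breaks", "noise_nm", "switch_prob", "switch_pairs"),
    stochastic = TRUE
  ),
  synth_2dir = list(
    required = c("peaks", "omega_tau", "omega_m", "out"),
    optional = c("t_w"),
    stochastic = FALSE
  ),
  synth_decay = list(
    required = c("a1", "b1", "a2", "b2", "t_grid", "out", "seed"),
    optional = c("noise_sd"),
    stochastic = TRUE
  ),
  synth_cd = list(
    required = c("fh_by_t", "nr", "out"),
    optional = character(),
    stochastic = FALSE
  ),
  synth_well = list(
    required = c("dg_kjmol", "barrier_kjmol", "minima", "out"),
    optional = c("sigma_nm", "grid_n"),
    stochastic = FALSE
  ),
  ham_linear = list(
    required = c("traj", "out"),
    optional = c("lifetime_ps", "grid", "t_max_ps", "n_starts", "timestep_ps"),
    stochastic = FALSE
  ),
  twodir = list(
    required = c("traj", "out"),
    optional = c("t_w", "anharmonicity", "lifetime_ps", "t1_max", "t3_max",
                 "grid", "n_starts", "timestep_ps"),
    stochastic = FALSE
  ),
  fit2d = list(
    required = c("spectrum", "out"),
    optional = c("preset", "with_cross"),
    stochastic = FALSE
  ),
  pp_fit = list(
    required = c("decay", "out"),
    optional = c("t_min_ps"),
    stochastic = FALSE
  ),
  cd_helicity = list(
    required = c("cd", "nr", "out"),
    optional = character(),
    stochastic = FALSE
  ),
  conf_hbond = list(
    required = c("traj", "out"),
    optional = c("cutoff_nm"),
    stochastic = FALSE
  ),
  conf_metad = list(
    required = c("dg_kjmol", "barrier_kjmol", "minima", "steps", "out", "seed"),
    optional = c("sigma_nm", "height", "pace", "width", "biasfactor",
                 "temperature_k", "grid_n"),
    stochastic = TRUE
  ),
  conf_fes = list(
    required = c("fes", "out"),
    optional = c("temperature_k"),
    stochastic = FALSE
  )
)

validate_config <- function(stage, config) {
  schema <- STAGE_SCHEMAS[[stage]]
  if (is.null(schema)) {
    abort(paste0("unknown stage '", stage, "'; available: ",
                 paste(names(STAGE_SCHEMAS), collapse = ", ")))
  }
  keys <- names(config)
  unknown <- setdiff(keys, c(schema$required, schema$optional))
  if (length(unknown)) {
    abort(paste0("unknown config key(s) for stage ", stage, ": ",
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(schema$required, keys)
  if (length(missing)) {
    abort(paste0("missing required config key(s) for stage ", stage, ": ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

axis_from <- function(x) {
  if (is.list(x) && all(c("from", "to", "by") %in% names(x))) {
    seq(x$from, x$to, by = x$by)
  } else {
    as.numeric(x)
  }
}

spec_from_config <- function(config) {
  peptide_spec(
    config$sequence,
    n_terminal_cap = config$n_terminal_cap %||% "acetyl",
    c_terminal = config$c_terminal %||% "carboxylic_acid"
  )
}

pairs_from_config <- function(x) lapply(x, function(p) as.integer(unlist(p)))

write_provenance <- function(out, stage, config) {
  side <- paste0(out, ".meta.json")
  payload <- list(
    stage = stage,
    config_hash = rlang::hash(config),
    seed = config$seed %||% NA,
    package = "helixspec",
    version = as.character(utils::packageVersion("helixspec"))
  )
  atomic_write(side, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, pretty = TRUE)
  })
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches to the package's generators and analyses from a named list (or
#' JSON file) of typed parameters, writes the stage artifact plus a
#' provenance sidecar, and returns the computed object invisibly. Unknown
#' keys are rejected with the offending name; stochastic stages must carry an
#' explicit `seed`.
#'
#' @param stage One of `synth_helix`, `synth_traj`, `synth_2dir`,
#'   `synth_decay`, `synth_cd`, `synth_well`, `ham_linear`, `twodir`,
#'   `fit2d`, `pp_fit`, `cd_helicity`, `conf_hbond`, `conf_metad`,
#'   `conf_fes`.
#' @param config Named list of stage parameters, or a path to a JSON file
#'   containing them.
#' @return The computed object, invisibly; artifacts land at `config$out`.
#' @examples
#' \donttest{
#' out <- tempfile(fileext = ".pdb")
#' run_stage("synth_helix", list(sequence = "ALAALAALAA", out = out))
#' }
#' @export
run_stage <- function(stage, config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  validate_config(stage, config)
  out <- config$out
  result <- switch(
    stage,
    synth_helix = {
      spec <- spec_from_config(config)
      traj <- if (length(config$breaks %||% list())) {
        make_bent_helix(spec, pairs_from_config(config$breaks),
                        phi_deg = config$phi_deg %||% -57.8,
                        psi_deg = config$psi_deg %||% -47.0)
      } else {
        make_ideal_helix(spec, config$phi_deg %||% -57.8,
                         config$psi_deg %||% -47.0)
      }
      write_trajectory_pdb(traj, out)
      traj
    },
    synth_traj = {
      spec <- spec_from_config(config)
      base <- if (length(config$breaks %||% list())) {
        make_bent_helix(spec, pairs_from_config(config$breaks))
      } else {
        make_ideal_helix(spec)
      }
      traj <- make_trajectory(
        base, config$n_frames, noise_nm = config$noise_nm %||% 0,
        switch_prob = config$switch_prob %||% 0, seed = config$seed,
        switch_pairs = if (length(config$switch_pairs %||% list())) {
          pairs_from_config(config$switch_pairs)
        }
      )
      write_trajectory_pdb(traj, out)
      traj
    },
    synth_2dir = {
      s <- make_synthetic_2dir(
        dplyr::bind_rows(lapply(config$peaks, as_tibble)),
        axis_from(config$omega_tau), axis_from(config$omega_m),
        t_w = config$t_w %||% 0
      )
      write_spectrum2d(s, out)
      s
    },
    synth_decay = {
      d <- make_biexp_decay(config$a1, config$b1, config$a2, config$b2,
                            axis_from(config$t_grid),
                            noise_sd = config$noise_sd %||% 0,
                            seed = config$seed)
      atomic_write(out, function(tmp) readr::write_tsv(d, tmp))
      d
    },
    synth_cd = {
      d <- make_cd_curve(dplyr::bind_rows(lapply(config$fh_by_t, as_tibble)),
                         nr = config$nr)
      atomic_write(out, function(tmp) readr::write_tsv(d, tmp))
      d
    },
    synth_well = {
      w <- make_double_well(config$dg_kjmol, config$barrier_kjmol,
                            lapply(config$minima, unlist),
                            sigma_nm = config$sigma_nm)
      n <- config$grid_n %||% 121L
      gx <- seq(w$domain[1, 1], w$domain[2, 1], length.out = n)
      gy <- seq(w$domain[1, 2], w$domain[2, 2], length.out = n)
      z <- matrix(w$fn(as.matrix(expand.grid(gx, gy))), n, n)
      fes <- new_fes_grid(gx, gy, z - min(z))
      write_fes(fes, out)
      w
    },
    ham_linear = {
      traj <- read_trajectory_pdb(config$traj,
                                  timestep_ps = config$timestep_ps %||% 0.02)
      traj$spec <- guess_spec(traj)
      hs <- build_hamiltonian_series(traj)
      s <- linear_spectrum_td(
        hs, lifetime_ps = config$lifetime_ps %||% 1,
        grid = if (is.null(config$grid)) seq(1500, 1800, 0.5) else axis_from(config$grid),
        t_max_ps = config$t_max_ps %||% 16,
        n_starts = config$n_starts %||% 1L
      )
      write_spectrum1d(s, out)
      s
    },
    twodir = {
      traj <- read_trajectory_pdb(config$traj,
                                  timestep_ps = config$timestep_ps %||% 0.02)
      traj$spec <- guess_spec(traj)
      hs <- build_hamiltonian_series(traj)
      grid <- if (is.null(config$grid)) seq(1600, 1700, 1) else axis_from(config$grid)
      s <- absorptive(response_functions(
        hs, t_w = config$t_w %||% 0,
        t1_max = config$t1_max %||% 2, t3_max = config$t3_max %||% 2,
        anharmonicity = config$anharmonicity %||% 16,
        lifetime_ps = config$lifetime_ps %||% 1,
        n_starts = config$n_starts %||% 1L
      ), grid, grid)
      write_spectrum2d(s, out)
      s
    },
    fit2d = {
      s <- read_spectrum2d(config$spectrum)
      fit <- fit_peaks2d(s, config = config$preset %||% "experimental",
                         with_cross = config$with_cross %||% TRUE)
      atomic_write(out, function(tmp) {
        jsonlite::write_json(
          list(model = fit$model, residual = fit$residual,
               converged = fit$converged, t_w = fit$t_w),
          tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE
        )
      })
      fit
    },
    pp_fit = {
      d <- readr::read_tsv(config$decay, col_types = "dd", progress = FALSE)
      fit <- biexp_fit(d, t_min_ps = config$t_min_ps %||% 0.5)
      atomic_write(out, function(tmp) {
        jsonlite::write_json(
          list(a1 = fit$a1, b1 = fit$b1, a2 = fit$a2, b2 = fit$b2,
               residual = fit$residual, reduced = fit$reduced,
               null_fit = fit$null_fit),
          tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE
        )
      })
      fit
    },
    cd_helicity = {
      d <- readr::read_tsv(config$cd, col_types = readr::cols(), progress = FALSE)
      res <- helical_fraction(d$theta_222, d$temperature_c, nr = config$nr)
      atomic_write(out, function(tmp) readr::write_tsv(res, tmp))
      res
    },
    conf_hbond = {
      traj <- read_trajectory_pdb(config$traj)
      traj$spec <- guess_spec(traj)
      hb <- hbond_series(traj, cutoff_nm = config$cutoff_nm %||% 0.35)
      atomic_write(out, function(tmp) readr::write_tsv(hb, tmp))
      hb
    },
    conf_metad = {
      w <- make_double_well(config$dg_kjmol, config$barrier_kjmol,
                            lapply(config$minima, unlist),
                            sigma_nm = config$sigma_nm)
      fes <- wtmetad(
        w, steps = config$steps, height = config$height %||% 1.2,
        pace = config$pace %||% 500L, width = config$width %||% 0.05,
        biasfactor = config$biasfactor %||% 6.0,
        temperature_k = config$temperature_k %||% 298.15,
        seed = config$seed, grid_n = config$grid_n %||% 81L
      )
      write_fes(fes, out)
      fes
    },
    conf_fes = {
      fes <- read_fes(config$fes)
      an <- fes_analyze(fes, temperature_k = config$temperature_k)
      atomic_write(out, function(tmp) {
        jsonlite::write_json(
          list(minima = an$minima, barriers = an$barriers,
               kt_kjmol = an$kt_kjmol),
          tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE
        )
      })
      an
    }
  )
  write_provenance(out, stage, config)
  invisible(result)
}

# Reconstruct a peptide_spec from a parsed trajectory's residue table
# (sequence from 3-letter codes; caps from ACE / OXT / NT markers).
guess_spec <- function(traj) {
  at <- traj$atoms
  resnos <- sort(unique(at$resno[at$resno > 0]))
  codes <- vapply(resnos, function(r) {
    names(AA3)[match(at$resid[at$resno == r][1], AA3)]
  }, character(1))
  if (anyNA(codes)) abort("trajectory contains residues outside the 20 standard amino acids")
  peptide_spec(
    paste(codes, collapse = ""),
    n_terminal_cap = if (any(at$resno == 0L)) "acetyl" else "none",
    c_terminal = if (any(at$atom == "NT")) "amide" else "carboxylic_acid"
  )
}
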