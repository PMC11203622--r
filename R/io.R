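# File I/O. Coordinates are nm internally; PDB files are Angstrom, converted
# at this boundary. All writers go through a temp-file + rename so partial
# files are never left behind.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort(paste0("could not write ", path))
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Each frame becomes one MODEL/ENDMDL block; coordinates are converted from
#' nm to Angstrom. Residue numbering is 1-based with the acetyl cap as
#' residue 0 (`ACE`).
#'
#' @param traj A [new_trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  at <- traj$atoms
  nf <- n_frames(traj)
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("REMARK   generated by helixspec, %d frame(s)", nf), con)
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- frame_coords(traj, f) * 10 # nm -> Angstrom
      lines <- sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        seq_len(nrow(at)),
        ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom),
        at$resid, "A", at$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0
      )
      writeLines(lines, con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  })
}

# light pre-validation so parse errors carry line numbers
validate_pdb_lines <- function(lines) {
  atom_lines <- grep("^ATOM|^HETATM", lines)
  for (i in atom_lines) {
    l <- lines[i]
    if (nchar(l) < 54) {
      abort(paste0("malformed PDB ATOM record (truncated) at line ", i))
    }
    coords <- c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      abort(paste0("malformed PDB coordinates at line ", i))
    }
  }
  invisible(TRUE)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Honors the MODEL/ENDMDL dialect, preserves atom order and converts
#' Angstrom to nm. Malformed ATOM records raise an error naming the line.
#'
#' @param path PDB file.
#' @param timestep_ps Frame spacing to record (ps).
#' @return A [new_trajectory()].
#' @export
read_trajectory_pdb <- function(path, timestep_ps = 0.02) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- tibble(
    resno = as.integer(pdb$atom$resno),
    resid = pdb$atom$resid,
    atom = pdb$atom$elety
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(at)
  arr <- array(0, dim = c(na, 3L, nf))
  for (f in seq_len(nf)) {
    arr[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  }
  new_trajectory(arr, at, timestep_ps = timestep_ps)
}

#' Write / read a 1D spectrum as 2-column TSV
#'
#' @param s A [new_spectrum1d()].
#' @param path File path.
#' @return `path` (write) or a `spectrum1d` (read).
#' @export
write_spectrum1d <- function(s, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines("# frequency_cm1\tintensity", con)
    writeLines(sprintf("%.17g\t%.17g", s$frequency, s$intensity), con)
  })
}

#' @rdname write_spectrum1d
#' @export
read_spectrum1d <- function(path) {
  d <- readr::read_tsv(path, comment = "#",
                       col_names = c("frequency", "intensity"),
                       col_types = "dd", progress = FALSE)
  if (nrow(d) == 0L) abort(paste0("empty or unreadable spectrum file: ", path))
  new_spectrum1d(d$frequency, d$intensity, meta = list(source = path))
}

#' Write / read a 2D spectrum as long-format TSV
#'
#' Columns `omega_tau`, `omega_m`, `intensity`; wait time and component are
#' stored in header comments and restored on read.
#'
#' @param s A [new_spectrum2d()].
#' @param path File path.
#' @return `path` (write) or a `spectrum2d` (read).
#' @export
write_spectrum2d <- function(s, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(
      sprintf("# t_w_ps: %.17g", s$t_w),
      sprintf("# component: %s", s$component),
      "# omega_tau\tomega_m\tintensity"
    ), con)
    d <- tidy(s)
    writeLines(sprintf("%.17g\t%.17g\t%.17g", d$omega_tau, d$omega_m,
                       d$intensity), con)
  })
}

#' @rdname write_spectrum2d
#' @export
read_spectrum2d <- function(path) {
  hdr <- readLines(path, n = 10L)
  tw <- as.numeric(sub("^# t_w_ps: ", "", grep("^# t_w_ps:", hdr, value = TRUE)[1]))
  comp <- sub("^# component: ", "", grep("^# component:", hdr, value = TRUE)[1])
  d <- readr::read_tsv(path, comment = "#",
                       col_names = c("omega_tau", "omega_m", "intensity"),
                       col_types = "ddd", progress = FALSE)
  if (nrow(d) == 0L) abort(paste0("empty or unreadable spectrum file: ", path))
  ot <- sort(unique(d$omega_tau))
  om <- sort(unique(d$omega_m))
  if (nrow(d) != length(ot) * length(om)) {
    abort(paste0("incomplete 2D grid in ", path))
  }
  z <- matrix(NA_real_, length(ot), length(om))
  z[cbind(match(d$omega_tau, ot), match(d$omega_m, om))] <- d$intensity
  new_spectrum2d(ot, om, z, t_w = if (is.na(tw)) 0 else tw,
                 component = if (is.na(comp) || !comp %in%
                                 c("absorptive", "rephasing", "nonrephasing"))
                   "absorptive" else comp,
                 meta = list(source = path))
}

#' Write / read a free-energy surface in PLUMED-style grid text
#'
#' Whitespace-delimited columns `d1 d2 free_energy` with a `#! FIELDS` header
#' line, row-major over d2 blocks.
#'
#' @param fes An [new_fes_grid()].
#' @param path File path.
#' @return `path` (write) or an `fes_grid` (read).
#' @export
write_fes <- function(fes, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(
      "#! FIELDS d1 d2 file.free",
      sprintf("#! SET temperature_k %.17g", fes$temperature_k)
    ), con)
    d <- tidy(fes)
    writeLines(sprintf("%.17g %.17g %.17g", d$d1, d$d2, d$free_energy), con)
  })
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  hdr <- readLines(path, n = 5L)
  tk_line <- grep("^#! SET temperature_k", hdr, value = TRUE)
  tk <- if (length(tk_line)) as.numeric(sub("^#! SET temperature_k ", "", tk_line[1])) else 298.15
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("d1", "d2", "free_energy"))
  if (nrow(d) == 0L) abort(paste0("empty FES file: ", path))
  x <- sort(unique(d$d1))
  y <- sort(unique(d$d2))
  if (nrow(d) != length(x) * length(y)) abort(paste0("incomplete FES grid in ", path))
  z <- matrix(NA_real_, length(x), length(y))
  z[cbind(match(d$d1, x), match(d$d2, y))] <- d$free_energy
  new_fes_grid(x, y, z, temperature_k = tk, meta = list(source = path))
}
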