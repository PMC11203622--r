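#' Describe a peptide and its terminal chemistry
#'
#' A `peptide_spec` records the one-letter sequence plus the N-terminal cap
#' and C-terminal group. These three pieces determine the backbone topology
#' used by the structure generators and the number of amide I chromophores
#' counted by [enumerate_oscillators()].
#'
#' @param sequence One-letter amino-acid string (length >= 2).
#' @param n_terminal_cap `"acetyl"` or `"none"`.
#' @param c_terminal `"carboxylic_acid"` or `"amide"`.
#'
#' @return An object of class `peptide_spec`.
#' @examples
#' peptide_spec("ALAALAALAA")
#' @export
peptide_spec <- function(sequence,
                         n_terminal_cap = c("acetyl", "none"),
                         c_terminal = c("carboxylic_acid", "amide")) {
  n_terminal_cap <- match.arg(n_terminal_cap)
  c_terminal <- match.arg(c_terminal)
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("`sequence` must be a single string")
  }
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) < 2L) {
    abort("`sequence` must contain at least 2 residues")
  }
  ok <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, ok)
  if (length(bad) > 0L) {
    abort(paste0("unknown residue code(s): ", paste(unique(bad), collapse = ", ")))
  }
  structure(
    list(
      sequence = sequence,
      residues = res,
      n_residues = length(res),
      n_terminal_cap = n_terminal_cap,
      c_terminal = c_terminal
    ),
    class = "peptide_spec"
  )
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(
    "<peptide_spec> ", x$n_residues, " residues, N-cap: ", x$n_terminal_cap,
    ", C-terminus: ", x$c_terminal, "\n  ", x$sequence, "\n",
    sep = ""
  )
  invisible(x)
}

#' The myosin relay helix peptide
#'
#' The 35-residue peptide spanning the relay helix of Dictyostelium myosin II
#' (residues 465-499), acetyl-capped at the N-terminus with a free carboxylic
#' acid at the C-terminus. Its bent/straight interconversion couples ATP
#' hydrolysis to the myosin power stroke, and with these caps it carries 36
#' amide I oscillators.
#'
#' @return A [peptide_spec()].
#' @examples
#' relay_helix_peptide()
#' @export
relay_helix_peptide <- function() {
  peptide_spec(
    "SFEQLCINYTNEKLQQFFNHHMFKVEQEEYLKEKI",
    n_terminal_cap = "acetyl",
    c_terminal = "carboxylic_acid"
  )
}

AA3 <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR"
)
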