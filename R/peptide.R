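# Peptide bookkeeping: sequences, average residue masses, presets.

# Average (isotope-abundance weighted) residue masses in Da, i.e. the mass of
# the amino acid minus one water; add 18.0153 Da per chain for the termini.
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS <- 18.0153

#' Define a peptide for the coarse-grained generator
#'
#' A peptide is modelled as one bead per residue. Surface residues are the
#' positions that form the solvent-accessible surface of the assemblies (for
#' R5, the C-terminal RRIL motif); they keep stronger NMR signals and lose
#' them faster during silicification.
#'
#' @param name Label for the peptide.
#' @param sequence One-letter amino-acid sequence (20 standard codes).
#' @param per_residue_mass Optional numeric vector of per-residue masses in
#'   Da (defaults to the average residue-mass table).
#' @param bead_radius Bead radius in Angstrom (default 3.0).
#' @param surface_residues Integer vector of 1-based residue indices flagged
#'   as assembly-surface residues.
#' @return An object of class `peptide_spec`.
#' @export
#' @examples
#' pep <- peptide_spec("R5", "SSKKSGSYSGSKGSKRRIL", surface_residues = 16:19)
#' peptide_mass(pep)
peptide_spec <- function(name, sequence, per_residue_mass = NULL,
                         bead_radius = 3.0, surface_residues = integer(0)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(AVERAGE_RESIDUE_MASS))
  if (length(bad)) {
    stop("invalid residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  n <- length(res)
  if (is.null(per_residue_mass)) {
    per_residue_mass <- unname(AVERAGE_RESIDUE_MASS[res])
  }
  stopifnot(length(per_residue_mass) == n)
  if (any(per_residue_mass <= 0)) stop("masses must be > 0", call. = FALSE)
  surface_residues <- as.integer(surface_residues)
  if (length(surface_residues) &&
      (any(surface_residues < 1L) || any(surface_residues > n))) {
    stop("surface_residues outside 1..", n, call. = FALSE)
  }
  stop_if_not_scalar_pos(bead_radius, "bead_radius")
  structure(
    list(name = name, sequence = sequence, residues = res,
         per_residue_mass = per_residue_mass, bead_radius = bead_radius,
         surface_residues = sort(unique(surface_residues))),
    class = "peptide_spec"
  )
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat("<peptide_spec> ", x$name, ": ", x$sequence,
      " (", length(x$residues), " residues, ",
      sprintf("%.1f", peptide_mass(x)), " Da)\n", sep = "")
  if (length(x$surface_residues)) {
    cat("  surface residues:", paste(x$surface_residues, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param spec A `peptide_spec`, or a one-letter sequence string.
#' @return Mass in Da.
#' @export
#' @examples
#' peptide_mass("G")   # glycine, 75.07 Da
peptide_mass <- function(spec) {
  if (is.character(spec)) spec <- peptide_spec("peptide", spec)
  stopifnot(inherits(spec, "peptide_spec"))
  sum(spec$per_residue_mass) + WATER_MASS
}

#' Preset: the R5 silaffin-derived peptide
#'
#' 19-mer SSKKSGSYSGSKGSKRRIL. The C-terminal RRIL motif (residues 16-19)
#' carries the arginines that trap phosphate counterions and sits on the
#' solvent-accessible surface of the self-assemblies.
#' @return A `peptide_spec`.
#' @export
r5_peptide <- function() {
  peptide_spec("R5", "SSKKSGSYSGSKGSKRRIL", surface_residues = 16:19)
}

#' Preset: the synSil-1A1 peptide backbone
#'
#' 15-mer sharing the R5 primary sequence but lacking the RRIL motif; in the
#' real molecule every serine is phosphorylated and the lysines carry
#' polyamine/phosphocholine modifications (represented here only through the
#' LCPA counterion bridges). The central K12, the dominant LCPA interaction
#' site, is flagged as surface.
#' @return A `peptide_spec`.
#' @export
synsil_peptide <- function() {
  peptide_spec("synSil-1A1", "SSKKSGSYSGSKGSK", surface_residues = 12L)
}
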