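# NMR data containers: peak tables, DOSY series, kinetic traces.

# Gyromagnetic ratio of 1H in rad s^-1 T^-1.
GAMMA_1H <- 2.6752218744e8

# Boltzmann constant, J/K.
KB <- 1.380649e-23

#' Construct a peak table
#'
#' One record per residue: two chemical shifts (e.g. 1H and 15N in a
#' 1H-15N HSQC) and a peak intensity.
#'
#' @param residue Integer residue indices (unique).
#' @param label Residue labels (e.g. "S1", "R16").
#' @param shift_a First-dimension chemical shift in ppm.
#' @param shift_b Second-dimension chemical shift in ppm.
#' @param intensity Peak intensity (arbitrary units, >= 0); `NA` marks a
#'   peak below the detection threshold.
#' @param nucleus Nucleus pair tag: "H-N", "C-N" or "H-P".
#' @return An object of class `peak_table` (a data.frame).
#' @export
peak_table <- function(residue, label = NULL, shift_a, shift_b, intensity,
                       nucleus = c("H-N", "C-N", "H-P")) {
  nucleus <- match.arg(nucleus)
  residue <- as.integer(residue)
  if (anyDuplicated(residue)) stop("residue indices must be unique",
                                   call. = FALSE)
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  df <- data.frame(
    residue = residue,
    label = as.character(label %||% paste0("r", residue)),
    shift_a = as.numeric(shift_a), shift_b = as.numeric(shift_b),
    intensity = as.numeric(intensity),
    stringsAsFactors = FALSE
  )
  attr(df, "nucleus") <- nucleus
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Construct a DOSY series
#'
#' Gradient-strength/integral pairs plus the acquisition constants required
#' by the Stejskal-Tanner fit and the Stokes-Einstein conversion.
#'
#' @param gradient Gradient strengths in T/m, non-negative and strictly
#'   increasing, at least 5 points.
#' @param integral Signal integrals (arbitrary units).
#' @param Delta Diffusion delay in s.
#' @param delta Gradient pulse length in s (must be < Delta).
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1 (default: 1H).
#' @param temperature Sample temperature in K.
#' @param viscosity Solvent viscosity in Pa s.
#' @return An object of class `dosy_series` (a data.frame).
#' @export
dosy_series <- function(gradient, integral, Delta = 0.06, delta = 0.015,
                        gamma = GAMMA_1H, temperature = 298.15,
                        viscosity = 8.937e-4) {
  gradient <- as.numeric(gradient)
  integral <- as.numeric(integral)
  if (length(gradient) < 5L) stop("need at least 5 gradient points",
                                  call. = FALSE)
  if (any(gradient < 0)) stop("gradient strengths must be non-negative",
                              call. = FALSE)
  if (any(diff(gradient) <= 0)) {
    stop("gradient grid must be strictly increasing", call. = FALSE)
  }
  if (delta >= Delta) stop("delta must be smaller than Delta", call. = FALSE)
  df <- data.frame(gradient = gradient, integral = integral)
  attr(df, "Delta") <- Delta
  attr(df, "delta") <- delta
  attr(df, "gamma") <- gamma
  attr(df, "temperature") <- temperature
  attr(df, "viscosity") <- viscosity
  class(df) <- c("dosy_series", "data.frame")
  df
}

# Stejskal-Tanner attenuation factor b(g) such that I = I0 exp(-D b).
st_b_factor <- function(series) {
  g <- series$gradient
  attr(series, "gamma")^2 * g^2 * attr(series, "delta")^2 *
    (attr(series, "Delta") - attr(series, "delta") / 3)
}

#' Construct kinetic traces
#'
#' Time grid by residue matrix of normalized signal intensities from
#' real-time monitoring of silicification.
#'
#' @param time Time grid in s, strictly increasing.
#' @param intensities Matrix (time x residue) of intensities; each column is
#'   normalized to its first point.
#' @param residues Integer residue indices, one per column.
#' @param surface_residues Residue indices flagged as assembly-surface.
#' @param normalize Normalize columns to their first point (default TRUE).
#' @return An object of class `kinetic_traces`.
#' @export
kinetic_traces <- function(time, intensities, residues = NULL,
                           surface_residues = integer(0), normalize = TRUE) {
  time <- as.numeric(time)
  if (!length(time)) stop("empty time grid", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing",
                                 call. = FALSE)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(time)) {
    stop("intensity matrix must have one row per time point", call. = FALSE)
  }
  residues <- as.integer(residues %||% seq_len(ncol(intensities)))
  stopifnot(length(residues) == ncol(intensities))
  if (normalize) {
    first <- intensities[1, ]
    if (any(first == 0)) stop("first-point intensity is zero; cannot normalize",
                              call. = FALSE)
    intensities <- sweep(intensities, 2, first, "/")
  }
  colnames(intensities) <- paste0("r", residues)
  structure(
    list(time = time, intensities = intensities, residues = residues,
         surface_residues = as.integer(surface_residues)),
    class = "kinetic_traces"
  )
}

#' @export
print.kinetic_traces <- function(x, ...) {
  cat("<kinetic_traces> ", length(x$time), " time points x ",
      length(x$residues), " residues", sep = "")
  if (length(x$surface_residues)) {
    cat(" (surface: ", paste(x$surface_residues, collapse = ","), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}
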