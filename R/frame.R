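# AssemblyFrame and Trajectory containers.
#
# An assembly frame is a data.frame with one row per bead and columns
#   x, y, z   coordinates in Angstrom
#   chain     chain label (peptide chains; counterion beads share chain "0")
#   resid     1-based residue index within the chain
#   resname   residue name (three-letter code, or "PI"/"LCP" for counterions)
#   mass      bead mass in Da
#   type      "peptide" or "counterion"
#   radius    bead radius in Angstrom
# plus attributes `box` (orthorhombic edge lengths in Angstrom, or NULL) and
# `time` (frame time label).

#' Construct an assembly frame
#'
#' @param x,y,z Numeric coordinates in Angstrom.
#' @param chain Character chain labels.
#' @param resid Integer 1-based residue indices.
#' @param resname Character residue names.
#' @param mass Numeric bead masses in Da.
#' @param type "peptide" or "counterion" per bead.
#' @param radius Bead radii in Angstrom.
#' @param box Optional orthorhombic box edge lengths (length-3, Angstrom).
#' @param time Frame time label (default 0).
#' @return An object of class `assembly_frame` (a data.frame).
#' @export
assembly_frame <- function(x, y, z, chain, resid, resname, mass,
                           type = "peptide", radius = 3.0,
                           box = NULL, time = 0) {
  n <- length(x)
  df <- data.frame(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    chain = as.character(chain), resid = as.integer(resid),
    resname = as.character(resname), mass = as.numeric(mass),
    type = rep_len(as.character(type), n),
    radius = rep_len(as.numeric(radius), n),
    stringsAsFactors = FALSE
  )
  validate_frame(df, box)
  attr(df, "box") <- box
  attr(df, "time") <- time
  class(df) <- c("assembly_frame", "data.frame")
  df
}

validate_frame <- function(df, box = attr(df, "box")) {
  lens <- vapply(df, length, integer(1))
  if (length(unique(lens)) != 1L) stop("frame columns differ in length")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (any(df$resid < 1L)) stop("residue indices must be positive", call. = FALSE)
  if (any(df$mass <= 0)) stop("bead masses must be > 0", call. = FALSE)
  if (!all(df$type %in% c("peptide", "counterion"))) {
    stop("bead type must be 'peptide' or 'counterion'", call. = FALSE)
  }
  if (!is.null(box)) {
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive edge lengths", call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.assembly_frame <- function(x, ...) {
  np <- sum(x$type == "peptide")
  cat("<assembly_frame> ", nrow(x), " beads (", np, " peptide, ",
      nrow(x) - np, " counterion), ",
      length(unique(x$chain[x$type == "peptide"])), " peptide chains\n",
      sep = "")
  if (!is.null(attr(x, "box"))) {
    cat("  box:", paste(sprintf("%.2f", attr(x, "box")), collapse = " x "),
        "Angstrom\n")
  }
  invisible(x)
}

coords_matrix <- function(frame, rows = NULL) {
  m <- cbind(frame$x, frame$y, frame$z)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

set_coords <- function(frame, m) {
  frame$x <- m[, 1]; frame$y <- m[, 2]; frame$z <- m[, 3]
  frame
}

# Topology signature used to check that trajectory frames agree.
topology_signature <- function(frame) {
  paste(frame$chain, frame$resid, frame$resname, frame$type,
        signif(frame$mass, 7), sep = "|")
}

#' Bundle frames into a trajectory
#'
#' All frames must share an identical topology (chains, residues, masses,
#' bead types) and carry strictly increasing time labels.
#'
#' @param frames List of `assembly_frame` objects.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames) {
  if (inherits(frames, "assembly_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L)
  lapply(frames, function(f) stopifnot(inherits(f, "assembly_frame")))
  sig <- topology_signature(frames[[1]])
  for (i in seq_along(frames)[-1]) {
    if (!identical(topology_signature(frames[[i]]), sig)) {
      stop("frame ", i, " has a different topology than frame 1",
           call. = FALSE)
    }
  }
  times <- vapply(frames, function(f) as.numeric(attr(f, "time") %||% 0),
                  numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, times = times), class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frame(s), ",
      nrow(x$frames[[1]]), " beads each\n", sep = "")
  invisible(x)
}
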