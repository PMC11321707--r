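# Structure and table I/O.
#
# PDB dialect: one MODEL/ENDMDL block per frame, CRYST1 when a box is
# present, HETATM records for counterion beads. Chain labels use column 22;
# assemblies with more than 26 peptide chains use a documented two-character
# extension occupying columns 21-22. Bead radius is stored in the occupancy
# field and bead mass in the B-factor field (coarse-grained beads have no
# element-implied mass).
#
# XYZ dialect: standard multi-frame XYZ plus a CSV topology sidecar
# (<path>.topology.csv) carrying chain/resid/resname/mass/type/radius.

make_chain_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  if (n > 26L + 26L * 26L) stop("more than 702 chains not supported")
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, two)[seq_len(n)]
}

#' Write coordinates to PDB or XYZ
#'
#' @param traj A `trajectory` or a single `assembly_frame`.
#' @param path Output file path.
#' @param format "pdb" or "xyz".
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (inherits(traj, "assembly_frame")) traj <- trajectory(list(traj))
  stopifnot(inherits(traj, "trajectory"))
  switch(format,
    pdb = write_pdb(traj, path),
    xyz = write_xyz(traj, path)
  )
  invisible(path)
}

write_pdb <- function(traj, path) {
  frames <- traj$frames
  lines <- character(0)
  box <- attr(frames[[1]], "box")
  if (!is.null(box)) {
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1], box[2], box[3], 90, 90, 90))
  }
  multi <- length(frames) > 1L
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", i))
    rec <- ifelse(f$type == "counterion", "HETATM", "ATOM  ")
    serial <- seq_len(nrow(f)) %% 100000L
    atname <- ifelse(f$type == "counterion", " P  ", " CA ")
    elem <- ifelse(f$type == "counterion", " P", " C")
    ch <- format_chain_field(f$chain)
    lines <- c(lines, sprintf(
      "%s%5d %s %-3s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %s",
      rec, serial, atname, substr(f$resname, 1, 3), ch,
      f$resid %% 10000L, f$x, f$y, f$z, f$radius, f$mass, elem))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
}

# Columns 21-22: single-character chains occupy column 22 (standard PDB);
# two-character chains use both columns (documented extension).
format_chain_field <- function(chain) {
  nc <- nchar(chain)
  if (any(nc > 2L)) stop("chain labels longer than 2 characters", call. = FALSE)
  ifelse(nc == 1L, paste0(" ", chain), chain)
}

#' Read coordinates from PDB or XYZ
#'
#' @param path Input file.
#' @param format "pdb" or "xyz".
#' @param topology For XYZ, path of the CSV topology sidecar (defaults to
#'   `<path>.topology.csv`).
#' @return A `trajectory`.
#' @export
read_coordinates <- function(path, format = c("pdb", "xyz"),
                             topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    pdb = read_pdb(path),
    xyz = read_xyz(path, topology %||% paste0(path, ".topology.csv"))
  )
}

read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("parse error: empty PDB file", call. = FALSE)
  rec <- substr(lines, 1, 6)
  box <- NULL
  icr <- which(rec == "CRYST1")
  if (length(icr)) {
    l <- lines[icr[1]]
    box <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)))
  }
  atom_sel <- rec %in% c("ATOM  ", "HETATM")
  if (!any(atom_sel)) stop("parse error: no ATOM/HETATM records", call. = FALSE)
  model_starts <- which(rec == "MODEL ")
  frame_id <- cumsum(rec == "MODEL ")
  if (!length(model_starts)) frame_id <- rep(1L, length(lines))
  frame_id[!atom_sel] <- NA
  frames <- list()
  for (k in sort(unique(stats::na.omit(frame_id)))) {
    idx <- which(!is.na(frame_id) & frame_id == k)
    ls <- lines[idx]
    xyz <- suppressWarnings(cbind(as.numeric(substr(ls, 31, 38)),
                                  as.numeric(substr(ls, 39, 46)),
                                  as.numeric(substr(ls, 47, 54))))
    if (any(!is.finite(xyz))) {
      bad <- idx[which(!stats::complete.cases(xyz))[1]]
      stop("parse error at line ", bad, ": malformed coordinates",
           call. = FALSE)
    }
    f <- assembly_frame(
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      chain = trimws(substr(ls, 21, 22)),
      resid = as.integer(substr(ls, 23, 26)),
      resname = trimws(substr(ls, 18, 20)),
      mass = as.numeric(substr(ls, 61, 66)),
      type = ifelse(substr(ls, 1, 6) == "HETATM", "counterion", "peptide"),
      radius = as.numeric(substr(ls, 55, 60)),
      box = box, time = as.numeric(k) - 1
    )
    frames[[length(frames) + 1L]] <- f
  }
  trajectory(frames)
}

write_xyz <- function(traj, path) {
  frames <- traj$frames
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    box <- attr(f, "box")
    comment <- sprintf("frame=%d time=%g", i, traj$times[i])
    if (!is.null(box)) {
      comment <- paste0(comment, sprintf(" box=%.6f,%.6f,%.6f",
                                         box[1], box[2], box[3]))
    }
    writeLines(as.character(nrow(f)), con)
    writeLines(comment, con)
    el <- ifelse(f$type == "counterion", "P", "C")
    writeLines(sprintf("%s %.6f %.6f %.6f", el, f$x, f$y, f$z), con)
  }
  topo <- frames[[1]][, c("chain", "resid", "resname", "mass", "type", "radius")]
  utils::write.csv(topo, paste0(path, ".topology.csv"), row.names = FALSE)
  invisible(path)
}

read_xyz <- function(path, topology) {
  if (!file.exists(topology)) {
    stop("missing XYZ topology sidecar: ", topology, call. = FALSE)
  }
  topo <- utils::read.csv(topology, stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("parse error: empty XYZ file", call. = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("parse error at line ", i, ": expected atom count",
                       call. = FALSE)
    if (i + 1L + n > length(lines)) {
      stop("parse error: truncated XYZ frame starting at line ", i,
           call. = FALSE)
    }
    comment <- lines[i + 1L]
    box <- NULL
    bm <- regmatches(comment, regexec("box=([0-9.eE+-]+),([0-9.eE+-]+),([0-9.eE+-]+)",
                                      comment))[[1]]
    if (length(bm) == 4L) box <- as.numeric(bm[2:4])
    tm <- regmatches(comment, regexec("time=([0-9.eE+-]+)", comment))[[1]]
    tlab <- if (length(tm) == 2L) as.numeric(tm[2]) else length(frames)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(vapply(parts, length, integer(1)) < 4L)) {
      stop("parse error: malformed XYZ atom line in frame starting at line ",
           i, call. = FALSE)
    }
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (nrow(topo) != n) {
      stop("topology sidecar has ", nrow(topo), " rows but frame has ", n,
           " atoms", call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- assembly_frame(
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      chain = topo$chain, resid = topo$resid, resname = topo$resname,
      mass = topo$mass, type = topo$type, radius = topo$radius,
      box = box, time = tlab
    )
    i <- i + 2L + n
  }
  trajectory(frames)
}

# ---- Tabular I/O -----------------------------------------------------------

TABLE_SCHEMAS <- list(
  peaks = c("residue", "label", "shift_a", "shift_b", "intensity"),
  dosy = c("gradient", "integral"),
  kinetics = c("time")   # plus one numeric column per residue
)

#' Read a typed CSV table (peaks, dosy, kinetics)
#'
#' Acquisition constants and flags are carried in `# key=value` comment
#' lines preceding the header and surface in the returned object's
#' attributes.
#'
#' @param path CSV file path.
#' @param schema One of "peaks", "dosy", "kinetics".
#' @return A `peak_table`, `dosy_series` or `kinetic_traces` object.
#' @export
read_table <- function(path, schema = c("peaks", "dosy", "kinetics")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_meta(meta_lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- TABLE_SCHEMAS[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(names(df), "label")
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stop("schema error: non-numeric value in column '", cn,
             "', row ", bad[1], call. = FALSE)
      }
      df[[cn]] <- vn
    }
  }
  switch(schema,
    peaks = peak_table(df$residue, df$label, df$shift_a, df$shift_b,
                       df$intensity, nucleus = meta$nucleus %||% "H-N"),
    dosy = dosy_series(df$gradient, df$integral,
                       Delta = as.numeric(meta$Delta %||% 0.06),
                       delta = as.numeric(meta$delta %||% 0.015),
                       gamma = as.numeric(meta$gamma %||% GAMMA_1H),
                       temperature = as.numeric(meta$temperature %||% 298.15),
                       viscosity = as.numeric(meta$viscosity %||% 8.937e-4)),
    kinetics = {
      rescols <- setdiff(names(df), "time")
      surf <- if (!is.null(meta$surface)) {
        as.integer(strsplit(meta$surface, ";")[[1]])
      } else {
        integer(0)
      }
      kinetic_traces(df$time,
                     as.matrix(df[, rescols, drop = FALSE]),
                     residues = as.integer(sub("^r", "", rescols)),
                     surface_residues = surf, normalize = FALSE)
    }
  )
}

parse_meta <- function(lines) {
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+)$", l))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Write a typed table to CSV
#'
#' @param x A `peak_table`, `dosy_series` or `kinetic_traces` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "peak_table")) {
    writeLines(sprintf("# nucleus=%s", attr(x, "nucleus")), path)
    suppressWarnings(utils::write.table(
      as.data.frame(x), path, sep = ",", row.names = FALSE,
      col.names = TRUE, append = TRUE, qmethod = "double"))
  } else if (inherits(x, "dosy_series")) {
    hdr <- c(
      sprintf("# Delta=%.10g", attr(x, "Delta")),
      sprintf("# delta=%.10g", attr(x, "delta")),
      sprintf("# gamma=%.10g", attr(x, "gamma")),
      sprintf("# temperature=%.10g", attr(x, "temperature")),
      sprintf("# viscosity=%.10g", attr(x, "viscosity"))
    )
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(
      as.data.frame(x), path, sep = ",", row.names = FALSE,
      col.names = TRUE, append = TRUE))
  } else if (inherits(x, "kinetic_traces")) {
    df <- data.frame(time = x$time, x$intensities, check.names = FALSE)
    names(df) <- c("time", paste0("r", x$residues))
    if (length(x$surface_residues)) {
      writeLines(sprintf("# surface=%s",
                         paste(x$surface_residues, collapse = ";")), path)
      suppressWarnings(utils::write.table(df, path, sep = ",",
                                          row.names = FALSE, col.names = TRUE,
                                          append = TRUE))
    } else {
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else {
    stop("unsupported table type: ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  invisible(path)
}
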