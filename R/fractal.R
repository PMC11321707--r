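# Fractal-cluster metrics: radius of gyration, contact graphs and valency,
# compactness, fractal dimension, mass-radius oracle, trajectory windows.
#
# The central quantities, computed on the largest connected cluster of an
# assembly frame:
#   Rg      mass-weighted radius of gyration (Angstrom)
#   V_mol   kappa * Mw, kappa = 1.21 Angstrom^3/Da (protein specific-volume
#           prefactor)
#   phi     compactness, V_mol / ((4/3) pi Rg^3)
#   valency mean number of distinct peptide-peptide contact partners per
#           monomer (chain)
#   d_f     fractal dimension, 3 / (1 - log(phi) / log(valency))
#
# The mass-radius estimator is an independent oracle: the slope of
# log N(< r) against log r over the fractal scaling window.

#' Radius of gyration
#'
#' Mass-weighted (default) root-mean-square distance of the selected beads
#' from their centre of mass. Chains straddling a periodic boundary are
#' unwrapped first when the frame carries a box.
#'
#' @param frame An `assembly_frame`.
#' @param selection Optional row selection (logical or integer indices), or
#'   a character vector of chain labels.
#' @param mass_weighted Use bead masses as weights (default TRUE).
#' @return Rg in Angstrom.
#' @export
compute_rg <- function(frame, selection = NULL, mass_weighted = TRUE) {
  rows <- resolve_selection(frame, selection)
  if (!length(rows)) stop("empty selection", call. = FALSE)
  f <- if (!is.null(attr(frame, "box"))) unwrap_frame(frame) else frame
  m <- coords_matrix(f, rows)
  w <- if (mass_weighted) f$mass[rows] else rep(1, length(rows))
  com <- colSums(m * w) / sum(w)
  d2 <- rowSums(sweep(m, 2, com)^2)
  sqrt(sum(w * d2) / sum(w))
}

resolve_selection <- function(frame, selection) {
  if (is.null(selection)) return(seq_len(nrow(frame)))
  if (is.character(selection)) return(which(frame$chain %in% selection))
  if (is.logical(selection)) return(which(selection))
  as.integer(selection)
}

# Unwrap beads across periodic boundaries: sequential minimum-image walk
# within each chain, then minimum-image placement of chain centroids
# relative to the first chain. Orthorhombic boxes only.
unwrap_frame <- function(frame) {
  box <- attr(frame, "box")
  if (is.null(box)) return(frame)
  m <- coords_matrix(frame)
  for (ch in unique(frame$chain)) {
    idx <- which(frame$chain == ch)
    if (length(idx) < 2L) next
    for (k in 2:length(idx)) {
      d <- m[idx[k], ] - m[idx[k - 1L], ]
      m[idx[k], ] <- m[idx[k], ] - round(d / box) * box
    }
  }
  chains <- unique(frame$chain)
  ref <- colMeans(m[frame$chain == chains[1], , drop = FALSE])
  for (ch in chains[-1]) {
    idx <- which(frame$chain == ch)
    cen <- colMeans(m[idx, , drop = FALSE])
    shift <- round((cen - ref) / box) * box
    m[idx, ] <- sweep(m[idx, , drop = FALSE], 2, shift)
  }
  set_coords(frame, m)
}

#' Detect peptide-peptide contacts between chains
#'
#' Two peptide chains are in contact when any bead pair approaches within
#' `cutoff` of their surfaces (centre distance minus the sum of bead radii).
#' Counterion beads never contribute peptide-peptide contacts; counterion
#' bridges (a counterion bead touching two chains) are reported separately.
#'
#' @param frame An `assembly_frame`.
#' @param cutoff Surface-surface contact cutoff in Angstrom (default 4.5).
#' @param bridges Also detect counterion bridges (default TRUE; skipping
#'   them speeds up repeated calls that only need the peptide graph).
#' @return A `contact_graph`: list with the igraph `graph`, `chains`,
#'   per-chain `degrees`, per-edge bead-pair counts `pair_counts`, and a
#'   data.frame `bridges` of counterion-bridged chain pairs.
#' @export
detect_contacts <- function(frame, cutoff = 4.5, bridges = TRUE) {
  stop_if_not_scalar_pos(cutoff, "cutoff")
  f <- if (!is.null(attr(frame, "box"))) unwrap_frame(frame) else frame
  pep_idx <- which(f$type == "peptide")
  xyz <- coords_matrix(f)
  geo <- chain_geometry(f, pep_idx, xyz)
  el <- contact_edges(xyz, f$radius, geo, cutoff)
  nc <- length(geo$chains)
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = geo$chains)
  if (length(el$edges)) {
    g <- igraph::add_edges(g, el$edges)
    g <- igraph::set_edge_attr(g, "pairs", value = el$counts)
  }
  br <- if (bridges) {
    counterion_bridges(f, geo, xyz, cutoff)
  } else {
    data.frame(chain_i = character(0), chain_j = character(0),
               n_bridges = integer(0), stringsAsFactors = FALSE)
  }
  structure(
    list(graph = g, chains = geo$chains,
         degrees = stats::setNames(igraph::degree(g), geo$chains),
         pair_counts = el$counts, cutoff = cutoff, bridges = br),
    class = "contact_graph"
  )
}

# Per-chain bead indices, centroids and bounding radii (vectorized).
chain_geometry <- function(f, pep_idx, xyz) {
  chain_f <- factor(f$chain[pep_idx], levels = unique(f$chain[pep_idx]))
  by_chain <- split(pep_idx, chain_f)
  cen <- rowsum(xyz[pep_idx, , drop = FALSE], chain_f, reorder = FALSE) /
    as.vector(table(chain_f))
  ci <- as.integer(chain_f)
  dev <- xyz[pep_idx, , drop = FALSE] - cen[ci, , drop = FALSE]
  rad <- sqrt(rowSums(dev^2)) + f$radius[pep_idx]
  ext <- vapply(split(rad, chain_f), max, numeric(1))
  list(chains = levels(chain_f), by_chain = by_chain, cen = cen,
       ext = unname(ext))
}

# Chain-pair contact edges with bead-pair counts; centroid prefilter keeps
# the O(n^2) bead work on near pairs only.
contact_edges <- function(xyz, radius, geo, cutoff) {
  nc <- length(geo$chains)
  edges <- integer(0); counts <- integer(0)
  if (nc < 2L) return(list(edges = edges, counts = counts))
  cend <- as.matrix(stats::dist(geo$cen))
  thr <- outer(geo$ext, geo$ext, "+") + cutoff
  cand <- which(upper.tri(cend) & cend <= thr, arr.ind = TRUE)
  if (nrow(cand)) {
    e_list <- vector("list", nrow(cand))
    c_list <- integer(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      ii <- geo$by_chain[[i]]; jj <- geo$by_chain[[j]]
      d <- cross_dist(xyz[ii, , drop = FALSE], xyz[jj, , drop = FALSE])
      npair <- sum(d - outer(radius[ii], radius[jj], "+") <= cutoff)
      if (npair > 0L) {
        e_list[[r]] <- c(i, j)
        c_list[r] <- npair
      }
    }
    keep <- !vapply(e_list, is.null, logical(1))
    edges <- unlist(e_list[keep])
    counts <- c_list[keep]
  }
  list(edges = edges, counts = counts)
}

counterion_bridges <- function(f, geo, xyz, cutoff) {
  ion <- which(f$type == "counterion")
  out <- data.frame(chain_i = character(0), chain_j = character(0),
                    n_bridges = integer(0), stringsAsFactors = FALSE)
  if (!length(ion)) return(out)
  chains <- geo$chains
  # prefilter ion/chain pairs by centroid distance
  icd <- cross_dist(xyz[ion, , drop = FALSE], geo$cen)
  lim <- outer(f$radius[ion], geo$ext, "+") + cutoff
  touched <- lapply(seq_along(ion), function(bi) {
    b <- ion[bi]
    ks <- which(icd[bi, ] <= lim[bi, ])
    hit <- vapply(ks, function(k) {
      ii <- geo$by_chain[[k]]
      d <- sqrt(colSums((t(xyz[ii, , drop = FALSE]) - xyz[b, ])^2))
      any(d - (f$radius[ii] + f$radius[b]) <= cutoff)
    }, logical(1))
    chains[ks[hit]]
  })
  pair_key <- unlist(lapply(touched, function(ch) {
    if (length(ch) < 2L) return(character(0))
    cmb <- utils::combn(sort(ch), 2L)
    paste(cmb[1, ], cmb[2, ], sep = "|")
  }))
  if (!length(pair_key)) return(out)
  tab <- table(pair_key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  data.frame(chain_i = vapply(parts, `[`, "", 1L),
             chain_j = vapply(parts, `[`, "", 2L),
             n_bridges = as.integer(tab), stringsAsFactors = FALSE)
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("<contact_graph> ", length(x$chains), " chains, ",
      igraph::ecount(x$graph), " contacts, mean valency ",
      sprintf("%.2f", mean_valency(x)), "\n", sep = "")
  invisible(x)
}

#' Mean per-monomer contact valency
#'
#' Mean number of peptide-peptide contacts per monomer. The default counts
#' distinct contact partners (graph degree); `mode = "pairs"` counts bead
#' pairs within the cutoff instead.
#'
#' @param graph A `contact_graph`.
#' @param mode "partners" (default) or "pairs".
#' @return Mean valency.
#' @export
mean_valency <- function(graph, mode = c("partners", "pairs")) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "contact_graph"))
  if (!length(graph$chains)) stop("graph has no nodes", call. = FALSE)
  if (mode == "partners") return(mean(graph$degrees))
  if (!igraph::ecount(graph$graph)) return(0)
  mean(igraph::strength(graph$graph, weights =
                          igraph::E(graph$graph)$pairs))
}

#' Connected clusters of a contact graph
#'
#' @param graph A `contact_graph`.
#' @return List with `membership` (named by chain), `sizes`, `n_clusters`,
#'   and `largest` (chain labels of the largest cluster, the assembly).
#' @export
connected_clusters <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  comp <- igraph::components(graph$graph)
  largest_id <- which.max(comp$csize)
  list(
    membership = stats::setNames(comp$membership, graph$chains),
    sizes = as.integer(comp$csize),
    n_clusters = comp$no,
    largest = graph$chains[comp$membership == largest_id]
  )
}

#' Molecular volume from molecular weight
#'
#' `V_mol = kappa * Mw` with the default prefactor 1.21 Angstrom^3/Da.
#'
#' @param Mw_total Total molecular weight in Da.
#' @param kappa Specific-volume prefactor in Angstrom^3/Da.
#' @return Volume in Angstrom^3.
#' @export
molecular_volume <- function(Mw_total, kappa = 1.21) {
  if (any(Mw_total < 0)) stop("Mw_total must be >= 0", call. = FALSE)
  kappa * Mw_total
}

#' Compactness of a cluster
#'
#' `phi = V_mol / ((4/3) pi Rg^3)` using the cluster's total peptide mass
#' and mass-weighted Rg.
#'
#' @param frame An `assembly_frame`.
#' @param cluster Chain labels of the cluster (default: all peptide chains).
#' @param kappa Specific-volume prefactor.
#' @return List with `phi`, `Rg`, `Mw_total`, `V_mol`.
#' @export
compactness <- function(frame, cluster = NULL, kappa = 1.21) {
  pep <- frame$type == "peptide"
  if (is.null(cluster)) cluster <- unique(frame$chain[pep])
  sel <- which(pep & frame$chain %in% cluster)
  if (!length(sel)) stop("empty cluster selection", call. = FALSE)
  rg <- compute_rg(frame, sel)
  if (rg <= 0) stop("undefined compactness: cluster Rg is zero",
                    call. = FALSE)
  mw <- sum(frame$mass[sel])
  vm <- molecular_volume(mw, kappa)
  list(phi = vm / ((4 / 3) * pi * rg^3), Rg = rg, Mw_total = mw, V_mol = vm)
}

#' Fractal dimension from compactness and valency
#'
#' `d_f = 3 / (1 - log(phi) / log(valency))` (log-base invariant). For a
#' maximally compact object (`phi = 1`) the formula gives exactly 3; looser
#' packing (`phi < 1`) lowers `d_f` toward rod- and sheet-like values.
#' Undefined inputs (`phi <= 0`, `valency <= 1`, or the pole `phi = valency`)
#' and values outside [0, 3] are flagged, not clipped: `NA` with flag
#' "undefined", or the raw value with flag "out-of-range".
#'
#' @param phi Compactness (vectorized).
#' @param valency Mean valency (vectorized).
#' @return Numeric vector of `d_f` with a character attribute `flag`
#'   ("ok", "undefined" or "out-of-range").
#' @export
fractal_dimension <- function(phi, valency) {
  n <- max(length(phi), length(valency))
  phi <- rep_len(as.numeric(phi), n)
  valency <- rep_len(as.numeric(valency), n)
  df <- rep(NA_real_, n)
  flag <- rep("undefined", n)
  valid <- is.finite(phi) & is.finite(valency) & phi > 0 & valency > 1
  ok <- valid
  ok[valid] <- abs(log(phi[valid]) - log(valency[valid])) > 1e-12
  denom <- 1 - log(phi[ok]) / log(valency[ok])
  df[ok] <- 3 / denom
  flag[ok] <- ifelse(df[ok] >= 0 & df[ok] <= 3, "ok", "out-of-range")
  attr(df, "flag") <- flag
  df
}

#' Mass-radius fractal dimension (independent oracle)
#'
#' Estimates the fractal dimension directly from the mass-size scaling: the
#' slope of `log N(< r)` (number of beads within radius `r` of the cluster
#' centre) against `log r`. The centre is the bead closest to the centre of
#' mass, so that clusters whose centre of mass falls into a void are not
#' undercounted at small radii. The fit window runs from the smallest
#' fractal scale to the cluster Rg: for assemblies built from rigid
#' building blocks (frames carrying a `block_rg` attribute) the lower bound
#' is 1.25 x the block Rg, below which the counts probe intra-block chain
#' structure rather than the aggregation scaling; for plain bead clusters
#' it is twice the largest bead radius.
#'
#' @param frame An `assembly_frame`.
#' @param cluster Chain labels (default: all peptide chains; needs >= 20
#'   beads).
#' @param r_min,r_max Fit window in Angstrom (defaults as described above).
#' @param n_r Number of log-spaced radii (default 24).
#' @return List with `estimate` (the slope), `r_min`, `r_max`, `n_points`,
#'   and the count profile `profile` (data.frame r, n).
#' @export
mass_radius_dimension <- function(frame, cluster = NULL, r_min = NULL,
                                  r_max = NULL, n_r = 24L) {
  pep <- frame$type == "peptide"
  if (is.null(cluster)) cluster <- unique(frame$chain[pep])
  sel <- which(pep & frame$chain %in% cluster)
  if (length(sel) < 20L) stop("need at least 20 beads", call. = FALSE)
  f <- if (!is.null(attr(frame, "box"))) unwrap_frame(frame) else frame
  m <- coords_matrix(f, sel)
  w <- f$mass[sel]
  com <- colSums(m * w) / sum(w)
  d_com <- sqrt(rowSums(sweep(m, 2, com)^2))
  rg <- sqrt(sum(w * d_com^2) / sum(w))
  center <- m[which.min(d_com), ]
  r <- sqrt(rowSums(sweep(m, 2, center)^2))
  block_rg <- attr(frame, "block_rg")
  r_min <- r_min %||% if (!is.null(block_rg)) 1.25 * block_rg else
    2 * max(f$radius[sel])
  r_max <- r_max %||% rg
  if (r_max <= r_min) r_max <- r_min * 2
  grid <- exp(seq(log(r_min), log(r_max), length.out = n_r))
  n_in <- vapply(grid, function(rr) sum(r <= rr), numeric(1))
  keep <- n_in >= 2
  if (sum(keep) < 4L) stop("too few radii with >= 2 beads for a fit",
                           call. = FALSE)
  fit <- stats::lm(log(n_in[keep]) ~ log(grid[keep]))
  list(estimate = unname(stats::coef(fit)[2]), r_min = r_min, r_max = r_max,
       n_points = sum(keep), profile = data.frame(r = grid, n = n_in))
}

#' Convert radius of gyration to hydrodynamic radius
#'
#' `Rh = Rg / 1.1`, the empirical conversion for disordered peptide chains.
#'
#' @param Rg Radius of gyration (any length unit).
#' @return Rh in the same unit.
#' @export
rg_to_rh <- function(Rg) {
  if (any(Rg < 0)) stop("Rg must be >= 0", call. = FALSE)
  Rg / 1.1
}

#' Windowed fractal metrics over a trajectory
#'
#' Computes per-frame metrics (on the largest connected cluster) and their
#' mean and standard deviation over an analysis window, mirroring the
#' practice of averaging over the equilibrated tail of a simulation.
#'
#' @param traj A `trajectory`.
#' @param window `"all"`, `"last:<p>%"` (e.g. `"last:20%"`), or a numeric
#'   `c(t0, t1)` time span.
#' @param cutoff Contact cutoff in Angstrom.
#' @param kappa Specific-volume prefactor.
#' @return An object of class `fractal_metrics`: list with `summary`
#'   (mean/sd per metric) and `per_frame` (one row per analysed frame).
#' @export
analyze_trajectory <- function(traj, window = "last:20%", cutoff = 4.5,
                               kappa = 1.21) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- window_frames(traj, window)
  if (!length(idx)) stop("empty analysis window", call. = FALSE)
  rows <- lapply(idx, function(i) {
    f <- traj$frames[[i]]
    cg <- detect_contacts(f, cutoff = cutoff)
    cl <- connected_clusters(cg)
    largest <- cl$largest
    cp <- compactness(f, cluster = largest, kappa = kappa)
    val <- mean(cg$degrees[largest])
    df <- fractal_dimension(cp$phi, val)
    data.frame(
      frame = i, time = traj$times[i], Rg = cp$Rg, Mw_total = cp$Mw_total,
      V_mol = cp$V_mol, phi = cp$phi, valency = val, d_f = as.numeric(df),
      d_f_flag = attr(df, "flag"), n_chains = length(cg$chains),
      n_clusters = cl$n_clusters, stringsAsFactors = FALSE
    )
  })
  per_frame <- do.call(rbind, rows)
  num <- c("Rg", "Mw_total", "V_mol", "phi", "valency", "d_f")
  summary <- data.frame(
    metric = num,
    mean = vapply(num, function(cn) mean(per_frame[[cn]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(num, function(cn) stats::sd(per_frame[[cn]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL
  )
  summary$sd[is.na(summary$sd)] <- 0
  structure(list(summary = summary, per_frame = per_frame,
                 window = window, cutoff = cutoff, kappa = kappa),
            class = "fractal_metrics")
}

window_frames <- function(traj, window) {
  n <- length(traj$frames)
  if (is.character(window)) {
    if (identical(window, "all")) return(seq_len(n))
    m <- regmatches(window, regexec("^last:([0-9.]+)%$", window))[[1]]
    if (length(m) == 2L) {
      frac <- as.numeric(m[2]) / 100
      if (frac <= 0 || frac > 1) stop("window fraction outside (0, 100]",
                                      call. = FALSE)
      k <- max(1L, ceiling(frac * n))
      return(seq.int(n - k + 1L, n))
    }
    stop("unrecognized window: ", window, call. = FALSE)
  }
  if (is.numeric(window) && length(window) == 2L) {
    return(which(traj$times >= window[1] & traj$times <= window[2]))
  }
  stop("unrecognized window specification", call. = FALSE)
}

#' @export
print.fractal_metrics <- function(x, ...) {
  cat("<fractal_metrics> window", x$window, "over",
      nrow(x$per_frame), "frame(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
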