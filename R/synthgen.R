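# Synthetic-data generator: trimer building blocks, morphology-controlled
# assemblies, peak tables, DOSY decays, kinetic traces, crowded boxes.
#
# The generator emulates the data streams of a peptide/counterion
# silicification study with known ground truth: coarse-grained (one bead per
# residue) trimeric building blocks bridged by counterion beads, aggregated
# into assemblies of controlled dimensionality; HSQC-like peak tables with
# counterion-dependent attenuation; Stejskal-Tanner DOSY decays; and
# two-rate (surface faster than core) silicification decay traces.

# Atomic mass unit in grams.
AMU_G <- 1.66053906660e-24

COUNTERION_MASS <- c(phosphate = 96.99, LCPA = 600.0)
COUNTERION_RESNAME <- c(phosphate = "PI", LCPA = "LCP")
COUNTERION_RADIUS <- 2.0

#' Define a trimeric building block
#'
#' Assemblies are built from rigid blocks of `n_copies` peptide chains held
#' together by counterion beads bridging the `linker_sites` residue pairs of
#' adjacent chains (for R5, Arg-phosphate-Arg bridges at the RRIL motif and a
#' secondary contact at the N-terminal SKKS motif).
#'
#' @param peptide A `peptide_spec`.
#' @param n_copies Number of peptide chains per block (default 3).
#' @param linker_sites List of residue-index pairs bridged by counterion
#'   beads between adjacent chains.
#' @param counterion "phosphate" or "LCPA".
#' @return An object of class `building_block`.
#' @export
building_block <- function(peptide, n_copies = 3L,
                           linker_sites = list(c(16L, 17L), c(3L, 4L)),
                           counterion = c("phosphate", "LCPA")) {
  stopifnot(inherits(peptide, "peptide_spec"))
  counterion <- match.arg(counterion)
  n_copies <- as.integer(n_copies)
  if (n_copies < 1L) stop("n_copies must be >= 1", call. = FALSE)
  nres <- length(peptide$residues)
  for (p in linker_sites) {
    if (length(p) != 2L || any(p < 1L) || any(p > nres)) {
      stop("linker_sites must be pairs of valid residue indices",
           call. = FALSE)
    }
  }
  structure(
    list(peptide = peptide, n_copies = n_copies,
         linker_sites = linker_sites, counterion = counterion),
    class = "building_block"
  )
}

#' Default R5/phosphate trimer block
#' @return A `building_block`.
#' @export
r5_block <- function() building_block(r5_peptide())

#' Default synSil-1A1/LCPA trimer block
#' @return A `building_block`.
#' @export
synsil_block <- function() {
  building_block(synsil_peptide(), linker_sites = list(c(12L, 12L), c(5L, 14L)),
                 counterion = "LCPA")
}

# Coarse-grained chain geometry: beads on a compact helix with 5 Angstrom
# bonds so that no two beads approach below 0.8 x bead diameter. Radius and
# rise give a globular 19-residue chain whose Rg/1.1 is on the 0.7-0.8 nm
# scale of a disordered peptide monomer.
helix_chain <- function(n, phase = 0, helix_radius = 4.5, turn_deg = 65) {
  th <- (seq_len(n) - 1) * turn_deg * pi / 180 + phase
  chord <- 2 * helix_radius * sin(turn_deg * pi / 360)
  rise <- sqrt(max(25 - chord^2, 0.5))
  cbind(helix_radius * cos(th), helix_radius * sin(th),
        (seq_len(n) - 1) * rise)
}

min_separation_ok <- function(xyz, radii, scale = 0.8) {
  n <- nrow(xyz)
  if (n < 2L) return(TRUE)
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(radii, radii, "+") * scale
  diag(d) <- Inf
  all(d >= lim)
}

#' Generate one rigid trimer building block
#'
#' Places `n_copies` helical bead chains (one bead per residue) around a
#' common axis so that all chain pairs are in contact, and bridges adjacent
#' chains with counterion beads at the block's linker sites. Retries the
#' random placement until no two beads overlap below 0.8 x the sum of their
#' radii; geometrically infeasible specifications raise a placement error.
#'
#' @param block A `building_block`.
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @return An `assembly_frame` centred on the block's centre of mass.
#' @export
generate_building_block <- function(block, seed = 1L) {
  stopifnot(inherits(block, "building_block"))
  pep <- block$peptide
  n <- block$n_copies
  nres <- length(pep$residues)
  with_seed(derive_seed(seed, "block"), {
    for (attempt in seq_len(60L)) {
      chains <- vector("list", n)
      if (n == 1L) {
        axis_pos <- matrix(0, 1, 2)
      } else {
        d_axis <- 14.0
        a <- d_axis / (2 * sin(pi / n))
        ang <- 2 * pi * (seq_len(n) - 1) / n
        axis_pos <- cbind(a * cos(ang), a * sin(ang))
      }
      for (i in seq_len(n)) {
        ch <- helix_chain(nres, phase = stats::runif(1, 0, 2 * pi))
        ch <- ch %*% rot_z(stats::runif(1, 0, 2 * pi))
        ch[, 1] <- ch[, 1] + axis_pos[i, 1]
        ch[, 2] <- ch[, 2] + axis_pos[i, 2]
        ch[, 3] <- ch[, 3] + stats::runif(1, -2, 2)
        chains[[i]] <- ch
      }
      xyz <- do.call(rbind, chains)
      radii <- rep(pep$bead_radius, n * nres)
      if (!min_separation_ok(xyz, radii)) next
      if (n >= 2L && !chains_all_in_contact(chains, pep$bead_radius)) next

      ion <- place_counterions(chains, block, xyz, radii)
      if (is.null(ion) && n >= 2L && length(block$linker_sites)) next

      frame <- block_frame(block, chains, ion)
      attr(frame, "block") <- block
      attr(frame, "seed") <- seed
      return(frame)
    }
    stop("placement error: could not build a non-overlapping block after ",
         "bounded retries", call. = FALSE)
  })
}

rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

chains_all_in_contact <- function(chains, bead_radius, cutoff = 4.5) {
  n <- length(chains)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- min(cross_dist(chains[[i]], chains[[j]]))
      if (d - 2 * bead_radius > cutoff) return(FALSE)
    }
  }
  TRUE
}

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# Counterion beads bridge linker-site residues of adjacent chain pairs;
# start at the pair midpoint and relax outward until clash-free.
place_counterions <- function(chains, block, pep_xyz, pep_radii) {
  n <- length(chains)
  if (n < 2L || !length(block$linker_sites)) {
    return(matrix(numeric(0), 0, 3))
  }
  pairs <- if (n == 2L) list(c(1L, 2L)) else {
    lapply(seq_len(n), function(i) c(i, i %% n + 1L))
  }
  pts <- list()
  for (pr in pairs) {
    for (site in block$linker_sites) {
      p1 <- chains[[pr[1]]][site[1], ]
      p2 <- chains[[pr[2]]][site[2], ]
      cand <- (p1 + p2) / 2
      for (it in seq_len(40L)) {
        all_xyz <- rbind(pep_xyz, do.call(rbind, pts), deparse.level = 0)
        all_r <- c(pep_radii, rep(COUNTERION_RADIUS, length(pts)))
        d <- sqrt(colSums((t(all_xyz) - cand)^2))
        lim <- 0.8 * (all_r + COUNTERION_RADIUS)
        viol <- which(d < lim)
        if (!length(viol)) break
        k <- viol[which.min(d[viol])]
        dir <- cand - all_xyz[k, ]
        nd <- sqrt(sum(dir^2))
        if (nd < 1e-9) dir <- stats::rnorm(3) else dir <- dir / nd
        cand <- cand + dir * (lim[k] - d[k] + 0.1)
      }
      if (length(viol)) return(NULL)
      pts[[length(pts) + 1L]] <- cand
    }
  }
  do.call(rbind, pts)
}

block_frame <- function(block, chains, ion_xyz) {
  pep <- block$peptide
  n <- length(chains)
  nres <- length(pep$residues)
  labels <- make_chain_labels(n)
  xyz <- do.call(rbind, chains)
  df_p <- data.frame(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = rep(labels, each = nres),
    resid = rep(seq_len(nres), n),
    resname = rep(aa_three(pep$residues), n),
    mass = rep(pep$per_residue_mass, n),
    type = "peptide", radius = pep$bead_radius,
    stringsAsFactors = FALSE
  )
  if (!is.null(ion_xyz) && nrow(ion_xyz)) {
    df_i <- data.frame(
      x = ion_xyz[, 1], y = ion_xyz[, 2], z = ion_xyz[, 3],
      chain = "0", resid = seq_len(nrow(ion_xyz)),
      resname = COUNTERION_RESNAME[[block$counterion]],
      mass = COUNTERION_MASS[[block$counterion]],
      type = "counterion", radius = COUNTERION_RADIUS,
      stringsAsFactors = FALSE
    )
    df_p <- rbind(df_p, df_i)
  }
  com <- colSums(coords_matrix(df_p) * df_p$mass) / sum(df_p$mass)
  f <- assembly_frame(df_p$x - com[1], df_p$y - com[2], df_p$z - com[3],
                      df_p$chain, df_p$resid, df_p$resname, df_p$mass,
                      df_p$type, df_p$radius)
  f
}

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aa_three <- function(res) unname(AA_THREE[res])

#' Define an assembly morphology
#'
#' Morphology is the generator's ground-truth knob: `linear` grows along one
#' axis (dimensionality 1), `planar` within a plane (2), `compact`
#' isotropically (3), and `dla` by random-walk attachment.
#'
#' @param mode One of "linear", "planar", "compact", "dla".
#' @param n_blocks Number of building-block copies (>= 1).
#' @param target_valency Target mean peptide-peptide contacts per monomer.
#' @param contact_gap Surface-surface contact cutoff in Angstrom used when
#'   calibrating the block spacing (default 4.5).
#' @param seed Integer seed.
#' @return An object of class `morphology_spec`.
#' @export
morphology_spec <- function(mode = c("linear", "planar", "compact", "dla"),
                            n_blocks, target_valency = 4, contact_gap = 4.5,
                            seed = 1L) {
  mode <- match.arg(mode)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
  if (target_valency < 0) stop("target_valency must be >= 0", call. = FALSE)
  structure(
    list(mode = mode, n_blocks = n_blocks, target_valency = target_valency,
         contact_gap = contact_gap, seed = as.integer(seed)),
    class = "morphology_spec"
  )
}

# Unit-spacing block centres per morphology mode. `jitter` breaks the
# neighbour-distance degeneracy of the regular lattices, which would
# otherwise make valency a step function of the spacing.
morphology_centers <- function(mode, n, jitter = 0.04) {
  if (n == 1L) return(matrix(0, 1, 3))
  jit <- matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
  base <- switch(mode,
    linear = cbind(0, 0, seq_len(n) - 1),
    planar = {
      # hexagonal lattice sites sorted by distance from the origin
      k <- ceiling(sqrt(n)) + 3L
      g <- expand.grid(i = -k:k, j = -k:k)
      pts <- cbind(g$i + g$j / 2, g$j * sqrt(3) / 2, 0)
      pts[order(rowSums(pts^2))[seq_len(n)], , drop = FALSE]
    },
    compact = {
      # fcc lattice sites (unit nearest-neighbour distance) sorted by radius
      k <- ceiling(n^(1 / 3)) + 3L
      g <- expand.grid(i = -k:k, j = -k:k, l = -k:k)
      keep <- (g$i + g$j + g$l) %% 2 == 0
      pts <- cbind(g$i[keep], g$j[keep], g$l[keep]) / sqrt(2)
      pts[order(rowSums(pts^2))[seq_len(n)], , drop = FALSE]
    },
    dla = {
      pts <- matrix(0, n, 3)
      for (k in 2:n) {
        placed <- FALSE
        for (try in seq_len(400L)) {
          anchor <- pts[sample.int(k - 1L, 1L), ]
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- anchor + u
          dmin <- min(sqrt(rowSums((pts[seq_len(k - 1L), , drop = FALSE] -
                                      matrix(cand, k - 1L, 3,
                                             byrow = TRUE))^2)))
          if (dmin >= 0.95) { pts[k, ] <- cand; placed <- TRUE; break }
        }
        if (!placed) stop("placement error: dla growth stalled", call. = FALSE)
      }
      pts
    }
  )
  base + jit
}

#' Aggregate building blocks into an assembly of controlled morphology
#'
#' Places `n_blocks` randomly oriented copies of the block on a connected
#' scaffold (line, plane, close packing, or random-walk cluster) and
#' calibrates the block spacing by bisection so that the mean per-monomer
#' contact valency matches `target_valency`. If the target is unreachable
#' for the mode, the best-effort assembly is returned with a warning and the
#' achieved valency recorded.
#'
#' @param block_frame An `assembly_frame` from [generate_building_block()].
#' @param morph A `morphology_spec`.
#' @return An `assembly_frame` with attributes `achieved_valency`,
#'   `spacing`, and `morphology`.
#' @export
aggregate_assembly <- function(block_frame, morph) {
  stopifnot(inherits(block_frame, "assembly_frame"),
            inherits(morph, "morphology_spec"))
  n <- morph$n_blocks
  with_seed(derive_seed(morph$seed, "aggregate"), {
    local <- coords_matrix(block_frame)
    # characteristic block size sets the spacing search bracket
    rb <- max(sqrt(rowSums(local^2)))
    pep_rows <- block_frame$type == "peptide"
    block_rg <- compute_rg(block_frame, pep_rows)
    target <- morph$target_valency
    best <- NULL
    # if the regular scaffold's neighbour-distance degeneracy leaves the
    # target valency in a gap of the valency-vs-spacing curve, retry with
    # stronger lattice jitter, which smears the gap
    for (jitter in c(0.04, 0.1, 0.16)) {
      centers <- morphology_centers(morph$mode, n, jitter = jitter)
      rots <- replicate(n, random_rotation(), simplify = FALSE)
      rotated <- lapply(rots, function(R) local %*% t(R))
      build <- function(s) {
        xyz <- do.call(rbind, lapply(seq_len(n), function(k) {
          sweep(rotated[[k]], 2, s * centers[k, ], "+")
        }))
        relabel_assembly(block_frame, xyz, n)
      }
      if (n == 1L) {
        out <- build(2 * rb)
        attr(out, "achieved_valency") <- mean_valency(
          detect_contacts(out, cutoff = morph$contact_gap))
        attr(out, "spacing") <- NA_real_
        attr(out, "morphology") <- morph
        attr(out, "block_rg") <- block_rg
        return(out)
      }
      val_at <- function(s) {
        mean_valency(detect_contacts(build(s), cutoff = morph$contact_gap,
                                     bridges = FALSE))
      }
      lo <- 0.9 * rb; hi <- 2.6 * rb
      v_lo <- val_at(lo); v_hi <- val_at(hi)
      if (target >= v_lo) {
        s_best <- lo
      } else if (target <= v_hi) {
        s_best <- hi
      } else {
        for (it in seq_len(14L)) {
          mid <- (lo + hi) / 2
          v_mid <- val_at(mid)
          if (v_mid > target) lo <- mid else hi <- mid
          if (abs(v_mid - target) / max(target, 1e-9) < 0.03) break
        }
        s_best <- (lo + hi) / 2
      }
      out <- build(s_best)
      v_best <- mean_valency(detect_contacts(out, cutoff = morph$contact_gap,
                                             bridges = FALSE))
      if (is.null(best) || abs(v_best - target) < abs(best$v - target)) {
        best <- list(out = out, v = v_best, s = s_best)
      }
      if (target <= 0 || abs(v_best - target) / target <= 0.25) break
    }
    if (target > 0 && abs(best$v - target) / target > 0.25) {
      warning("target_valency ", target, " unreachable for mode '",
              morph$mode, "'; achieved ", sprintf("%.2f", best$v),
              call. = FALSE)
    }
    out <- best$out
    attr(out, "achieved_valency") <- best$v
    attr(out, "spacing") <- best$s
    attr(out, "morphology") <- morph
    attr(out, "block_radius") <- rb
    attr(out, "block_rg") <- block_rg
    out
  })
}

# Replicate the block topology n times with globally unique chain labels.
relabel_assembly <- function(block_frame, xyz, n) {
  pep_sel <- block_frame$type == "peptide"
  chains0 <- unique(block_frame$chain[pep_sel])
  n_pep_chain <- length(chains0)
  labels <- make_chain_labels(n * n_pep_chain)
  one <- as.data.frame(block_frame)
  rows <- do.call(rbind, lapply(seq_len(n), function(k) {
    d <- one
    idx <- match(d$chain, chains0)
    newch <- ifelse(is.na(idx), "0", labels[(k - 1L) * n_pep_chain + idx])
    d$chain <- newch
    # keep counterion residue ids unique across blocks
    ion <- d$type == "counterion"
    d$resid[ion] <- d$resid[ion] + (k - 1L) * sum(ion)
    d
  }))
  assembly_frame(xyz[, 1], xyz[, 2], xyz[, 3], rows$chain, rows$resid,
                 rows$resname, rows$mass, rows$type, rows$radius)
}

# ---- Peak tables -----------------------------------------------------------

#' Reference peak table for a peptide
#'
#' Draws plausible backbone amide (or side-chain) shifts for use as the
#' free-peptide reference state of a perturbation experiment.
#'
#' @param peptide A `peptide_spec`.
#' @param nucleus Nucleus pair tag.
#' @param seed Integer seed.
#' @return A `peak_table`.
#' @export
reference_peak_table <- function(peptide, nucleus = "H-N", seed = 1L) {
  stopifnot(inherits(peptide, "peptide_spec"))
  n <- length(peptide$residues)
  with_seed(derive_seed(seed, "reference"), {
    peak_table(
      residue = seq_len(n),
      label = paste0(peptide$residues, seq_len(n)),
      shift_a = stats::rnorm(n, 8.3, 0.25),
      shift_b = stats::rnorm(n, 119, 3.5),
      intensity = stats::runif(n, 0.9, 1.1),
      nucleus = nucleus
    )
  })
}

#' Synthesize a perturbed peak table
#'
#' Emulates the spectral signature of self-assembly: chemical shifts move by
#' a chosen per-residue perturbation profile and intensities attenuate with
#' the fraction of peptides bound into (NMR-invisible) large assemblies,
#' with an optional boost for surface residues that retain flexibility.
#'
#' @param reference A `peak_table` for the free state.
#' @param bound_fraction Fraction of peptides bound into large assemblies
#'   (0..1); the residual dissolved fraction is `1 - bound_fraction`.
#' @param csp_profile Optional list with numeric vectors `a` and `b`:
#'   per-residue shift offsets in ppm added to `shift_a`/`shift_b`.
#' @param noise_sd Gaussian noise sd applied to shifts (ppm) and intensities.
#' @param seed Integer seed.
#' @param surface_residues Residue indices whose intensities are boosted.
#' @param surface_boost Multiplicative intensity boost for surface residues
#'   (default 1, no boost).
#' @return A perturbed `peak_table`.
#' @export
synth_peak_tables <- function(reference, bound_fraction, csp_profile = NULL,
                              noise_sd = 0, seed = 1L,
                              surface_residues = integer(0),
                              surface_boost = 1) {
  stopifnot(inherits(reference, "peak_table"))
  if (bound_fraction < 0 || bound_fraction > 1) {
    stop("bound_fraction must be within [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- nrow(reference)
  da <- db <- numeric(n)
  if (!is.null(csp_profile)) {
    da <- rep_len(csp_profile$a %||% 0, n)
    db <- rep_len(csp_profile$b %||% 0, n)
  }
  boost <- ifelse(reference$residue %in% surface_residues, surface_boost, 1)
  with_seed(derive_seed(seed, "peaks"), {
    shift_a <- reference$shift_a + da + stats::rnorm(n, 0, noise_sd)
    shift_b <- reference$shift_b + db + stats::rnorm(n, 0, noise_sd)
    intensity <- reference$intensity * (1 - bound_fraction) * boost +
      stats::rnorm(n, 0, noise_sd)
    intensity <- pmax(intensity, 0)
    peak_table(reference$residue, reference$label, shift_a, shift_b,
               intensity, nucleus = attr(reference, "nucleus"))
  })
}

# ---- DOSY ------------------------------------------------------------------

#' Synthesize a Stejskal-Tanner DOSY decay
#'
#' `I(g) = I0 exp(-D gamma^2 g^2 delta^2 (Delta - delta/3))` plus Gaussian
#' noise. Defaults follow a 128-point acquisition with gradients 0 to
#' 0.1 T/m and a 60 ms diffusion delay.
#'
#' @param D Diffusion coefficient in m^2/s (> 0).
#' @param gradients Gradient grid in T/m, strictly increasing.
#' @param Delta Diffusion delay in s.
#' @param delta Gradient pulse length in s.
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#' @param I0 Zero-gradient integral.
#' @param noise_sd Gaussian noise sd (same units as `I0`).
#' @param seed Integer seed.
#' @param temperature,viscosity Carried in the series for the
#'   Stokes-Einstein conversion.
#' @return A `dosy_series`.
#' @export
synth_dosy_series <- function(D, gradients = seq(0, 0.1, length.out = 128),
                              Delta = 0.06, delta = 0.015, gamma = GAMMA_1H,
                              I0 = 1, noise_sd = 0, seed = 1L,
                              temperature = 298.15, viscosity = 8.937e-4) {
  stop_if_not_scalar_pos(D, "D")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  series <- dosy_series(gradients, rep(0, length(gradients)), Delta = Delta,
                        delta = delta, gamma = gamma,
                        temperature = temperature, viscosity = viscosity)
  b <- st_b_factor(series)
  with_seed(derive_seed(seed, "dosy"), {
    series$integral <- I0 * exp(-D * b) +
      stats::rnorm(length(b), 0, noise_sd)
  })
  attr(series, "true_D") <- D
  series
}

# ---- Kinetics --------------------------------------------------------------

#' Synthesize real-time silicification decay traces
#'
#' Each residue decays as `I_r(t) = (1 - plateau) exp(-k_r t) + plateau`
#' toward the residual dissolved plateau; surface residues (adjacent to the
#' silica nucleation sites) use the faster `surface_rate`, all others
#' `core_rate`. Defaults mirror a 7 h acquisition with one spectrum every
#' 140 s and a 17% residual plateau.
#'
#' @param residues Integer residue indices.
#' @param surface_residues Residues using `surface_rate`.
#' @param surface_rate,core_rate Decay rates in s^-1
#'   (`surface_rate >= core_rate > 0`).
#' @param plateau_fraction Residual dissolved fraction in [0, 1].
#' @param times Time grid in s.
#' @param noise_sd Gaussian noise sd on normalized intensities.
#' @param seed Integer seed.
#' @return A `kinetic_traces` object with attribute `true_rates`.
#' @export
synth_kinetic_traces <- function(residues = 1:19,
                                 surface_residues = 16:19,
                                 surface_rate = 2e-3, core_rate = 1e-3,
                                 plateau_fraction = 0.17,
                                 times = seq(0, 25200, by = 140),
                                 noise_sd = 0, seed = 1L) {
  if (!length(times)) stop("empty time grid", call. = FALSE)
  if (!(surface_rate >= core_rate && core_rate > 0)) {
    stop("need surface_rate >= core_rate > 0", call. = FALSE)
  }
  if (plateau_fraction < 0 || plateau_fraction > 1) {
    stop("plateau_fraction must be within [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  rates <- ifelse(residues %in% surface_residues, surface_rate, core_rate)
  clean <- vapply(rates, function(k) {
    (1 - plateau_fraction) * exp(-k * times) + plateau_fraction
  }, numeric(length(times)))
  with_seed(derive_seed(seed, "kinetics"), {
    noisy <- clean + matrix(stats::rnorm(length(clean), 0, noise_sd),
                            nrow = nrow(clean))
  })
  out <- kinetic_traces(times, noisy, residues = residues,
                        surface_residues = surface_residues,
                        normalize = FALSE)
  attr(out, "true_rates") <- stats::setNames(rates, paste0("r", residues))
  attr(out, "true_plateau") <- plateau_fraction
  out
}

# ---- Crowded box -----------------------------------------------------------

#' Crowded-box density and edge length
#'
#' Peptide packing density matched to the hydrodynamic radius of the trimer
#' building block, `d = 9 m u / (4 pi Rh^3)` (three peptides in a sphere of
#' radius `Rh`), and the cubic box edge that holds `n_peptides` at that
#' density.
#'
#' @param peptide_mass_Da Peptide molecular weight in Da.
#' @param n_peptides Number of peptide copies in the box.
#' @param Rh_nm Hydrodynamic radius of the trimer block in nm.
#' @return List with `density_g_per_ml` and `edge_nm`.
#' @export
#' @examples
#' build_crowded_box(peptide_mass(r5_peptide()), n_peptides = 75, Rh_nm = 1.3)
build_crowded_box <- function(peptide_mass_Da, n_peptides, Rh_nm) {
  stop_if_not_scalar_pos(peptide_mass_Da, "peptide_mass_Da")
  stop_if_not_scalar_pos(n_peptides, "n_peptides")
  stop_if_not_scalar_pos(Rh_nm, "Rh_nm")
  rh_cm <- Rh_nm * 1e-7
  density <- 9 * peptide_mass_Da * AMU_G / (4 * pi * rh_cm^3)
  vol_cm3 <- n_peptides * peptide_mass_Da * AMU_G / density
  list(density_g_per_ml = density, edge_nm = vol_cm3^(1 / 3) * 1e7)
}

# ---- Manifest --------------------------------------------------------------

#' Ground-truth manifest for a synthetic dataset
#'
#' Records every generator parameter plus the ground-truth quantities
#' (dimensionality, bound fraction, decay rates, diffusion coefficient) so a
#' dataset can be regenerated bit-identically from its seed.
#'
#' @param seed Master seed.
#' @param ... Named generator parameters and ground-truth values.
#' @return An object of class `ground_truth_manifest`.
#' @export
ground_truth_manifest <- function(seed, ...) {
  structure(c(list(seed = as.integer(seed)), list(...)),
            class = "ground_truth_manifest")
}

#' Write a manifest as JSON
#' @param manifest A `ground_truth_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a manifest from JSON
#' @param path JSON path.
#' @return A `ground_truth_manifest`.
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "ground_truth_manifest")
}
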