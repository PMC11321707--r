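# Shared fixtures, built once per test run.

# Single R5/phosphate trimer block (deterministic).
fixture_block <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_building_block(r5_block(), seed = 42)
    cache
  }
})

# Small aggregate per morphology, cached by (mode, n_blocks, seed).
fixture_assembly <- local({
  cache <- list()
  function(mode, n_blocks = 12, seed = 1, target_valency = 4) {
    key <- paste(mode, n_blocks, seed, target_valency, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- aggregate_assembly(
        fixture_block(),
        morphology_spec(mode, n_blocks, target_valency, seed = seed))
    }
    cache[[key]]
  }
})

# A plain frame of unit-mass beads at given coordinates (no generator).
bead_frame <- function(xyz, chain = "A", mass = 1, radius = 3,
                       box = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  chain <- rep_len(chain, n)
  assembly_frame(xyz[, 1], xyz[, 2], xyz[, 3], chain = chain,
                 resid = stats::ave(seq_len(n), chain, FUN = seq_along),
                 resname = "GLY", mass = rep_len(mass, n),
                 type = "peptide", radius = radius, box = box)
}

# Independent brute-force oracles ------------------------------------------

# Mass-radius dimension by direct counting and log-log regression,
# written independently of the package implementation.
oracle_mass_radius <- function(xyz, r_min, r_max, n_r = 24) {
  ctr <- colMeans(xyz)
  ctr <- xyz[which.min(colSums((t(xyz) - ctr)^2)), ]
  r <- sqrt(colSums((t(xyz) - ctr)^2))
  grid <- exp(seq(log(r_min), log(r_max), length.out = n_r))
  counts <- sapply(grid, function(g) sum(r <= g))
  keep <- counts >= 2
  unname(coef(lm(log(counts[keep]) ~ log(grid[keep])))[2])
}

# Debye sum as a literal double loop.
oracle_debye <- function(xyz_nm, w, q) {
  n <- nrow(xyz_nm)
  sapply(q, function(qq) {
    s <- 0
    for (i in 1:n) for (j in 1:n) {
      r <- sqrt(sum((xyz_nm[i, ] - xyz_nm[j, ])^2))
      s <- s + w[i] * w[j] * (if (qq * r < 1e-12) 1 else sin(qq * r) / (qq * r))
    }
    s
  })
}
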