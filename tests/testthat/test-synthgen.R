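# Synthetic-data generator: masses, blocks, aggregates, signal streams.

test_that("peptide_mass sums average residue masses plus one water", {
  expect_equal(peptide_mass("G"), 75.07, tolerance = 0.001)
  # brute-force oracle over the residue table for R5
  tab <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
           C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
           H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
           M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
           T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  r5 <- "SSKKSGSYSGSKGSKRRIL"
  oracle <- sum(tab[strsplit(r5, "")[[1]]]) + 18.0153
  expect_equal(peptide_mass(r5_peptide()), oracle)
  expect_lt(abs(peptide_mass(r5_peptide()) - 2013.3), 0.5)
  expect_error(peptide_spec("bad", ""), "non-empty")
  expect_error(peptide_mass("GXZ"), "invalid residue")
})

test_that("building blocks have the right bookkeeping and no overlaps", {
  blk <- fixture_block()
  pep <- blk[blk$type == "peptide", ]
  expect_identical(sort(unique(pep$chain)), c("A", "B", "C"))
  expect_equal(nrow(pep), 3 * 19)
  expect_gt(sum(blk$type == "counterion"), 0)
  # no two beads closer than 0.8 x the sum of their radii
  d <- as.matrix(dist(cbind(blk$x, blk$y, blk$z)))
  diag(d) <- Inf
  lim <- outer(blk$radius, blk$radius, "+") * 0.8
  expect_true(all(d >= lim - 1e-9))
  # single-copy block is a single chain
  single <- generate_building_block(
    building_block(r5_peptide(), n_copies = 1), seed = 3)
  expect_equal(length(unique(single$chain[single$type == "peptide"])), 1L)
})

test_that("block generation is deterministic under a fixed seed", {
  a <- generate_building_block(r5_block(), seed = 7)
  b <- generate_building_block(r5_block(), seed = 7)
  expect_identical(a$x, b$x)
  expect_identical(a$z, b$z)
  c <- generate_building_block(r5_block(), seed = 8)
  expect_false(identical(a$x, c$x))
})

test_that("invalid block specifications are rejected", {
  expect_error(building_block(r5_peptide(), n_copies = 0), "n_copies")
  expect_error(building_block(r5_peptide(), linker_sites = list(c(1, 99))),
               "linker_sites")
})

test_that("aggregation preserves the block and hits the target valency", {
  one <- aggregate_assembly(fixture_block(),
                            morphology_spec("compact", 1, seed = 1))
  # single block: same bead count and same internal distances (rigid move)
  expect_equal(nrow(one), nrow(fixture_block()))
  d0 <- dist(cbind(fixture_block()$x, fixture_block()$y, fixture_block()$z))
  d1 <- dist(cbind(one$x, one$y, one$z))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-8)

  asm <- fixture_assembly("compact", 12, seed = 2)
  expect_equal(length(unique(asm$chain[asm$type == "peptide"])), 36L)
  v <- attr(asm, "achieved_valency")
  expect_lt(abs(v - 4) / 4, 0.25)
  # determinism
  asm2 <- aggregate_assembly(fixture_block(),
                             morphology_spec("compact", 12, 4, seed = 2))
  expect_identical(asm$x, asm2$x)
})

test_that("morphology modes produce connected, dimension-ordered assemblies", {
  dims <- sapply(c("linear", "planar", "compact"), function(mode) {
    asm <- fixture_assembly(mode, 30, seed = 5)
    mass_radius_dimension(asm)$estimate
  })
  expect_true(dims["linear"] < dims["planar"])
  expect_true(dims["planar"] < dims["compact"])
  # dla mode grows a connected cluster too
  dla <- fixture_assembly("dla", 15, seed = 1)
  cl <- connected_clusters(detect_contacts(dla, bridges = FALSE))
  expect_lte(cl$n_clusters, 3L)
})

test_that("synthetic peak tables implement the attenuation model", {
  ref <- reference_peak_table(r5_peptide(), seed = 1)
  # zero perturbation reproduces the reference
  same <- synth_peak_tables(ref, bound_fraction = 0, noise_sd = 0)
  expect_equal(same$shift_a, ref$shift_a)
  expect_equal(same$intensity, ref$intensity)
  # 83% bound -> all ratios 0.17
  pert <- synth_peak_tables(ref, bound_fraction = 0.83, noise_sd = 0)
  ir <- intensity_ratio(ref, pert)
  expect_equal(ir$ratio, rep(0.17, nrow(ref)), tolerance = 1e-12)
  # round trip through residual_fraction at moderate noise
  noisy <- synth_peak_tables(ref, bound_fraction = 0.83, noise_sd = 0.01,
                             seed = 11)
  expect_lt(abs(residual_fraction(ref, noisy) - 0.17), 2 * 0.01)
  expect_error(synth_peak_tables(ref, bound_fraction = 1.2), "bound_fraction")
  expect_error(synth_peak_tables(ref, 0.5, noise_sd = -1), "noise_sd")
})

test_that("DOSY decays follow the Stejskal-Tanner closed form", {
  D <- 3e-10
  ser <- synth_dosy_series(D, noise_sd = 0, seed = 1)
  expect_equal(ser$integral[1], 1)  # g = 0
  # scaling identity: curve of D at g equals curve of 2D at g/sqrt(2)
  g <- seq(0, 0.1, length.out = 64)
  s1 <- synth_dosy_series(D, gradients = g[-1], noise_sd = 0)
  s2 <- synth_dosy_series(2 * D, gradients = g[-1] / sqrt(2), noise_sd = 0)
  expect_equal(s1$integral, s2$integral, tolerance = 1e-12)
  # noise-free round trip
  fit <- fit_stejskal_tanner(ser)
  expect_lt(abs(fit$D - D) / D, 1e-3)
  expect_error(synth_dosy_series(D, gradients = c(0, 0.02, 0.05, 0.04, 0.1)),
               "increasing")
  expect_error(synth_dosy_series(D, Delta = 0.01, delta = 0.02), "Delta")
})

test_that("kinetic traces decay from 1 toward the plateau", {
  tr <- synth_kinetic_traces(noise_sd = 0, seed = 1)
  expect_true(all(abs(tr$intensities[1, ] - 1) < 1e-12))
  long <- synth_kinetic_traces(times = seq(0, 2e4, length.out = 50) + 1e6,
                               noise_sd = 0)
  expect_true(all(abs(long$intensities - 0.17) < 1e-6))
  # noise-free rate recovery
  rates <- fit_kinetic_traces(tr)
  expect_true(all(abs(rates$k - rates$true_k) / rates$true_k < 1e-3))
  expect_error(synth_kinetic_traces(times = numeric(0)), "time grid")
  expect_error(synth_kinetic_traces(surface_rate = 1e-4, core_rate = 1e-3),
               "surface_rate")
})

test_that("crowded-box density follows d = 9 m u / (4 pi Rh^3)", {
  bx <- build_crowded_box(2013.3, 75, 1.3)
  expect_equal(bx$density_g_per_ml, 1.09, tolerance = 0.005)
  # Rh^-3 scaling
  bx2 <- build_crowded_box(2013.3, 75, 2.6)
  expect_equal(bx$density_g_per_ml / bx2$density_g_per_ml, 8,
               tolerance = 1e-9)
  # mass conservation: edge^3 x density = total mass
  u <- 1.66053906660e-24
  vol_ml <- (bx$edge_nm * 1e-7)^3
  expect_equal(vol_ml * bx$density_g_per_ml, 75 * 2013.3 * u)
})

test_that("manifests round-trip through JSON", {
  man <- ground_truth_manifest(13, mode = "compact", n_blocks = 20,
                               true_bound_fraction = 0.83)
  path <- tempfile(fileext = ".json")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back$seed, 13)
  expect_equal(back$true_bound_fraction, 0.83)
  expect_equal(back$mode, "compact")
})
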