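# Fractal-cluster metrics: Rg, contacts, valency, compactness, d_f,
# mass-radius oracle, trajectory windows.

test_that("compute_rg matches closed-form cases and is rigid-motion invariant", {
  expect_equal(compute_rg(bead_frame(matrix(0, 1, 3))), 0)
  two <- bead_frame(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(compute_rg(two), 1)
  cube <- bead_frame(as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2))))
  expect_equal(compute_rg(cube), sqrt(3), tolerance = 1e-12)
  # translation + rotation invariance
  xyz <- matrix(rnorm(60), 20, 3)
  f <- bead_frame(xyz)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  g <- bead_frame(sweep(xyz %*% R, 2, c(5, -3, 11), "+"))
  expect_equal(compute_rg(f), compute_rg(g), tolerance = 1e-10)
  # mass weighting changes the answer when masses differ
  fm <- bead_frame(rbind(c(0, 0, 0), c(2, 0, 0)), mass = c(1, 3))
  expect_equal(compute_rg(fm), sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(compute_rg(fm, mass_weighted = FALSE), 1)
  expect_error(compute_rg(f, integer(0)), "empty selection")
})

test_that("contact detection counts chain partners and counterion bridges", {
  # two chains far apart: no contacts
  far <- bead_frame(rbind(c(0, 0, 0), c(100, 0, 0)), chain = c("A", "B"))
  expect_equal(igraph::ecount(detect_contacts(far)$graph), 0)
  # touching chains: one edge
  near <- bead_frame(rbind(c(0, 0, 0), c(7, 0, 0)), chain = c("A", "B"))
  g <- detect_contacts(near)  # surface gap 1 < 4.5
  expect_equal(igraph::ecount(g$graph), 1)
  expect_equal(mean_valency(g), 1)
  # four mutually touching chains: complete graph, valency 3
  sq <- bead_frame(rbind(c(0, 0, 0), c(7, 0, 0), c(0, 7, 0), c(7, 7, 0)),
                   chain = c("A", "B", "C", "D"))
  g4 <- detect_contacts(sq)
  expect_equal(unname(g4$degrees), rep(3L, 4))
  expect_equal(mean_valency(g4), 3)
  # counterion bead bridging two chains is excluded from the peptide graph
  # but reported as a bridge
  bridged <- assembly_frame(
    x = c(0, 20, 10), y = c(0, 0, 0), z = c(0, 0, 0),
    chain = c("A", "B", "0"), resid = c(1, 1, 1),
    resname = c("GLY", "GLY", "PI"), mass = c(57, 57, 97),
    type = c("peptide", "peptide", "counterion"), radius = c(3, 3, 2))
  gb <- detect_contacts(bridged, cutoff = 6)
  expect_equal(igraph::ecount(gb$graph), 0)
  expect_equal(nrow(gb$bridges), 1)
  expect_equal(gb$bridges$n_bridges, 1L)
})

test_that("pair-count valency mode counts bead pairs, not partners", {
  # chains of 2 beads each, all 4 cross pairs in contact
  f <- bead_frame(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 7, 0), c(5, 7, 0)),
                  chain = c("A", "A", "B", "B"))
  g <- detect_contacts(f, cutoff = 4.5)
  expect_equal(mean_valency(g), 1)           # one partner each
  expect_equal(mean_valency(g, "pairs"), 4)  # four bead pairs each
})

test_that("connected_clusters partitions chains and flags the assembly", {
  f <- bead_frame(rbind(c(0, 0, 0), c(7, 0, 0), c(100, 0, 0), c(107, 0, 0),
                        c(114, 0, 0)),
                  chain = c("A", "B", "C", "D", "E"))
  cl <- connected_clusters(detect_contacts(f))
  expect_equal(cl$n_clusters, 2L)
  expect_setequal(cl$largest, c("C", "D", "E"))
})

test_that("molecular volume and compactness follow the closed forms", {
  expect_equal(molecular_volume(1000), 1210)
  expect_equal(molecular_volume(0), 0)
  expect_equal(molecular_volume(2000), 2 * molecular_volume(1000))
  # direct arithmetic: Mw 6000 Da, kappa 1.21, Rg 12 A
  cube_edge <- 2 * 12 / sqrt(3)  # 8 corners at distance 12 from centre
  corners <- as.matrix(expand.grid(c(0, cube_edge), c(0, cube_edge),
                                   c(0, cube_edge)))
  f <- bead_frame(corners, mass = 750)  # total 6000 Da
  cp <- compactness(f)
  expect_equal(cp$Rg, 12, tolerance = 1e-12)
  expect_equal(cp$phi, 7260 / ((4 / 3) * pi * 12^3), tolerance = 1e-12)
  expect_equal(cp$phi, 1.003, tolerance = 1e-3)
  # phi scales as Rg^-3 at fixed mass
  f2 <- bead_frame(corners * 2, mass = 750)
  expect_equal(compactness(f2)$phi, cp$phi / 8, tolerance = 1e-10)
  expect_error(compactness(bead_frame(matrix(0, 1, 3))), "Rg is zero")
})

test_that("fractal dimension implements d_f = 3 / (1 - log phi / log valency)", {
  # maximally compact limit: phi = 1 gives exactly 3 for any valency > 1
  expect_equal(as.numeric(fractal_dimension(1, 2)), 3)
  expect_equal(as.numeric(fractal_dimension(1, 7.3)), 3)
  # closed form away from the limit
  expect_equal(as.numeric(fractal_dimension(2, 4)),
               3 / (1 - log(2) / log(4)))
  expect_equal(as.numeric(fractal_dimension(0.5, 4)),
               3 / (1 + log(2) / log(4)))
  # looser packing (smaller phi) lowers d_f: increasing in phi on (0, v)
  phis <- c(0.01, 0.1, 0.5, 0.9, 1)
  dfs <- as.numeric(fractal_dimension(phis, 4))
  expect_true(all(diff(dfs) > 0))
  expect_true(all(dfs <= 3))
  # undefined inputs are flagged, not thrown
  out <- fractal_dimension(c(1, -1, 2, 4), c(2, 3, 1, 4))
  expect_equal(attr(out, "flag"),
               c("ok", "undefined", "undefined", "undefined"))
  expect_true(all(is.na(out[2:4])))
  # phi > 1 pushes d_f above 3: reported with an out-of-range flag
  hi <- fractal_dimension(2, 4)
  expect_equal(attr(hi, "flag"), "out-of-range")
  expect_gt(as.numeric(hi), 3)
})

test_that("mass-radius estimator recovers the dimension of reference shapes", {
  # straight line of 100 beads
  line <- bead_frame(cbind(seq(0, 495, by = 5), 0, 0))
  mr <- mass_radius_dimension(line)
  expect_gt(mr$estimate, 0.8); expect_lt(mr$estimate, 1.4)
  # filled 5x5x5 cubic lattice (125 beads)
  lat <- bead_frame(as.matrix(expand.grid(0:4, 0:4, 0:4)) * 6)
  mr3 <- mass_radius_dimension(lat)
  expect_gt(mr3$estimate, 2.6); expect_lt(mr3$estimate, 3.2)
  # 10x10 square sheet
  sheet <- bead_frame(cbind(as.matrix(expand.grid(0:9, 0:9)) * 6, 0))
  mr2 <- mass_radius_dimension(sheet)
  expect_gt(mr2$estimate, 1.7); expect_lt(mr2$estimate, 2.3)
  # agreement with the independently coded counting oracle
  xyz <- as.matrix(expand.grid(0:4, 0:4, 0:4)) * 6
  expect_equal(mr3$estimate,
               oracle_mass_radius(xyz, mr3$r_min, mr3$r_max),
               tolerance = 1e-10)
  expect_error(mass_radius_dimension(bead_frame(matrix(rnorm(30), 10, 3))),
               "at least 20 beads")
})

test_that("rg_to_rh divides by 1.1", {
  expect_equal(rg_to_rh(1.1), 1)
  expect_equal(rg_to_rh(0), 0)
  expect_equal(rg_to_rh(0.88), 0.8)
  expect_error(rg_to_rh(-1), ">= 0")
})

test_that("chains are unwrapped across periodic boundaries before Rg", {
  # a 3-bead chain straddling the x boundary of a 30 A box
  wrapped <- bead_frame(rbind(c(29, 0, 0), c(1, 0, 0), c(3, 0, 0)),
                        box = c(30, 30, 30))
  # unwrapped equivalent
  flat <- bead_frame(rbind(c(29, 0, 0), c(31, 0, 0), c(33, 0, 0)))
  expect_equal(compute_rg(wrapped), compute_rg(flat), tolerance = 1e-10)
  # contacts across the boundary: chains at opposite box faces touch
  pair <- bead_frame(rbind(c(1, 0, 0), c(29, 0, 0)), chain = c("A", "B"),
                     box = c(30, 30, 30))
  expect_equal(igraph::ecount(detect_contacts(pair)$graph), 1)
})

test_that("trajectory windows average per-frame metrics", {
  asm <- fixture_assembly("compact", 8, seed = 3)
  frames <- lapply(0:4, function(k) {
    f <- asm
    attr(f, "time") <- k
    f
  })
  traj <- trajectory(frames)
  fm <- analyze_trajectory(traj, window = "last:40%")
  expect_equal(nrow(fm$per_frame), 2L)
  expect_true(all(fm$summary$sd == 0))  # frozen trajectory
  # full window equals the mean of per-frame values (trivially, frozen)
  fm_all <- analyze_trajectory(traj, window = "all")
  expect_equal(nrow(fm_all$per_frame), 5L)
  expect_equal(fm_all$summary$mean, fm$summary$mean)
  # single-frame metrics match a direct computation on the largest cluster
  cg <- detect_contacts(asm, bridges = FALSE)
  cl <- connected_clusters(cg)
  cp <- compactness(asm, cl$largest)
  expect_equal(fm$summary$mean[fm$summary$metric == "Rg"], cp$Rg)
  expect_equal(fm$summary$mean[fm$summary$metric == "phi"], cp$phi)
  expect_error(analyze_trajectory(traj, window = c(100, 200)), "empty")
})
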