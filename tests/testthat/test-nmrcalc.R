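# NMR observables: CSP, intensity ratios, decay rates, DOSY, relaxation.

make_peaks <- function(shift_a, shift_b, intensity,
                       residue = seq_along(shift_a), nucleus = "H-N") {
  peak_table(residue, paste0("r", residue), shift_a, shift_b, intensity,
             nucleus = nucleus)
}

test_that("CSP follows the weighted Euclidean convention", {
  ref <- make_peaks(c(8.1, 8.3, 8.5), c(118, 120, 122), c(1, 1, 1))
  expect_equal(chemical_shift_perturbation(ref, ref)$csp, c(0, 0, 0))
  # pure 1H shift passes through unweighted
  p1 <- make_peaks(c(8.2, 8.3, 8.5), c(118, 120, 122), c(1, 1, 1))
  expect_equal(chemical_shift_perturbation(ref, p1)$csp[1], 0.1,
               tolerance = 1e-12)
  # pure 15N shift is scaled by 0.14
  p2 <- make_peaks(c(8.1, 8.3, 8.5), c(119, 120, 122), c(1, 1, 1))
  expect_equal(chemical_shift_perturbation(ref, p2)$csp[1], 0.14,
               tolerance = 1e-12)
  # 13C-15N pairs weight both dimensions
  refc <- make_peaks(c(55, 56), c(118, 120), c(1, 1), nucleus = "C-N")
  pc <- make_peaks(c(56, 56), c(118, 120), c(1, 1), nucleus = "C-N")
  expect_equal(chemical_shift_perturbation(refc, pc)$csp[1], 0.30,
               tolerance = 1e-12)
  # mismatched nucleus tags are an error
  expect_error(chemical_shift_perturbation(ref, pc), "nucleus")
})

test_that("CSP is symmetric and invariant under a common shift offset", {
  set.seed(5)
  ref <- make_peaks(rnorm(10, 8.3, 0.2), rnorm(10, 119, 3), runif(10))
  pert <- make_peaks(ref$shift_a + rnorm(10, 0, 0.05),
                     ref$shift_b + rnorm(10, 0, 0.5), runif(10))
  a <- chemical_shift_perturbation(ref, pert)$csp
  b <- chemical_shift_perturbation(pert, ref)$csp
  expect_equal(a, b, tolerance = 1e-12)
  shift <- function(pt, d) {
    make_peaks(pt$shift_a + d, pt$shift_b + d, pt$intensity)
  }
  c2 <- chemical_shift_perturbation(shift(ref, 3), shift(pert, 3))$csp
  expect_equal(a, c2, tolerance = 1e-10)
  # residues missing in one table are flagged absent, not zero
  miss <- make_peaks(ref$shift_a[-3], ref$shift_b[-3], ref$intensity[-3],
                     residue = ref$residue[-3])
  out <- chemical_shift_perturbation(ref, miss)
  expect_equal(out$status[out$residue == 3], "absent")
  expect_true(is.na(out$csp[out$residue == 3]))
})

test_that("intensity ratios and residual fraction behave as scalars demand", {
  ref <- make_peaks(rep(8.3, 5), rep(119, 5), c(1, 2, 0.5, 1.5, 1))
  expect_equal(intensity_ratio(ref, ref)$ratio, rep(1, 5))
  scaled <- make_peaks(ref$shift_a, ref$shift_b, 0.17 * ref$intensity)
  expect_equal(intensity_ratio(ref, scaled)$ratio, rep(0.17, 5),
               tolerance = 1e-12)
  # residual_fraction(x, c x) = c to machine precision
  for (cc in c(0.007, 0.17, 0.83)) {
    sc <- make_peaks(ref$shift_a, ref$shift_b, cc * ref$intensity)
    expect_equal(residual_fraction(ref, sc), cc, tolerance = 1e-14)
  }
  # explicit mean: {0.1, 0.3} -> 0.2
  r2 <- make_peaks(c(8, 8.2), c(119, 120), c(1, 1), residue = 1:2)
  p2 <- make_peaks(c(8, 8.2), c(119, 120), c(0.1, 0.3), residue = 1:2)
  expect_equal(residual_fraction(r2, p2), 0.2)
  # detection floor removes residues from the mean
  p3 <- make_peaks(c(8, 8.2), c(119, 120), c(0.001, 0.3), residue = 1:2)
  ir <- intensity_ratio(r2, p3, floor = 0.01)
  expect_equal(ir$status, c("below_detection", "ok"))
  expect_equal(residual_fraction(r2, p3, floor = 0.01), 0.3)
  # I0 = 0 is undefined per residue
  r0 <- make_peaks(c(8, 8.2), c(119, 120), c(0, 1), residue = 1:2)
  expect_equal(intensity_ratio(r0, p2)$status[1], "undefined")
})

test_that("exponential decay fits recover rates and plateaus", {
  t <- seq(0, 25200, by = 140)
  # constant trace: k = 0 exactly
  flat <- fit_exponential_decay(t, rep(0.8, length(t)))
  expect_equal(flat$k, 0)
  # noise-free plateau model recovered to 0.1%
  y <- 0.83 * exp(-0.01 * t / 10) + 0.17
  fit <- fit_exponential_decay(t, y)
  expect_lt(abs(fit$k - 1e-3) / 1e-3, 1e-3)
  expect_lt(abs(fit$B - 0.17), 1e-4)
  # short traces are rejected
  expect_error(fit_exponential_decay(1:3, c(3, 2, 1)), "time points")
})

test_that("rate fits stay within 5% at 1% noise across seeds", {
  errs <- sapply(1:10, function(s) {
    tr <- synth_kinetic_traces(noise_sd = 0.01, seed = s)
    rates <- fit_kinetic_traces(tr)
    max(abs(rates$k - rates$true_k) / rates$true_k)
  })
  expect_lt(max(errs), 0.05)
})

test_that("surface/core classification finds the fast residues", {
  tr <- synth_kinetic_traces(noise_sd = 0.01, seed = 9)
  rates <- classify_residue_kinetics(fit_kinetic_traces(tr))
  expect_setequal(rates$residue[rates$class == "surface"], 16:19)
  # uniform rates: no surface labels (noise-free)
  uni <- synth_kinetic_traces(surface_rate = 1e-3, core_rate = 1e-3,
                              noise_sd = 0, seed = 1)
  ru <- classify_residue_kinetics(fit_kinetic_traces(uni))
  expect_equal(sum(ru$class == "surface"), 0L)
  # single outlier: exactly one surface label
  out <- data.frame(residue = 1:5, k = c(1, 1.001, 0.999, 1, 5),
                    converged = TRUE)
  co <- classify_residue_kinetics(out)
  expect_equal(which(co$class == "surface"), 5L)
  expect_error(classify_residue_kinetics(
    data.frame(residue = 1:2, k = c(1, 2), converged = TRUE)),
    "at least 3")
})

test_that("Stejskal-Tanner fits recover D and flag degenerate data", {
  D <- 3e-10
  ser <- synth_dosy_series(D, noise_sd = 0)
  fit <- fit_stejskal_tanner(ser)
  expect_lt(abs(fit$D - D) / D, 1e-3)
  # linearized cross-check: ln I vs g^2 slope equals -D gamma^2 delta^2 (Delta - delta/3)
  g <- ser$gradient[-1]
  sl <- unname(coef(lm(log(ser$integral[-1]) ~ I(g^2)))[2])
  k_st <- attr(ser, "gamma")^2 * attr(ser, "delta")^2 *
    (attr(ser, "Delta") - attr(ser, "delta") / 3)
  expect_equal(sl, -D * k_st, tolerance = 1e-6 * abs(D * k_st))
  # constant integrals: D = 0 with a no-decay flag
  flat <- dosy_series(seq(0.001, 0.1, length.out = 20), rep(1, 20))
  ff <- fit_stejskal_tanner(flat)
  expect_equal(ff$D, 0)
  expect_equal(ff$flag, "no-decay")
})

test_that("Stokes-Einstein conversions are exact inverses", {
  expect_equal(stokes_einstein_radius(3.054e-10), 0.80, tolerance = 0.002)
  # Rh inversely proportional to eta and D
  expect_equal(stokes_einstein_radius(3e-10, viscosity = 2 * 8.937e-4),
               stokes_einstein_radius(3e-10) / 2, tolerance = 1e-12)
  expect_equal(stokes_einstein_radius(6e-10),
               stokes_einstein_radius(3e-10) / 2, tolerance = 1e-12)
  # round trip through the inverse
  for (rh in c(0.7, 0.8, 1.3, 1.6)) {
    expect_equal(stokes_einstein_radius(stokes_einstein_d(rh)), rh,
                 tolerance = 1e-12)
  }
  expect_error(stokes_einstein_radius(-1), "D must be > 0")
})

test_that("relaxation rates come from a zero-plateau exponential fit", {
  tau <- seq(0.001, 0.5, length.out = 12)
  y <- 2.5 * exp(-10 * tau)
  fit <- fit_relaxation_rate(tau, y)
  expect_lt(abs(fit$R2 - 10) / 10, 1e-3)
  # 2% noise: mean recovery error across seeds stays within 5%
  errs <- sapply(1:50, function(s) {
    set.seed(s)
    yn <- y + rnorm(length(y), 0, 0.02 * y[1])
    abs(fit_relaxation_rate(tau, yn)$R2 - 10) / 10
  })
  expect_lt(mean(errs), 0.05)
  expect_error(fit_relaxation_rate(c(1, 2, 3), c(3, 2, 1)), "delay points")
})

test_that("fits are deterministic given the same data", {
  tr <- synth_kinetic_traces(noise_sd = 0.02, seed = 31)
  r1 <- fit_kinetic_traces(tr)
  r2 <- fit_kinetic_traces(tr)
  expect_identical(r1$k, r2$k)
  ser <- synth_dosy_series(2e-10, noise_sd = 0.01, seed = 5)
  expect_identical(fit_stejskal_tanner(ser)$D, fit_stejskal_tanner(ser)$D)
})
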