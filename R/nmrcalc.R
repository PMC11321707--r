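# NMR-derived observables: chemical shift perturbations, intensity ratios
# and residual dissolved fractions, exponential decay-rate fitting with
# surface/core classification, Stejskal-Tanner diffusion fits and
# Stokes-Einstein radii, relaxation rates.

CSP_WEIGHTS <- list(
  "H-N" = c(a = 1.00, b = 0.14),
  "C-N" = c(a = 0.30, b = 0.14),
  "H-P" = c(a = 1.00, b = 0.14)
)

#' Chemical shift perturbations between two peak tables
#'
#' Weighted Euclidean distance between peak positions,
#' `CSP = sqrt((w_a d_a)^2 + (w_b d_b)^2)`, with the conventional
#' downweighting of the second (heteronuclear) dimension: `w_b = 0.14` for
#' 15N against 1H, and `w_a = 0.30`, `w_b = 0.14` for 13C-15N pairs.
#' Residues missing in either table are flagged absent, not zero.
#'
#' @param reference,perturbed `peak_table`s with the same nucleus pair tag.
#' @param weights Optional length-2 numeric `c(a, b)` overriding the
#'   defaults.
#' @return data.frame with residue, label, csp (ppm), status
#'   ("ok"/"absent").
#' @export
chemical_shift_perturbation <- function(reference, perturbed,
                                        weights = NULL) {
  stopifnot(inherits(reference, "peak_table"),
            inherits(perturbed, "peak_table"))
  nuc <- attr(reference, "nucleus")
  if (!identical(nuc, attr(perturbed, "nucleus"))) {
    stop("nucleus pair tags differ: ", nuc, " vs ",
         attr(perturbed, "nucleus"), call. = FALSE)
  }
  w <- weights %||% CSP_WEIGHTS[[nuc]]
  stopifnot(length(w) == 2L)
  all_res <- sort(union(reference$residue, perturbed$residue))
  i_ref <- match(all_res, reference$residue)
  i_per <- match(all_res, perturbed$residue)
  da <- perturbed$shift_a[i_per] - reference$shift_a[i_ref]
  db <- perturbed$shift_b[i_per] - reference$shift_b[i_ref]
  csp <- sqrt((w[1] * da)^2 + (w[2] * db)^2)
  status <- ifelse(is.na(i_ref) | is.na(i_per), "absent", "ok")
  lab <- ifelse(is.na(i_ref), perturbed$label[i_per], reference$label[i_ref])
  data.frame(residue = all_res, label = lab, csp = csp, status = status,
             stringsAsFactors = FALSE)
}

#' Per-residue intensity ratios I/I0
#'
#' Ratio of perturbed to reference intensity per residue. Peaks with
#' intensity below the detection floor are reported as missing
#' (status "below_detection"), mirroring residues that vanish into large
#' assemblies; `I0 = 0` yields an undefined flag rather than a ratio.
#'
#' @param reference,perturbed `peak_table`s.
#' @param floor Detection threshold on the perturbed intensity (default 0:
#'   report everything).
#' @return data.frame with residue, label, ratio, status.
#' @export
intensity_ratio <- function(reference, perturbed, floor = 0) {
  stopifnot(inherits(reference, "peak_table"),
            inherits(perturbed, "peak_table"))
  all_res <- sort(union(reference$residue, perturbed$residue))
  i_ref <- match(all_res, reference$residue)
  i_per <- match(all_res, perturbed$residue)
  i0 <- reference$intensity[i_ref]
  ii <- perturbed$intensity[i_per]
  ratio <- rep(NA_real_, length(all_res))
  status <- rep("ok", length(all_res))
  status[is.na(i_ref) | is.na(i_per) | is.na(i0) | is.na(ii)] <- "absent"
  und <- status == "ok" & i0 == 0
  status[und] <- "undefined"
  below <- status == "ok" & ii < floor
  status[below] <- "below_detection"
  ok <- status == "ok"
  ratio[ok] <- ii[ok] / i0[ok]
  lab <- ifelse(is.na(i_ref), perturbed$label[i_per], reference$label[i_ref])
  data.frame(residue = all_res, label = lab, ratio = ratio, status = status,
             stringsAsFactors = FALSE)
}

#' Residual dissolved fraction
#'
#' Mean of the per-residue intensity ratios over detected residues: the
#' fraction of peptides remaining outside the large (NMR-invisible)
#' self-assemblies, judged from the average residual signal intensity.
#'
#' @param reference,perturbed `peak_table`s.
#' @param floor Detection threshold passed to [intensity_ratio()].
#' @param mean_type "arithmetic" (default) or "median".
#' @return The dissolved fraction (scalar).
#' @export
residual_fraction <- function(reference, perturbed, floor = 0,
                              mean_type = c("arithmetic", "median")) {
  mean_type <- match.arg(mean_type)
  ir <- intensity_ratio(reference, perturbed, floor = floor)
  ok <- ir$status == "ok"
  if (!any(ok)) stop("no matched residues above the detection floor",
                     call. = FALSE)
  if (mean_type == "arithmetic") mean(ir$ratio[ok]) else
    stats::median(ir$ratio[ok])
}

# ---- Exponential decay fitting --------------------------------------------

#' Fit an exponential decay to one trace
#'
#' Nonlinear least squares of `I(t) = A exp(-k t) + B` (`B` fixed to 0 in
#' "no-plateau" mode), with a deterministic multistart over log-linear
#' initial estimates. Non-convergence is flagged, never thrown, so batch
#' fits survive bad traces. A constant trace returns `k = 0` exactly.
#'
#' @param time Time grid in s (>= 5 points).
#' @param intensity Signal intensities.
#' @param model "plateau" or "no-plateau".
#' @param min_points Minimum number of points required (default 5).
#' @return List with `k`, `k_se`, `A`, `B`, `converged`, `sse`.
#' @export
fit_exponential_decay <- function(time, intensity,
                                  model = c("plateau", "no-plateau"),
                                  min_points = 5L) {
  model <- match.arg(model)
  time <- as.numeric(time); intensity <- as.numeric(intensity)
  stopifnot(length(time) == length(intensity))
  if (length(time) < min_points) {
    stop("need at least ", min_points, " time points", call. = FALSE)
  }
  rng <- diff(range(intensity))
  if (rng < 1e-12 * max(abs(intensity), 1)) {
    b <- if (model == "plateau") mean(intensity) else 0
    return(list(k = 0, k_se = 0, A = mean(intensity) - b, B = b,
                converged = TRUE, sse = sum((intensity - mean(intensity))^2)))
  }
  b0 <- if (model == "plateau") max(min(intensity), 0) else 0
  a0 <- intensity[1] - b0
  # log-linear initial rate over the decaying part
  pos <- intensity - b0 > max(1e-8, 0.02 * abs(a0))
  k0 <- if (sum(pos) >= 3L && abs(a0) > 0) {
    sl <- stats::coef(stats::lm(log(intensity[pos] - b0) ~ time[pos]))[2]
    max(-sl, 1e-9)
  } else {
    1 / max(diff(range(time)), 1e-9)
  }
  starts <- unique(pmax(k0 * c(0.3, 1, 3), 1e-10))
  best <- NULL
  for (ks in starts) {
    fit <- if (model == "plateau") {
      try_nls(intensity ~ A * exp(-k * time) + B,
              data = list(time = time, intensity = intensity),
              start = list(A = a0, k = ks, B = b0),
              lower = c(A = -Inf, k = 0, B = -Inf))
    } else {
      try_nls(intensity ~ A * exp(-k * time),
              data = list(time = time, intensity = intensity),
              start = list(A = if (abs(a0) > 0) a0 else intensity[1], k = ks),
              lower = c(A = -Inf, k = 0))
    }
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(list(k = NA_real_, k_se = NA_real_, A = NA_real_, B = NA_real_,
                converged = FALSE, sse = NA_real_))
  }
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  list(k = unname(cf["k"]), k_se = unname(se["k"]), A = unname(cf["A"]),
       B = if (model == "plateau") unname(cf["B"]) else 0,
       converged = TRUE, sse = best$sse)
}

try_nls <- function(formula, data, start, lower) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL
  )
}

#' Fit decay rates for every residue of a kinetic-traces object
#'
#' @param traces A `kinetic_traces` object.
#' @param model Passed to [fit_exponential_decay()].
#' @return data.frame (class `rate_result`) with residue, k, k_se, A,
#'   plateau, converged, sse and (if ground truth is attached) true_k.
#' @export
fit_kinetic_traces <- function(traces, model = c("plateau", "no-plateau")) {
  model <- match.arg(model)
  stopifnot(inherits(traces, "kinetic_traces"))
  rows <- lapply(seq_along(traces$residues), function(j) {
    f <- fit_exponential_decay(traces$time, traces$intensities[, j], model)
    data.frame(residue = traces$residues[j], k = f$k, k_se = f$k_se,
               A = f$A, plateau = f$B, converged = f$converged, sse = f$sse)
  })
  out <- do.call(rbind, rows)
  tr <- attr(traces, "true_rates")
  if (!is.null(tr)) out$true_k <- unname(tr[paste0("r", out$residue)])
  out$surface_truth <- out$residue %in% traces$surface_residues
  class(out) <- c("rate_result", "data.frame")
  out
}

#' Classify residues into surface and core kinetics
#'
#' Surface residues sit next to the silica nucleation sites and lose signal
#' faster. A residue is labelled "surface" when its fitted rate exceeds the
#' robust outlier threshold `median + n_mad * MAD`, "core" when it lies
#' within `median +/- n_mad * MAD`, and "undetermined" otherwise
#' (including failed fits).
#'
#' @param rates A `rate_result` data.frame from [fit_kinetic_traces()], or
#'   any data.frame with columns `residue`, `k`, `converged`.
#' @param n_mad Width of the core band in MADs (default 3, the conventional
#'   robust outlier cut).
#' @return The input with an added `class` column.
#' @export
classify_residue_kinetics <- function(rates, n_mad = 3) {
  stopifnot(is.data.frame(rates), all(c("residue", "k") %in% names(rates)))
  conv <- if ("converged" %in% names(rates)) rates$converged else
    rep(TRUE, nrow(rates))
  ok <- conv & is.finite(rates$k)
  if (sum(ok) < 3L) stop("need at least 3 converged fits", call. = FALSE)
  med <- stats::median(rates$k[ok])
  mad <- stats::mad(rates$k[ok])
  cls <- rep("undetermined", nrow(rates))
  cls[ok & rates$k > med + n_mad * mad] <- "surface"
  cls[ok & abs(rates$k - med) <= n_mad * mad] <- "core"
  rates$class <- cls
  rates
}

# ---- DOSY ------------------------------------------------------------------

#' Fit the Stejskal-Tanner equation to a DOSY series
#'
#' Least squares of `I(g) = I0 exp(-D gamma^2 g^2 delta^2 (Delta -
#' delta/3))`, initialized from the linearized `ln I` vs `g^2` slope.
#' Non-decaying data return `D = 0` with a "no-decay" flag.
#'
#' @param series A `dosy_series`.
#' @return List with `D` (m^2/s), `D_se`, `I0`, `converged`, `flag`.
#' @export
fit_stejskal_tanner <- function(series) {
  stopifnot(inherits(series, "dosy_series"))
  b <- st_b_factor(series)
  I <- series$integral
  pos <- I > 0
  if (sum(pos) < 5L) {
    return(list(D = NA_real_, D_se = NA_real_, I0 = NA_real_,
                converged = FALSE, flag = "non-positive"))
  }
  sl <- unname(stats::coef(stats::lm(log(I[pos]) ~ b[pos]))[2])
  if (!is.finite(sl) || sl >= 0) {
    return(list(D = 0, D_se = NA_real_, I0 = mean(I), converged = TRUE,
                flag = "no-decay"))
  }
  fit <- try_nls(I ~ I0 * exp(-D * b), data = list(I = I, b = b),
                 start = list(I0 = max(I), D = -sl),
                 lower = c(I0 = 0, D = 0))
  if (is.null(fit)) {
    return(list(D = -sl, D_se = NA_real_, I0 = exp(mean(log(I[pos]))),
                converged = FALSE, flag = "nls-failed"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  list(D = unname(cf["D"]), D_se = unname(se["D"]), I0 = unname(cf["I0"]),
       converged = TRUE, flag = "ok")
}

#' Stokes-Einstein hydrodynamic radius
#'
#' `Rh = kB T / (6 pi eta D)`, assuming a spherical particle.
#'
#' @param D Diffusion coefficient in m^2/s.
#' @param temperature Temperature in K (default 298.15).
#' @param viscosity Solvent viscosity in Pa s (default 8.937e-4, water at
#'   298.15 K).
#' @return Rh in nm.
#' @export
#' @examples
#' stokes_einstein_radius(3.054e-10)  # about 0.80 nm
stokes_einstein_radius <- function(D, temperature = 298.15,
                                   viscosity = 8.937e-4) {
  stop_if_not_scalar_pos(temperature, "temperature")
  stop_if_not_scalar_pos(viscosity, "viscosity")
  if (any(D <= 0)) stop("D must be > 0", call. = FALSE)
  KB * temperature / (6 * pi * viscosity * D) * 1e9
}

#' Diffusion coefficient of a sphere of given hydrodynamic radius
#'
#' Inverse of [stokes_einstein_radius()]; used to generate DOSY decays for
#' a particle of known size.
#'
#' @param Rh_nm Hydrodynamic radius in nm.
#' @param temperature Temperature in K.
#' @param viscosity Viscosity in Pa s.
#' @return D in m^2/s.
#' @export
stokes_einstein_d <- function(Rh_nm, temperature = 298.15,
                              viscosity = 8.937e-4) {
  if (any(Rh_nm <= 0)) stop("Rh_nm must be > 0", call. = FALSE)
  KB * temperature / (6 * pi * viscosity * Rh_nm * 1e-9)
}

#' Fit a transverse relaxation rate
#'
#' Mono-exponential `I(tau) = I0 exp(-R2 tau)`; the same engine as
#' [fit_exponential_decay()] with the plateau fixed to zero.
#'
#' @param delays Relaxation delays in s (>= 4 points).
#' @param intensities Peak intensities.
#' @return List with `R2` (s^-1), `R2_se`, `I0`, `converged`.
#' @export
fit_relaxation_rate <- function(delays, intensities) {
  if (length(delays) < 4L) stop("need at least 4 delay points", call. = FALSE)
  f <- fit_exponential_decay(delays, intensities, model = "no-plateau",
                             min_points = 4L)
  list(R2 = f$k, R2_se = f$k_se, I0 = f$A, converged = f$converged)
}
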