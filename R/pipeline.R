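# Orchestration: reproducible generate -> analyze -> report runs.
#
# A run config is a plain named list (or a JSON file of one) with at least
# `subcommand` and `out`; every run writes its config, a log, and its
# results into the output directory so the run is self-describing and
# replayable.

#' Execute a pipeline stage
#'
#' Subcommands: `generate` (kind = assembly | peaks | dosy | kinetics |
#' box), `analyze-assembly`, `analyze-nmr`, `analyze-kinetics`,
#' `analyze-dosy`, `saxs`, and `demo` (a small end-to-end run exercising
#' generation, fractal metrics, DOSY and kinetics recovery).
#'
#' @param config Named list, or path to a JSON config file. Common fields:
#'   `subcommand`, `out` (output directory), `seed` (master seed); stage
#'   fields are documented per subcommand in the package vignette.
#' @return The stage's result list, invisibly. Results, the effective
#'   config, and a run log are written into `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$subcommand))
  out_dir <- config$out %||% "silafract-run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  config$seed <- seed
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("silafract %s | subcommand=%s seed=%d",
       as.character(utils::packageVersion("silafract")),
       config$subcommand, seed)
  result <- switch(config$subcommand,
    "generate" = stage_generate(config, out_dir),
    "analyze-assembly" = stage_analyze_assembly(config, out_dir),
    "analyze-nmr" = stage_analyze_nmr(config, out_dir),
    "analyze-kinetics" = stage_analyze_kinetics(config, out_dir),
    "analyze-dosy" = stage_analyze_dosy(config, out_dir),
    "saxs" = stage_saxs(config, out_dir),
    "demo" = stage_demo(config, out_dir),
    stop("unknown subcommand: ", config$subcommand, call. = FALSE)
  )
  jsonlite::write_json(result, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  logf("done")
  invisible(result)
}

default_block <- function(config) {
  if (identical(config$peptide %||% "R5", "synSil")) synsil_block()
  else r5_block()
}

require_input <- function(path, what) {
  if (is.null(path)) stop("config is missing required input: ", what,
                          call. = FALSE)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  path
}

stage_generate <- function(config, out_dir) {
  kind <- config$kind %||% "assembly"
  seed <- config$seed
  switch(kind,
    assembly = {
      block <- generate_building_block(default_block(config), seed = seed)
      morph <- morphology_spec(config$mode %||% "compact",
                               n_blocks = config$n_blocks %||% 20L,
                               target_valency = config$target_valency %||% 4,
                               seed = seed)
      asm <- aggregate_assembly(block, morph)
      write_coordinates(asm, file.path(out_dir, "assembly.pdb"), "pdb")
      man <- ground_truth_manifest(
        seed, kind = "assembly", mode = morph$mode, n_blocks = morph$n_blocks,
        target_valency = morph$target_valency,
        achieved_valency = attr(asm, "achieved_valency"),
        true_dimensionality = switch(morph$mode, linear = 1, planar = 2,
                                     compact = 3, dla = NA)
      )
      write_manifest(man, file.path(out_dir, "manifest.json"))
      list(kind = kind, n_beads = nrow(asm),
           achieved_valency = attr(asm, "achieved_valency"))
    },
    peaks = {
      blk <- default_block(config)
      ref <- reference_peak_table(blk$peptide, seed = seed)
      bound <- config$bound_fraction %||% 0.83
      pert <- synth_peak_tables(ref, bound_fraction = bound,
                                noise_sd = config$noise_sd %||% 0,
                                seed = seed,
                                surface_residues = blk$peptide$surface_residues)
      write_table(ref, file.path(out_dir, "peaks_reference.csv"))
      write_table(pert, file.path(out_dir, "peaks_perturbed.csv"))
      write_manifest(ground_truth_manifest(seed, kind = kind,
                                           true_bound_fraction = bound),
                     file.path(out_dir, "manifest.json"))
      list(kind = kind, bound_fraction = bound)
    },
    dosy = {
      D <- config$D %||% stokes_einstein_d(config$Rh_nm %||% 1.3)
      ser <- synth_dosy_series(D, noise_sd = config$noise_sd %||% 0,
                               seed = seed)
      write_table(ser, file.path(out_dir, "dosy.csv"))
      write_manifest(ground_truth_manifest(seed, kind = kind, true_D = D),
                     file.path(out_dir, "manifest.json"))
      list(kind = kind, true_D = D)
    },
    kinetics = {
      blk <- default_block(config)
      nres <- length(blk$peptide$residues)
      tr <- synth_kinetic_traces(
        residues = seq_len(nres),
        surface_residues = blk$peptide$surface_residues,
        surface_rate = config$surface_rate %||% 2e-3,
        core_rate = config$core_rate %||% 1e-3,
        plateau_fraction = config$plateau_fraction %||% 0.17,
        noise_sd = config$noise_sd %||% 0, seed = seed)
      write_table(tr, file.path(out_dir, "kinetics.csv"))
      write_manifest(ground_truth_manifest(
        seed, kind = kind,
        true_rates = as.list(attr(tr, "true_rates")),
        true_plateau = attr(tr, "true_plateau")),
        file.path(out_dir, "manifest.json"))
      list(kind = kind, plateau = attr(tr, "true_plateau"))
    },
    box = {
      m <- config$peptide_mass_Da %||% peptide_mass(r5_peptide())
      bx <- build_crowded_box(m, config$n_peptides %||% 75,
                              config$Rh_nm %||% 1.3)
      c(list(kind = kind, peptide_mass_Da = m), bx)
    },
    stop("unknown generate kind: ", kind, call. = FALSE)
  )
}

stage_analyze_assembly <- function(config, out_dir) {
  path <- require_input(config$traj, "traj")
  fmt <- config$format %||% (if (grepl("\\.xyz$", path)) "xyz" else "pdb")
  traj <- read_coordinates(path, fmt)
  fm <- analyze_trajectory(traj, window = config$window %||% "last:20%",
                           cutoff = config$cutoff %||% 4.5,
                           kappa = config$kappa %||% 1.21)
  utils::write.csv(fm$per_frame, file.path(out_dir, "metrics_per_frame.csv"),
                   row.names = FALSE)
  utils::write.csv(fm$summary, file.path(out_dir, "metrics_summary.csv"),
                   row.names = FALSE)
  s <- fm$summary
  as.list(stats::setNames(s$mean, s$metric))
}

stage_analyze_nmr <- function(config, out_dir) {
  ref <- read_table(require_input(config$ref, "ref"), "peaks")
  pert <- read_table(require_input(config$pert, "pert"), "peaks")
  mode <- config$mode %||% "csp"
  switch(mode,
    csp = {
      res <- chemical_shift_perturbation(ref, pert)
      utils::write.csv(res, file.path(out_dir, "csp.csv"), row.names = FALSE)
      list(mode = mode, mean_csp = mean(res$csp[res$status == "ok"]))
    },
    ratio = {
      res <- intensity_ratio(ref, pert, floor = config$floor %||% 0)
      utils::write.csv(res, file.path(out_dir, "intensity_ratio.csv"),
                       row.names = FALSE)
      list(mode = mode, mean_ratio = mean(res$ratio[res$status == "ok"]))
    },
    residual = list(mode = mode,
                    residual_fraction = residual_fraction(
                      ref, pert, floor = config$floor %||% 0)),
    stop("unknown nmr mode: ", mode, call. = FALSE)
  )
}

stage_analyze_kinetics <- function(config, out_dir) {
  tr <- read_table(require_input(config$traces, "traces"), "kinetics")
  rates <- fit_kinetic_traces(tr, model = config$model %||% "plateau")
  rates <- classify_residue_kinetics(rates)
  utils::write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)
  list(n_residues = nrow(rates),
       median_k = stats::median(rates$k[rates$converged]),
       n_surface = sum(rates$class == "surface"))
}

stage_analyze_dosy <- function(config, out_dir) {
  ser <- read_table(require_input(config$series, "series"), "dosy")
  fit <- fit_stejskal_tanner(ser)
  rh <- if (is.finite(fit$D) && fit$D > 0) {
    stokes_einstein_radius(fit$D,
                           config$temperature %||% attr(ser, "temperature"),
                           config$viscosity %||% attr(ser, "viscosity"))
  } else {
    NA_real_
  }
  list(D = fit$D, D_se = fit$D_se, Rh_nm = rh, flag = fit$flag)
}

stage_saxs <- function(config, out_dir) {
  path <- require_input(config$traj, "traj")
  fmt <- config$format %||% (if (grepl("\\.xyz$", path)) "xyz" else "pdb")
  frame <- read_coordinates(path, fmt)$frames[[1]]
  if (is.null(config$qmin) && is.null(config$qmax)) {
    # default: analyse over the aggregation window scaled to the
    # assembly's own Rg
    sc <- assembly_scattering(frame, n_q = config$n_q %||% 120L,
                              form_factor = config$form_factor %||% "mass")
    utils::write.csv(as.data.frame(sc$curve),
                     file.path(out_dir, "curve.csv"), row.names = FALSE)
    return(list(guinier_Rg_nm = sc$guinier$Rg,
                beaucage_Rg_nm = sc$beaucage$Rg,
                beaucage_P = sc$beaucage$P,
                direct_Rg_nm = sc$rg_direct_nm))
  }
  q <- exp(seq(log(config$qmin %||% 0.02), log(config$qmax %||% 5),
               length.out = config$n_q %||% 150))
  curve <- debye_curve(frame, q, form_factor = config$form_factor %||% "mass")
  utils::write.csv(as.data.frame(curve), file.path(out_dir, "curve.csv"),
                   row.names = FALSE)
  gf <- guinier_fit(curve)
  bf <- beaucage_fit(curve)
  list(guinier_Rg_nm = gf$Rg, beaucage_Rg_nm = bf$Rg, beaucage_P = bf$P,
       direct_Rg_nm = compute_rg(frame, frame$type == "peptide") / 10)
}

stage_demo <- function(config, out_dir) {
  seed <- config$seed
  block <- generate_building_block(r5_block(), seed = seed)
  asm <- aggregate_assembly(block,
                            morphology_spec("compact", n_blocks = 10L,
                                            target_valency = 4, seed = seed))
  fm <- analyze_trajectory(trajectory(asm), window = "all")
  s <- fm$summary
  ser <- synth_dosy_series(stokes_einstein_d(1.3), noise_sd = 0.01,
                           seed = seed)
  dfit <- fit_stejskal_tanner(ser)
  tr <- synth_kinetic_traces(noise_sd = 0.01, seed = seed)
  rates <- classify_residue_kinetics(fit_kinetic_traces(tr))
  list(
    assembly = as.list(stats::setNames(s$mean, s$metric)),
    dosy_Rh_nm = stokes_einstein_radius(dfit$D),
    kinetics_surface_residues =
      rates$residue[rates$class == "surface"],
    kinetics_median_k = stats::median(rates$k)
  )
}
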