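# Pipeline orchestration: stage configuration with validated defaults,
# one-shot reproduction of the insert-property and kinetics tables, a
# descriptor/rate correlation demonstration, fixture generation and a full
# run that writes its outputs plus a reproducibility manifest.

.default_config <- list(
  ball_radius = 50,
  fit_tol = 1e-10,
  fit_max_iter = 500,
  hbond_dist_cutoff = 3.5,
  hbond_angle_cutoff = 150,
  sasa_probe = 1.4,
  sasa_n_points = 960,
  noise_sd = 0.02,
  n_replicates = 3,
  times = c(0, 1, 2, 4, 8, 16, 32, 64),
  seed = 1L
)

#' Build a validated run configuration
#'
#' Starts from the documented defaults and overrides the named values;
#' unknown keys are rejected.
#'
#' @param ... Named overrides of the default parameters (`ball_radius`,
#'   `fit_tol`, `fit_max_iter`, `hbond_dist_cutoff`, `hbond_angle_cutoff`,
#'   `sasa_probe`, `sasa_n_points`, `noise_sd`, `n_replicates`, `times`,
#'   `seed`).
#' @return Named list of parameters.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.default_config))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  utils::modifyList(.default_config, over)
}

#' Insert property table
#'
#' The six loop-insert property rows — SPLAT and AGPGA at 1, 2 and 4 tandem
#' copies: added mass, free-peptide isoelectric point and Wimley-White
#' octanol hydrophobicity, reported at 2 decimals.
#'
#' @return Tibble with columns `insert_label`, `insert`, `repeats`,
#'   `mass_da`, `pi`, `ww_octanol_kcal_mol`.
#' @examples
#' run_insert_table()
#' @export
run_insert_table <- function() {
  tidyr::expand_grid(insert = c("SPLAT", "AGPGA"), repeats = c(1L, 2L, 4L)) %>%
    insert_properties() %>%
    dplyr::mutate(
      insert_label = ifelse(.data$repeats == 1L, .data$insert,
                            paste0(.data$insert, "x", .data$repeats)),
      .before = 1
    ) %>%
    dplyr::arrange(dplyr::desc(.data$insert), .data$repeats)
}

#' Kinetic parameter recovery over the construct panel
#'
#' Generates a noiseless time course for every folding construct from the
#' reference (rate, yield) parameters on the standard sampling schedule,
#' refits with the package optimizer, and reports fitted values with
#' relative errors — a self-consistency check of the whole kinetics stage.
#' The non-folding construct propagates as a labelled "did not fold" row.
#' Optionally repeats the fits at a configured noise level for error-bar
#' calibration.
#'
#' @param seed Seed for the stochastic pass.
#' @param noise_sd Noise sd of the stochastic pass; `NULL` skips it.
#' @param config A [run_config()].
#' @return Tibble with one row per construct: reference `k_ref`/`yield_ref`,
#'   noiseless fits `k_fit`/`yield_fit`, relative errors, `did_not_fold`,
#'   and (if run) the noisy-pass estimates `k_noisy`, `yield_noisy`,
#'   `k_se_noisy`, `yield_se_noisy`.
#' @export
run_table2_recovery <- function(seed = 1L, noise_sd = NULL,
                                config = run_config()) {
  params <- reference_folding_params()
  clean <- gen_timecourse_panel(params, times = config$times, noise_sd = 0,
                                n_replicates = 1, seed = NULL)
  fits <- fit_folding_panel(clean, max_iter = config$fit_max_iter,
                            tol = config$fit_tol)
  out <- params %>%
    dplyr::select("construct", k_ref = "k", yield_ref = "yield", "folds") %>%
    dplyr::left_join(fits, by = "construct") %>%
    dplyr::mutate(
      k_fit = .data$k_per_min, yield_fit = .data$yield,
      k_rel_err = abs(.data$k_fit - .data$k_ref) / .data$k_ref,
      yield_rel_err = abs(.data$yield_fit - .data$yield_ref) / .data$yield_ref,
      status = dplyr::if_else(.data$did_not_fold, "did not fold", "fitted")
    ) %>%
    dplyr::select("construct", "k_ref", "yield_ref", "k_fit", "yield_fit",
                  "k_rel_err", "yield_rel_err", "did_not_fold", "status")
  if (!is.null(noise_sd)) {
    noisy <- gen_timecourse_panel(params, times = config$times,
                                  noise_sd = noise_sd,
                                  n_replicates = config$n_replicates,
                                  seed = seed)
    nf <- fit_folding_panel(noisy, max_iter = config$fit_max_iter,
                            tol = config$fit_tol) %>%
      dplyr::select("construct", k_noisy = "k_per_min", k_se_noisy = "k_se",
                    yield_noisy = "yield", yield_se_noisy = "yield_se")
    out <- dplyr::left_join(out, nf, by = "construct")
  }
  out
}

#' @rdname run_table2_recovery
#' @export
run_panel_recovery <- run_table2_recovery

#' Descriptor/rate correlation demonstration
#'
#' Builds a synthetic descriptor with a negative linear dependence on the
#' measured folding rates of the 14 folding constructs (mimicking the
#' observed inverse correlation of loop contact area and intra-loop
#' hydrogen bonds with folding rate), fits the descriptor-rate regression,
#' and reports slope, intercept, R-squared and point count.
#'
#' @param seed Integer seed.
#' @param slope,intercept Line used to generate the descriptor from the
#'   rates (descriptor = slope_inv * rate + ..., chosen so the fitted
#'   rate-on-descriptor slope is negative).
#' @param noise_sd Gaussian noise on the descriptor (descriptor units).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
run_correlation_demo <- function(seed = 1L, slope = -300, intercept = 100,
                                 noise_sd = 5) {
  rates <- reference_folding_params() %>% dplyr::filter(.data$folds)
  desc <- with_seed_maybe(seed, function() {
    slope * rates$k + intercept + rnorm(nrow(rates), sd = noise_sd)
  })
  descriptor_rate_regression(
    tibble::tibble(descriptor = desc, rate = rates$k)
  )
}

#' Write synthetic fixtures for every pipeline stage
#'
#' Generates a gel image (16-bit TIFF), a panel of folding time courses
#' (CSV), a toy multi-model PDB trajectory, a descriptor/rate table (CSV)
#' and a JSON manifest of every ground truth, all seeded.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  gel <- gen_gel_lane(seed = seed)
  write_gel(gel$image / 65535, p("gel_lane.tiff"))

  tc <- gen_timecourse_panel(seed = seed)
  write.csv(tc, p("timecourses.csv"), row.names = FALSE)

  traj <- gen_toy_trajectory(n_frames = 20, seed = seed)
  write_traj_pdb(traj$trajectory, p("toy_trajectory.pdb"))

  dr <- gen_descriptor_rate_set(slope = -0.01, intercept = 2, noise_sd = 0.1,
                                n = 14, seed = seed)
  write.csv(dr, p("descriptor_rate.csv"), row.names = FALSE)

  manifest <- list(
    seed = seed,
    gel = gel$truth,
    trajectory = traj$truth[c("sd_per_residue", "inter_loop_gap",
                              "contact_regime")],
    descriptor_rate = attr(dr, "truth"),
    files = c("gel_lane.tiff", "timecourses.csv", "toy_trajectory.pdb",
              "descriptor_rate.csv")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates every stage on seeded synthetic inputs: construct building
#' and insert physicochemistry, gel densitometry, kinetic fitting over the
#' construct panel, trajectory descriptors on a toy trajectory, and the
#' descriptor/rate regression. All outputs are written as CSV/FASTA plus a
#' manifest (parameters, seed, package version) sufficient to reproduce the
#' run.
#'
#' @param out_dir Output directory.
#' @param config A [run_config()] (its `seed` drives every stage).
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  seed <- config$seed

  panel <- construct_panel()
  write_fasta(stats::setNames(panel$sequence, panel$construct),
              p("constructs.fasta"))
  props <- run_insert_table()
  write.csv(props, p("insert_properties.csv"), row.names = FALSE)

  gel <- gen_gel_lane(seed = seed)
  gel_q <- quantify_gel(
    gel$image,
    tibble::tibble(lane = 1L, col_start = 1L, col_end = ncol(gel$image) + 1L),
    folded = c(170, 231), unfolded = c(370, 431),
    radius = config$ball_radius
  )
  write.csv(gel_q, p("gel_quant.csv"), row.names = FALSE)

  tc <- gen_timecourse_panel(times = config$times, noise_sd = config$noise_sd,
                             n_replicates = config$n_replicates, seed = seed)
  fits <- fit_folding_panel(tc, max_iter = config$fit_max_iter,
                            tol = config$fit_tol)
  write.csv(fits, p("kinetic_fits.csv"), row.names = FALSE)

  traj <- gen_toy_trajectory(n_frames = 20, seed = seed)
  series <- descriptor_series(traj$trajectory,
                              probe = config$sasa_probe,
                              n_points = config$sasa_n_points,
                              dist_cutoff = config$hbond_dist_cutoff,
                              angle_cutoff = config$hbond_angle_cutoff)
  write.csv(series, p("descriptors.csv"), row.names = FALSE)
  write.csv(summarise_descriptors(series), p("descriptor_summary.csv"),
            row.names = FALSE)

  corr <- run_correlation_demo(seed = seed)
  write.csv(corr, p("correlation.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("loopfold")),
    config = config,
    gel_truth = gel$truth,
    outputs = c(list.files(out_dir), "manifest.json")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(insert_properties = props, gel = gel_q, fits = fits,
                 descriptors = series, correlation = corr))
}
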