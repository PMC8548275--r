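# End-to-end pipeline: simulate (or ingest) -> volumetrics -> flux ->
# model fit -> doublet sweep -> summary bundle, with provenance.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config] describing the dataset to simulate
#'   (ingestion of external tables goes through the `cells_csv` /
#'   `field_basename` paths instead).
#' @param cells_csv,field_basename optional paths to an existing cell table
#'   CSV and velocity field (see [read_velocity_field()]); when given they
#'   replace the corresponding synthetic inputs.
#' @param n_bins bins for volumetrics.
#' @param n_boot bootstrap replicates for transition CIs.
#' @param sg_window Savitzky-Golay window for J and S (NULL: 1/10 of grid).
#' @param fit_starts multi-starts of the parameter fit.
#' @param use_piv run the image-pair PIV path instead of using the velocity
#'   field directly (slow; default FALSE).
#' @param doublet template for the doublet sweep ([doublet_params]); its S
#'   and Pc-Pr entries are taken from the fitted model solution. Default is
#'   built by [default_doublet_template()].
#' @param seed global seed recorded in all outputs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            cells_csv = NULL, field_basename = NULL,
                            n_bins = synthetic$axis_grid, n_boot = 100,
                            sg_window = NULL, fit_starts = 8,
                            use_piv = FALSE, doublet = NULL,
                            seed = synthetic$seed) {
  structure(list(synthetic = synthetic, cells_csv = cells_csv,
                 field_basename = field_basename, n_bins = n_bins,
                 n_boot = n_boot, sg_window = sg_window,
                 fit_starts = fit_starts, use_piv = use_piv,
                 doublet = doublet, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Doublet parameter template consistent with a model solution
#'
#' Chooses the doublet's fixed physical constants from the synthetic
#' geometry: combined cross-section of two cells from the gonad radius, the
#' bridge conductivity `alpha0` as the per-doublet share of the tissue
#' conductivity, and a cortical tension scale set a priori to 10 percent of
#' the solution's peak |Pc - Pr| times the gonad radius (a small
#' destabilizing term relative to the hydraulic pressure scale; see the
#' methods vignette).
#'
#' @param sol a `model_solution`.
#' @param config a [synthetic_config].
#' @param cell_length_frac axial fraction of one doublet (default 0.05).
#' @return a [doublet_params] template.
#' @export
default_doublet_template <- function(sol, config,
                                     cell_length_frac = 0.05) {
  p_scale <- max(abs(sol$Pc - sol$Pr))
  alpha0 <- attr(sol, "params")$alpha * cell_length_frac
  doublet_params(S = 0, A_c = pi * config$gonad_radius_um^2 / 2,
                 alpha0 = alpha0, Pc_minus_Pr = 0,
                 Tension = 0.1 * p_scale * config$gonad_radius_um,
                 R = config$gonad_radius_um)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or ingest) the dataset; locate the volume transition
#' (slope break and dip scan); estimate Qr from the velocity field and Qc
#' from the cell table; infer J and S from the flux balances; fit the
#' hydraulic model to the observed Qr given the inferred S; sweep the
#' doublet bifurcation along the fitted solution; write all outputs with
#' provenance. Any stage failure aborts with the stage name; outputs written
#' so far are preserved.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with `transition_slope`, `transition_dip`,
#'   `profile`, `fit`, `solution`, `bifurcation`, `consistency`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("gonad_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config$synthetic
  meta <- list(seed = config$seed, config_hash = config_hash(unclass(scfg)))
  log_msg <- function(...) message(sprintf("[gonad] %s", sprintf(...)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort_stage(name, conditionMessage(e)))
  }

  log_msg("stage simulate")
  data <- stage("simulate", {
    ds <- generate_dataset(scfg, with_field = is.null(config$field_basename))
    if (!is.null(config$cells_csv))
      ds$cells <- read_cell_table(config$cells_csv)
    if (!is.null(config$field_basename))
      ds$field <- read_velocity_field(config$field_basename)
    ds
  })
  write_cell_table(data$cells, file.path(out_dir, "cells.csv"), meta)

  log_msg("stage volumes")
  trans <- stage("volumes", {
    bs <- bin_volumes(data$cells, n_bins = config$n_bins)
    list(slope = detect_transition_slope(bs, cells = data$cells,
                                         n_boot = config$n_boot,
                                         seed = config$seed),
         dip = detect_transition_bimodality(data$cells, "dip",
                                            n_bins = config$n_bins,
                                            n_boot = min(config$n_boot, 50),
                                            seed = config$seed))
  })
  jsonlite::write_json(
    list(slope = trans$slope[c("x_star", "ci_low", "ci_high", "method")],
         dip = trans$dip[c("x_star", "ci_low", "ci_high", "method")],
         seed = config$seed, config_hash = meta$config_hash),
    file.path(out_dir, "transition.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  log_msg("stage flux")
  grid <- data$truth$params$grid
  prof <- stage("flux", {
    field <- data$field
    if (config$use_piv) {
      pair <- generate_image_pair(field, scfg)
      field <- piv_displacement(pair$frame_a, pair$frame_b,
                                piv_params(frame_interval_s = scfg$frame_interval_s,
                                           pixel_size_um = scfg$pixel_size_um),
                                mask = pair$mask)
    }
    qr <- flux_from_field(field, lumen_radius = scfg$rachis_radius_um,
                          gonad_length_um = scfg$gonad_length_um,
                          grid = grid)
    qc <- cell_volume_flux(data$cells, data$truth$v_c_um_min,
                           scfg$gonad_length_um, grid = grid)
    p <- axial_profile(grid, Qr = qr$Qr, Qc = qc$Qc, rhoV = qc$rhoV)
    p <- infer_J(p, window = config$sg_window)
    infer_S(p, window = config$sg_window)
  })
  write_axial_profile(prof, file.path(out_dir, "profile.csv"), meta)

  log_msg("stage fit")
  fitted <- stage("fit", {
    init <- data$truth$params
    fit_parameters(prof[, c("x", "Qr")],
                   axial_profile(grid, S = prof$S), init,
                   n_starts = config$fit_starts, seed = config$seed)
  })
  write_params_json(c(fitted[c("alpha", "kappa_r", "gamma_c")],
                      list(residual = attr(fitted, "residual"),
                           seed = config$seed,
                           config_hash = meta$config_hash)),
                    file.path(out_dir, "fit.json"))
  solution <- solve_steady_state(axial_profile(grid, S = prof$S), fitted)

  log_msg("stage doublet")
  bif <- stage("doublet", {
    tmpl <- config$doublet %||% default_doublet_template(solution, scfg)
    bifurcation_along_gonad(solution, tmpl)
  })
  write_table_csv(bif$branches, file.path(out_dir, "bifurcation.csv"), meta)

  log_msg("stage stats")
  consistency <- stage("stats", {
    list(x_transition = trans$slope$x_star,
         x_transition_dip = trans$dip$x_star,
         x_j_zero = zero_crossing_x(prof, "J"),
         x_s_zero = zero_crossing_x(prof, "S"),
         x_bifurcation = bif$x_bifurcation)
  })
  manifest <- c(meta, list(out_dir = out_dir,
                           stages = c("simulate", "volumes", "flux", "fit",
                                      "doublet", "stats"),
                           consistency = consistency,
                           n_cells = nrow(data$cells),
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(transition_slope = trans$slope, transition_dip = trans$dip,
                 profile = prof, fit = fitted, solution = solution,
                 bifurcation = bif, consistency = consistency,
                 manifest = manifest))
}
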