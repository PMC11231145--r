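#' Default run configuration for the simulate-to-classify pipeline
#'
#' A nested list bundling every stage's settings; fully serializable to and
#' from YAML so a run can be reproduced from its manifest. Stage seeds are
#' derived deterministically from the global seed.
#'
#' @param seed global RNG seed.
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "reconstruct", "analyze", "classify")`.
#' @param optics,geometry,scene,recon,analysis,noise stage settings; see the
#'   corresponding constructors for the meaning of each field.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L,
                       stages = c("simulate", "reconstruct", "analyze"),
                       optics = list(wavelength_um = 0.5, na_mo = 0.25,
                                     magnification = 4, pixel_pitch_um = 2,
                                     grid = 64),
                       geometry = list(rows = 5, cols = 5, pitch_mm = 4,
                                       height_mm = 28, disk_radius = Inf),
                       scene = list(stress = 0, exposure = "T3",
                                    density_cells_ml = 190000,
                                    min_chains = 2),
                       noise = list(photons = Inf, read_sigma = 0),
                       recon = list(iters = 20, pupil_recovery = TRUE),
                       analysis = list(threshold_rad = 0.2,
                                       r_local = NULL, flatten = TRUE)) {
  structure(list(seed = as.integer(seed), stages = stages, optics = optics,
                 geometry = geometry, scene = scene, noise = noise,
                 recon = recon, analysis = analysis),
            class = "run_config")
}

#' Load / save a run configuration as YAML
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param config `run_config` to save.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic assay pipeline for one field of view
#'
#' Executes the configured stages in order — scene simulation and FPM
#' acquisition, iterative reconstruction, descriptor analysis, and
#' (optionally, given calibration models) dose classification — writing each
#' intermediate artifact plus a JSON manifest (config hash, seeds, stage
#' wall times) into `out_dir`. Identical config + seed re-runs produce
#' identical descriptor output.
#'
#' @param config [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file artifacts.
#' @param models optional list of calibration models for the classify stage
#'   (see [classify_dose()]).
#' @param table decision table for the classify stage.
#' @return list with `descriptors` (one-row data frame), `call`
#'   (`dose_call` or `NULL`), `truth`, `recon`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, models = NULL,
                         table = build_decision_table()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cfg_yaml <- yaml::as.yaml(unclass(config))
  manifest <- list(config_hash = fnv1a_hash(cfg_yaml), seed = config$seed,
                   stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, elapsed = proc.time()[["elapsed"]] - t0)
  }

  optics <- do.call(fpm_optics, config$optics)
  geom <- do.call(build_led_geometry,
                  c(config$geometry, list(optics = optics)))

  truth <- NULL; stack <- NULL; recon <- NULL; pm <- NULL
  desc <- NULL; call_out <- NULL

  if ("simulate" %in% config$stages) {
    st <- t_stage({
      spec <- do.call(scene_spec,
                      c(config$scene, list(seed = config$seed)))
      sim <- simulate_acquisition(spec, geom, optics)
      stk <- sim$stack
      if (is.finite(config$noise$photons) || config$noise$read_sigma > 0)
        stk <- add_noise(stk, config$noise$photons, config$noise$read_sigma,
                         seed = config$seed + 1L)
      list(truth = sim$truth, stack = stk)
    })
    truth <- st$value$truth; stack <- st$value$stack
    manifest$stages$simulate <- list(elapsed_s = st$elapsed,
                                     n_leds = geom$n_leds)
    if (!is.null(out_dir)) {
      write_stack(stack, file.path(out_dir, "stack.tiff"))
      write_phase_map(truth$phase, file.path(out_dir, "truth_phase.tiff"),
                      pitch_um = truth$pitch_um)
    }
  }

  if ("reconstruct" %in% config$stages) {
    if (is.null(stack)) stop("reconstruct stage needs a simulated stack")
    st <- t_stage({
      rc <- recon_config(iters = config$recon$iters,
                         pupil_recovery = isTRUE(config$recon$pupil_recovery))
      reconstruct(stack, geom, optics, rc)
    })
    recon <- st$value
    manifest$stages$reconstruct <-
      list(elapsed_s = st$elapsed,
           final_misfit = utils::tail(recon$history, 1))
    pm <- extract_phase_map(recon$field,
                            flatten = isTRUE(config$analysis$flatten))
    if (!is.null(out_dir)) {
      write_phase_map(pm, file.path(out_dir, "recon_phase.tiff"))
      utils::write.csv(
        data.frame(outer_loop = seq_along(recon$history),
                   misfit = recon$history),
        file.path(out_dir, "misfit_history.csv"), row.names = FALSE)
    }
  }

  if ("analyze" %in% config$stages) {
    if (is.null(pm)) {
      if (is.null(truth)) stop("analyze stage needs a phase map")
      pm <- as_phase_map(truth$phase, truth$pitch_um, "simulated")
    }
    st <- t_stage({
      phase_descriptors(pm, method = "fixed",
                        param = config$analysis$threshold_rad,
                        r_local = config$analysis$r_local)
    })
    desc <- st$value
    desc$exposure <- config$scene$exposure
    desc$stress <- config$scene$stress
    desc$seed <- config$seed
    manifest$stages$analyze <- list(elapsed_s = st$elapsed)
    if (!is.null(out_dir))
      utils::write.csv(desc, file.path(out_dir, "descriptors.csv"),
                       row.names = FALSE)
  }

  if ("classify" %in% config$stages) {
    if (is.null(desc)) stop("classify stage needs descriptors")
    if (is.null(models)) stop("classify stage needs calibration models")
    st <- t_stage(classify_dose(desc$MSL, desc$delta_s, models, table))
    call_out <- st$value
    manifest$stages$classify <- list(elapsed_s = st$elapsed,
                                     label = call_out$label)
    if (!is.null(out_dir))
      jsonlite::write_json(unclass(call_out),
                           file.path(out_dir, "dose_call.json"),
                           auto_unbox = TRUE, digits = NA)
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  list(descriptors = desc, call = call_out, truth = truth, recon = recon,
       manifest = manifest)
}
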