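# deterministic per-stage seed: mixes the base seed with a hash of the stage
# name, so each stage is independently reproducible from (seed, stage)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' @param model a \code{channel_model} or path to a model JSON.
#' @param sim a \code{simulation_config} (its seed is overridden by the
#'   pipeline's per-stage seed derivation).
#' @param out_dir output directory.
#' @param seed master seed; fans out to stages via [stage_seed()].
#' @param pmf_coords list of coordinate sets for PMF grids.
#' @param pmf_occupancy occupancy to condition each PMF on (recycled).
#' @param cutoffs a [complex_cutoffs()] object.
#' @param event_planes c(upper, lower) crossing planes, or NULL for
#'   [default_event_planes()].
#' @param fep run the site FEP leg (logical).
#' @param channel_range analysis channel region (A).
#' @param equil_discard fraction of frames discarded as equilibration.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(model = build_model(),
                            sim = simulation_config(),
                            out_dir = tempfile("ionperm_run_"),
                            seed = 1,
                            pmf_coords = list("z1", c("z1", "z2")),
                            pmf_occupancy = c(1, 2),
                            cutoffs = complex_cutoffs(),
                            event_planes = NULL,
                            fep = FALSE,
                            channel_range = c(-15, 15),
                            equil_discard = 0.1) {
  if (is.character(model)) {
    if (!file.exists(model)) stop("model path does not exist: ", model)
    model <- model_from_json(model)
  }
  structure(list(model = model, sim = sim, out_dir = out_dir,
                 seed = as.integer(seed), pmf_coords = pmf_coords,
                 pmf_occupancy = pmf_occupancy, cutoffs = cutoffs,
                 event_planes = event_planes, fep = fep,
                 channel_range = channel_range,
                 equil_discard = equil_discard),
            class = "pipeline_config")
}

#' Run the simulate-analyze-report pipeline
#'
#' Stages: sample a trajectory, build occupancy-conditioned PMF grids,
#' classify complex states, count permeation events, optionally run the
#' site/bulk FEP legs; write every artifact plus a JSON manifest recording
#' parameters, per-stage seeds and files. Re-running with the same
#' configuration and seed reproduces all outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly), a list describing every artifact.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, artifacts = list())
  add <- function(stage, file, params = NULL) {
    manifest$artifacts[[length(manifest$artifacts) + 1L]] <<-
      list(stage = stage, file = basename(file), params = params)
  }
  # -- simulate
  sim <- config$sim
  sim$seed <- stage_seed(config$seed, "simulate")
  traj <- run_sampler(config$model, sim)
  traj_path <- file.path(config$out_dir, "trajectory.xyz")
  write_trajectory_xyz(traj, traj_path)
  model_to_json(config$model, file.path(config$out_dir, "model.json"))
  add("simulate", traj_path, list(seed = sim$seed, n_steps = sim$n_steps,
                                  sampler = sim$sampler))
  add("simulate", file.path(config$out_dir, "model.json"))
  # -- axial states + PMFs
  states <- axial_states(traj, config$channel_range, config$equil_discard)
  kT <- kBT(sim$temperature)
  occ <- rep(config$pmf_occupancy, length.out = length(config$pmf_coords))
  for (k in seq_along(config$pmf_coords)) {
    co <- config$pmf_coords[[k]]
    grid <- try(pmf(states, co, occupancy = occ[k], kT = kT,
                    seed = stage_seed(config$seed, paste0("pmf", k))),
                silent = TRUE)
    if (inherits(grid, "try-error")) next   # occupancy never sampled
    f <- file.path(config$out_dir,
                   sprintf("pmf_%s_n%d.tsv", paste(co, collapse = "_"), occ[k]))
    write_pmf_tsv(grid, f)
    add("pmf", f, list(coords = co, occupancy = occ[k]))
  }
  od <- occupancy_distribution(states,
                               seed = stage_seed(config$seed, "occupancy"))
  occ_path <- file.path(config$out_dir, "occupancy.json")
  jsonlite::write_json(list(prob = as.list(od$prob), mean = od$mean,
                            se = od$se), occ_path, auto_unbox = TRUE,
                       digits = NA)
  add("occupancy", occ_path)
  # -- complexes
  cls <- classify_frames(traj, config$cutoffs, config$channel_range)
  cls_path <- file.path(config$out_dir, "classification.tsv")
  utils::write.table(as.data.frame(cls), cls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  smry <- complex_summary(cls)
  smry_path <- file.path(config$out_dir, "complex_summary.json")
  jsonlite::write_json(list(
    state_fraction = as.data.frame.matrix(smry$state_fraction),
    carb_involvement = as.data.frame(smry$carb_involvement),
    ring_involvement = as.data.frame(smry$ring_involvement),
    ion_lys_fraction = smry$ion_lys_fraction), smry_path, digits = NA)
  add("complexes", cls_path,
      list(cutoffs = lapply(unclass(config$cutoffs), as.list)))
  add("complexes", smry_path)
  # -- events
  planes <- if (is.null(config$event_planes))
    default_event_planes(traj) else config$event_planes
  ev <- detect_events(traj, upper_plane = planes[["upper"]],
                      lower_plane = planes[["lower"]])
  ev_path <- file.path(config$out_dir, "events.tsv")
  utils::write.table(as.data.frame(ev), ev_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  add("events", ev_path, list(planes = as.list(planes),
                              summary = summarize_events(ev)[c("total",
                                "inward", "outward", "distinct_ions")]))
  # -- FEP
  if (isTRUE(config$fep)) {
    sp <- names(config$model$ion_species)
    if (length(sp) >= 2) {
      site <- fep_site()
      pf <- transform_species(config$model, site, sp[1], sp[2],
                              seed = stage_seed(config$seed, "fep_fwd"))
      est <- fep_estimate(pf)
      res <- fep_cycle(c(est$dG, est$se),
                       correction = c(restraint_correction(
                         config$model, site, sp[1], standard_radius = site$radius), 0))
      fep_path <- file.path(config$out_dir, "fep.json")
      jsonlite::write_json(unclass(res), fep_path, auto_unbox = TRUE,
                           digits = NA)
      add("fep", fep_path, list(from = sp[1], to = sp[2]))
    }
  }
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  listed <- vapply(manifest$artifacts, function(a) a$file, "")
  listed <- c(listed, paste0(basename(traj_path), ".json"))
  if (!all(files %in% listed))
    warning("manifest is missing: ",
            paste(setdiff(files, listed), collapse = ", "))
  invisible(manifest)
}
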