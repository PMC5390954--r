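# Study pipeline: the stages a command-line run chains together.
# Each stage reads/writes plain container files under the run directory
# so that a study is reproducible from its manifest alone.

#' Default run configuration
#'
#' One seed governs all stochastic steps (phantom jitter). The
#' configuration is fully serializable to YAML.
#'
#' @param seed integer seed
#' @param preset phantom preset ("test" or "clinical")
#' @param outdir run directory
#' @return nested configuration list
#' @export
default_config <- function(seed = 1L, preset = "test", outdir = "ids_run") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    phantom = list(preset = preset, jitter_mm = 3,
                   dims = NULL, spacing = NULL,
                   rx = list(boost = 76, ptv = 73)),
    beams = list(angles = seq(0, 320, by = 40), sad = 1000, bixel = c(5, 5)),
    kernel = list(mu = 0.005, sigma = 3, threshold = 1e-4, march_step = 2),
    dmr = list(tau = NULL, nr = 15L, sphere_radius_vox = 3),
    goals = list(budget = 3000L),
    init = list(margin = 5),
    sequencer = list(levels = 7L),
    baseline = list(iters = 60L)
  )
}

#' Read a run configuration from YAML
#' @param path YAML file
#' @return configuration list merged over [default_config()]
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' Write a run configuration as YAML
#' @param cfg configuration list
#' @param path YAML file
#' @return `path`, invisibly
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

cfg_phantom_spec <- function(cfg) {
  phantom_spec(seed = cfg$seed, preset = cfg$phantom$preset,
               dims = cfg$phantom$dims, spacing = cfg$phantom$spacing,
               jitter_mm = cfg$phantom$jitter_mm,
               rx = prescription(cfg$phantom$rx$boost, cfg$phantom$rx$ptv))
}

stage_dir <- function(cfg, ...) {
  d <- file.path(cfg$outdir, ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

require_stage <- function(path, stage) {
  if (!file.exists(path))
    ids_stop(sprintf("missing input '%s': run the '%s' stage first",
                     path, stage), "ids_io_error")
  path
}

#' Pipeline stage: generate and write the phantom
#' @param cfg configuration list
#' @return the phantom, invisibly
#' @export
stage_phantom <- function(cfg) {
  ph <- generate_phantom(cfg_phantom_spec(cfg))
  d <- stage_dir(cfg, "phantom")
  for (nm in names(ph$vois))
    write_nrrd(ph$vois[[nm]]$mask, file.path(d, paste0(nm, ".nrrd")),
               ph$grid, encoding = "raw")
  jsonlite::write_json(list(rx = unclass(ph$rx),
                            dims = ph$grid$dims, spacing = ph$grid$spacing,
                            origin = ph$grid$origin),
                       file.path(d, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ph)
}

load_phantom_stage <- function(cfg) {
  d <- file.path(cfg$outdir, "phantom")
  require_stage(file.path(d, "phantom.json"), "phantom")
  meta <- jsonlite::read_json(file.path(d, "phantom.json"), simplifyVector = TRUE)
  roles <- c(body = "body", ptv = "target", boost = "boost",
             rectum = "oar", bladder = "oar")
  vois <- list(); grid <- NULL
  for (nm in names(roles)) {
    r <- read_nrrd(file.path(d, paste0(nm, ".nrrd")))
    vois[[nm]] <- voi(nm, roles[[nm]], r$data)
    grid <- r$grid
  }
  list(grid = grid, vois = vois, rx = prescription(meta$rx$boost, meta$rx$ptv))
}

#' Pipeline stage: build and persist the dose-influence operator
#' @param cfg configuration list
#' @param phantom optional phantom (loaded from the phantom stage if `NULL`)
#' @return the `ids_influence`, invisibly
#' @export
stage_influence <- function(cfg, phantom = NULL) {
  if (is.null(phantom)) phantom <- load_phantom_stage(cfg)
  beams <- beam_set(cfg$beams$angles, cfg$beams$sad, bixel = cfg$beams$bixel)
  kern <- do.call(kernel_params, cfg$kernel)
  infl <- build_influence(phantom$grid, phantom$vois$body, beams, kern)
  save_influence(infl, file.path(stage_dir(cfg, "dij"), "influence"))
  invisible(infl)
}

#' Pipeline stage: initialize the plan from open fields
#' @param cfg configuration list
#' @param phantom,infl optional upstream objects
#' @return the initialized `ids_plan`, invisibly
#' @export
stage_init <- function(cfg, phantom = NULL, infl = NULL) {
  if (is.null(phantom)) phantom <- load_phantom_stage(cfg)
  if (is.null(infl)) {
    require_stage(file.path(cfg$outdir, "dij", "influence.json"), "dij")
    infl <- load_influence(file.path(cfg$outdir, "dij", "influence"))
  }
  state <- init_plan(phantom, infl, margin = cfg$init$margin)
  save_state(state, stage_dir(cfg, "state_init"))
  invisible(state)
}

#' Pipeline stage: run the goal-driven shaping script
#' @param cfg configuration list
#' @param state optional initialized plan
#' @return the shaped `ids_plan`, invisibly
#' @export
stage_shape <- function(cfg, state = NULL) {
  if (is.null(state)) {
    infl <- load_influence(file.path(require_stage(
      file.path(cfg$outdir, "dij"), "dij"), "influence"))
    state <- load_state(require_stage(file.path(cfg$outdir, "state_init"),
                                      "init"), infl)
  }
  state <- goal_script_run(state, default_goals(cfg$goals$budget),
                           tau = cfg$dmr$tau, nr = cfg$dmr$nr,
                           sphere_radius_vox = cfg$dmr$sphere_radius_vox)
  save_state(state, stage_dir(cfg, "state_shaped"))
  log <- attr(state, "goal_log")
  write.csv(log, file.path(cfg$outdir, "shape_log.csv"), row.names = FALSE)
  invisible(state)
}

#' Pipeline stage: metrics report and DVH curves
#' @param cfg configuration list
#' @param state optional shaped plan
#' @return the metrics report, invisibly
#' @export
stage_metrics <- function(cfg, state = NULL) {
  if (is.null(state))
    state <- load_state(require_stage(file.path(cfg$outdir, "state_shaped"),
                                      "shape"))
  rep <- metrics_report(state$dose, state$vois, state$rx, state$grid)
  d <- stage_dir(cfg, "metrics")
  write_metrics(rep, file.path(d, "metrics"))
  for (nm in names(state$vois)) {
    curve <- dvh(state$dose, state$vois[[nm]])
    write.csv(curve, file.path(d, paste0("dvh_", nm, ".csv")), row.names = FALSE)
  }
  invisible(rep)
}

#' Pipeline stage: sequencing and deliverability report
#' @param cfg configuration list
#' @param state optional shaped plan (must carry its influence operator)
#' @return the deliverability report, invisibly
#' @export
stage_sequence <- function(cfg, state = NULL) {
  if (is.null(state)) {
    infl <- load_influence(file.path(require_stage(
      file.path(cfg$outdir, "dij"), "dij"), "influence"))
    state <- load_state(require_stage(file.path(cfg$outdir, "state_shaped"),
                                      "shape"), infl)
  }
  del <- deliverability_delta(state, levels = cfg$sequencer$levels)
  d <- stage_dir(cfg, "sequence")
  write_segments(del$segments, state$infl, file.path(d, "segments.json"))
  strat <- stratify(state$infl, state$w, cfg$sequencer$levels)
  for (bi in seq_along(strat$level))
    write.csv(strat$level[[bi]], file.path(d, sprintf("levels_beam%02d.csv", bi)),
              row.names = FALSE)
  jsonlite::write_json(list(per_beam = del$counts$per_beam,
                            total = del$counts$total,
                            max_dose_delta = del$max_dose_delta),
                       file.path(d, "counts.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(del)
}

report_indicator_table <- function(rep_ids, rep_base) {
  rows <- list()
  for (voi in c("boost", "ptv", "rectum", "bladder", "body")) {
    for (plan in c("ids", "reference")) {
      rp <- if (plan == "ids") rep_ids else rep_base
      r <- rp$indicators[rp$indicators$voi == voi, ]
      row <- data.frame(voi = voi, plan = plan, mean = r$mean, med = r$d50,
                        d98 = r$d98, d2 = r$d2, hi = r$hi)
      if (voi %in% c("boost", "ptv")) {
        row$ci1 <- rp$conformity[[voi]]$ci1
        row$ci2 <- rp$conformity[[voi]]$ci2
      } else {
        row$ci1 <- NA_real_; row$ci2 <- NA_real_
      }
      rows <- c(rows, list(row))
    }
  }
  do.call(rbind, rows)
}

#' Pipeline stage: study comparison report (IDS vs baseline)
#'
#' Emits indicator tables in the shape of a per-structure comparison
#' (mean/median/CI/D98/D2/HI per plan), the nine-row Quantec table for
#' both plans, NTID, DVH curves and segment counts.
#'
#' @param cfg configuration list
#' @param state optional shaped plan (with influence)
#' @param baseline optional baseline plan
#' @return list of report tables, invisibly
#' @export
stage_report <- function(cfg, state = NULL, baseline = NULL) {
  infl <- NULL
  if (is.null(state)) {
    infl <- load_influence(file.path(require_stage(
      file.path(cfg$outdir, "dij"), "dij"), "influence"))
    state <- load_state(require_stage(file.path(cfg$outdir, "state_shaped"),
                                      "shape"), infl)
  }
  if (is.null(baseline)) {
    phantom <- list(grid = state$grid, vois = state$vois, rx = state$rx)
    baseline <- baseline_optimize(phantom, state$infl,
                                  iters = cfg$baseline$iters,
                                  margin = cfg$init$margin)
  }
  rep_ids <- metrics_report(state$dose, state$vois, state$rx, state$grid)
  rep_base <- metrics_report(baseline$dose, baseline$vois, baseline$rx,
                             baseline$grid)
  del_ids <- deliverability_delta(state, cfg$sequencer$levels)
  del_base <- deliverability_delta(baseline, cfg$sequencer$levels)
  d <- stage_dir(cfg, "report")
  tab <- report_indicator_table(rep_ids, rep_base)
  write.csv(tab, file.path(d, "indicators.csv"), row.names = FALSE)
  q <- rbind(cbind(plan = "ids", rep_ids$quantec),
             cbind(plan = "reference", rep_base$quantec))
  write.csv(q, file.path(d, "quantec.csv"), row.names = FALSE)
  seg <- data.frame(plan = c("ids", "reference"),
                    segments = c(del_ids$counts$total, del_base$counts$total))
  write.csv(seg, file.path(d, "segments.csv"), row.names = FALSE)
  jsonlite::write_json(list(ntid_ids = rep_ids$ntid,
                            ntid_reference = rep_base$ntid),
                       file.path(d, "ntid.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(state$vois)) {
    write.csv(dvh(state$dose, state$vois[[nm]]),
              file.path(d, paste0("dvh_ids_", nm, ".csv")), row.names = FALSE)
    write.csv(dvh(baseline$dose, baseline$vois[[nm]]),
              file.path(d, paste0("dvh_reference_", nm, ".csv")),
              row.names = FALSE)
  }
  invisible(list(indicators = tab, quantec = q, segments = seg,
                 ntid = list(ids = rep_ids$ntid, reference = rep_base$ntid)))
}

#' Run the full study pipeline on one seeded phantom
#'
#' Chains phantom generation, dose-influence computation, open-field
#' initialization, goal-driven shaping, metrics, sequencing and the
#' comparison report, and writes a manifest with a hash of the
#' configuration so a run is reproducible from the manifest alone.
#'
#' @param cfg configuration list (see [default_config()])
#' @return list with the shaped plan, baseline plan and report tables
#' @export
run_study <- function(cfg = default_config()) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- file.path(cfg$outdir, "config.yaml")
  write_run_config(cfg, cfg_file)
  manifest <- list(config = cfg,
                   config_hash = unname(tools::md5sum(cfg_file)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ph <- stage_phantom(cfg)
  infl <- stage_influence(cfg, ph)
  state <- stage_init(cfg, ph, infl)
  state <- stage_shape(cfg, state)
  stage_metrics(cfg, state)
  stage_sequence(cfg, state)
  rep <- stage_report(cfg, state)
  invisible(list(plan = state, report = rep))
}
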