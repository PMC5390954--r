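#' Assemble a plan state from its parts
#'
#' Low-level constructor: wraps an influence operator, fluence weights
#' and structure set into a consistent `ids_plan` (the dose is computed
#' from the weights unless given explicitly).
#'
#' @param infl an `ids_influence`
#' @param w fluence weights
#' @param vois named list of `ids_voi`
#' @param rx an [prescription()]
#' @param dose optional per-voxel dose (defaults to `compute_dose(infl, w)`)
#' @return an `ids_plan`
#' @export
plan_state <- function(infl, w, vois, rx = prescription(), dose = NULL) {
  if (is.null(dose)) dose <- compute_dose(infl, w)
  structure(list(grid = infl$grid, vois = vois, rx = rx, infl = infl,
                 w = w, dose = dose, scale_factor = 1,
                 post_shaping_scale = 1, history = list(),
                 snapshots = list()),
            class = "ids_plan")
}

#' Initialize a plan from open fields
#'
#' Opens every bixel whose ray intersects the PTV dilated by `margin`,
#' then scales all weights by a single factor so that the PTV median dose
#' D50% equals the average of the PTV and boost prescriptions. D50% is
#' exactly linear in the scale factor, so the condition is met by one
#' closed-form rescaling.
#'
#' @param phantom `list(grid, vois, rx)` as from [generate_phantom()]
#' @param infl an `ids_influence` built on the phantom
#' @param margin open-field margin, mm (default 5)
#' @return an `ids_plan`: fluence weights `w`, per-voxel `dose`, the
#'   prescription, operation history and saved snapshots
#' @export
init_plan <- function(phantom, infl, margin = 5) {
  w <- open_field(infl, phantom$vois$ptv, margin = margin)
  dose <- compute_dose(infl, w)
  d50 <- dose_at_volume(dose, phantom$vois$ptv, 50)
  if (d50 <= 0) ids_stop("open fields deliver no dose to the PTV",
                         "ids_infeasible")
  target <- (phantom$rx$ptv + phantom$rx$boost) / 2
  s <- target / d50
  structure(list(grid = phantom$grid, vois = phantom$vois, rx = phantom$rx,
                 infl = infl, w = w * s, dose = dose * s,
                 scale_factor = s, post_shaping_scale = 1,
                 history = list(list(type = "init", margin = margin, scale = s)),
                 snapshots = list()),
            class = "ids_plan")
}

#' @export
print.ids_plan <- function(x, ...) {
  cat(sprintf("IDS plan: %d bixels, %d history entries, D50%%(PTV) = %.2f Gy\n",
              length(x$w), length(x$history),
              dose_at_volume(x$dose, x$vois$ptv, 50)))
  invisible(x)
}

#' Default hierarchical goal list
#'
#' Strict-priority goals mirroring the Quantec-first workflow: rectum
#' constraints, then bladder constraints, then a target-coverage floor
#' explored as trade-off. Budgets are counted in DMR instances.
#'
#' @param budget per-goal budget of DMR instances
#' @return list of goals
#' @export
default_goals <- function(budget = 3000L) {
  list(
    list(name = "rectum_quantec", type = "quantec", structure = "rectum",
         budget = budget),
    list(name = "bladder_quantec", type = "quantec", structure = "bladder",
         budget = budget),
    list(name = "target_coverage", type = "coverage", budget = budget)
  )
}

plan_objective <- function(state, d98_floor_frac = 0.95, coverage_weight = 10) {
  q <- quantec_check(state$dose, state$vois$rectum, state$vois$bladder)
  viol <- sum(pmax(0, q$value - q$limit))
  cov <- coverage_weight *
    (max(0, d98_floor_frac * state$rx$ptv -
            dose_at_volume(state$dose, state$vois$ptv, 98)) +
     max(0, d98_floor_frac * state$rx$boost -
            dose_at_volume(state$dose, state$vois$boost, 98)))
  viol + cov
}

#' Scripted hierarchical goal-driven shaping
#'
#' Automated stand-in for interactive shaping: per goal, a greedy loop
#' finds the most-violating constraint, places a sphere-decrease gesture
#' at the hottest contributing organ-at-risk voxel (or a sphere-increase
#' at the coldest target voxel for the coverage goal), and accepts the
#' gesture only if a scalar objective — summed Quantec violation plus a
#' weighted target-coverage penalty — strictly improves and no
#' previously satisfied higher-priority constraint becomes violated;
#' otherwise the gesture is rolled back and the voxel blacklisted. The
#' loop stops at goal satisfaction or budget exhaustion (reported, not
#' fatal). The objective over accepted gestures is strictly decreasing.
#'
#' @param state an initialized `ids_plan`
#' @param goals as from [default_goals()]
#' @param tau,nr DMR parameters
#' @param sphere_radius_vox gesture sphere radius in voxel units
#'   (default 3)
#' @param max_dd_gy cap on the magnitude of a single gesture's requested
#'   dose change (Gy); gentle repeated gestures keep the collateral
#'   damage within what the recovery budget can restore
#' @return the shaped `ids_plan`; attribute `"goal_log"` holds one row
#'   per gesture (goal, voxel, accepted, objective)
#' @export
goal_script_run <- function(state, goals = default_goals(), tau = NULL,
                            nr = 15L, sphere_radius_vox = 3, max_dd_gy = 4) {
  radius <- sphere_radius_vox * mean(state$grid$spacing)
  log <- list()
  obj <- plan_objective(state)
  for (goal in goals) {
    blacklist <- integer(0)
    spent <- 0L
    repeat {
      if (spent >= goal$budget) break
      if (goal$type == "quantec") {
        within <- state$vois[[goal$structure]]$mask
        q <- quantec_check(state$dose, state$vois$rectum, state$vois$bladder)
        q <- q[q$structure == goal$structure, ]
        excess <- q$value - q$limit
        if (all(excess < 0)) break      # goal satisfied (strict inequalities)
        con <- q[which.max(excess), ]
        cand <- which(within & array(state$dose >= con$x, state$grid$dims))
        cand <- setdiff(cand, blacklist)
        if (length(cand) == 0L) break
        vsel <- cand[which.max(state$dose[cand])]
        dd <- max(-max_dd_gy, -(state$dose[vsel] - 0.95 * con$x))
      } else {
        within <- state$vois$ptv$mask
        floor_gy <- 0.95 * state$rx$ptv
        d98 <- dose_at_volume(state$dose, state$vois$ptv, 98)
        if (d98 >= floor_gy) break
        cand <- setdiff(which(within & array(state$dose < floor_gy,
                                             state$grid$dims)), blacklist)
        if (length(cand) == 0L) break
        vsel <- cand[which.min(state$dose[cand])]
        dd <- min(max_dd_gy, floor_gy - state$dose[vsel])
      }
      snap_w <- state$w; snap_dose <- state$dose; snap_hist <- state$history
      passed_before <- quantec_check(state$dose, state$vois$rectum,
                                     state$vois$bladder)$pass
      gesture <- list(type = "sphere",
                      center = as.numeric(voxel_centers(state$grid, vsel)),
                      radius = radius, dd = dd, within = within)
      state <- execute_tool(state, gesture, tau = tau, nr = nr)
      n_inst <- length(attr(state, "tool_results"))
      spent <- spent + max(1L, n_inst)
      new_obj <- plan_objective(state)
      passed_after <- quantec_check(state$dose, state$vois$rectum,
                                    state$vois$bladder)$pass
      accept <- (new_obj < obj) && !any(passed_before & !passed_after)
      if (accept) {
        obj <- new_obj
      } else {
        state$w <- snap_w; state$dose <- snap_dose; state$history <- snap_hist
        blacklist <- c(blacklist, vsel)
      }
      log <- c(log, list(data.frame(goal = goal$name, voxel = vsel, dd = dd,
                                    instances = n_inst, accepted = accept,
                                    objective = if (accept) new_obj else obj)))
    }
    state$history <- c(state$history,
                       list(list(type = "goal", name = goal$name,
                                 instances_spent = spent,
                                 objective = obj)))
  }
  attr(state, "goal_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(goal = character(0), voxel = integer(0), dd = numeric(0),
               instances = integer(0), accepted = logical(0),
               objective = numeric(0))
  state
}

#' Baseline fluence optimization (quadratic penalty, projected gradient)
#'
#' A conventional inverse-planning baseline: minimizes a piece-wise
#' quadratic objective `sum_voi weight/n * sum_i (max(0, dmin - d)^2 +
#' max(0, d - dmax)^2)` over non-negative bixel weights by projected
#' gradient descent with backtracking, started from uniform open-field
#' weights. Deterministic; the objective is non-increasing per
#' iteration.
#'
#' @param phantom `list(grid, vois, rx)`
#' @param infl an `ids_influence`
#' @param objectives named list per VOI:
#'   `list(dmin, dmax, weight)`; `NULL` for the defaults (prescription on
#'   PTV/boost, upper bounds on OARs and body)
#' @param iters gradient iterations
#' @param margin open-field margin for the starting point, mm
#' @return an `ids_plan`
#' @export
baseline_optimize <- function(phantom, infl, objectives = NULL, iters = 60L,
                              margin = 5) {
  rx <- phantom$rx
  if (is.null(objectives)) {
    objectives <- list(
      boost = list(dmin = rx$boost, dmax = rx$boost, weight = 100),
      ptv = list(dmin = rx$ptv, dmax = rx$boost, weight = 50),
      rectum = list(dmin = 0, dmax = 0.6 * rx$ptv, weight = 5),
      bladder = list(dmin = 0, dmax = 0.7 * rx$ptv, weight = 5),
      body = list(dmin = 0, dmax = 0.8 * rx$ptv, weight = 1)
    )
  }
  for (o in objectives) if (o$weight < 0)
    ids_stop("objective weights must be >= 0", "ids_value_error")
  vidx <- lapply(names(objectives), function(nm) which(phantom$vois[[nm]]$mask))
  names(vidx) <- names(objectives)

  fval <- function(dose) {
    s <- 0
    for (nm in names(objectives)) {
      o <- objectives[[nm]]; d <- dose[vidx[[nm]]]
      s <- s + o$weight / length(d) *
        sum(pmax(0, o$dmin - d)^2 + pmax(0, d - o$dmax)^2)
    }
    s
  }
  grad_r <- function(dose) {
    r <- numeric(length(dose))
    for (nm in names(objectives)) {
      o <- objectives[[nm]]; ii <- vidx[[nm]]; d <- dose[ii]
      r[ii] <- r[ii] + o$weight / length(ii) *
        2 * (pmax(0, d - o$dmax) - pmax(0, o$dmin - d))
    }
    r
  }

  w <- open_field(infl, phantom$vois$ptv, margin = margin)
  dose <- compute_dose(infl, w)
  d50 <- dose_at_volume(dose, phantom$vois$ptv, 50)
  if (d50 > 0) { s0 <- (rx$ptv + rx$boost) / 2 / d50; w <- w * s0; dose <- dose * s0 }
  f <- fval(dose)
  trace <- f
  step <- 1
  for (it in seq_len(iters)) {
    g <- as.vector(infl$Dt %*% grad_r(dose))
    ok <- FALSE
    for (bt in 1:30) {
      w2 <- pmax(0, w - step * g)
      dose2 <- compute_dose(infl, w2)
      f2 <- fval(dose2)
      if (!is.finite(f2)) ids_stop("non-finite objective", "ids_value_error")
      if (f2 <= f) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break
    w <- w2; dose <- dose2; f <- f2
    trace <- c(trace, f)
    step <- step * 1.5
  }
  structure(list(grid = phantom$grid, vois = phantom$vois, rx = rx,
                 infl = infl, w = w, dose = dose,
                 scale_factor = 1, post_shaping_scale = 1,
                 history = list(list(type = "baseline", iters = iters,
                                     objective = f,
                                     objective_trace = trace)),
                 snapshots = list()),
            class = "ids_plan")
}

#' Save a plan state ("dose state") to a directory container
#'
#' Writes a JSON manifest (prescription, history, scale factors, grid),
#' the fluence weights as full-precision CSV, and the dose as a raw
#' binary block. A save/load/save round trip is byte-identical and
#' preserves the fluence bit-exactly.
#'
#' @param state an `ids_plan`
#' @param path directory (created if needed)
#' @return `path`, invisibly
#' @export
save_state <- function(state, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "ids_plan/1",
    grid = list(dims = state$grid$dims, spacing = state$grid$spacing,
                origin = state$grid$origin),
    rx = unclass(state$rx),
    scale_factor = state$scale_factor,
    post_shaping_scale = state$post_shaping_scale,
    n_bixels = length(state$w),
    history = state$history
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c("weight", sprintf("%.17g", state$w)),
             file.path(path, "fluence.csv"))
  con <- file(file.path(path, "dose.bin"), "wb")
  writeBin(state$dose, con, size = 8, endian = "little")
  close(con)
  for (nm in names(state$vois))
    write_nrrd(state$vois[[nm]]$mask, file.path(path, paste0(nm, ".nrrd")),
               state$grid, encoding = "raw")
  invisible(path)
}

#' Load a plan state saved by [save_state()]
#'
#' @param path container directory
#' @param infl the dose-influence operator for the stored geometry, or
#'   `NULL` to load without one (dose comes from the stored block)
#' @return an `ids_plan`
#' @export
load_state <- function(path, infl = NULL) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    ids_stop(sprintf("no plan-state manifest under '%s'", path), "ids_io_error")
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  grid <- voxel_grid(unlist(manifest$grid$dims), unlist(manifest$grid$spacing),
                     unlist(manifest$grid$origin))
  w <- as.numeric(readLines(file.path(path, "fluence.csv"))[-1])
  con <- file(file.path(path, "dose.bin"), "rb")
  dose <- readBin(con, "double", n_voxels(grid), size = 8, endian = "little")
  close(con)
  roles <- c(body = "body", ptv = "target", boost = "boost",
             rectum = "oar", bladder = "oar")
  vois <- list()
  for (nm in names(roles)) {
    f <- file.path(path, paste0(nm, ".nrrd"))
    if (file.exists(f)) vois[[nm]] <- voi(nm, roles[[nm]], read_nrrd(f)$data)
  }
  structure(list(grid = grid, vois = vois,
                 rx = prescription(manifest$rx$boost, manifest$rx$ptv),
                 infl = infl, w = w, dose = dose,
                 scale_factor = manifest$scale_factor,
                 post_shaping_scale = manifest$post_shaping_scale,
                 history = manifest$history, snapshots = list()),
            class = "ids_plan")
}
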