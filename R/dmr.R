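#' Minimum-norm fluence patch enforcing a local dose change
#'
#' Given the influence row `a = D[v, ]` of voxel `v`, the unconstrained
#' patch is the minimum-norm solution `P = dd * a / ||a||^2` of
#' `a . P = dd`. Entries that would drive a weight negative are clamped
#' to `-w` and the remainder is re-solved over the unclamped bixels (at
#' most `max_passes` passes), so the returned patch best-approaches the
#' requested change under the non-negativity constraint.
#'
#' @param infl an `ids_influence`
#' @param w current fluence weights
#' @param v 1-based linear voxel index; its influence row must be nonzero
#' @param dd requested dose change at `v`, Gy (signed)
#' @param exclude bixel indices barred from the patch support (used to
#'   protect an earlier modification from being undone by recovery)
#' @param max_passes clamping passes
#' @return `list(bixels, delta, achieved)`; `achieved` is the dose change
#'   at `v` actually enforced (same sign as `dd`, or zero)
#' @export
fluence_patch <- function(infl, w, v, dd, exclude = integer(0),
                          max_passes = 10L) {
  row <- influence_row(infl, v)
  if (length(exclude)) {
    keep <- !(row$bixels %in% exclude)
    row$bixels <- row$bixels[keep]; row$a <- row$a[keep]
  }
  if (length(row$a) == 0L || sum(row$a^2) == 0)
    ids_stop(sprintf("voxel %d has no usable influence row", v),
             "ids_infeasible")
  if (dd == 0)
    return(list(bixels = row$bixels, delta = numeric(length(row$bixels)),
                achieved = 0))
  a <- row$a
  wv <- w[row$bixels]
  P <- dd * a / sum(a^2)
  fixed <- rep(FALSE, length(a))
  for (pass in seq_len(max_passes)) {
    viol <- !fixed & (wv + P < 0)
    if (!any(viol)) break
    P[viol] <- -wv[viol]
    fixed <- fixed | viol
    free <- !fixed
    resid <- dd - sum(a[fixed] * P[fixed])
    den <- sum(a[free]^2)
    if (!any(free) || den == 0) break
    P[free] <- resid * a[free] / den
  }
  # final safety clamp (numerical)
  P <- pmax(P, -wv)
  list(bixels = row$bixels, delta = P, achieved = sum(a * P))
}

#' Identify voxels for dose recovery
#'
#' After a modification patch, lists the voxels outside the intended
#' modification region whose dose deviates from the reference by more
#' than the tolerance, sorted by decreasing absolute deviation (ties by
#' ascending linear voxel index) and truncated to the recovery budget.
#'
#' @param dose_ref reference (pre-modification) dose vector
#' @param dose_new current dose vector
#' @param vm logical mask (or integer indices) of the modification region
#' @param tau deviation tolerance, Gy
#' @param nr recovery budget: maximum number of voxels
#' @return `list(voxels, deviations)` (parallel vectors, possibly empty)
#' @export
identify_recovery <- function(dose_ref, dose_new, vm, tau, nr) {
  if (length(dose_ref) != length(dose_new))
    ids_stop("dose vectors differ in length", "ids_shape_error")
  dev <- dose_new - dose_ref
  if (is.logical(vm)) dev[vm] <- 0 else dev[as.integer(vm)] <- 0
  cand <- which(abs(dev) > tau)
  if (length(cand) == 0L) return(list(voxels = integer(0), deviations = numeric(0)))
  o <- order(-abs(dev[cand]), cand)
  cand <- cand[o][seq_len(min(nr, length(cand)))]
  list(voxels = cand, deviations = dev[cand])
}

protected_bixels <- function(patch, infl, v, frac = 0.9) {
  if (length(patch$bixels) == 0L || patch$achieved == 0) return(integer(0))
  row <- influence_row(infl, v)
  a <- numeric(length(patch$bixels))
  m <- match(patch$bixels, row$bixels)
  a[!is.na(m)] <- row$a[m[!is.na(m)]]
  contrib <- patch$delta * a
  o <- order(-abs(contrib))
  cs <- cumsum(abs(contrib[o]))
  need <- frac * abs(patch$achieved)
  k <- which(cs >= need)[1]
  if (is.na(k)) k <- length(o)
  patch$bixels[o[seq_len(k)]]
}

#' Two-step dose modification and recovery (DMR)
#'
#' The central shaping operator. Step one applies a minimum-norm fluence
#' patch enforcing the requested dose change at the selected voxel and
#' updates the dose incrementally. Step two ranks the collateral
#' deviations outside the modification region against the
#' pre-modification dose and, for up to `nr` voxels in order of
#' decreasing deviation, applies a counter-patch restoring the original
#' dose. Recovery is single-pass: recovery patches trigger no further
#' recovery. Bixels that carried at least 90% of the modification's
#' enforced change are excluded from recovery patches so that a recovery
#' cannot immediately undo the modification it follows.
#'
#' @param state an `ids_plan` (see [init_plan()])
#' @param req a request: `list(v = voxel index, dd = Gy, vm = logical
#'   mask or indices of the intended modification region)`; `vm` defaults
#'   to `{v}`
#' @param tau recovery tolerance, Gy; default 0.5% of the boost
#'   prescription
#' @param nr recovery budget N_R (number of recovered voxels; default 15)
#' @return the updated `ids_plan`; the DMR record (achieved change,
#'   residual deviation summary, patches) is appended to `state$history`
#'   and also attached as attribute `"dmr_result"`
#' @export
apply_dmr <- function(state, req, tau = NULL, nr = 15L) {
  if (is.null(tau)) tau <- 0.005 * state$rx$boost
  v <- req$v
  vm <- req$vm
  if (is.null(vm)) vm <- v
  ref <- state$dose
  mod <- fluence_patch(state$infl, state$w, v, req$dd)  # may signal ids_infeasible
  w <- state$w; dose <- state$dose
  w[mod$bixels] <- w[mod$bixels] + mod$delta
  dose <- incremental_dose(state$infl, dose, mod$bixels, mod$delta)

  protect <- protected_bixels(mod, state$infl, v)
  plan <- identify_recovery(ref, dose, vm, tau, nr)
  dev_pre <- abs(dose - ref)
  dev_pre[vm] <- 0
  cand_set <- which(dev_pre > tau)  # candidate set of the recovery ranking
  n_over_pre <- length(cand_set)

  # Recovery patches are applied sequentially in patch space; the full
  # dose grid is updated once with the accumulated fluence delta. The
  # dose at each recovery voxel is tracked exactly through sparse dot
  # products with the deltas accumulated so far.
  patches <- list(mod)
  recovered <- integer(0)
  acc <- numeric(length(w))
  for (r in plan$voxels) {
    row_r <- influence_row(state$infl, r)
    dr <- dose[r] + sum(row_r$a * acc[row_r$bixels]) - ref[r]
    if (abs(dr) <= tau) next
    rp <- tryCatch(
      fluence_patch(state$infl, w, r, -dr, exclude = protect),
      ids_infeasible = function(e) NULL)
    if (is.null(rp)) next
    w[rp$bixels] <- w[rp$bixels] + rp$delta
    acc[rp$bixels] <- acc[rp$bixels] + rp$delta
    patches <- c(patches, list(rp))
    recovered <- c(recovered, r)
  }
  touched <- which(acc != 0)
  if (length(touched))
    dose <- incremental_dose(state$infl, dose, touched, acc[touched])
  dev_post <- abs(dose - ref)
  dev_post[vm] <- 0
  res <- list(
    v = v, requested = req$dd, achieved = mod$achieved,
    recovery_voxels = recovered,
    planned_recovery = plan$voxels,
    residual_max = if (length(dev_post)) max(dev_post) else 0,
    residual_rms = sqrt(mean(dev_post^2)),
    n_over_tau_pre = n_over_pre,
    n_over_tau_post = sum(dev_post[cand_set] > tau),
    n_patches = length(patches),
    patches = patches
  )
  state$w <- w
  state$dose <- dose
  state$history <- c(state$history, list(list(type = "dmr", v = v,
                                              requested = req$dd,
                                              achieved = mod$achieved,
                                              n_recovered = length(recovered),
                                              residual_max = res$residual_max)))
  attr(state, "dmr_result") <- res
  state
}

#' Translate an interactive shaping gesture into DMR requests
#'
#' Three gestures mirror the interactive tools: single-voxel
#' manipulation, isodose-line dragging, and spherical isodose-surface
#' manipulation (the sphere radius controls the locality of the change;
#' the requested change falls off with a radial cosine towards the sphere
#' surface).
#'
#' @param state an `ids_plan`
#' @param gesture one of
#'   `list(type = "voxel", v, dd)`,
#'   `list(type = "sphere", center = mm triple, radius = mm, dd)`,
#'   `list(type = "isodose_drag", level = Gy, from = mm triple, to = mm triple)`.
#'   A sphere gesture may carry an optional `within` logical mask
#'   restricting the touched voxels (and the modification region) to one
#'   structure — the scripted planner uses this to confine its decrease
#'   gestures to the organ at risk, emulating a click on the isodose
#'   surface inside that organ.
#' @return list of DMR requests (each `list(v, dd, vm)`), in ascending
#'   voxel order for the sphere gesture and along the drag segment for
#'   the isodose gesture
#' @export
tool_requests <- function(state, gesture) {
  grid <- state$infl$grid
  body <- state$vois$body$mask
  switch(gesture$type,
    voxel = list(list(v = gesture$v, dd = gesture$dd, vm = gesture$v)),
    sphere = {
      ctr <- gesture$center; R <- gesture$radius
      lo <- point_to_voxel(grid, ctr - R); hi <- point_to_voxel(grid, ctr + R)
      d <- grid$dims
      ix <- max(1, lo[1]):min(d[1], hi[1])
      iy <- max(1, lo[2]):min(d[2], hi[2])
      iz <- max(1, lo[3]):min(d[3], hi[3])
      idx <- as.integer(outer(outer(ix, (iy - 1) * d[1], "+"),
                              (iz - 1) * d[1] * d[2], "+"))
      cc <- voxel_centers(grid, idx)
      r <- sqrt((cc[, 1] - ctr[1])^2 + (cc[, 2] - ctr[2])^2 + (cc[, 3] - ctr[3])^2)
      inside <- r <= R & body[idx]
      if (!is.null(gesture$within)) inside <- inside & gesture$within[idx]
      if (!any(inside)) {
        # degenerate small sphere: fall back to the center voxel if in body
        cvox <- voxel_index(grid, ctr)
        if (!is.na(cvox) && body[cvox])
          return(list(list(v = cvox, dd = gesture$dd, vm = cvox)))
        ids_stop("sphere does not intersect the body", "ids_geometry_error")
      }
      idx <- idx[inside]; r <- r[inside]
      o <- order(idx); idx <- idx[o]; r <- r[o]
      fall <- 0.5 * (1 + cos(pi * r / R))
      lapply(seq_along(idx), function(q)
        list(v = idx[q], dd = gesture$dd * fall[q], vm = idx))
    },
    isodose_drag = {
      lvl <- gesture$level
      dr <- range(state$dose[body])
      if (lvl < dr[1] || lvl > dr[2])
        ids_stop("isodose level outside the current dose range", "ids_value_error")
      from <- gesture$from; to <- gesture$to
      seg <- sqrt(sum((to - from)^2))
      if (seg == 0) return(list())
      step <- min(grid$spacing) / 2
      tt <- seq(0, 1, length.out = max(2, ceiling(seg / step) + 1))
      pts <- cbind(from[1] + tt * (to[1] - from[1]),
                   from[2] + tt * (to[2] - from[2]),
                   from[3] + tt * (to[3] - from[3]))
      vox <- unique(apply(pts, 1, function(p) voxel_index(grid, p)))
      vox <- vox[!is.na(vox)]
      vox <- vox[body[vox]]
      if (length(vox) == 0) return(list())
      outward <- state$dose[vox[length(vox)]] < lvl
      eps <- 1e-3 * lvl
      reqs <- list()
      for (v in vox) {
        d0 <- state$dose[v]
        if (outward && d0 < lvl)
          reqs <- c(reqs, list(list(v = v, dd = lvl - d0, vm = vox)))
        else if (!outward && d0 >= lvl)
          reqs <- c(reqs, list(list(v = v, dd = (lvl - eps) - d0, vm = vox)))
      }
      reqs
    },
    ids_stop(sprintf("unknown gesture type '%s'", gesture$type), "ids_value_error")
  )
}

point_to_voxel <- function(grid, p) {
  as.integer(floor((p - grid$origin) / grid$spacing)) + 1L
}

#' Linear voxel index of a physical point
#' @param grid an `ids_grid`
#' @param p mm triple
#' @return 1-based linear index, or `NA` if outside the grid
#' @export
voxel_index <- function(grid, p) {
  ijk <- point_to_voxel(grid, p)
  d <- grid$dims
  if (any(ijk < 1L) || any(ijk > d)) return(NA_integer_)
  ijk[1] + d[1] * (ijk[2] - 1L) + d[1] * d[2] * (ijk[3] - 1L)
}

#' Execute a shaping gesture as consecutive DMR instances
#'
#' Translates the gesture via [tool_requests()] and applies the requests
#' through [apply_dmr()] in order. The first infeasible instance aborts
#' the remainder; instances already executed persist.
#'
#' @inheritParams tool_requests
#' @param tau,nr DMR parameters passed to [apply_dmr()]
#' @return the updated `ids_plan`, with attribute `"tool_results"` (list
#'   of per-instance DMR records) and `"aborted"` (logical)
#' @export
execute_tool <- function(state, gesture, tau = NULL, nr = 15L) {
  reqs <- tool_requests(state, gesture)
  results <- list(); aborted <- FALSE
  for (rq in reqs) {
    new_state <- tryCatch(apply_dmr(state, rq, tau = tau, nr = nr),
                          ids_infeasible = function(e) NULL)
    if (is.null(new_state)) { aborted <- TRUE; break }
    state <- new_state
    results <- c(results, list(attr(state, "dmr_result")))
  }
  attr(state, "tool_results") <- results
  attr(state, "aborted") <- aborted
  state
}
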