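#' Stratify fluence maps to equidistant levels
#'
#' Per beam, the level step is `max(weight) / levels` and each bixel is
#' rounded half-up to the nearest integer level in `0..levels`, so the
#' quantization error never exceeds half a step. An all-zero beam gets
#' step 0 and produces no segments.
#'
#' @param infl an `ids_influence` (supplies the per-beam layout)
#' @param w fluence weight vector, all >= 0
#' @param levels number of equidistant fluence levels (default 7)
#' @return an `ids_stratified`: list with per-beam integer `level`
#'   matrices, per-beam `step` (weight units) and `levels`
#' @export
stratify <- function(infl, w, levels = 7L) {
  if (any(w < 0)) ids_stop("fluence weights must be >= 0", "ids_value_error")
  maps <- fluence_maps(infl, w)
  steps <- vapply(maps, function(m) max(m) / levels, numeric(1))
  lv <- lapply(seq_along(maps), function(bi) {
    if (steps[bi] == 0) return(matrix(0L, nrow(maps[[bi]]), ncol(maps[[bi]])))
    matrix(as.integer(floor(maps[[bi]] / steps[bi] + 0.5)),
           nrow(maps[[bi]]), ncol(maps[[bi]]))
  })
  structure(list(level = lv, step = steps, levels = as.integer(levels)),
            class = "ids_stratified")
}

#' Stratified weights back on the bixel lattice
#' @param strat an `ids_stratified`
#' @return fluence weight vector `level * step`
#' @export
stratified_weights <- function(strat) {
  unlist(lapply(seq_along(strat$level), function(bi)
    as.vector(strat$level[[bi]]) * strat$step[bi]), use.names = FALSE)
}

# sweep decomposition of one integer row profile: returns, for segment
# index k, the half-open aperture [left_k, right_k) in column units.
sweep_row <- function(f) {
  n <- length(f)
  inc <- pmax(0, diff(c(0, f)))
  dec <- pmax(0, -diff(c(0, f)))
  A <- cumsum(inc); B <- cumsum(dec)
  K <- if (n) A[n] else 0L
  list(A = A, B = B, K = K)
}

#' Step-and-shoot MLC sweep sequencing
#'
#' Decomposes each beam's stratified fluence into unit-level apertures by
#' the classic unidirectional sweep: per leaf-pair row, the left and
#' right leaf trajectories follow the cumulative positive and negative
#' gradients of the integer profile, and rows are synchronized into
#' global segments of one level step each. The decomposition is exact
#' (the apertures sum back to the stratified map bit for bit) and both
#' leaves move monotonically left to right across segments.
#'
#' In a segment, a row's aperture is the half-open column interval
#' `[left, right)`; a closed row has `left == right`.
#'
#' @param strat an `ids_stratified`
#' @return list of segments, each
#'   `list(beam, weight, left, right)` with `left`/`right` integer
#'   vectors over the beam's rows (the matrix rows of the level map are
#'   lateral columns, its columns the leaf-pair rows; leaves travel
#'   along the lateral axis)
#' @export
sequence_sweep <- function(strat) {
  segs <- list()
  for (bi in seq_along(strat$level)) {
    lvm <- strat$level[[bi]]       # nk x nm: lateral columns x leaf rows
    nrows <- ncol(lvm); ncols <- nrow(lvm)
    rowdec <- lapply(seq_len(nrows), function(m) sweep_row(lvm[, m]))
    K <- max(0L, vapply(rowdec, function(r) as.integer(r$K), integer(1)))
    if (K == 0L) next
    for (k in seq_len(K)) {
      left <- integer(nrows); right <- integer(nrows)
      for (m in seq_len(nrows)) {
        rd <- rowdec[[m]]
        if (rd$K >= k) {
          left[m] <- match(TRUE, rd$A >= k)
          r <- match(TRUE, rd$B >= k)
          right[m] <- if (is.na(r)) ncols + 1L else r
        } else {
          left[m] <- right[m] <- ncols + 1L  # swept past; row closed
        }
      }
      segs <- c(segs, list(list(beam = bi, weight = strat$step[bi],
                                left = left, right = right)))
    }
  }
  segs
}

#' Reconstruct the integer fluence map from MLC segments
#'
#' Sums the unit-weight aperture indicators of all segments of each
#' beam. Used as the deliverability check: sequencing is exact when the
#' reconstruction equals the stratified map.
#'
#' @param segments list as from [sequence_sweep()]
#' @param strat the `ids_stratified` the segments were derived from
#'   (supplies beam layout)
#' @return list of integer matrices, one per beam
#' @export
reconstruct_fluence <- function(segments, strat) {
  out <- lapply(strat$level, function(m) matrix(0L, nrow(m), ncol(m)))
  for (s in segments) {
    m <- out[[s$beam]]
    for (r in seq_along(s$left)) {
      if (s$right[r] > s$left[r])
        m[s$left[r]:(s$right[r] - 1L), r] <- m[s$left[r]:(s$right[r] - 1L), r] + 1L
    }
    out[[s$beam]] <- m
  }
  out
}

#' Segment counts per beam and in total
#' @param segments list as from [sequence_sweep()]
#' @param n_beams number of beams
#' @return `list(per_beam, total)`
#' @export
segment_counts <- function(segments, n_beams) {
  per <- integer(n_beams)
  for (s in segments) per[s$beam] <- per[s$beam] + 1L
  list(per_beam = per, total = sum(per))
}

#' Deliverability check: metric deltas after sequencing
#'
#' Stratifies the current fluence, sequences it, reconstructs the
#' deliverable fluence, recomputes dose, and reports the full metrics
#' for both the shaped and the sequenced plan together with per-voxel
#' dose-difference bounds. Since dose is linear in fluence and each
#' bixel moves by at most half a level step, the per-voxel dose change
#' is bounded by the dose of a uniform step/2 fluence.
#'
#' @param state an `ids_plan` (with its influence operator)
#' @param levels stratification levels (default 7)
#' @return list: `metrics_plan`, `metrics_sequenced`, `segments`,
#'   `counts`, `max_dose_delta`, `dose_delta_bound`
#' @export
deliverability_delta <- function(state, levels = 7L) {
  infl <- state$infl
  strat <- stratify(infl, state$w, levels)
  segs <- sequence_sweep(strat)
  rec <- reconstruct_fluence(segs, strat)
  w2 <- unlist(lapply(seq_along(rec), function(bi)
    as.vector(rec[[bi]]) * strat$step[bi]), use.names = FALSE)
  dose2 <- compute_dose(infl, w2)
  halfstep <- unlist(lapply(seq_along(strat$level), function(bi)
    rep(strat$step[bi] / 2, length(strat$level[[bi]]))), use.names = FALSE)
  bound <- compute_dose(infl, halfstep)
  list(
    metrics_plan = metrics_report(state$dose, state$vois, state$rx, state$grid),
    metrics_sequenced = metrics_report(dose2, state$vois, state$rx, state$grid),
    segments = segs,
    counts = segment_counts(segs, length(strat$level)),
    max_dose_delta = max(abs(dose2 - state$dose)),
    dose_delta_bound = bound,
    dose_sequenced = dose2
  )
}

#' Write segments as JSON
#'
#' Leaf positions are reported both in bixel-column units and in mm
#' using the lateral bixel pitch (5 mm leaves by default).
#'
#' @param segments list as from [sequence_sweep()]
#' @param infl the `ids_influence` (for the bixel pitch)
#' @param path output JSON file
#' @return `path`, invisibly
#' @export
write_segments <- function(segments, infl, path) {
  pitch <- if (!is.null(infl$beams)) infl$beams$bixel[1] else 5
  out <- lapply(segments, function(s)
    list(beam = s$beam, weight = s$weight,
         left_bixel = s$left, right_bixel = s$right,
         left_mm = (s$left - 1) * pitch, right_mm = (s$right - 1) * pitch))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
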