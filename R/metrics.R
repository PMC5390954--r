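mask_values <- function(dose, mask) {
  m <- if (inherits(mask, "ids_voi")) mask$mask else mask
  v <- dose[if (is.logical(m)) which(m) else as.integer(m)]
  if (length(v) == 0L) ids_stop("mask is empty", "ids_value_error")
  v
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure receiving at least each dose. The curve is
#' evaluated at bin edges `0, bin, 2*bin, ...` up to just past the
#' structure maximum; it starts at 1 and is non-increasing.
#'
#' @param dose per-voxel dose vector
#' @param mask logical mask, voxel indices, or `ids_voi`
#' @param bin bin width, Gy
#' @return data.frame with columns `dose` (Gy) and `volume` (fraction)
#' @export
dvh <- function(dose, mask, bin = 0.1) {
  d <- mask_values(dose, mask)
  edges <- seq(0, max(d) + bin, by = bin)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  data.frame(dose = edges, volume = frac)
}

#' Dose received by the hottest q% of a structure (Dq%)
#'
#' Voxel-exact (interpolation-free): the largest dose d such that at
#' least q% of the structure receives at least d. `dose_at_volume(.., 50)`
#' is the median dose.
#'
#' @inheritParams dvh
#' @param q percentage in (0, 100]
#' @return dose in Gy
#' @export
dose_at_volume <- function(dose, mask, q) {
  if (!(q > 0 && q <= 100)) ids_stop("q must be in (0, 100]", "ids_value_error")
  d <- sort(mask_values(dose, mask), decreasing = TRUE)
  d[ceiling(q / 100 * length(d))]
}

#' Percent of a structure receiving at least x Gy (Vx)
#'
#' @inheritParams dvh
#' @param x dose threshold, Gy (inclusive)
#' @return percentage in [0, 100]
#' @export
volume_at_dose <- function(dose, mask, x) {
  if (x < 0) ids_stop("x must be >= 0", "ids_value_error")
  100 * mean(mask_values(dose, mask) >= x)
}

#' Conformity index (CI = CI1 * CI2)
#'
#' `V_t,ref` is the target volume receiving at least `threshold * rx`;
#' CI1 = V_t,ref / V_t (target coverage), CI2 = V_t,ref / V_ref with
#' V_ref the whole-body volume above the same threshold (dose spill). If
#' no voxel reaches the threshold, all three are defined as 0.
#'
#' @param dose per-voxel dose vector
#' @param target,body masks (target must be contained in body)
#' @param rx prescribed dose, Gy
#' @param threshold threshold fraction of the prescription (default 0.95)
#' @return `list(ci1, ci2, ci)`
#' @export
conformity <- function(dose, target, body, rx, threshold = 0.95) {
  if (rx <= 0) ids_stop("rx must be > 0", "ids_value_error")
  thr <- threshold * rx
  dt <- mask_values(dose, target)
  db <- mask_values(dose, body)
  vt_ref <- sum(dt >= thr)
  v_ref <- sum(db >= thr)
  if (v_ref == 0) return(list(ci1 = 0, ci2 = 0, ci = 0))
  ci1 <- vt_ref / length(dt)
  ci2 <- vt_ref / v_ref
  list(ci1 = ci1, ci2 = ci2, ci = ci1 * ci2)
}

#' Homogeneity index: dose standard deviation within a structure
#'
#' Population standard deviation (divisor n) of the voxel doses.
#'
#' @inheritParams dvh
#' @return Gy
#' @export
homogeneity <- function(dose, mask) {
  d <- mask_values(dose, mask)
  sqrt(mean((d - mean(d))^2))
}

#' Non-tumor integral dose
#'
#' `NTID = rho * (V/N) * sum_i D_i = rho * V * mean dose`, with V the
#' structure volume in litres. The structure is conventionally the body
#' minus the PTV (see [nontumor_mask()]); density rho defaults to 1.
#'
#' @inheritParams dvh
#' @param voxel_volume_mm3 voxel volume in mm^3
#' @param rho density (dimensionless multiplier), default 1
#' @return litre * Gy
#' @export
ntid <- function(dose, mask, voxel_volume_mm3, rho = 1) {
  d <- mask_values(dose, mask)
  rho * voxel_volume_mm3 * 1e-6 * sum(d)
}

#' Quantec dose-volume constraint table for rectum and bladder
#'
#' Evaluates the rectum constraints V50<50, V60<35, V65<25, V70<20,
#' V75<15 (%) and the bladder constraints V65<50, V70<35, V75<25,
#' V80<15 (%), all strict inequalities.
#'
#' @param dose per-voxel dose vector
#' @param rectum,bladder masks
#' @return data.frame with columns structure, x (Gy), limit (%),
#'   value (%), pass (logical); 5 rectum rows then 4 bladder rows
#' @export
quantec_check <- function(dose, rectum, bladder) {
  cons <- quantec_constraints()
  val <- mapply(function(st, x) {
    volume_at_dose(dose, if (st == "rectum") rectum else bladder, x)
  }, cons$structure, cons$x)
  cons$value <- as.numeric(val)
  cons$pass <- cons$value < cons$limit
  cons
}

quantec_constraints <- function() {
  data.frame(
    structure = c(rep("rectum", 5), rep("bladder", 4)),
    x = c(50, 60, 65, 70, 75, 65, 70, 75, 80),
    limit = c(50, 35, 25, 20, 15, 50, 35, 25, 15)
  )
}

#' Full plan-quality report
#'
#' Per-VOI mean, median (D50%), D98%, D2% and HI; conformity indices for
#' boost and PTV (threshold 95% of each prescription); the Quantec
#' table; Vx tables for the OARs; and the non-tumor integral dose over
#' body minus PTV.
#'
#' @param dose per-voxel dose vector
#' @param vois named list of `ids_voi` (body, ptv, boost, rectum, bladder)
#' @param rx an [prescription()]
#' @param grid an `ids_grid` (for the voxel volume entering NTID)
#' @return list with elements `indicators` (data.frame), `conformity`
#'   (list of boost/ptv CI triples), `quantec` (data.frame), `ntid`
#'   (litre Gy)
#' @export
metrics_report <- function(dose, vois, rx, grid) {
  ind <- do.call(rbind, lapply(names(vois), function(nm) {
    d <- mask_values(dose, vois[[nm]])
    data.frame(voi = nm, n_voxels = length(d), mean = mean(d),
               d50 = dose_at_volume(dose, vois[[nm]], 50),
               d98 = dose_at_volume(dose, vois[[nm]], 98),
               d2 = dose_at_volume(dose, vois[[nm]], 2),
               hi = homogeneity(dose, vois[[nm]]))
  }))
  conf <- list(
    boost = conformity(dose, vois$boost, vois$body, rx$boost),
    ptv = conformity(dose, vois$ptv, vois$body, rx$ptv)
  )
  nt <- ntid(dose, nontumor_mask(vois$body, vois$ptv), voxel_volume(grid))
  list(indicators = ind,
       conformity = conf,
       quantec = quantec_check(dose, vois$rectum, vois$bladder),
       ntid = nt)
}

#' Write a metrics report as JSON and flat CSV
#'
#' @param report as from [metrics_report()]
#' @param path basename; writes `<path>.json` and `<path>.csv`
#' @return `path`, invisibly
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  long <- rbind(
    do.call(rbind, lapply(seq_len(nrow(report$indicators)), function(i) {
      r <- report$indicators[i, ]
      data.frame(voi = r$voi,
                 indicator = c("mean", "d50", "d98", "d2", "hi"),
                 value = as.numeric(r[c("mean", "d50", "d98", "d2", "hi")]))
    })),
    data.frame(voi = c("boost", "boost", "ptv", "ptv"),
               indicator = c("ci1", "ci2", "ci1", "ci2"),
               value = c(report$conformity$boost$ci1, report$conformity$boost$ci2,
                         report$conformity$ptv$ci1, report$conformity$ptv$ci2)),
    data.frame(voi = report$quantec$structure,
               indicator = sprintf("V%g", report$quantec$x),
               value = report$quantec$value),
    data.frame(voi = "nontumor", indicator = "ntid", value = report$ntid)
  )
  write.csv(long, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
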