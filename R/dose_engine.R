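#' Beam configuration
#'
#' Co-planar beams rotating about the z (inferior-superior) axis. Gantry
#' angle 0 has the source anterior of the patient; the beam direction at
#' angle g (degrees) is (sin g, cos g, 0), i.e. the beam travels towards
#' +y (posterior) at g = 0. The in-plane lateral bixel axis is
#' (cos g, -sin g, 0) and the row axis is z, so one bixel row maps onto
#' one MLC leaf pair.
#'
#' @param angles gantry angles in degrees, distinct modulo 360 (default
#'   nine equispaced beams)
#' @param sad source-axis distance, mm (geometry bookkeeping only; the
#'   pencil kernel uses parallel rays)
#' @param isocenter mm triple; if `NULL`, set at plan time (PTV centroid)
#' @param bixel bixel size (lateral, row) in mm; default 5 x 5 so that
#'   one bixel row matches the 5 mm MLC leaf pitch
#' @return an `ids_beams`
#' @export
beam_set <- function(angles = seq(0, 320, by = 40), sad = 1000,
                     isocenter = NULL, bixel = c(5, 5)) {
  a <- angles %% 360
  if (anyDuplicated(a)) ids_stop("beam angles must be distinct modulo 360",
                                 "ids_value_error")
  if (any(bixel <= 0)) ids_stop("bixel size must be > 0", "ids_value_error")
  structure(list(angles = as.numeric(angles), sad = sad,
                 isocenter = isocenter, bixel = as.numeric(bixel)),
            class = "ids_beams")
}

#' Analytic pencil-beam kernel parameters
#'
#' The body is treated as homogeneous water of unit density. A bixel's
#' dose per unit weight at a voxel is
#' `exp(-mu * depth) * lat(u) * lat(z)` where `depth` is the radiological
#' depth along the (parallel) ray and `lat` is a finite-bixel lateral
#' profile built from error-function edges with penumbra width `sigma`.
#' Entries below `threshold` times the bixel's maximum are dropped from
#' the sparse operator.
#'
#' @param mu linear attenuation coefficient, 1/mm
#' @param sigma lateral penumbra width, mm
#' @param threshold relative sparsity cutoff per bixel column
#' @param march_step ray-march sampling step for radiological depth, mm
#' @export
kernel_params <- function(mu = 0.005, sigma = 3, threshold = 1e-4,
                          march_step = 2) {
  structure(list(mu = mu, sigma = sigma, threshold = threshold,
                 march_step = march_step), class = "ids_kernel")
}

beam_basis <- function(angle_deg) {
  g <- angle_deg * pi / 180
  list(dir = c(sin(g), cos(g), 0),   # direction of beam travel
       b1 = c(cos(g), -sin(g), 0),   # lateral (column) axis
       b2 = c(0, 0, 1))              # row axis (leaf pairs)
}

# erf-edge lateral profile of a finite bixel of width w centered at 0
lateral_profile <- function(d, w, sigma) {
  pnorm((d + w / 2) / sigma) - pnorm((d - w / 2) / sigma)
}

#' Build the sparse dose-influence operator
#'
#' Computes, for every bixel b and voxel i of the body, the dose per unit
#' fluence weight `D[i, b]`. Rows span the full voxel grid (voxels outside
#' the body have empty rows); columns are bixels on a per-beam rectangular
#' lattice covering the body's beam's-eye-view projection. The transpose
#' is kept alongside for fast row (voxel) access during dose shaping.
#'
#' @param grid an `ids_grid`
#' @param body body `ids_voi` (non-empty)
#' @param beams an [beam_set()]; a `NULL` isocenter defaults to the body
#'   centroid
#' @param kernel an [kernel_params()]
#' @return an `ids_influence` with elements `D` (dgCMatrix, voxels x
#'   bixels), `Dt` (its transpose), `bixels` (data.frame: beam, k, m,
#'   colid), `lattice` (per-beam k/m ranges), `grid`, `beams`, `kernel`
#' @export
build_influence <- function(grid, body, beams, kernel = kernel_params()) {
  bm <- if (inherits(body, "ids_voi")) body$mask else body
  bidx <- which(bm)
  if (length(bidx) == 0L) ids_stop("body mask is empty", "ids_geometry_error")
  iso <- beams$isocenter
  if (is.null(iso)) iso <- colMeans(voxel_centers(grid, bidx))
  P <- voxel_centers(grid, bidx)
  wx <- beams$bixel[1]; wz <- beams$bixel[2]
  nvox <- n_voxels(grid)
  half <- 3L  # lateral half-window in bixels; beyond this the profile is
              # far below the sparsity threshold
  mats <- list(); lattice <- list(); bixrows <- list()
  for (bi in seq_along(beams$angles)) {
    bb <- beam_basis(beams$angles[bi])
    rel <- sweep(P, 2, iso)
    u <- as.vector(rel %*% bb$b1)
    z <- as.vector(rel %*% bb$b2)
    depth <- ray_depth_cpp(as.vector(bm), grid$dims, grid$spacing,
                           grid$origin, bb$dir, bidx, kernel$march_step)
    atten <- exp(-kernel$mu * depth)
    k0 <- floor(u / wx); m0 <- floor(z / wz)
    kmin <- min(k0) - half; kmax <- max(k0) + half
    mmin <- min(m0) - half; mmax <- max(m0) + half
    nk <- kmax - kmin + 1L; nm <- mmax - mmin + 1L
    offs <- seq(-half, half)
    Lx <- vapply(offs, function(o)
      lateral_profile(u - (k0 + o + 0.5) * wx, wx, kernel$sigma),
      numeric(length(u)))
    Lz <- vapply(offs, function(o)
      lateral_profile(z - (m0 + o + 0.5) * wz, wz, kernel$sigma),
      numeric(length(z)))
    ti <- tj <- tx <- vector("list", length(offs)^2)
    q <- 0L
    for (ox in seq_along(offs)) for (oz in seq_along(offs)) {
      val <- atten * Lx[, ox] * Lz[, oz]
      keep <- val > 0
      if (!any(keep)) next
      q <- q + 1L
      col <- (k0[keep] + offs[ox] - kmin) + nk * (m0[keep] + offs[oz] - mmin) + 1
      ti[[q]] <- bidx[keep]; tj[[q]] <- col; tx[[q]] <- val[keep]
    }
    M <- sparseMatrix(i = unlist(ti[seq_len(q)]), j = unlist(tj[seq_len(q)]),
                      x = unlist(tx[seq_len(q)]), dims = c(nvox, nk * nm))
    # per-column relative threshold
    nc <- ncol(M)
    colent <- rep.int(seq_len(nc), diff(M@p))
    if (length(M@x)) {
      cm <- rep(0, nc)
      agg <- tapply(M@x, colent, max)
      cm[as.integer(names(agg))] <- agg
      keep <- M@x >= kernel$threshold * cm[colent]
      M <- sparseMatrix(i = M@i[keep] + 1L, j = colent[keep], x = M@x[keep],
                        dims = c(nvox, nc))
    }
    mats[[bi]] <- M
    lattice[[bi]] <- list(kmin = kmin, kmax = kmax, mmin = mmin, mmax = mmax,
                          nk = nk, nm = nm)
    ks <- rep(kmin:kmax, times = nm); ms <- rep(mmin:mmax, each = nk)
    bixrows[[bi]] <- data.frame(beam = bi, k = ks, m = ms)
  }
  D <- do.call(cbind, mats)
  bixels <- do.call(rbind, bixrows)
  bixels$colid <- seq_len(nrow(bixels))
  structure(list(D = D, Dt = Matrix::t(D), bixels = bixels,
                 lattice = lattice, grid = grid, beams = beams,
                 kernel = kernel, isocenter = iso),
            class = "ids_influence")
}

#' @export
print.ids_influence <- function(x, ...) {
  cat(sprintf("dose-influence operator: %d voxels x %d bixels (%d beams), %d nonzeros\n",
              nrow(x$D), ncol(x$D), length(x$beams$angles), length(x$D@x)))
  invisible(x)
}

n_bixels <- function(infl) ncol(infl$D)

#' Influence row of a voxel
#'
#' Sparse row `D[v, ]`: the bixels that irradiate voxel `v` and their dose
#' per unit weight.
#'
#' @param infl an `ids_influence`
#' @param v 1-based linear voxel index
#' @return `list(bixels = column indices, a = values)`
#' @export
influence_row <- function(infl, v) {
  p <- infl$Dt@p
  j <- seq.int(p[v] + 1L, length.out = p[v + 1L] - p[v])
  list(bixels = infl$Dt@i[j] + 1L, a = infl$Dt@x[j])
}

#' Wrap a dense influence matrix as an `ids_influence` (toy problems)
#'
#' Convenience constructor used for small hand-built problems and oracle
#' tests: rows are voxels of `grid`, columns bixels of a single notional
#' beam.
#'
#' @param M numeric matrix or dgCMatrix (voxels x bixels)
#' @param grid an `ids_grid` with `prod(dims) == nrow(M)`
#' @return an `ids_influence`
#' @export
influence_from_matrix <- function(M, grid) {
  stopifnot(nrow(M) == n_voxels(grid))
  D <- methods::as(methods::as(methods::as(M, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  bix <- data.frame(beam = 1L, k = seq_len(ncol(D)) - 1L, m = 0L,
                    colid = seq_len(ncol(D)))
  structure(list(D = D, Dt = Matrix::t(D), bixels = bix,
                 lattice = list(list(kmin = 0L, kmax = ncol(D) - 1L,
                                     mmin = 0L, mmax = 0L,
                                     nk = ncol(D), nm = 1L)),
                 grid = grid, beams = NULL, kernel = NULL, isocenter = NULL),
            class = "ids_influence")
}

#' Compute dose from a fluence vector
#'
#' `dose = D %*% w`, linear in `w`. The result is a numeric vector over
#' the full voxel grid (zero outside the body).
#'
#' @param infl an `ids_influence`
#' @param w fluence weights, one per bixel, all >= 0
#' @return numeric vector of per-voxel dose
#' @export
compute_dose <- function(infl, w) {
  if (length(w) != n_bixels(infl))
    ids_stop("fluence length does not match the bixel count", "ids_shape_error")
  if (any(w < 0)) ids_stop("fluence weights must be >= 0", "ids_value_error")
  as.vector(infl$D %*% w)
}

#' Incremental dose update for a sparse fluence change
#'
#' Adds `sum_k D[, bixels[k]] * delta[k]` to `dose`, touching only the
#' voxels influenced by the changed bixels. Equivalent (to rounding) to a
#' full recomputation with the updated weights, but at the cost of the
#' patch's sparse columns only — the fast-update contract that makes
#' per-voxel dose shaping interactive.
#'
#' @param infl an `ids_influence`
#' @param dose current per-voxel dose vector
#' @param bixels column indices with nonzero change
#' @param delta weight changes, same length as `bixels`
#' @param w current fluence weights; when supplied, a change driving any
#'   weight negative is an error
#' @return updated dose vector
#' @export
incremental_dose <- function(infl, dose, bixels, delta, w = NULL) {
  stopifnot(length(bixels) == length(delta))
  if (!is.null(w) && any(w[bixels] + delta < -1e-12))
    ids_stop("fluence change drives a weight negative", "ids_value_error")
  if (length(bixels) == 0L) return(dose)
  csc_axpy_cpp(infl$D@p, infl$D@i, infl$D@x,
               as.integer(bixels), as.numeric(delta), dose)
}

#' Open-field fluence for a target
#'
#' Weight 1 on every bixel whose (parallel) ray passes within half a
#' bixel, per axis, of the target dilated by `margin`; 0 elsewhere. This
#' is the initialization the shaping workflow starts from.
#'
#' @param infl an `ids_influence` (carries beams and bixel lattice)
#' @param target target `ids_voi` or logical mask, non-empty
#' @param margin isotropic beam's-eye-view margin, mm
#' @return fluence weight vector (0/1) over all bixels
#' @export
open_field <- function(infl, target, margin = 0) {
  tm <- if (inherits(target, "ids_voi")) target$mask else target
  tidx <- which(tm)
  if (length(tidx) == 0L) ids_stop("target mask is empty", "ids_geometry_error")
  P <- voxel_centers(infl$grid, tidx)
  wx <- infl$beams$bixel[1]; wz <- infl$beams$bixel[2]
  w <- numeric(n_bixels(infl))
  off <- 0L
  for (bi in seq_along(infl$beams$angles)) {
    bb <- beam_basis(infl$beams$angles[bi])
    rel <- sweep(P, 2, infl$isocenter)
    u <- as.vector(rel %*% bb$b1)
    z <- as.vector(rel %*% bb$b2)
    lat <- infl$lattice[[bi]]
    klo <- pmax(ceiling((u - wx / 2 - margin) / wx - 0.5), lat$kmin)
    khi <- pmin(floor((u + wx / 2 + margin) / wx - 0.5), lat$kmax)
    mlo <- pmax(ceiling((z - wz / 2 - margin) / wz - 0.5), lat$mmin)
    mhi <- pmin(floor((z + wz / 2 + margin) / wz - 0.5), lat$mmax)
    act <- matrix(FALSE, lat$nk, lat$nm)
    for (q in which(klo <= khi & mlo <= mhi)) {
      act[(klo[q]:khi[q]) - lat$kmin + 1L, (mlo[q]:mhi[q]) - lat$mmin + 1L] <- TRUE
    }
    w[off + which(act)] <- 1
    off <- off + lat$nk * lat$nm
  }
  w
}

#' Per-beam fluence matrices
#'
#' Reshape a fluence weight vector into one matrix per beam (rows = MLC
#' leaf-pair rows, columns = lateral bixel columns).
#'
#' @param infl an `ids_influence`
#' @param w fluence weight vector
#' @return list of matrices, one per beam
#' @export
fluence_maps <- function(infl, w) {
  out <- list(); off <- 0L
  for (bi in seq_along(infl$lattice)) {
    lat <- infl$lattice[[bi]]
    out[[bi]] <- matrix(w[off + seq_len(lat$nk * lat$nm)], lat$nk, lat$nm)
    off <- off + lat$nk * lat$nm
  }
  out
}

#' Flatten per-beam fluence matrices back to a weight vector
#' @param maps list of per-beam matrices as from [fluence_maps()]
#' @return numeric weight vector
#' @export
fluence_from_maps <- function(maps) unlist(lapply(maps, as.vector), use.names = FALSE)

#' Persist a dose-influence operator (binary sparse container + JSON sidecar)
#'
#' @param infl an `ids_influence`
#' @param path basename; writes `<path>.bin` and `<path>.json`
#' @return `path`, invisibly
#' @export
save_influence <- function(infl, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(c(nrow(infl$D), ncol(infl$D), length(infl$D@x)), con, size = 8)
  writeBin(infl$D@p, con, size = 4, endian = "little")
  writeBin(infl$D@i, con, size = 4, endian = "little")
  writeBin(infl$D@x, con, size = 8, endian = "little")
  side <- list(dims = infl$grid$dims, spacing = infl$grid$spacing,
               origin = infl$grid$origin,
               angles = infl$beams$angles, sad = infl$beams$sad,
               bixel = infl$beams$bixel, isocenter = infl$isocenter,
               kernel = unclass(infl$kernel),
               lattice = infl$lattice)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a dose-influence operator saved by [save_influence()]
#' @param path basename used at save time
#' @return an `ids_influence`
#' @export
load_influence <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 3, size = 8)
  p <- readBin(con, "integer", hdr[2] + 1, size = 4, endian = "little")
  i <- readBin(con, "integer", hdr[3], size = 4, endian = "little")
  x <- readBin(con, "double", hdr[3], size = 8, endian = "little")
  D <- sparseMatrix(i = i + 1L, p = p, x = x, dims = hdr[1:2])
  grid <- voxel_grid(side$dims, side$spacing, side$origin)
  beams <- beam_set(side$angles, side$sad, side$isocenter, side$bixel)
  latdf <- side$lattice  # simplified to a data.frame by jsonlite
  lattice <- lapply(seq_len(nrow(latdf)), function(i)
    lapply(as.list(latdf[i, ]), as.integer))
  nk <- vapply(lattice, function(l) l$nk, integer(1))
  nm <- vapply(lattice, function(l) l$nm, integer(1))
  bixrows <- lapply(seq_along(lattice), function(bi) {
    l <- lattice[[bi]]
    data.frame(beam = bi, k = rep(l$kmin:l$kmax, times = l$nm),
               m = rep(l$mmin:l$mmax, each = l$nk))
  })
  bixels <- do.call(rbind, bixrows)
  bixels$colid <- seq_len(nrow(bixels))
  structure(list(D = D, Dt = Matrix::t(D), bixels = bixels,
                 lattice = lattice, grid = grid, beams = beams,
                 kernel = do.call(kernel_params, side$kernel),
                 isocenter = side$isocenter),
            class = "ids_influence")
}
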