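#' Voxel grid
#'
#' A regular 3D voxel grid. The axis convention throughout the package is
#' x = left-right, y = anterior-posterior (+y posterior), z =
#' inferior-superior (+z superior). Linear voxel indices are column-major
#' over (x, y, z); the center of voxel (i, j, k) (1-based) lies at
#' `origin + (c(i, j, k) - 0.5) * spacing` in mm.
#'
#' @param dims integer triple (nx, ny, nz), all >= 1
#' @param spacing mm triple, all > 0
#' @param origin mm triple of the grid corner (default 0)
#' @return an object of class `ids_grid`
#' @export
voxel_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(dims < 1L)) ids_stop("all grid dims must be >= 1", "ids_geometry_error")
  if (any(spacing <= 0)) ids_stop("all spacings must be > 0", "ids_geometry_error")
  structure(list(dims = dims, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ids_grid")
}

#' @export
print.ids_grid <- function(x, ...) {
  cat(sprintf("voxel grid %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param grid an `ids_grid`
#' @return scalar mm^3
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

n_voxels <- function(grid) prod(grid$dims)

#' Physical centers of voxels
#'
#' @param grid an `ids_grid`
#' @param idx 1-based linear voxel indices (default all)
#' @return numeric matrix with columns x, y, z in mm
#' @export
voxel_centers <- function(grid, idx = seq_len(n_voxels(grid))) {
  d <- grid$dims
  i0 <- idx - 1L
  ix <- i0 %% d[1]
  iy <- (i0 %/% d[1]) %% d[2]
  iz <- i0 %/% (d[1] * d[2])
  cbind(x = grid$origin[1] + (ix + 0.5) * grid$spacing[1],
        y = grid$origin[2] + (iy + 0.5) * grid$spacing[2],
        z = grid$origin[3] + (iz + 0.5) * grid$spacing[3])
}

#' Volume of interest
#'
#' @param name label
#' @param role one of "body", "target", "boost", "oar"
#' @param mask logical array with the grid dims
#' @return an `ids_voi`
#' @export
voi <- function(name, role, mask) {
  role <- match.arg(role, c("body", "target", "boost", "oar"))
  stopifnot(is.logical(mask))
  structure(list(name = name, role = role, mask = mask), class = "ids_voi")
}

#' @export
print.ids_voi <- function(x, ...) {
  cat(sprintf("VOI '%s' (%s): %d voxels\n", x$name, x$role, sum(x$mask)))
  invisible(x)
}

#' Per-structure dose prescription
#'
#' Boost and PTV prescriptions are mandatory; the boost (simultaneous
#' integrated boost volume) prescription must not be below the PTV one.
#'
#' @param boost prescribed boost dose, Gy
#' @param ptv prescribed PTV dose, Gy
#' @return an `ids_prescription`
#' @export
prescription <- function(boost = 76, ptv = 73) {
  if (!(boost > 0 && ptv > 0)) ids_stop("prescriptions must be > 0", "ids_value_error")
  if (boost < ptv) ids_stop("boost prescription must be >= PTV prescription",
                            "ids_value_error")
  structure(list(boost = boost, ptv = ptv), class = "ids_prescription")
}

#' Synthetic pelvic phantom specification
#'
#' Defines a seeded generator for a prostate-like geometry: a body
#' contour, a PTV with an interior simultaneous integrated boost volume,
#' a rectum posterior of the PTV and a bladder anterior/superior of it.
#' Organs are jittered superellipsoids; the jitter (organ centers and
#' radii) is drawn from a generator seeded by `seed` only, so the same
#' spec always yields voxel-identical masks.
#'
#' @param seed integer seed controlling all shape jitter
#' @param preset `"test"` (64 x 64 x 48 at 4 mm isotropic) or
#'   `"clinical"` (256 x 256 x 160 at 1.95 x 1.95 x 2.0 mm)
#' @param dims,spacing optional overrides of the preset grid
#' @param organs optional named list overriding per-organ geometry; each
#'   entry is `list(center = mm-offset-from-grid-center, radii = mm,
#'   power = superellipsoid exponent)`
#' @param jitter_mm amplitude (mm) of the uniform jitter applied to organ
#'   centers and radii
#' @param rx an [prescription()] (default boost 76 Gy / PTV 73 Gy)
#' @return an `ids_phantom_spec`
#' @export
phantom_spec <- function(seed = 1L, preset = c("test", "clinical"),
                         dims = NULL, spacing = NULL, organs = NULL,
                         jitter_mm = 3, rx = prescription()) {
  preset <- match.arg(preset)
  if (is.null(dims))
    dims <- if (preset == "test") c(64L, 64L, 48L) else c(256L, 256L, 160L)
  if (is.null(spacing))
    spacing <- if (preset == "test") c(4, 4, 4) else c(1.95, 1.95, 2.0)
  base <- list(
    body    = list(center = c(0, 0, 0),    radii = c(110, 85, 86), power = 2.5),
    ptv     = list(center = c(0, 8, 0),    radii = c(34, 28, 30),  power = 2),
    boost   = list(center = c(0, 4, 0),    radii = c(20, 16, 18),  power = 2),
    rectum  = list(center = c(0, 48, -5),  radii = c(16, 16, 50),  power = 2),
    bladder = list(center = c(0, -38, 18), radii = c(34, 30, 28),  power = 2)
  )
  if (preset == "clinical") base$body$radii <- c(115, 90, 150)
  for (nm in names(organs)) base[[nm]] <- utils::modifyList(base[[nm]], organs[[nm]])
  structure(list(seed = as.integer(seed), dims = as.integer(dims),
                 spacing = as.numeric(spacing), organs = base,
                 jitter_mm = jitter_mm, rx = rx),
            class = "ids_phantom_spec")
}

superellipsoid_mask <- function(grid, center, radii, power = 2) {
  d <- grid$dims
  cx <- grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(d[2]) - 0.5) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(d[3]) - 0.5) * grid$spacing[3]
  fx <- abs((cx - center[1]) / radii[1])^power
  fy <- abs((cy - center[2]) / radii[2])^power
  fz <- abs((cz - center[3]) / radii[3])^power
  v <- outer(outer(fx, fy, "+"), fz, "+")
  array(v <= 1, dim = d)
}

#' Generate a synthetic pelvic phantom
#'
#' Deterministic for a fixed spec: the jitter generator is seeded from
#' `spec$seed` and the caller's RNG state is left untouched. The returned
#' masks satisfy boost which is a subset of PTV which is a subset of body, and
#' rectum/bladder disjoint from the PTV, by construction (containment is
#' enforced by mask intersection/subtraction after jitter).
#'
#' @param spec an [phantom_spec()]
#' @return `list(grid, vois, rx)` where `vois` is a named list of
#'   `ids_voi` (body, ptv, boost, rectum, bladder)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "ids_phantom_spec"))
  grid <- voxel_grid(spec$dims, spec$spacing)
  gcen <- grid$origin + grid$dims * grid$spacing / 2
  ext_lo <- grid$origin
  ext_hi <- grid$origin + grid$dims * grid$spacing

  # jitter under a private RNG stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)

  a <- spec$jitter_mm
  geo <- lapply(spec$organs, function(o) {
    o$center <- gcen + o$center + runif(3, -a, a)
    o$radii <- pmax(o$radii + runif(3, -a, a), 1)
    o
  })
  for (nm in names(geo)) {
    o <- geo[[nm]]
    if (any(o$center - o$radii < ext_lo) || any(o$center + o$radii > ext_hi))
      ids_stop(sprintf("organ '%s' radii exceed the grid extent", nm),
               "ids_geometry_error")
  }

  m <- lapply(geo, function(o) superellipsoid_mask(grid, o$center, o$radii, o$power))
  m$ptv <- m$ptv & m$body
  m$boost <- m$boost & m$ptv
  m$rectum <- m$rectum & m$body & !m$ptv
  m$bladder <- m$bladder & m$body & !m$ptv

  vois <- list(
    body    = voi("body", "body", m$body),
    ptv     = voi("ptv", "target", m$ptv),
    boost   = voi("boost", "boost", m$boost),
    rectum  = voi("rectum", "oar", m$rectum),
    bladder = voi("bladder", "oar", m$bladder)
  )
  list(grid = grid, vois = vois, rx = spec$rx)
}

#' Non-tumor mask (body minus PTV)
#'
#' @param body,ptv `ids_voi` objects on the same grid
#' @return logical array `body & !ptv`
#' @export
nontumor_mask <- function(body, ptv) {
  bm <- if (inherits(body, "ids_voi")) body$mask else body
  pm <- if (inherits(ptv, "ids_voi")) ptv$mask else ptv
  if (!identical(dim(bm), dim(pm)))
    ids_stop("body and PTV masks have different shapes", "ids_shape_error")
  bm & !pm
}
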