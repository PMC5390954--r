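# Minimal NRRD volume I/O for masks and dose grids.
# Supports 3D volumes, types uchar/double, encodings text and raw
# (little-endian). The header carries spacings and origin so that a
# round trip preserves the grid geometry.

#' Write a 3D volume as NRRD
#'
#' @param x logical or numeric array (3D)
#' @param path output file
#' @param grid an `ids_grid` supplying spacings/origin
#' @param encoding "text" (portable, for small fixtures) or "raw"
#' @return `path`, invisibly
#' @export
write_nrrd <- function(x, path, grid, encoding = c("text", "raw")) {
  encoding <- match.arg(encoding)
  stopifnot(length(dim(x)) == 3)
  is_mask <- is.logical(x)
  type <- if (is_mask) "unsigned char" else "double"
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(x), collapse = " ")),
    paste0("spacings: ", paste(sprintf("%.17g", grid$spacing), collapse = " ")),
    paste0("axis mins: ", paste(sprintf("%.17g", grid$origin), collapse = " ")),
    paste0("encoding: ", encoding),
    if (encoding == "raw") "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "text") {
    vals <- if (is_mask) as.integer(x) else as.numeric(x)
    fmt <- if (is_mask) "%d" else "%.17g"
    writeLines(paste(sprintf(fmt, vals), collapse = " "), con)
  } else {
    if (is_mask) writeBin(as.raw(as.integer(x)), con)
    else writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a NRRD volume written by [write_nrrd()]
#'
#' @param path NRRD file
#' @return `list(data = array, grid = ids_grid)`; uchar volumes come back
#'   as logical masks
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD"))
    ids_stop(sprintf("'%s' is not a NRRD file", path), "ids_io_error")
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    fields[[kv[1]]] <- kv[2]
  }
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
  spacing <- as.numeric(strsplit(fields$spacings, " ")[[1]])
  origin <- if (!is.null(fields[["axis mins"]]))
    as.numeric(strsplit(fields[["axis mins"]], " ")[[1]]) else c(0, 0, 0)
  n <- prod(sizes)
  type <- fields$type
  if (fields$encoding == "text") {
    txt <- readLines(con)
    vals <- as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
    vals <- vals[!is.na(vals)]
  } else {
    vals <- if (type == "unsigned char") as.numeric(readBin(con, "raw", n))
            else readBin(con, "double", n, size = 8, endian = "little")
  }
  if (length(vals) != n)
    ids_stop("NRRD payload size does not match the header sizes", "ids_io_error")
  data <- array(vals, dim = sizes)
  if (type == "unsigned char") data <- array(data != 0, dim = sizes)
  list(data = data, grid = voxel_grid(sizes, spacing, origin))
}
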