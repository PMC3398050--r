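#' Gridded habitat surfaces
#'
#' A `value_grid` holds per-cell absolute habitat value V on a regular
#' toroidal raster (opposite edges adjacent); a `resource_grid` holds the
#' per-cell amount of one habitat resource (e.g. shrub cover, late-decay
#' downed woody debris, shade, substrate). Both are thin S3 wrappers around
#' a numeric matrix plus the cell resolution in metres.
#'
#' @param values numeric matrix of cell values (finite; resources must be
#'   non-negative).
#' @param resolution cell edge length in metres (default 15).
#' @param baseline the constant subtracted when the grid was derived from
#'   summed resource values (the lowest-value local habitat in the
#'   calibration data); 0 for grids supplied directly.
#' @param name resource identifier, e.g. `"shrub"`, `"dwd"`, `"shade"`,
#'   `"substrate"`.
#' @return An object of class `value_grid` or `resource_grid`.
#' @examples
#' g <- value_grid(matrix(runif(49), 7, 7))
#' dim(as.matrix(g))
#' @export
value_grid <- function(values, resolution = 15, baseline = 0) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be a numeric matrix with finite entries")
  stopifnot_scalar(resolution, "resolution")
  stopifnot_scalar(baseline, "baseline")
  structure(list(values = values, resolution = resolution, baseline = baseline),
            class = "value_grid")
}

#' @rdname value_grid
#' @export
resource_grid <- function(name, values, resolution = 15) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0))
    stop("resource amounts must be finite and non-negative")
  stopifnot_scalar(resolution, "resolution")
  structure(list(name = as.character(name), values = values,
                 resolution = resolution),
            class = "resource_grid")
}

#' @export
as.matrix.value_grid <- function(x, ...) x$values

#' @export
as.matrix.resource_grid <- function(x, ...) x$values

#' @export
print.value_grid <- function(x, ...) {
  cat(sprintf("<value_grid> %d x %d cells @ %g m (baseline %.4g)\n",
              nrow(x$values), ncol(x$values), x$resolution, x$baseline))
  cat(sprintf("  cell value: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.resource_grid <- function(x, ...) {
  cat(sprintf("<resource_grid '%s'> %d x %d cells @ %g m, mean %.3f\n",
              x$name, nrow(x$values), ncol(x$values), x$resolution,
              mean(x$values)))
  invisible(x)
}

#' Neighbourhood mean of a resource grid
#'
#' Replaces each cell by the mean of all cell centres within `radius`
#' metres (toroidal distance, the focal cell included). Used to aggregate
#' finely sampled habitat layers to the 15-m analysis grid, mirroring
#' field protocols that average measurements within 26 m of a trap
#' station.
#'
#' @param grid a [resource_grid()].
#' @param radius neighbourhood radius in metres (> 0); default 26.
#' @return A `resource_grid` of the same shape.
#' @export
local_mean <- function(grid, radius = 26) {
  if (!inherits(grid, "resource_grid")) stop("`grid` must be a resource_grid")
  stopifnot_scalar(radius, "radius")
  if (radius <= 0) stop("`radius` must be positive")
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  # offsets whose toroidal centre-to-centre distance is within the radius
  dr <- 0:(nr - 1); dc <- 0:(nc - 1)
  wr <- pmin(dr, nr - dr) * grid$resolution
  wc <- pmin(dc, nc - dc) * grid$resolution
  keep <- which(outer(wr^2, wc^2, "+") <= radius^2, arr.ind = TRUE)
  acc <- matrix(0, nr, nc)
  for (k in seq_len(nrow(keep))) {
    i <- keep[k, 1] - 1L; j <- keep[k, 2] - 1L
    acc <- acc + v[((seq_len(nr) - 1L + i) %% nr) + 1L,
                   ((seq_len(nc) - 1L + j) %% nc) + 1L, drop = FALSE]
  }
  resource_grid(grid$name, acc / nrow(keep), grid$resolution)
}

# ---- file formats ----------------------------------------------------------

#' Read and write grids
#'
#' Two plain-text formats are supported: a headerless matrix CSV, and the
#' ESRI ASCII grid format (`ncols`/`nrows`/`cellsize` header). For ESRI
#' grids the header `cellsize` must match `resolution` (default 15 m);
#' pass the file's cellsize explicitly to accept other resolutions.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"asc"`.
#' @param resolution expected cell size in metres.
#' @param baseline stored baseline for value grids read from file.
#' @param grid object to write.
#' @param name resource name to attach on read.
#' @return `read_value_grid()` / `read_resource_grid()` return grid
#'   objects; the writers return the path, invisibly.
#' @export
read_value_grid <- function(path, format = c("auto", "csv", "asc"),
                            resolution = 15, baseline = 0) {
  m <- read_grid_matrix(path, match.arg(format), resolution)
  value_grid(m, resolution, baseline)
}

#' @rdname read_value_grid
#' @export
read_resource_grid <- function(path, name, format = c("auto", "csv", "asc"),
                               resolution = 15) {
  m <- read_grid_matrix(path, match.arg(format), resolution)
  resource_grid(name, m, resolution)
}

#' @rdname read_value_grid
#' @export
write_grid <- function(grid, path, format = c("auto", "csv", "asc")) {
  m <- as.matrix(grid)
  format <- match.arg(format)
  if (format == "auto") format <- guess_grid_format(path)
  if (format == "csv") {
    write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    res <- if (is.list(grid) && !is.null(grid$resolution)) grid$resolution else 15
    hdr <- c(sprintf("ncols %d", ncol(m)),
             sprintf("nrows %d", nrow(m)),
             "xllcorner 0", "yllcorner 0",
             sprintf("cellsize %g", res),
             "NODATA_value -9999")
    writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), path)
  }
  invisible(path)
}

guess_grid_format <- function(path) {
  if (grepl("\\.asc$", path, ignore.case = TRUE)) "asc" else "csv"
}

read_grid_matrix <- function(path, format, resolution) {
  if (format == "auto") format <- guess_grid_format(path)
  if (format == "csv") {
    m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  } else {
    lines <- readLines(path)
    is_hdr <- grepl("^[A-Za-z]", lines)
    hdr <- lines[is_hdr]
    kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
    keys <- tolower(kv[, 1]); vals <- as.numeric(kv[, 2])
    cellsize <- vals[match("cellsize", keys)]
    if (!is.na(cellsize) && abs(cellsize - resolution) > 1e-9)
      stop(sprintf(
        "grid cellsize is %g but resolution %g was expected; pass `resolution = %g` to override",
        cellsize, resolution, cellsize))
    body <- lines[!is_hdr & nzchar(trimws(lines))]
    m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
    nr <- vals[match("nrows", keys)]; nc <- vals[match("ncols", keys)]
    if (!is.na(nr) && !is.na(nc) && (nrow(m) != nr || ncol(m) != nc))
      stop("grid body does not match the declared nrows/ncols")
  }
  dimnames(m) <- NULL
  m
}
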