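#' Raster surface container
#'
#' A minimal in-memory raster: a numeric matrix of cell values on a regular
#' grid in projected coordinates. Row 1 is the northernmost row and cell
#' values are registered at cell centers, so the center of cell
#' `[r, c]` is at `x = origin[1] + (c - 0.5) * cell_size`,
#' `y = origin[2] + (nrow - r + 0.5) * cell_size` with `origin` the
#' lower-left corner of the grid. Missing cells are `NA`.
#'
#' @param values numeric matrix of cell values (`NA` = missing).
#' @param cell_size cell edge length in meters (> 0).
#' @param origin numeric length-2, projected x/y of the lower-left corner.
#' @param tag short name of the surface (e.g. `"dem"`, `"tri"`).
#' @return An object of class `raster_surface`.
#' @export
raster_surface <- function(values, cell_size = 100, origin = c(0, 0),
                           tag = "surface") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be two finite coordinates")
  structure(
    list(values = values, cell_size = cell_size,
         origin = as.numeric(origin), tag = as.character(tag)[1L]),
    class = "raster_surface"
  )
}

#' @export
print.raster_surface <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_surface '%s'> %d x %d cells, cell_size = %g m\n",
              x$tag, nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (lower-left): (%g, %g)\n", x$origin[1], x$origin[2]))
  ok <- is.finite(v)
  if (any(ok)) {
    cat(sprintf("  values: [%g, %g], %d missing\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  } else cat("  values: all missing\n")
  invisible(x)
}

#' @export
dim.raster_surface <- function(x) dim(x$values)

is_raster <- function(x) inherits(x, "raster_surface")

stopifnot_raster <- function(x) {
  if (!is_raster(x)) stop("expected a raster_surface object")
  invisible(x)
}

#' Cell-center coordinates of a raster
#'
#' @param r a [raster_surface()].
#' @param cells optional integer vector of cell indices (column-major, as in
#'   R matrix indexing); default all cells.
#' @return A two-column matrix of x/y cell-center coordinates.
#' @export
cell_centers <- function(r, cells = NULL) {
  stopifnot_raster(r)
  nr <- nrow(r$values)
  if (is.null(cells)) cells <- seq_len(length(r$values))
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cbind(x = r$origin[1] + (col - 0.5) * r$cell_size,
        y = r$origin[2] + (nr - row + 0.5) * r$cell_size)
}

#' Read / write rasters as ESRI ASCII grids
#'
#' Plain-text grid interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south.
#'
#' @param path file path.
#' @param tag surface name attached on read.
#' @return `read_ascii_grid` returns a [raster_surface()];
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, tag = "surface") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  if (!is.null(hdr$nodata_value))
    vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  raster_surface(m, cell_size = hdr$cellsize,
                 origin = c(hdr$xllcorner, hdr$yllcorner), tag = tag)
}

#' @rdname read_ascii_grid
#' @param r a [raster_surface()] to write.
#' @param nodata value used to encode missing cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot_raster(r)
  v <- r$values
  v[!is.finite(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2]),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  rows <- apply(v, 1L, function(z) paste(format(z, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
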