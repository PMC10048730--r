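# 8-neighbor shifts of a matrix, padding with NA
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

neighbor_offsets8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                           dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Terrain ruggedness index (TRI)
#'
#' Local elevation variability: for each cell, the square root of the sum of
#' squared elevation differences between the cell and its eight neighbors
#' (the Riley convention). Border cells (and cells next to missing data)
#' use the available neighbors only, rather than inventing elevations by
#' padding. A `"mean_abs"` variant (mean absolute difference to available
#' neighbors) is selectable.
#'
#' @param dem a [raster_surface()] digital elevation model, at least 3 x 3.
#' @param method `"riley"` (default) or `"mean_abs"`.
#' @return A [raster_surface()] tagged `"tri"`; non-negative everywhere.
#' @export
tri <- function(dem, method = c("riley", "mean_abs")) {
  method <- match.arg(method)
  stopifnot_raster(dem)
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) stop("DEM must be at least 3 x 3")
  if (!any(is.finite(z))) stop("DEM is entirely missing")
  acc <- matrix(0, nrow(z), ncol(z))
  cnt <- matrix(0L, nrow(z), ncol(z))
  for (k in seq_len(nrow(neighbor_offsets8))) {
    zn <- shift_matrix(z, neighbor_offsets8[k, 1], neighbor_offsets8[k, 2])
    d <- z - zn
    has <- is.finite(d)
    if (method == "riley") acc[has] <- acc[has] + d[has]^2
    else acc[has] <- acc[has] + abs(d[has])
    cnt <- cnt + has
  }
  out <- if (method == "riley") sqrt(acc) else acc / pmax(cnt, 1L)
  out[cnt == 0L | !is.finite(z)] <- NA_real_
  raster_surface(out, dem$cell_size, dem$origin, tag = "tri")
}

#' Topographic position index (TPI)
#'
#' Elevation of each cell relative to the mean of its eight neighbors:
#' positive on ridges, negative in valleys, near zero on flats and constant
#' slopes. Border cells use available neighbors.
#'
#' @inheritParams tri
#' @return A [raster_surface()] tagged `"tpi"`.
#' @export
tpi <- function(dem) {
  stopifnot_raster(dem)
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) stop("DEM must be at least 3 x 3")
  if (!any(is.finite(z))) stop("DEM is entirely missing")
  acc <- matrix(0, nrow(z), ncol(z))
  cnt <- matrix(0L, nrow(z), ncol(z))
  for (k in seq_len(nrow(neighbor_offsets8))) {
    zn <- shift_matrix(z, neighbor_offsets8[k, 1], neighbor_offsets8[k, 2])
    has <- is.finite(zn)
    acc[has] <- acc[has] + zn[has]
    cnt <- cnt + has
  }
  out <- z - acc / pmax(cnt, 1L)
  out[cnt == 0L | !is.finite(z)] <- NA_real_
  raster_surface(out, dem$cell_size, dem$origin, tag = "tpi")
}

#' Kernel density surface of point events
#'
#' Heat-map style kernel density estimate of point events (e.g. satellite
#' fire detections) on the grid of a template raster, using a quartic
#' (biweight) kernel truncated at `radius`:
#' `K(d) = 3 / (pi r^2) * (1 - (d/r)^2)^2` for `d < r`. Cells with no event
#' within `radius` are 0 (not missing), and the surface is linear in point
#' multiplicity. Events can carry a detection confidence used as an
#' inclusion filter.
#'
#' @param points matrix or data frame with columns `x`, `y` and optionally
#'   `confidence` (percent).
#' @param template a [raster_surface()] defining the output grid.
#' @param radius kernel truncation radius in meters (> 0).
#' @param min_confidence drop events with confidence below this value
#'   (default `NULL`: keep all).
#' @return A [raster_surface()] tagged `"density"`, in events per m^2.
#' @export
point_density <- function(points, template, radius, min_confidence = NULL) {
  stopifnot_raster(template)
  if (radius <= 0) stop("radius must be positive")
  pts <- as.data.frame(points)
  if (nrow(pts) && is.null(names(pts))) names(pts) <- c("x", "y")
  if (nrow(pts) && !all(c("x", "y") %in% names(pts)))
    names(pts)[1:2] <- c("x", "y")
  if (!is.null(min_confidence) && nrow(pts) && "confidence" %in% names(pts))
    pts <- pts[pts$confidence >= min_confidence, , drop = FALSE]
  ctr <- cell_centers(template)
  dens <- numeric(nrow(ctr))
  if (nrow(pts)) {
    for (p in seq_len(nrow(pts))) {
      d2 <- (ctr[, 1] - pts$x[p])^2 + (ctr[, 2] - pts$y[p])^2
      inside <- d2 < radius^2
      dens[inside] <- dens[inside] +
        3 / (pi * radius^2) * (1 - d2[inside] / radius^2)^2
    }
  }
  out <- matrix(dens, nrow = nrow(template$values))
  raster_surface(out, template$cell_size, template$origin, tag = "density")
}
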