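#' Resistance transformation families
#'
#' The eight parametric curves used to map a rescaled environmental surface
#' (values in `[0, 10]`) onto resistance, plus the degenerate `"Distance"`
#' family (a flat surface, i.e. a pure isolation-by-distance null).
#'
#' Base curves: Monomolecular `g(x) = 1 - exp(-x / shape)` and Ricker
#' `g(x) = x * exp(-x / shape)`. `"Reverse"` evaluates the base curve at
#' `10 - x`; `"Inverse"` reflects the curve vertically. After the curve is
#' evaluated, the surface is affinely rescaled so the minimum resistance is
#' 1 and the maximum is `maximum`.
#'
#' @param family one of `"Monomolecular"`, `"Reverse Monomolecular"`,
#'   `"Inverse Monomolecular"`, `"Inverse-Reverse Monomolecular"`,
#'   `"Ricker"`, `"Reverse Ricker"`, `"Inverse Ricker"`,
#'   `"Inverse-Reverse Ricker"`, or `"Distance"`.
#' @param shape positive shape parameter (ignored for `"Distance"`).
#' @param maximum maximum resistance, `> 1` (ignored for `"Distance"`).
#' @return A `transform_spec` object.
#' @export
transform_spec <- function(family, shape = NA_real_, maximum = NA_real_) {
  family <- match.arg(family, transform_families())
  if (family != "Distance") {
    if (!is.finite(shape) || shape <= 0) stop("shape must be positive")
    if (!is.finite(maximum) || maximum <= 1) stop("maximum must exceed 1")
  }
  structure(list(family = family, shape = as.numeric(shape),
                 maximum = as.numeric(maximum)),
            class = "transform_spec")
}

#' @rdname transform_spec
#' @export
transform_families <- function() {
  c("Monomolecular", "Reverse Monomolecular", "Inverse Monomolecular",
    "Inverse-Reverse Monomolecular", "Ricker", "Reverse Ricker",
    "Inverse Ricker", "Inverse-Reverse Ricker", "Distance")
}

#' @export
print.transform_spec <- function(x, ...) {
  if (x$family == "Distance") cat("<transform_spec> Distance (flat)\n")
  else cat(sprintf("<transform_spec> %s, shape = %.4g, maximum = %.4g\n",
                   x$family, x$shape, x$maximum))
  invisible(x)
}

#' Serialize / deserialize a transform spec as JSON
#'
#' @param spec a [transform_spec()]; `path` optional file.
#' @export
write_transform_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_spec
#' @export
read_transform_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_spec(x$family, x$shape, x$maximum)
}

#' Rescale a continuous surface onto [0, 10]
#'
#' Affine map of the observed values onto `[0, 10]`, the domain expected by
#' [apply_transform()]. Missing cells are preserved.
#'
#' @param surface a [raster_surface()] with at least two distinct values.
#' @return A [raster_surface()].
#' @export
rescale_surface <- function(surface) {
  stopifnot_raster(surface)
  v <- surface$values
  ok <- is.finite(v)
  rng <- range(v[ok])
  if (diff(rng) == 0)
    stop("constant surface: transformation is unidentifiable")
  out <- (v - rng[1]) / diff(rng) * 10
  raster_surface(out, surface$cell_size, surface$origin,
                 tag = paste0(surface$tag, "_rescaled"))
}

# base curve value on [0, 10] before min/max anchoring; sign conveys
# 'Inverse' (vertical reflection is equivalent to negation up to the final
# affine rescale)
transform_curve <- function(x, family, shape) {
  rev_ <- grepl("Reverse", family)
  inv <- grepl("Inverse", family)
  xx <- if (rev_) 10 - x else x
  g <- if (grepl("Monomolecular", family)) 1 - exp(-xx / shape)
       else xx * exp(-xx / shape)
  if (inv) -g else g
}

#' Apply a resistance transformation to a rescaled surface
#'
#' Evaluates the family curve of `spec` on the surface (values must lie in
#' `[0, 10]`, see [rescale_surface()]) and rescales the result affinely so
#' the minimum resistance is exactly 1 and the maximum is `spec$maximum`.
#' The `"Distance"` family yields a flat surface of 1s.
#'
#' @param surface a rescaled [raster_surface()].
#' @param spec a [transform_spec()].
#' @return A [raster_surface()] of resistances in `[1, spec$maximum]`.
#' @export
apply_transform <- function(surface, spec) {
  stopifnot_raster(surface)
  if (!inherits(spec, "transform_spec")) stop("spec must be a transform_spec")
  v <- surface$values
  ok <- is.finite(v)
  if (any(v[ok] < -1e-8 | v[ok] > 10 + 1e-8))
    stop("surface values must lie in [0, 10]; call rescale_surface() first")
  out <- v
  if (spec$family == "Distance") {
    out[ok] <- 1
  } else {
    gv <- transform_curve(pmin(pmax(v[ok], 0), 10), spec$family, spec$shape)
    rng <- range(gv)
    if (diff(rng) < 1e-12) {
      out[ok] <- 1
    } else {
      out[ok] <- 1 + (spec$maximum - 1) * (gv - rng[1]) / diff(rng)
    }
  }
  raster_surface(out, surface$cell_size, surface$origin,
                 tag = paste0(surface$tag, "_resistance"))
}

#' Categorical resistance assignment
#'
#' Resistance values for the classes of a categorical surface, with exactly
#' one reference class fixed at 1 and all values in `(0, bound]`.
#'
#' @param values named numeric vector of per-class resistances; at least
#'   one must equal 1 (the reference class held constant).
#' @param bound upper limit for any class value (5000 for single surfaces,
#'   10000 within composites).
#' @return A `categorical_assignment` object.
#' @export
categorical_assignment <- function(values, bound = 5000) {
  if (is.null(names(values)) || any(names(values) == ""))
    stop("values must be a fully named vector")
  if (!any(values == 1))
    stop("a reference class with resistance 1 is required")
  if (any(values <= 0 | values > bound))
    stop("class resistances must lie in (0, bound]")
  structure(list(values = values, bound = bound),
            class = "categorical_assignment")
}

#' Apply a categorical assignment to a labeled surface
#'
#' @param surface a [raster_surface()] whose values are class codes; class
#'   labels are taken from a `levels` attribute on the raster (set by
#'   [make_landscape()]) or from the codes themselves.
#' @param assignment a [categorical_assignment()] covering every class
#'   present.
#' @return A [raster_surface()] of resistances.
#' @export
apply_categorical <- function(surface, assignment) {
  stopifnot_raster(surface)
  if (!inherits(assignment, "categorical_assignment"))
    stop("assignment must be a categorical_assignment")
  v <- surface$values
  lev <- attr(surface, "levels")
  key <- if (!is.null(lev)) lev[as.integer(v)] else as.character(v)
  present <- unique(stats::na.omit(key))
  missing_classes <- setdiff(present, names(assignment$values))
  if (length(missing_classes))
    stop("no resistance assigned for class(es): ",
         paste(missing_classes, collapse = ", "))
  out <- matrix(assignment$values[key], nrow = nrow(v))
  out[!is.finite(v)] <- NA_real_
  raster_surface(out, surface$cell_size, surface$origin,
                 tag = paste0(surface$tag, "_resistance"))
}

#' Combine resistance surfaces into a composite
#'
#' Cell-wise sum of the component resistances (resistances are additive
#' costs), then shifted so the composite minimum is exactly 1.
#'
#' @param surfaces list of aligned resistance [raster_surface()] objects.
#' @return A [raster_surface()] tagged `"composite"`.
#' @export
combine_surfaces <- function(surfaces) {
  if (!length(surfaces)) stop("no surfaces to combine")
  lapply(surfaces, stopifnot_raster)
  dims <- vapply(surfaces, function(s) dim(s$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("surfaces are not aligned (differing grids)")
  acc <- Reduce(`+`, lapply(surfaces, function(s) s$values))
  ok <- is.finite(acc)
  acc[ok] <- acc[ok] - min(acc[ok]) + 1
  raster_surface(acc, surfaces[[1]]$cell_size, surfaces[[1]]$origin,
                 tag = "composite")
}

#' Percent contribution of composite components
#'
#' Share of each transformed component in the composite, measured as the
#' range of its transformed values relative to the summed ranges. A
#' component transformed to (near) `"Distance"` contributes ~0.
#'
#' @param surfaces list of transformed component [raster_surface()]s.
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_contribution <- function(surfaces) {
  rngs <- vapply(surfaces, function(s) {
    v <- s$values[is.finite(s$values)]
    diff(range(v))
  }, numeric(1))
  nm <- names(surfaces)
  if (is.null(nm)) nm <- vapply(surfaces, function(s) s$tag, character(1))
  stats::setNames(100 * rngs / sum(rngs), nm)
}
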