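#' Pairwise (dyadic) matrix container
#'
#' A symmetric matrix of dyadic values among named individuals or nodes,
#' tagged with the metric it holds. The diagonal is `NA` by convention:
#' self-pairs are undefined for every metric used here.
#'
#' @param values square numeric matrix (symmetric up to numerical noise).
#' @param ids character vector of labels; defaults to existing dimnames.
#' @param metric one of `"relatedness_r"`, `"rousset_ar"`, `"dps"`,
#'   `"commute"`, `"euclidean"`, `"resistance"`.
#' @return A matrix of class `pairwise_matrix` with a `metric` attribute.
#' @export
pairwise_matrix <- function(values,
                           ids = NULL,
                           metric = c("relatedness_r", "rousset_ar", "dps",
                                      "commute", "euclidean", "resistance")) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pairwise matrix must be square")
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("I", seq_len(nrow(values)))
  if (length(ids) != nrow(values)) stop("ids length does not match matrix")
  if (anyDuplicated(ids)) stop("duplicate ids in pairwise matrix")
  off <- values[upper.tri(values) | lower.tri(values)]
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-8 * (1 + max(abs(off), na.rm = TRUE)))
    stop("pairwise matrix is not symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- NA_real_
  dimnames(values) <- list(ids, ids)
  if (metric == "dps") {
    bad <- off[is.finite(off) & (off < -1e-9 | off > 1 + 1e-9)]
    if (length(bad)) stop("dps values must lie in [0, 1]")
  }
  if (metric %in% c("commute", "euclidean") &&
      any(is.finite(off) & off < -1e-9))
    stop(metric, " distances must be non-negative")
  structure(values, class = c("pairwise_matrix", "matrix"),
            metric = metric)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix '%s'> %d ids\n", attr(x, "metric"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

pm_metric <- function(x) attr(x, "metric")

pm_ids <- function(x) rownames(x)

#' Extract lower-triangle dyad values
#'
#' Returns one row per unordered dyad `(i, j)` with `i` before `j` in the
#' matrix id ordering, giving a canonical dyad ordering shared by all
#' pairwise outputs.
#'
#' @param x a [pairwise_matrix()].
#' @return A data frame with columns `id1`, `id2`, `value`.
#' @export
dyad_values <- function(x) {
  ids <- pm_ids(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  # lower.tri row > col: dyad (col, row) keeps id order i < j
  data.frame(id1 = ids[idx[, "col"]], id2 = ids[idx[, "row"]],
             value = x[idx], stringsAsFactors = FALSE)
}

#' Restrict a pairwise matrix to a subset of ids
#'
#' @param x a [pairwise_matrix()].
#' @param ids labels to keep (order respected).
#' @return A [pairwise_matrix()] over `ids`.
#' @export
pm_restrict <- function(x, ids) {
  missing_ids <- setdiff(ids, pm_ids(x))
  if (length(missing_ids))
    stop("ids not present in pairwise matrix: ",
         paste(missing_ids, collapse = ", "))
  pairwise_matrix(unclass(x)[ids, ids, drop = FALSE], ids = ids,
                  metric = pm_metric(x))
}

#' Pairwise Euclidean distances between coordinates
#'
#' @param coords two-column matrix or data frame of projected x/y (meters);
#'   row names (or an `id` column) become dyad labels.
#' @return A [pairwise_matrix()] with metric `"euclidean"`.
#' @export
euclidean_distances <- function(coords) {
  ids <- NULL
  if (is.data.frame(coords) && "id" %in% names(coords)) {
    ids <- as.character(coords$id)
    coords <- coords[, setdiff(names(coords), "id"), drop = FALSE]
  }
  coords <- as.matrix(coords[, 1:2])
  if (is.null(ids)) ids <- rownames(coords)
  d <- as.matrix(stats::dist(coords))
  pairwise_matrix(d, ids = ids, metric = "euclidean")
}

#' Read / write pairwise matrices as square CSV
#'
#' Square layout with an id header row and id first column.
#'
#' @param x a [pairwise_matrix()]; `path` a file path; `metric` the metric
#'   tag to attach on read.
#' @return `read_pairwise_csv` returns a [pairwise_matrix()].
#' @export
write_pairwise_csv <- function(x, path) {
  df <- data.frame(id = pm_ids(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairwise_csv
#' @export
read_pairwise_csv <- function(path, metric = "resistance") {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  diag(m)[is.na(diag(m))] <- NA_real_
  pairwise_matrix(m, ids = ids, metric = metric)
}
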