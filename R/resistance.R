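#' Conductance graph of a resistance raster
#'
#' Nodes are the non-missing cells; edges link 4- or 8-neighbor cells with
#' conductance `1 / mean(R_i, R_j)` (the average pairwise resistance of the
#' two cells). Diagonal edges are geometry-corrected: their conductance is
#' additionally divided by `sqrt(2)` to account for the longer step.
#'
#' @param r a [raster_surface()] of resistances (positive; >= 1 by the
#'   conventions of [apply_transform()]).
#' @param connectivity 4 or 8 (default) neighbor scheme.
#' @return A `conductance_graph`: node/cell maps, an edge table with
#'   conductances, and the source raster geometry.
#' @export
conductance_graph <- function(r, connectivity = 8) {
  stopifnot_raster(r)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  v <- r$values
  if (any(is.finite(v) & v <= 0)) stop("resistances must be positive")
  nr <- nrow(v); nc <- ncol(v)
  ok <- is.finite(v)
  if (sum(ok) < 2L) stop("need at least two non-missing cells")
  node_of_cell <- integer(length(v))
  node_of_cell[ok] <- seq_len(sum(ok))
  cell_of_node <- which(ok)

  offsets <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offsets <- c(offsets, list(c(1, 1), c(1, -1)))
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rows <- seq_len(nr - abs(dr) * (dr != 0)) # dr is 0 or 1
    if (dr == 1) rows <- seq_len(nr - 1L)
    cols <- if (dc == 1) seq_len(nc - 1L) else if (dc == -1) 2:nc else
      seq_len(nc)
    if (!length(rows) || !length(cols)) next
    from_cells <- as.vector(outer(rows, (cols - 1L) * nr, `+`))
    to_cells <- from_cells + dr + dc * nr
    keep <- ok[from_cells] & ok[to_cells]
    if (!any(keep)) next
    fc <- from_cells[keep]; tc <- to_cells[keep]
    w <- 1 / ((v[fc] + v[tc]) / 2)
    if (abs(dr) + abs(dc) == 2L) w <- w / sqrt(2)
    ei <- c(ei, node_of_cell[fc])
    ej <- c(ej, node_of_cell[tc])
    ew <- c(ew, w)
  }
  if (!length(ew)) stop("graph has no edges")
  structure(list(n = sum(ok),
                 edges = data.frame(i = ei, j = ej, w = ew),
                 cell_of_node = cell_of_node,
                 node_of_cell = node_of_cell,
                 nrow = nr, ncol = nc,
                 cell_size = r$cell_size, origin = r$origin),
            class = "conductance_graph")
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf("<conductance_graph> %d nodes, %d edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

# sparse weighted adjacency / graph Laplacian
graph_adjacency <- function(g) {
  Matrix::sparseMatrix(i = c(g$edges$i, g$edges$j),
                       j = c(g$edges$j, g$edges$i),
                       x = c(g$edges$w, g$edges$w),
                       dims = c(g$n, g$n))
}

graph_laplacian <- function(g) {
  A <- graph_adjacency(g)
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

# connected-component labels by frontier expansion on the adjacency pattern
graph_components <- function(g) {
  A <- graph_adjacency(g) != 0
  comp <- integer(g$n)
  cur <- 0L
  while (any(comp == 0L)) {
    cur <- cur + 1L
    frontier <- logical(g$n)
    frontier[which(comp == 0L)[1L]] <- TRUE
    member <- frontier
    while (any(frontier)) {
      frontier <- as.vector(A %*% frontier) > 0 & !member
      member <- member | frontier
    }
    comp[member] <- cur
  }
  comp
}

#' Snap point coordinates to graph nodes
#'
#' Each query point maps to the nearest non-missing cell center; exact ties
#' resolve toward the lower row index, then lower column index.
#'
#' @param g a [conductance_graph()].
#' @param coords two-column matrix / data frame of x/y (an `id` column is
#'   carried through to names).
#' @return Integer node indices, named when ids are available.
#' @export
snap_nodes <- function(g, coords) {
  ids <- NULL
  if (is.data.frame(coords) && "id" %in% names(coords)) {
    ids <- as.character(coords$id)
    coords <- coords[, setdiff(names(coords), "id"), drop = FALSE]
  }
  coords <- as.matrix(coords[, 1:2, drop = FALSE])
  if (is.null(ids)) ids <- rownames(coords)
  nr <- g$nrow
  cells <- g$cell_of_node
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cx <- g$origin[1] + (col - 0.5) * g$cell_size
  cy <- g$origin[2] + (nr - row + 0.5) * g$cell_size
  nodes <- vapply(seq_len(nrow(coords)), function(k) {
    d2 <- (cx - coords[k, 1])^2 + (cy - coords[k, 2])^2
    cand <- which(d2 == min(d2))
    cand[order(row[cand], col[cand])][1L]
  }, integer(1))
  names(nodes) <- ids
  nodes
}

# Cholesky factor of the Laplacian with one grounded node, for reuse across
# right-hand sides; returns solve closure mapping reduced rhs -> potentials
grounded_solver <- function(L, ground) {
  keep <- setdiff(seq_len(nrow(L)), ground)
  Lr <- L[keep, keep, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), perm = TRUE)
  list(keep = keep, ground = ground,
       solve = function(b_full) {
         x <- numeric(nrow(L))
         x[keep] <- as.vector(Matrix::solve(ch, b_full[keep]))
         x
       })
}

#' Commute distances between query nodes
#'
#' Circuit-theory resistance distance: the commute distance between nodes i
#' and j is the expected number of steps of a random walk from i to j and
#' back, `C(i, j) = vol(G) * R_eff(i, j)`, with `vol(G)` the sum of
#' (weighted) node degrees and `R_eff` the effective resistance
#' `Lplus_ii + Lplus_jj - 2 Lplus_ij` from the Laplacian pseudoinverse.
#' Computed by grounding one node and factoring the reduced Laplacian once
#' (identical to the dense pseudoinverse to high precision). All query
#' nodes must lie in a single connected component; the volume is that of
#' the component carrying the query nodes.
#'
#' @param g a [conductance_graph()].
#' @param nodes integer node indices, or coordinates (see [snap_nodes()]).
#' @return A [pairwise_matrix()] with metric `"commute"`.
#' @export
commute_distance <- function(g, nodes) {
  if (is.matrix(nodes) || is.data.frame(nodes)) nodes <- snap_nodes(g, nodes)
  nodes <- as.integer(nodes) |> stats::setNames(names(nodes))
  if (any(nodes < 1L | nodes > g$n)) stop("node index out of range")
  comp <- graph_components(g)
  qc <- unique(comp[nodes])
  if (length(qc) > 1L)
    stop("query nodes span ", length(qc), " disconnected components (",
         paste(qc, collapse = ", "), ")")
  member <- comp == qc
  A <- graph_adjacency(g)
  vol <- sum(Matrix::rowSums(A)[member])
  # reduce to the query component, ground its last node
  sub <- which(member)
  relab <- integer(g$n); relab[sub] <- seq_along(sub)
  Ls <- graph_laplacian_sub(g, sub, relab)
  sol <- grounded_solver(Ls, length(sub))
  q <- relab[nodes]
  # columns of a generalized inverse of L at the query nodes
  G <- matrix(0, length(sub), length(q))
  for (k in seq_along(q)) {
    b <- numeric(length(sub)); b[q[k]] <- 1
    G[, k] <- sol$solve(b)
  }
  Gq <- G[q, , drop = FALSE]
  dg <- diag(Gq)
  Reff <- outer(dg, dg, `+`) - Gq - t(Gq)
  cm <- vol * Reff
  cm[cm < 0] <- 0
  ids <- names(nodes)
  if (is.null(ids)) ids <- paste0("N", nodes)
  pairwise_matrix(cm, ids = ids, metric = "commute")
}

graph_laplacian_sub <- function(g, sub, relab) {
  inset <- logical(g$n); inset[sub] <- TRUE
  keep <- inset[g$edges$i] & inset[g$edges$j]
  e <- g$edges[keep, , drop = FALSE]
  A <- Matrix::sparseMatrix(i = c(relab[e$i], relab[e$j]),
                            j = c(relab[e$j], relab[e$i]),
                            x = c(e$w, e$w),
                            dims = c(length(sub), length(sub)))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Solve one unit current flow between a node pair
#'
#' Injects unit current at `s`, extracts it at `t`, solves the Laplacian
#' system for node potentials, and returns per-edge currents plus per-node
#' current (half the summed absolute currents of incident edges, so an
#' interior node on a single series path carries current 1).
#'
#' @param g a [conductance_graph()].
#' @param s,t node indices (must be connected).
#' @return List with `potential`, `edge_current` (signed, i -> j), and
#'   `node_current`.
#' @export
solve_flow <- function(g, s, t) {
  comp <- graph_components(g)
  if (comp[s] != comp[t]) stop("nodes ", s, " and ", t, " are disconnected")
  L <- graph_laplacian(g)
  member <- comp == comp[s]
  if (any(!member)) {
    sub <- which(member)
    relab <- integer(g$n); relab[sub] <- seq_along(sub)
  } else {
    sub <- seq_len(g$n); relab <- sub
  }
  Ls <- graph_laplacian_sub(g, sub, relab)
  ground <- relab[t]
  sol <- grounded_solver(Ls, ground)
  b <- numeric(length(sub))
  b[relab[s]] <- 1
  b[relab[t]] <- b[relab[t]] - 1
  vloc <- sol$solve(b)
  v <- numeric(g$n)
  v[sub] <- vloc
  ec <- g$edges$w * (v[g$edges$i] - v[g$edges$j])
  nodecur <- numeric(g$n)
  agg_i <- tapply(abs(ec), g$edges$i, sum)
  agg_j <- tapply(abs(ec), g$edges$j, sum)
  nodecur[as.integer(names(agg_i))] <- agg_i
  nodecur[as.integer(names(agg_j))] <-
    nodecur[as.integer(names(agg_j))] + agg_j
  list(potential = v, edge_current = ec, node_current = nodecur / 2)
}

#' Cumulative current-flow map
#'
#' For each node pair, passes unit current between the pair and accumulates
#' per-cell current magnitude across pairs — the circuit-theory
#' visualization of where gene flow concentrates on the landscape.
#'
#' @param g a [conductance_graph()].
#' @param pairs two-column matrix of node indices (or a list of length-2
#'   vectors); all pairs must be connected.
#' @return A [raster_surface()] tagged `"current"` (NA on missing cells).
#' @export
current_map <- function(g, pairs) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  acc <- numeric(g$n)
  for (k in seq_len(nrow(pairs))) {
    fl <- solve_flow(g, pairs[k, 1], pairs[k, 2])
    acc <- acc + fl$node_current
  }
  out <- matrix(NA_real_, g$nrow, g$ncol)
  out[g$cell_of_node] <- acc
  raster_surface(out, g$cell_size, g$origin, tag = "current")
}
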