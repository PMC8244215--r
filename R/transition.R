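#' Build a sparse grid transition system from a conductance surface
#'
#' Nodes are the non-nodata cells of the largest connected component of the
#' 8-neighbour grid graph (cells with zero conductance become isolated and
#' are dropped, with a flag). Edge conductance between neighbouring cells i
#' and j is `g_ij = mean(c_i, c_j) / d_ij`, with the centre distance `d_ij`
#' in cell units (1 orthogonal, sqrt(2) diagonal). Reference transition
#' probabilities are the row-normalised conductances,
#' `p_ij = g_ij / sum_k g_ik`, and edge costs are `kappa_ij = 1 / g_ij`.
#' theta is therefore expressed per unit cost in cell units and depends on
#' the raster resolution.
#'
#' @param conductance a `raster2d` of cell conductances in (0, 1]; `NA` =
#'   nodata. Zero-conductance cells are allowed but end up isolated.
#' @return a `transition_system`: list with
#'   \describe{
#'     \item{node_cell}{integer vector, raster cell index of each node
#'       (ascending cell index: a deterministic ordering)}
#'     \item{cell_node}{integer vector over all raster cells mapping back
#'       to node index (`NA` off-graph)}
#'     \item{G}{sparse symmetric conductance matrix}
#'     \item{P}{sparse reference transition matrix (rows sum to 1)}
#'     \item{K}{sparse cost matrix, `1/g` on kept edges}
#'     \item{geometry}{the raster geometry (res, xll, yll, dim)}
#'     \item{dropped}{number of non-nodata cells outside the retained
#'       component}
#'   }
#' @export
build_transition_system <- function(conductance) {
  stopifnot(is_raster2d(conductance))
  v <- conductance$values
  d <- dim(v)
  nrows <- d[1]; ncols <- d[2]
  valid <- which(!is.na(v))
  if (length(valid) < 2L) stop("need at least 2 non-nodata cells")

  # candidate edges: each cell to its E, S, SW, SE neighbour (undirected)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, -1L), c(1L, 1L))
  row <- (valid - 1L) %% nrows + 1L
  col <- (valid - 1L) %/% nrows + 1L
  ei <- integer(0); ej <- integer(0); ed <- numeric(0)
  for (o in offs) {
    r2 <- row + o[1]; c2 <- col + o[2]
    keep <- r2 >= 1L & r2 <= nrows & c2 >= 1L & c2 <= ncols
    j <- (c2[keep] - 1L) * nrows + r2[keep]
    i <- valid[keep]
    ok <- !is.na(v[j])
    ei <- c(ei, i[ok]); ej <- c(ej, j[ok])
    ed <- c(ed, rep(if (all(o == c(0L, 1L)) || all(o == c(1L, 0L))) 1
                    else sqrt(2), sum(ok)))
  }
  g <- (v[ei] + v[ej]) / 2 / ed
  pos <- g > 0
  ei <- ei[pos]; ej <- ej[pos]; g <- g[pos]
  if (length(g) == 0L) stop("no positive-conductance edges in raster")

  # largest connected component over cells with kept edges
  cells <- sort(unique(c(ei, ej)))
  idx <- integer(nrows * ncols); idx[cells] <- seq_along(cells)
  gr <- igraph::graph_from_edgelist(cbind(idx[ei], idx[ej]), directed = FALSE)
  comp <- igraph::components(gr)
  main <- which.max(comp$csize)
  in_main <- comp$membership == main
  dropped <- length(valid) - sum(in_main)

  node_cell <- cells[in_main]
  cell_node <- rep(NA_integer_, nrows * ncols)
  cell_node[node_cell] <- seq_along(node_cell)
  keep <- in_main[idx[ei]]  # edge endpoints share components
  ei <- ei[keep]; ej <- ej[keep]; g <- g[keep]

  n <- length(node_cell)
  G <- Matrix::sparseMatrix(
    i = c(cell_node[ei], cell_node[ej]),
    j = c(cell_node[ej], cell_node[ei]),
    x = c(g, g), dims = c(n, n))
  rs <- Matrix::rowSums(G)
  P <- Matrix::Diagonal(n, 1 / rs) %*% G
  K <- G
  K@x <- 1 / K@x

  structure(
    list(node_cell = node_cell, cell_node = cell_node,
         G = methods::as(G, "CsparseMatrix"),
         P = methods::as(P, "CsparseMatrix"),
         K = methods::as(K, "CsparseMatrix"),
         geometry = list(dim = d, res = conductance$res,
                         xll = conductance$xll, yll = conductance$yll),
         dropped = dropped),
    class = "transition_system")
}

#' @export
print.transition_system <- function(x, ...) {
  cat(sprintf("transition_system: %d nodes, %d undirected edges (%d cells dropped)\n",
              length(x$node_cell), length(x$G@x) / 2, x$dropped))
  invisible(x)
}

#' Map nodes or coordinates to transition-system nodes
#'
#' `ts_node_from_xy` snaps planar coordinates to the nearest on-graph cell
#' centre (exact cell when it is on the graph).
#'
#' @param ts a `transition_system`.
#' @param x,y coordinates in map units.
#' @return integer node index.
#' @export
ts_node_from_xy <- function(ts, x, y) {
  g <- ts$geometry
  r <- raster2d(matrix(0, g$dim[1], g$dim[2]), res = g$res,
                xll = g$xll, yll = g$yll)
  cell <- xy_cell(r, x, y)
  node <- rep(NA_integer_, length(cell))
  inside <- !is.na(cell)
  node[inside] <- ts$cell_node[cell[inside]]
  miss <- which(is.na(node))
  if (length(miss)) {
    xy <- cell_xy(r, ts$node_cell)
    for (m in miss) {
      node[m] <- which.min((xy[, 1] - x[m])^2 + (xy[, 2] - y[m])^2)
    }
  }
  node
}

# empty raster matching a transition system's geometry
ts_raster <- function(ts, fill = NA_real_) {
  g <- ts$geometry
  raster2d(matrix(fill, g$dim[1], g$dim[2]), res = g$res,
           xll = g$xll, yll = g$yll)
}

# place per-node values onto the raster grid
ts_values_to_raster <- function(ts, values, fill = NA_real_) {
  r <- ts_raster(ts, fill)
  r$values[ts$node_cell] <- values
  r
}

# igraph view of the cost graph (weights = kappa), cached per call site
ts_cost_graph <- function(ts) {
  tri <- Matrix::which(Matrix::tril(ts$G) != 0, arr.ind = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = tri[, 1], to = tri[, 2],
               weight = 1 / ts$G[tri]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(ts$node_cell)))
}
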