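#' Randomized-shortest-path passage surface
#'
#' Computes the expected net throughflow of every cell for movement from
#' `source` to `dest` under the randomized-shortest-path (RSP) model: a
#' killed random walk whose step weights are
#' `w_ij = p_ij * exp(-theta * kappa_ij)`, interpolating between the
#' unbiased reference walk (`theta = 0`, equivalent to circuit theory) and
#' the deterministic least-cost path (`theta -> Inf`). The destination is
#' made absorbing by zeroing its outgoing row. Two sparse direct solves
#' give the forward visit expectations `u` (`(I - W')u = e_s`) and the
#' backward absorption weights `z` (`(I - W)z = e_d`); expected edge flows
#' are `eta_ij = u_i w_ij z_j / z_s` and net flows `f = eta - t(eta)`.
#' Per-cell net throughflow is `n_i = sum_j |f_ij| / 2` for interior
#' cells, and 1 at the two endpoints by convention.
#'
#' @param ts a `transition_system`.
#' @param source,dest node indices (see [ts_node_from_xy()]); must differ.
#' @param theta non-negative randomness parameter (0 = random walk,
#'   large = smoothed least-cost path). The admissible upper limit
#'   depends on the size of the graph and the conductance values: when
#'   `theta * kappa` exceeds the double-precision exponent range on some
#'   edge the killed weights underflow and an error is raised.
#' @return a `passage_surface`: list with `surface` (a `raster2d` of
#'   throughflow), `theta`, `source`, `dest`, `u`, `z`, `Z` (= `z[source]`,
#'   the path-weight normaliser), sparse `eta`, and `ts` geometry.
#' @export
rsp_passage <- function(ts, source, dest, theta) {
  stopifnot(inherits(ts, "transition_system"))
  n <- length(ts$node_cell)
  source <- as.integer(source); dest <- as.integer(dest)
  if (is.na(source) || is.na(dest) || source < 1L || dest < 1L ||
      source > n || dest > n) stop("invalid source/dest node")
  if (source == dest) stop("source and dest must differ")
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("'theta' must be a single non-negative number")

  W <- rsp_W(ts, theta, dest)
  A <- Matrix::Diagonal(n) - W
  u <- as.numeric(Matrix::solve(Matrix::t(A), e_vec(n, source)))
  z <- as.numeric(Matrix::solve(A, e_vec(n, dest)))
  Zsd <- z[source]
  if (!is.finite(Zsd) || Zsd <= 0)
    stop("destination unreachable under these killed-walk weights")

  eta <- Matrix::Diagonal(n, u) %*% W %*% Matrix::Diagonal(n, z) / Zsd
  f <- eta - Matrix::t(eta)
  nthrough <- Matrix::rowSums(abs(f)) / 2
  nthrough[c(source, dest)] <- 1

  structure(
    list(surface = ts_values_to_raster(ts, nthrough),
         theta = theta, source = source, dest = dest,
         u = u, z = z, Z = Zsd,
         eta = methods::as(eta, "CsparseMatrix"),
         ts = ts, geometry = ts$geometry),
    class = "passage_surface")
}

# killed-walk weight matrix with absorbing destination (dest row zeroed)
rsp_W <- function(ts, theta, dest) {
  W <- ts$P
  if (theta > 0) {
    damp <- -theta / ts$G@x   # kappa on the same sparsity pattern as G
    if (min(damp) < -700)
      stop(paste("theta too large for this graph: exp(-theta * kappa)",
                 "underflows; the admissible upper limit of theta depends",
                 "on the size of the graph and the conductance values"))
    # P shares G's pattern (row scaling preserves it)
    W@x <- W@x * exp(damp)
  }
  W[dest, ] <- 0
  methods::as(W, "CsparseMatrix")
}

e_vec <- function(n, i) {
  e <- numeric(n); e[i] <- 1
  e
}

#' @export
print.passage_surface <- function(x, ...) {
  cat(sprintf("passage_surface: theta = %g, source node %d -> dest node %d, Z = %g\n",
              x$theta, x$source, x$dest, x$Z))
  invisible(x)
}

#' Expected path cost of an RSP passage
#'
#' `sum_ij eta_ij * kappa_ij`: the expected accumulated cost of a walk
#' from source to destination under the RSP distribution. Non-increasing
#' in theta, and converging to the Dijkstra least-cost value as theta
#' grows.
#'
#' @param ps a `passage_surface`.
#' @return expected cost (cell-unit cost scale).
#' @export
expected_path_cost <- function(ps) {
  stopifnot(inherits(ps, "passage_surface"))
  idx <- Matrix::which(ps$eta != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  # eta's pattern is a subset of G's, so kappa = 1/g is defined there
  sum(ps$eta[idx] / ps$ts$G[idx])
}

#' Sum passage surfaces cellwise
#'
#' @param surfaces list of `passage_surface` or `raster2d` objects on a
#'   shared grid.
#' @return a `raster2d` with the cellwise sum (nodata where all inputs are
#'   nodata).
#' @export
sum_passages <- function(surfaces) {
  if (length(surfaces) == 0L) stop("empty surface list")
  rs <- lapply(surfaces, function(s)
    if (inherits(s, "passage_surface")) s$surface else s)
  stopifnot(all(vapply(rs, is_raster2d, logical(1))))
  for (r in rs[-1]) stop_if_geometry_differs(rs[[1]], r)
  acc <- rs[[1]]$values
  acc[is.na(acc)] <- 0
  anyval <- !is.na(rs[[1]]$values)
  for (r in rs[-1]) {
    v <- r$values
    ok <- !is.na(v)
    anyval <- anyval | ok
    v[!ok] <- 0
    acc <- acc + v
  }
  acc[!anyval] <- NA_real_
  raster2d(acc, res = rs[[1]]$res, xll = rs[[1]]$xll, yll = rs[[1]]$yll)
}

#' Least-cost path and LCP density surface
#'
#' `lcp_path` returns the Dijkstra least-cost node sequence on the
#' `kappa = 1/g` cost graph. `lcp_density` rasterises the least-cost path
#' of every pair as 1-valued cells, sums over pairs, and smooths with a
#' Gaussian kernel (the kernel-density buffering used by corridor LCP
#' tools); `kernel_sigma = 0` keeps the binary path raster.
#'
#' @param ts a `transition_system`.
#' @param source,dest node indices.
#' @return `lcp_path`: list with `nodes` (node index sequence) and `cost`
#'   (accumulated kappa).
#' @export
lcp_path <- function(ts, source, dest) {
  gr <- ts_cost_graph(ts)
  sp <- igraph::shortest_paths(gr, from = source, to = dest,
                               weights = igraph::E(gr)$weight,
                               output = "vpath")
  nodes <- as.integer(names(sp$vpath[[1]]))
  if (length(nodes) == 0L) return(NULL)
  cost <- igraph::distances(gr, v = source, to = dest,
                            weights = igraph::E(gr)$weight)[1, 1]
  list(nodes = nodes, cost = cost)
}

#' @rdname lcp_path
#' @param pairs list of length-2 vectors `c(source, dest)` of node indices.
#' @param kernel_sigma Gaussian kernel sd in cells (>= 0).
#' @return `lcp_density`: a `raster2d`.
#' @export
lcp_density <- function(ts, pairs, kernel_sigma = 0) {
  stopifnot(inherits(ts, "transition_system"), kernel_sigma >= 0)
  acc <- numeric(length(ts$node_cell))
  gr <- ts_cost_graph(ts)
  for (p in pairs) {
    sp <- igraph::shortest_paths(gr, from = p[1], to = p[2],
                                 weights = igraph::E(gr)$weight,
                                 output = "vpath")$vpath[[1]]
    nodes <- as.integer(names(sp))
    if (length(nodes) == 0L) {
      warning(sprintf("nodes %d and %d are disconnected; pair skipped",
                      p[1], p[2]))
      next
    }
    acc[nodes] <- acc[nodes] + 1
  }
  out <- ts_values_to_raster(ts, acc)
  if (kernel_sigma > 0) out <- gaussian_blur(out, kernel_sigma)
  out
}

#' Circuit-theory current flow
#'
#' Solves the graph Laplacian system `L v = e_s - e_d` with the
#' destination grounded (edge weights = conductances g), then reports the
#' per-node throughflow `sum_j |g_ij (v_i - v_j)| / 2`, with the endpoints
#' set to 1 (unit current injected). Identical to [rsp_passage()] at
#' `theta = 0`.
#'
#' @param ts a `transition_system`.
#' @param source,dest node indices.
#' @return a `raster2d` of current throughflow.
#' @export
circuit_flow <- function(ts, source, dest) {
  stopifnot(inherits(ts, "transition_system"))
  n <- length(ts$node_cell)
  if (source == dest) stop("source and dest must differ")
  L <- Matrix::Diagonal(n, Matrix::rowSums(ts$G)) - ts$G
  keep <- setdiff(seq_len(n), dest)
  rhs <- e_vec(n, source)[keep]
  v <- numeric(n)
  sol <- try(Matrix::solve(L[keep, keep], rhs), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("singular Laplacian system: graph disconnected between endpoints")
  v[keep] <- as.numeric(sol)
  # edge currents on G's pattern
  I <- ts$G
  tri <- Matrix::which(I != 0, arr.ind = TRUE)
  cur <- ts$G[tri] * (v[tri[, 1]] - v[tri[, 2]])
  flow <- numeric(n)
  tab <- tapply(abs(cur), tri[, 1], sum)
  flow[as.integer(names(tab))] <- as.numeric(tab) / 2
  flow[c(source, dest)] <- 1
  ts_values_to_raster(ts, flow)
}
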