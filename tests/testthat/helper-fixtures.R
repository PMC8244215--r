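# shared fixture builders and independent oracles

# raster with iid uniform conductance in [lo, hi]
random_cond_raster <- function(nr, nc, seed, lo = 0.1, hi = 1) {
  set.seed(seed)
  raster2d(matrix(stats::runif(nr * nc, lo, hi), nr, nc))
}

uniform_raster <- function(nr, nc, value = 0.5) {
  raster2d(matrix(value, nr, nc))
}

# hand-built transition system (for circuit fixtures with chosen edge
# conductances); G a dense symmetric matrix, nodes laid on a 1 x n strip
manual_ts <- function(G) {
  n <- nrow(G)
  structure(
    list(node_cell = seq_len(n),
         cell_node = seq_len(n),
         G = methods::as(Matrix::Matrix(G, sparse = TRUE),
                         "CsparseMatrix"),
         P = methods::as(Matrix::Diagonal(n, 1 / rowSums(G)) %*%
                           Matrix::Matrix(G, sparse = TRUE),
                         "CsparseMatrix"),
         K = NULL,
         geometry = list(dim = c(1L, n), res = 1, xll = 0, yll = 0),
         dropped = 0L),
    class = "transition_system")
}

# dense, from-first-principles RSP edge-flow oracle: fundamental matrix
# of the killed walk via base::solve on dense matrices
dense_rsp_eta <- function(ts, s, d, theta) {
  P <- as.matrix(ts$P)
  G <- as.matrix(ts$G)
  W <- P
  pos <- G > 0
  W[pos] <- P[pos] * exp(-theta / G[pos])
  W[d, ] <- 0
  n <- nrow(W)
  Ainv <- solve(diag(n) - W)
  u <- Ainv[s, ]          # row of (I - W)^-T applied to e_s
  z <- Ainv[, d]
  outer(u, z) * W / z[s]
}

dense_rsp_throughflow <- function(ts, s, d, theta) {
  eta <- dense_rsp_eta(ts, s, d, theta)
  f <- eta - t(eta)
  nthrough <- rowSums(abs(f)) / 2
  nthrough[c(s, d)] <- 1
  nthrough
}

# unit-current electrical flow via dense Laplacian solve (Doyle-Snell)
dense_current_flow <- function(ts, s, d) {
  G <- as.matrix(ts$G)
  n <- nrow(G)
  L <- diag(rowSums(G)) - G
  keep <- setdiff(seq_len(n), d)
  v <- numeric(n)
  v[keep] <- solve(L[keep, keep], ifelse(keep == s, 1, 0))
  I <- G * (matrix(v, n, n) - matrix(v, n, n, byrow = TRUE))
  flow <- rowSums(abs(I)) / 2
  flow[c(s, d)] <- 1
  flow
}

# exhaustive simple-path minimum cost between two nodes (tiny graphs)
brute_force_min_cost <- function(ts, s, d) {
  G <- as.matrix(ts$G)
  n <- nrow(G)
  best <- Inf
  visit <- function(node, cost, seen) {
    if (cost >= best) return()
    if (node == d) {
      best <<- cost
      return()
    }
    for (j in which(G[node, ] > 0)) {
      if (!seen[j]) {
        seen[j] <- TRUE
        visit(j, cost + 1 / G[node, j], seen)
        seen[j] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n)
  seen[s] <- TRUE
  visit(s, 0, seen)
  best
}

# same-class join count of a binary layer over 4-neighbour pairs
join_count <- function(m) {
  horiz <- m[, -ncol(m)] == m[, -1]
  vert <- m[-nrow(m), ] == m[-1, ]
  sum(horiz) + sum(vert)
}

# one-hot landcover stack from an integer class matrix
stack_from_classes <- function(classmat, classes = NULL, res = 1) {
  ks <- sort(unique(as.vector(classmat)))
  if (is.null(classes)) classes <- paste0("class_", LETTERS[ks])
  layers <- lapply(seq_along(ks), function(i)
    raster2d((classmat == ks[i]) * 1, res = res))
  names(layers) <- classes
  structure(list(layers = layers, classes = classes, res = res),
            class = "landcover_stack")
}

fixes_df <- function(x, y, t = NULL, animal = "a") {
  data.frame(animal_id = animal,
             t = if (is.null(t)) 4 * (seq_along(x) - 1) else t,
             x = x, y = y, stringsAsFactors = FALSE)
}
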