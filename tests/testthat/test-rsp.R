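test_that("transition systems encode the grid-graph conventions", {
  u <- build_transition_system(uniform_raster(3, 3, 0.5))
  # orthogonal edge conductance c, diagonal c/sqrt(2)
  expect_equal(u$G[1, 2], 0.5)
  expect_equal(u$G[1, 5], 0.5 / sqrt(2))
  expect_equal(u$G[1, 4], 0.5)
  expect_true(Matrix::isSymmetric(u$G))
  expect_equal(as.numeric(Matrix::rowSums(u$P)), rep(1, 9))

  two <- build_transition_system(raster2d(matrix(0.4, 1, 2)))
  expect_equal(as.numeric(two$P[1, 2]), 1)
  expect_equal(as.numeric(two$P[2, 1]), 1)

  # an edge between two zero-conductance cells is dropped (edge
  # conductance is the endpoint mean); rows still sum to 1
  m <- matrix(0.5, 4, 4)
  m[1, 1] <- 0; m[2, 1] <- 0
  z <- build_transition_system(raster2d(m))
  expect_equal(length(z$node_cell), 16)
  n1 <- z$cell_node[1]; n2 <- z$cell_node[2]
  expect_equal(z$G[n1, n2], 0)
  expect_equal(as.numeric(Matrix::rowSums(z$P)), rep(1, 16))

  # only the largest connected component is retained
  mm <- matrix(0.5, 4, 6)
  mm[, 3] <- NA
  comp <- build_transition_system(raster2d(mm))
  expect_equal(length(comp$node_cell), 12)
  expect_equal(comp$dropped, 8)

  expect_error(build_transition_system(raster2d(matrix(NA_real_, 2, 2))),
               "non-nodata")
})

test_that("theta = 0 passage equals electrical current flow", {
  for (seed in 1:3) {
    cond <- random_cond_raster(12, 12, seed = seed, lo = 0.05, hi = 1)
    ts <- build_transition_system(cond)
    n <- length(ts$node_cell)
    s <- 1L; d <- n
    ps <- rsp_passage(ts, s, d, 0)
    oracle <- dense_current_flow(ts, s, d)
    expect_lt(max(abs(ps$surface$values[ts$node_cell] - oracle)), 1e-8)
    # and the packaged circuit solver agrees too
    cf <- circuit_flow(ts, s, d)
    expect_lt(max(abs(ps$surface$values - cf$values), na.rm = TRUE), 1e-8)
  }
})

test_that("large theta concentrates throughflow on the least-cost path", {
  # an instance whose least-cost path is uniquely separated: near-ties
  # in path cost keep permanent throughflow shares at any finite theta,
  # so the deterministic limit is exhibited where the cost gap allows
  cond <- random_cond_raster(15, 15, seed = 5, lo = 0.2, hi = 1)
  ts <- build_transition_system(cond)
  s <- 1L; d <- length(ts$node_cell)
  lcp <- lcp_path(ts, s, d)
  # the largest numerically safe theta: path weights stay representable
  ps <- rsp_passage(ts, s, d, 600 / lcp$cost)
  v <- ps$surface$values[ts$node_cell]
  interior <- setdiff(seq_along(v), c(s, d))
  onpath <- intersect(interior, lcp$nodes)
  expect_gte(sum(v[onpath]) / sum(v[interior]), 0.99)
})

test_that("sparse eta matches the dense fundamental-matrix oracle", {
  for (case in list(c(5, 5, 1), c(4, 6, 2))) {
    cond <- random_cond_raster(case[1], case[2], seed = case[3],
                               lo = 0.2, hi = 1)
    ts <- build_transition_system(cond)
    n <- length(ts$node_cell)
    for (theta in c(0, 0.05, 1)) {
      ps <- rsp_passage(ts, 1L, n, theta)
      expect_lt(max(abs(as.matrix(ps$eta) -
                          dense_rsp_eta(ts, 1L, n, theta))), 1e-10)
    }
  }
})

test_that("passage surfaces conserve flow and normalise endpoints", {
  for (seed in 1:4) {
    cond <- random_cond_raster(8, 9, seed = seed + 10, lo = 0.1, hi = 1)
    ts <- build_transition_system(cond)
    n <- length(ts$node_cell)
    s <- 2L; d <- n - 1L
    for (theta in c(0, 1e-3, 0.2)) {
      ps <- rsp_passage(ts, s, d, theta)
      f <- ps$eta - Matrix::t(ps$eta)
      # unit net outflow at the source
      expect_equal(sum(f[s, ]), 1, tolerance = 1e-8)
      # zero divergence at interior nodes
      div <- Matrix::rowSums(f)[-c(s, d)]
      expect_lt(max(abs(div)), 1e-8)
      # forward/backward consistency
      expect_equal(ps$u[d] , ps$z[s] / ps$z[d], tolerance = 1e-8)
      # endpoint convention and non-negativity
      v <- ps$surface$values[ts$node_cell]
      expect_true(all(v >= -1e-12))
      expect_equal(v[c(s, d)], c(1, 1))
      # symmetry: swapping endpoints leaves the surface unchanged
      back <- rsp_passage(ts, d, s, theta)
      expect_lt(max(abs(back$surface$values - ps$surface$values),
                    na.rm = TRUE), 1e-8)
    }
  }
})

test_that("theta too large for the graph raises the underflow guard", {
  cond <- random_cond_raster(5, 5, seed = 1, lo = 1e-3, hi = 0.01)
  ts <- build_transition_system(cond)
  expect_error(rsp_passage(ts, 1L, 25L, 10), "upper limit")
})

test_that("expected path cost is the edge cost on a single edge", {
  two <- build_transition_system(raster2d(matrix(0.4, 1, 2)))
  ps <- rsp_passage(two, 1, 2, 0.5)
  expect_equal(expected_path_cost(ps), 1 / 0.4, tolerance = 1e-12)
})

test_that("expected path cost falls with theta to the Dijkstra cost", {
  thetas <- default_theta_grid()
  for (seed in 1:3) {
    cond <- random_cond_raster(10, 10, seed = seed + 20, lo = 0.1, hi = 1)
    ts <- build_transition_system(cond)
    n <- length(ts$node_cell)
    costs <- vapply(thetas, function(th)
      expected_path_cost(rsp_passage(ts, 1L, n, th)), numeric(1))
    expect_true(all(diff(costs) <= 1e-9))
    lcp <- lcp_path(ts, 1L, n)
    big <- expected_path_cost(rsp_passage(ts, 1L, n, 600 / lcp$cost))
    expect_lt(abs(big - lcp$cost) / lcp$cost, 0.01)
  }
})

test_that("passage surfaces sum cellwise", {
  cond <- random_cond_raster(6, 6, seed = 2, lo = 0.2, hi = 1)
  ts <- build_transition_system(cond)
  ps <- rsp_passage(ts, 1L, 36L, 0.01)
  one <- sum_passages(list(ps))
  expect_equal(one$values, ps$surface$values)
  twice <- sum_passages(list(ps, ps))
  expect_equal(twice$values, 2 * ps$surface$values)
  ps2 <- rsp_passage(ts, 1L, 36L, 0.1)
  three <- sum_passages(list(ps, ps, ps2))
  expect_equal(three$values[ts$node_cell][1], 3)   # shared source cell
})

test_that("two equal parallel routes split the flow evenly", {
  # 3x3 grid with the centre blocked: two symmetric corridors
  m <- matrix(0.5, 3, 3)
  m[2, 2] <- NA
  ts <- build_transition_system(raster2d(m))
  s <- ts$cell_node[1]          # top-left
  d <- ts$cell_node[9]          # bottom-right
  for (theta in c(0, 0.1, 2)) {
    v <- rsp_passage(ts, s, d, theta)$surface$values
    expect_equal(v[1, 3], v[3, 1], tolerance = 1e-10)
  }
})

test_that("lcp density rasterises least-cost routes and keeps mass", {
  cond <- random_cond_raster(7, 7, seed = 3, lo = 0.3, hi = 1)
  ts <- build_transition_system(cond)
  n <- length(ts$node_cell)
  raw <- lcp_density(ts, list(c(1L, n)), kernel_sigma = 0)
  expect_true(all(stats::na.omit(as.vector(raw$values)) %in% c(0, 1)))
  lcp <- lcp_path(ts, 1L, n)
  expect_equal(sum(raw$values, na.rm = TRUE), length(lcp$nodes))

  sm <- lcp_density(ts, list(c(1L, n)), kernel_sigma = 1)
  expect_equal(sum(sm$values, na.rm = TRUE),
               sum(raw$values, na.rm = TRUE), tolerance = 1e-6)

  # brute-force minimum-cost oracle on a tiny grid
  tiny <- build_transition_system(random_cond_raster(4, 4, seed = 9,
                                                     lo = 0.2, hi = 1))
  lp <- lcp_path(tiny, 1L, 16L)
  expect_equal(lp$cost, brute_force_min_cost(tiny, 1L, 16L),
               tolerance = 1e-10)
})

test_that("circuit flow reproduces series and parallel circuit laws", {
  # series chain: every node carries the full current
  chain <- manual_ts(rbind(c(0, 2, 0), c(2, 0, 1), c(0, 1, 0)))
  v <- circuit_flow(chain, 1, 3)$values
  expect_equal(as.numeric(v), c(1, 1, 1), tolerance = 1e-12)

  # parallel branches with conductances 2:1 split the current 2/3 : 1/3
  G <- matrix(0, 4, 4)
  G[1, 2] <- G[2, 1] <- 2; G[2, 4] <- G[4, 2] <- 2
  G[1, 3] <- G[3, 1] <- 1; G[3, 4] <- G[4, 3] <- 1
  par <- manual_ts(G)
  v2 <- as.numeric(circuit_flow(par, 1, 4)$values)
  expect_equal(v2[2], 2 / 3, tolerance = 1e-12)
  expect_equal(v2[3], 1 / 3, tolerance = 1e-12)
})
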