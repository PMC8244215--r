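straight_traj <- function(n = 20, step = 100, dt = 4) {
  trajectory(fixes_df(step * (0:(n - 1)), rep(0, n), t = dt * (0:(n - 1))))
}

test_that("brownian-bridge sigma estimation hits its structural limits", {
  # perfectly linear constant-speed track: deviations are zero, the
  # optimiser runs to the lower bound and flags it
  est <- estimate_bb_sigma(straight_traj(), delta = 0)
  expect_true(est$at_bound)
  expect_lt(est$sigma_m, 1e-3)

  # scale equivariance: doubling coordinates doubles sigma_m
  set.seed(2)
  n <- 100
  wob <- fixes_df(cumsum(rnorm(n, 0, 50)), cumsum(rnorm(n, 0, 50)))
  tr1 <- trajectory(wob)
  tr2 <- trajectory(transform(wob, x = 2 * x, y = 2 * y))
  e1 <- estimate_bb_sigma(tr1)$sigma_m
  e2 <- estimate_bb_sigma(tr2)$sigma_m
  expect_equal(e2 / e1, 2, tolerance = 1e-4)
})

test_that("brownian-bridge sigma recovers a known motion variance", {
  # brownian path sampled every 4 h with known sigma_m
  sigma_true <- 120
  set.seed(6)
  n <- 202
  dt <- 4
  tr <- trajectory(fixes_df(cumsum(c(0, rnorm(n - 1, 0, sigma_true * sqrt(dt)))),
                            cumsum(c(0, rnorm(n - 1, 0, sigma_true * sqrt(dt)))),
                            t = dt * (0:(n - 1))))
  est <- estimate_bb_sigma(tr, delta = 0)
  expect_false(est$at_bound)
  expect_lt(abs(est$sigma_m - sigma_true) / sigma_true, 0.15)
})

test_that("brownian-bridge surfaces are normalised, local and symmetric", {
  grid <- raster2d(matrix(0, 41, 41), res = 1)
  tr <- trajectory(fixes_df(c(10.5, 30.5), c(20.5, 20.5), t = c(0, 4)))
  s <- brownian_bridge_surface(list(tr), grid, sigma_m = 1, delta = 0.3)
  expect_equal(sum(s$values), 1, tolerance = 1e-9)

  # small variance: mass concentrates along the segment band
  band <- s$values[19:23, 10:31]
  expect_gte(sum(band), 0.95)

  # symmetry about the segment midpoint (x = 20.5): mirroring the
  # columns maps the surface onto itself
  expect_equal(s$values, s$values[, 41:1], tolerance = 1e-9)
  expect_equal(s$values[21, 16], s$values[21, 26], tolerance = 1e-9)

  expect_error(brownian_bridge_surface(list(tr), grid, 0, 0), "zero")
  # zero-duration segments (possible in hand-built inputs) are skipped
  zerod <- list(fixes = fixes_df(c(0, 1, 2), c(0, 0, 0), t = c(0, 0, 4)))
  expect_warning(brownian_bridge_surface(list(zerod), grid, 1),
                 "zero-duration")
})

test_that("mse score is zero on identity and symmetric in its arguments", {
  a <- raster2d(matrix(stats::runif(100), 10, 10))
  b <- raster2d(matrix(stats::runif(100), 10, 10))
  expect_equal(mse_score(a, a)$value, 0)
  expect_equal(mse_score(a, b)$value, mse_score(b, a)$value)
  expect_identical(mse_score(a, b)$direction, "lower")
  expect_error(mse_score(a, raster2d(matrix(0, 5, 5))), "geometry")
})

test_that("corridor representation scores fixes against the mask fraction", {
  set.seed(8)
  surf <- raster2d(matrix(stats::runif(2500), 50, 50))
  # fixes parked on the highest-value cells always fall inside
  top <- order(surf$values, decreasing = TRUE)[1:20]
  xy <- cell_xy(surf, top)
  all_in <- corridor_representation_score(
    surf, 90, data.frame(x = xy[, 1], y = xy[, 2]))
  expect_equal(all_in$value, 100)

  # uniform random fixes land inside at about the mask-area rate
  ufx <- data.frame(x = stats::runif(4000, 0, 50),
                    y = stats::runif(4000, 0, 50))
  u <- corridor_representation_score(surf, 90, ufx)
  expect_lt(abs(u$value - 10), 2)

  flat <- corridor_representation_score(
    raster2d(matrix(1, 10, 10)), 90, data.frame(x = 5, y = 5))
  expect_equal(flat$value, 0)
  expect_identical(flat$flag, "degenerate-constant-surface")
})

test_that("logistic validation returns null AIC without signal and flags separation", {
  set.seed(9)
  surf <- raster2d(matrix(stats::runif(2500), 50, 50))
  used <- data.frame(x = stats::runif(150, 5, 45),
                     y = stats::runif(150, 5, 45))
  gpd <- structure(list(xi = 0, sigma = 5, fallback = FALSE,
                        loglik = NA_real_), class = "gpd_params")
  av <- available_points(used, surf, radius = 4, gpd = gpd, seed = 1)
  sc <- logistic_validation_score(surf, used, av)
  # noise surface: coefficient ~ 0, AIC within a few units of null + 2
  n_eff <- 2 * nrow(used)
  p0 <- nrow(used) / n_eff
  null_aic <- -2 * (nrow(used) * log(p0) + nrow(used) * log(1 - p0)) + 2
  expect_lt(abs(sc$value - (null_aic + 2)), 4)

  # a surface that perfectly separates used from available
  sep <- raster2d(matrix(0, 50, 50))
  ucells <- xy_cell(sep, used$x, used$y)
  sep$values[ucells] <- 1
  av0 <- lapply(av, function(a)
    list(cells = setdiff(a$cells, ucells), weights = NULL))
  av0 <- lapply(av0, function(a)
    list(cells = a$cells, weights = rep(1 / length(a$cells),
                                        length(a$cells))))
  sc2 <- logistic_validation_score(sep, used, av0)
  expect_identical(sc2$flag, "possible-separation")
})

test_that("ranking scores implement the weighted mid-rank convention", {
  surf <- raster2d(matrix(1:100, 10, 10))
  gpd <- structure(list(xi = 0, sigma = 5, fallback = FALSE,
                        loglik = NA_real_), class = "gpd_params")

  # used cell above every available one -> 100
  used <- data.frame(x = 9.5, y = 0.5)    # bottom-right, value 100
  av <- list(list(cells = 1:50, weights = rep(1 / 50, 50)))
  expect_equal(ranking_score(surf, used, av)$value, 100)

  # used tied with all available -> exactly 50
  flat <- raster2d(matrix(7, 10, 10))
  expect_equal(ranking_score(flat, used, av)$value, 50)

  # iid noise surface: mean percentile near 50
  set.seed(10)
  noise <- raster2d(matrix(stats::rnorm(2500), 50, 50))
  u2 <- data.frame(x = stats::runif(300, 5, 45),
                   y = stats::runif(300, 5, 45))
  av2 <- available_points(u2, noise, radius = 4, gpd = gpd, seed = 2)
  expect_lt(abs(ranking_score(noise, u2, av2)$value - 50), 3)
})

test_that("theta selection honours direction and breaks ties low", {
  mk <- function(vals, dir, meth = "m") {
    lapply(seq_along(vals), function(i)
      validation_score(meth, default_theta_grid()[i], vals[i], dir))
  }
  # monotone decreasing mse: the largest theta wins
  dec <- mk(seq(1, 0, length.out = 11), "lower")
  expect_equal(select_optimal_theta(dec), 0.01)
  # single entry
  one <- mk(0.4, "higher")[1]
  expect_equal(select_optimal_theta(one), 0)
  # ties break toward the smaller theta
  tied <- mk(c(1, 0, 0, rep(2, 8)), "lower")
  expect_equal(select_optimal_theta(tied), 5e-7)
  expect_error(select_optimal_theta(mk(c(1, 1), "lower")[c(1, 1)]),
               "one value per theta")
})

test_that("path-length correlation matches direct computation", {
  d <- data.frame(trajectory_id = 1:30, length_km = 1:30,
                  mean_score = -(1:30))
  expect_equal(path_length_correlation(d)$r, -1)
  set.seed(11)
  d$mean_score <- d$length_km + rnorm(30, 0, 5)
  r <- path_length_correlation(d)$r
  expect_true(r >= 0.8 && r <= 1)
  d$mean_score <- 7
  expect_identical(path_length_correlation(d)$flag, "zero-variance")
})
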