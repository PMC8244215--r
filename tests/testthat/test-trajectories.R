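test_that("a-LoCoH hulls cover points and grow with the distance budget", {
  set.seed(1)
  fx <- fixes_df(c(0, 10, 5, rnorm(7, 5, 1)), c(0, 0, 8, rnorm(7, 3, 1)))
  hr <- alocoh_home_range(fx, a_param = 1e6, isopleth = 1)
  # huge budget: one hull is the global hull; every fix inside
  expect_true(all(point_in_polygon(fx$x, fx$y, hr$hulls[[1]]) |
                    classify_fixes(fx, hr) == "territorial"))
  expect_equal(hr$coverage, 1)

  hr0 <- alocoh_home_range(fx, a_param = 0, isopleth = 1)
  expect_true(hr0$degenerate)

  # union area is non-decreasing in a_param
  areas <- sapply(c(2, 5, 20, 1e3), function(a) {
    h <- alocoh_home_range(fx, a_param = a, isopleth = 1)
    sum(sapply(h$hulls, rspaths:::polygon_area))
  })
  expect_true(all(diff(areas) >= -1e-9))
})

test_that("home ranges separate territorial from exploratory truth", {
  terr <- simulate_territorial_fixes(c(0, 0), home_sd = 400, n_fixes = 200,
                                     seed = 2)
  # dispersal-scale steps (km-scale, as in real exploratory movement),
  # with cross-track jitter so local hulls are long and thin
  set.seed(9)
  expl <- fixes_df(seq(3000, 150000, length.out = 50) + rnorm(50, 0, 400),
                   seq(2000, 110000, length.out = 50) + rnorm(50, 0, 400),
                   t = 800 + 4 * (0:49))
  expl$behavior_truth <- "exploratory"
  all_fx <- rbind(terr[c("animal_id", "t", "x", "y")],
                  expl[c("animal_id", "t", "x", "y")])
  hr <- alocoh_home_range(all_fx, a_param = "auto", isopleth = 0.8)
  lab <- classify_fixes(all_fx, hr)
  terr_ok <- mean(lab[1:200] == "territorial")
  expl_ok <- mean(lab[201:250] == "exploratory")
  expect_gte(terr_ok, 0.9)
  expect_gte(expl_ok, 0.8)
})

test_that("fix classification respects closed polygon boundaries", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  hr <- structure(list(hulls = list(sq), a_param = 1, isopleth = 1,
                       degenerate = FALSE, coverage = 1),
                  class = "home_range")
  fx <- fixes_df(c(5, 10, 50), c(5, 5, 50))
  expect_identical(classify_fixes(fx, hr),
                   c("territorial", "territorial", "exploratory"))
})

test_that("trajectory splitting cuts at nuclei, labels and reversals", {
  # straight path through one nucleus -> 2 trajectories
  fx <- fixes_df(seq(0, 100, by = 5), rep(0, 21))
  nuc <- nuclei_set(list(disk_poly <- cbind(c(45, 55, 55, 45),
                                            c(-5, -5, 5, 5))))
  tr <- split_trajectories(fx, nuclei = nuc)
  expect_length(tr, 2)
  # concatenated fixes reproduce the input (no discards here)
  back <- do.call(rbind, lapply(tr, `[[`, "fixes"))
  expect_equal(back$x, fx$x)

  # V-shaped 175-degree reversal with threshold 150 -> 2 trajectories
  out <- seq(0, 50, by = 5)
  ang <- (180 - 175) * pi / 180
  vx <- c(out, 50 - cumsum(rep(5 * cos(ang), 10)))
  vy <- c(rep(0, 11), cumsum(rep(5 * sin(ang), 10)))
  vfx <- fixes_df(vx, vy)
  expect_length(split_trajectories(vfx, turn_threshold = 150, window = 3),
                2)
  # same geometry, stricter threshold: no cut
  expect_length(split_trajectories(vfx, turn_threshold = 178, window = 3),
                1)

  # label change cut
  lab <- rep(c("exploratory", "territorial"), c(10, 11))
  expect_length(split_trajectories(fx, labels = lab), 2)

  # nothing triggers: single trajectory equal to input
  one <- split_trajectories(fx)
  expect_length(one, 1)
  expect_equal(one[[1]]$fixes$x, fx$x)
  expect_identical(split_trajectories(fx[0, ]), list())

  # short segments are discarded
  fx2 <- fixes_df(c(0, 5, 10, 15, 20, 25), rep(0, 6))
  lab2 <- c("e", "e", "e", "e", "e", "t")   # last segment has 1 fix
  tr2 <- split_trajectories(fx2, labels = lab2)
  expect_length(tr2, 1)
  expect_equal(nrow(tr2[[1]]$fixes), 5)
})

test_that("trajectory container computes lengths and durations", {
  fx <- fixes_df(c(0, 3000, 3000), c(0, 0, 4000))
  tr <- trajectory(fx, id = "t1")
  expect_equal(tr$length_km, 7)
  expect_equal(tr$duration_days, 8 / 24)
  expect_equal(nrow(tr$inbetween), 1)
  expect_gte(tr$length_km * 1000,
             sqrt(diff(range(fx$x))^2 + diff(range(fx$y))^2))
  expect_error(trajectory(fx[1, , drop = FALSE]), "2")
})

test_that("displacement percentile interpolates and is monotone in q", {
  fx <- fixes_df(cumsum(c(0, 1, 2, 3, 4)), rep(0, 5))
  expect_equal(displacement_percentile(fx, 0.5), 2.5)
  qs <- c(0.1, 0.5, 0.9, 0.99)
  vals <- sapply(qs, function(q) displacement_percentile(fx, q))
  expect_true(all(diff(vals) >= 0))

  same <- fixes_df(seq(0, 40, by = 4), rep(0, 11))
  expect_equal(displacement_percentile(same, 0.25), 4)
  expect_equal(displacement_percentile(same, 0.99), 4)
  expect_error(displacement_percentile(fx, 1.2), "q")

  # gap exclusion: a pair across a data gap does not contribute
  gap <- fixes_df(c(0, 1, 2, 500), c(0, 0, 0, 0), t = c(0, 4, 8, 100))
  expect_lte(displacement_percentile(gap, 0.99), 1)
})

test_that("gpd fit recovers parameters and degrades gracefully", {
  set.seed(3)
  # inverse-cdf sampling from GPD(xi = 0.2, sigma = 500)
  u <- stats::runif(5000)
  x <- 500 / 0.2 * ((1 - u)^(-0.2) - 1)
  fit <- fit_gpd(x)
  expect_false(fit$fallback)
  expect_lt(abs(fit$xi - 0.2) / 0.2, 0.5)
  expect_lt(abs(fit$sigma - 500) / 500, 0.1)

  expo <- stats::rexp(5000, rate = 1 / 300)
  fit0 <- fit_gpd(expo)
  expect_lt(abs(fit0$xi), 0.1)

  const <- fit_gpd(rep(5, 100))
  expect_true(const$fallback)

  # density is non-increasing for xi >= 0 and integrates the weights
  g <- structure(list(xi = 0.2, sigma = 500, fallback = FALSE,
                      loglik = NA_real_), class = "gpd_params")
  d <- gpd_density(seq(0, 5000, by = 100), g)
  expect_true(all(diff(d) <= 0))
  expect_error(fit_gpd(c(1, 2, 3)), "30")
})

test_that("animal partition reserves the longest movers for validation", {
  mk <- function(animal, span) {
    trajectory(fixes_df(c(0, span / 2, span), c(0, 0, 0), animal = animal),
               id = animal)
  }
  trajs <- list(mk("a", 1000), mk("b", 9000), mk("c", 5000), mk("a", 200))
  p <- partition_by_movement(trajs, n_val = 2)
  expect_setequal(p$validation, c("b", "c"))
  expect_setequal(p$train, "a")
})
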