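#' Validation scores for theta selection
#'
#' Each of the four validation methods reduces one connectivity surface
#' (one theta) and the held-out telemetry to a single score with a fixed
#' optimisation direction: mean squared error against a Brownian-bridge
#' occupancy surface (lower better), percentage of fixes inside
#' percentile corridors (higher better), AIC of a logistic
#' used-versus-available fit on surface values (lower better), and the
#' mean weighted percentile rank of used over available surface values
#' (higher better).
#'
#' @param method one of `"brownian_bridge"`, `"corridors"`,
#'   `"logistic"`, `"ranking"`.
#' @param theta the theta the scored surface was computed at.
#' @param value score value.
#' @param direction `"lower"` or `"higher"` is better.
#' @param detail optional per-trajectory or per-fix breakdown.
#' @param flag optional degeneracy flag.
#' @return a `validation_score`.
#' @export
validation_score <- function(method, theta, value, direction,
                             detail = NULL, flag = NULL) {
  stopifnot(direction %in% c("lower", "higher"),
            is.na(theta) || is.finite(theta))
  structure(list(method = method, theta = theta, value = value,
                 direction = direction, detail = detail, flag = flag),
            class = "validation_score")
}

#' @export
print.validation_score <- function(x, ...) {
  cat(sprintf("validation_score: %s, theta = %g, value = %g (%s better)%s\n",
              x$method, x$theta, x$value, x$direction,
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Default theta grid
#'
#' Eleven values from the pure random walk (0) to a smoothed least-cost
#' path (0.01); the admissible upper limit depends on graph size and
#' conductance scale.
#'
#' @return numeric vector of 11 increasing theta values.
#' @export
default_theta_grid <- function() {
  c(0, 5e-7, 1e-6, 5e-6, 1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2)
}

#' Estimate Brownian-bridge motion variance
#'
#' Leave-one-out maximum likelihood: each interior fix is scored under
#' the bridge between its two neighbours, whose normal law has mean at
#' the time-interpolated point and variance
#' `T a (1 - a) sigma_m^2 + ((1 - a)^2 + a^2) delta^2` per coordinate
#' (`a` the fractional time of the middle fix, `T` the segment duration,
#' `delta` the GPS error sd). `sigma_m` maximises the summed
#' log-likelihood by 1-D bounded search; hitting a bound is flagged.
#'
#' @param traj a `trajectory` (>= 3 fixes).
#' @param delta GPS error sd in map units.
#' @param lower,upper search bounds for `sigma_m` (map units per sqrt
#'   hour).
#' @return list with `sigma_m`, `at_bound` flag, `loglik`.
#' @export
estimate_bb_sigma <- function(traj, delta = 0, lower = 1e-4,
                              upper = 1e5) {
  stopifnot(inherits(traj, "trajectory"))
  fx <- traj$fixes
  n <- nrow(fx)
  if (n < 3L) stop("need at least 3 fixes")
  if (delta < 0) stop("'delta' must be >= 0")
  i <- 2:(n - 1L)
  t0 <- fx$t[i - 1L]; t1 <- fx$t[i]; t2 <- fx$t[i + 1L]
  a <- (t1 - t0) / (t2 - t0)
  Tt <- t2 - t0
  mx <- (1 - a) * fx$x[i - 1L] + a * fx$x[i + 1L]
  my <- (1 - a) * fx$y[i - 1L] + a * fx$y[i + 1L]
  dev2 <- (fx$x[i] - mx)^2 + (fx$y[i] - my)^2
  nll <- function(logsm) {
    sm <- exp(logsm)
    v <- Tt * a * (1 - a) * sm^2 + ((1 - a)^2 + a^2) * delta^2
    if (any(v <= 0)) return(1e12)
    sum(log(2 * pi * v) + dev2 / (2 * v))
  }
  opt <- stats::optimize(nll, log(c(lower, upper)), tol = 1e-8)
  at_bound <- opt$minimum <= log(lower) + 1e-3 ||
    opt$minimum >= log(upper) - 1e-3
  list(sigma_m = exp(opt$minimum), at_bound = at_bound,
       loglik = -opt$objective)
}

#' Brownian-bridge occupancy surface
#'
#' For every consecutive-fix segment of every trajectory, the bridge
#' density is evaluated at `n_steps` fractional times and accumulated on
#' the grid (each segment weighted by its duration), then normalised to
#' sum 1 over the non-nodata cells. Evaluation is windowed to 5 sd
#' around each bridge mean. Zero-duration segments are skipped with a
#' warning.
#'
#' @param trajs list of `trajectory` objects.
#' @param grid a `raster2d` supplying the geometry (values unused).
#' @param sigma_m Brownian motion sd (map units per sqrt hour); a scalar
#'   shared by all trajectories or a vector with one value per
#'   trajectory.
#' @param delta GPS error sd (map units); `sigma_m` and `delta` must not
#'   both be zero.
#' @param n_steps bridge time steps per segment.
#' @return a `raster2d` occupancy surface summing to 1.
#' @export
brownian_bridge_surface <- function(trajs, grid, sigma_m, delta = 0,
                                    n_steps = 10L) {
  stopifnot(is_raster2d(grid), all(sigma_m >= 0), delta >= 0)
  if (all(sigma_m == 0) && delta == 0)
    stop("sigma_m and delta cannot both be zero")
  sigma_m <- rep_len(sigma_m, length(trajs))
  d <- dim(grid$values)
  acc <- matrix(0, d[1], d[2])
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  for (ti in seq_along(trajs)) {
    tr <- trajs[[ti]]
    sm <- sigma_m[ti]
    fx <- tr$fixes
    for (s in seq_len(nrow(fx) - 1L)) {
      Tt <- fx$t[s + 1L] - fx$t[s]
      if (Tt <= 0) {
        warning("zero-duration segment skipped")
        next
      }
      for (a in alphas) {
        mx <- (1 - a) * fx$x[s] + a * fx$x[s + 1L]
        my <- (1 - a) * fx$y[s] + a * fx$y[s + 1L]
        v <- Tt * a * (1 - a) * sm^2 + ((1 - a)^2 + a^2) * delta^2
        acc <- add_gauss(acc, grid, mx, my, v, Tt / n_steps)
      }
    }
  }
  acc[is.na(grid$values)] <- NA_real_
  tot <- sum(acc, na.rm = TRUE)
  if (tot > 0) acc <- acc / tot
  raster2d(acc, res = grid$res, xll = grid$xll, yll = grid$yll)
}

# accumulate an isotropic Gaussian (variance v per coordinate) evaluated
# at cell centres within 5 sd of (mx, my), scaled by weight w
add_gauss <- function(acc, grid, mx, my, v, w) {
  d <- dim(acc)
  res <- grid$res
  sd5 <- 5 * sqrt(v)
  col0 <- floor((mx - sd5 - grid$xll) / res) + 1L
  col1 <- floor((mx + sd5 - grid$xll) / res) + 1L
  rtop <- d[1] - floor((my + sd5 - grid$yll) / res)
  rbot <- d[1] - floor((my - sd5 - grid$yll) / res)
  cols <- max(1L, col0):min(d[2], col1)
  rows <- max(1L, rtop):min(d[1], rbot)
  if (length(cols) == 0L || length(rows) == 0L) return(acc)
  cx <- grid$xll + (cols - 0.5) * res
  cy <- grid$yll + (d[1] - rows + 0.5) * res
  dens <- outer(stats::dnorm(cy, my, sqrt(v)),
                stats::dnorm(cx, mx, sqrt(v)))
  acc[rows, cols] <- acc[rows, cols] + w * dens
  acc
}

#' Mean-squared-error score against a Brownian-bridge surface
#'
#' Both surfaces are normalised to unit sum over their shared non-nodata
#' cells before comparison (they live on different natural scales);
#' the score is the mean squared cellwise difference. Lower is better.
#'
#' @param rsp_surface connectivity `raster2d` for one theta.
#' @param bb_surface Brownian-bridge occupancy `raster2d`.
#' @param theta theta recorded on the score.
#' @return a `validation_score` (`method = "brownian_bridge"`).
#' @export
mse_score <- function(rsp_surface, bb_surface, theta = NA_real_) {
  stopifnot(is_raster2d(rsp_surface), is_raster2d(bb_surface))
  stop_if_geometry_differs(rsp_surface, bb_surface)
  ok <- !is.na(rsp_surface$values) & !is.na(bb_surface$values)
  a <- rsp_surface$values[ok]; b <- bb_surface$values[ok]
  if (sum(a) > 0) a <- a / sum(a)
  if (sum(b) > 0) b <- b / sum(b)
  validation_score("brownian_bridge", theta, mean((a - b)^2), "lower")
}

#' Representation-in-corridors score
#'
#' Corridor mask = cells at or above the given percentile of the
#' non-nodata surface values; the score is the percentage of validation
#' fixes falling inside the mask. A constant surface makes the mask
#' degenerate and scores 0 with a flag. Higher is better.
#'
#' @param surface connectivity `raster2d`.
#' @param percentile corridor percentile (85, 90, 95, 99 in the standard
#'   design; any value in (0, 100) is accepted).
#' @param validation_fixes data.frame of fixes.
#' @param theta theta recorded on the score.
#' @return a `validation_score` (`method = "corridors"`), with the
#'   per-fix inside indicator in `detail`.
#' @export
corridor_representation_score <- function(surface, percentile,
                                          validation_fixes,
                                          theta = NA_real_) {
  stopifnot(is_raster2d(surface), nrow(validation_fixes) >= 1L,
            percentile > 0, percentile < 100)
  vals <- surface$values[!is.na(surface$values)]
  if (stats::sd(vals) == 0)
    return(validation_score("corridors", theta, 0, "higher",
                            flag = "degenerate-constant-surface"))
  thr <- stats::quantile(vals, percentile / 100, type = 7)
  cells <- xy_cell(surface, validation_fixes$x, validation_fixes$y)
  inside <- !is.na(cells) & !is.na(surface$values[cells]) &
    surface$values[cells] >= thr
  validation_score("corridors", theta, 100 * mean(inside), "higher",
                   detail = inside)
}

#' Sample weighted available points around used fixes
#'
#' For each used fix, all cells within `radius` carry a GPD distance
#' weight; above `max_cells` cells a seeded subsample (probability
#' proportional to weight) caps the stratum. Shared by the logistic and
#' ranking validations so both see identical availability.
#'
#' @param fixes data.frame of used fixes.
#' @param grid a `raster2d` giving geometry and nodata.
#' @param radius availability radius (map units).
#' @param gpd a `gpd_params`.
#' @param max_cells per-fix cap (default 5000).
#' @param seed integer seed for the capped subsampling.
#' @return list (one per fix) of lists with `cells`, `weights`.
#' @export
available_points <- function(fixes, grid, radius, gpd, max_cells = 5000L,
                             seed = 1L) {
  stopifnot(is_raster2d(grid), inherits(gpd, "gpd_params"))
  set.seed(as.integer(seed))
  lapply(seq_len(nrow(fixes)), function(i) {
    disk <- disk_cells(grid, fixes$x[i], fixes$y[i], radius)
    w <- gpd_density(disk$dist, gpd)
    if (sum(w) <= 0) w <- rep(1, length(w))
    if (length(disk$cells) > max_cells) {
      pick <- sample.int(length(disk$cells), max_cells, prob = w)
      disk$cells <- disk$cells[pick]
      w <- w[pick]
    }
    list(cells = disk$cells, weights = w / sum(w))
  })
}

#' Logistic-regression validation score (AIC)
#'
#' Pools used (1) and available (0) points, regresses the role on the
#' surface value at each point by weighted logistic regression (each
#' stratum's available weights sum to 1, the used point weighs 1), and
#' reports the Akaike information criterion computed from the weighted
#' Bernoulli log-likelihood. A zero-variance predictor returns the null
#' model's AIC with a flag. Lower is better.
#'
#' @param surface connectivity `raster2d`.
#' @param used data.frame of used fixes.
#' @param available output of [available_points()] aligned with `used`.
#' @param theta theta recorded on the score.
#' @return a `validation_score` (`method = "logistic"`).
#' @export
logistic_validation_score <- function(surface, used, available,
                                      theta = NA_real_) {
  stopifnot(is_raster2d(surface), nrow(used) == length(available))
  ucells <- xy_cell(surface, used$x, used$y)
  xs <- c(); ys <- c(); ws <- c()
  for (i in seq_along(available)) {
    uv <- if (is.na(ucells[i])) NA_real_ else surface$values[ucells[i]]
    av <- surface$values[available[[i]]$cells]
    ok <- !is.na(av)
    if (is.na(uv) || !any(ok)) next
    xs <- c(xs, uv, av[ok])
    ys <- c(ys, 1L, rep(0L, sum(ok)))
    ws <- c(ws, 1, available[[i]]$weights[ok] /
              sum(available[[i]]$weights[ok]))
  }
  if (length(xs) == 0L) stop("no scorable fixes")
  if (stats::sd(xs) == 0) {
    ll0 <- weighted_bernoulli_ll(rep(stats::weighted.mean(ys, ws),
                                     length(ys)), ys, ws)
    return(validation_score("logistic", theta, -2 * ll0 + 2, "lower",
                            flag = "zero-variance-predictor"))
  }
  fit <- suppressWarnings(stats::glm(ys ~ xs, weights = ws,
                                     family = stats::binomial()))
  p <- stats::fitted(fit)
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 100)
  flag <- if (sep) "possible-separation" else NULL
  aic <- -2 * weighted_bernoulli_ll(p, ys, ws) + 2 * 2
  validation_score("logistic", theta, aic, "lower", flag = flag)
}

weighted_bernoulli_ll <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Ranking validation score
#'
#' For each used fix the score is the weighted percentile position of
#' its surface value among the available values: 100 times the weight of
#' strictly smaller available values plus half the weight of ties,
#' divided by the total weight (mid-rank convention). The method score
#' is the mean over used fixes; 50 is the uninformative-surface
#' expectation. Higher is better.
#'
#' @inheritParams logistic_validation_score
#' @return a `validation_score` (`method = "ranking"`), per-fix
#'   percentiles in `detail`.
#' @export
ranking_score <- function(surface, used, available, theta = NA_real_) {
  stopifnot(is_raster2d(surface), nrow(used) == length(available))
  ucells <- xy_cell(surface, used$x, used$y)
  pct <- rep(NA_real_, nrow(used))
  for (i in seq_along(available)) {
    uv <- if (is.na(ucells[i])) NA_real_ else surface$values[ucells[i]]
    av <- surface$values[available[[i]]$cells]
    w <- available[[i]]$weights
    ok <- !is.na(av)
    if (is.na(uv) || !any(ok)) next
    av <- av[ok]; w <- w[ok] / sum(w[ok])
    pct[i] <- 100 * (sum(w[av < uv]) + 0.5 * sum(w[av == uv]))
  }
  if (all(is.na(pct))) stop("no scorable fixes")
  validation_score("ranking", theta, mean(pct, na.rm = TRUE), "higher",
                   detail = pct)
}

#' Select the optimal theta from a method's score list
#'
#' Argmin or argmax according to the method's direction; ties break
#' toward the smaller theta.
#'
#' @param scores list of `validation_score` objects of one method, one
#'   per theta of a grid.
#' @return the optimal theta.
#' @export
select_optimal_theta <- function(scores) {
  stopifnot(length(scores) >= 1L,
            all(vapply(scores, inherits, logical(1), "validation_score")))
  meth <- unique(vapply(scores, `[[`, character(1), "method"))
  dirn <- unique(vapply(scores, `[[`, character(1), "direction"))
  if (length(meth) != 1L || length(dirn) != 1L)
    stop("scores must all come from one method")
  th <- vapply(scores, `[[`, numeric(1), "theta")
  if (anyNA(th) || anyDuplicated(th))
    stop("scores must carry one value per theta")
  val <- vapply(scores, `[[`, numeric(1), "value")
  ord <- order(th)
  th <- th[ord]; val <- val[ord]
  best <- if (dirn == "lower") which(val == min(val)) else
    which(val == max(val))
  th[best[1L]]
}

#' Correlation between path length and per-path validation score
#'
#' @param per_path data.frame with columns `trajectory_id`, `length_km`,
#'   `mean_score` (>= 3 rows).
#' @return list with Pearson `r` and a `flag` when a zero-variance
#'   column leaves the correlation undefined.
#' @export
path_length_correlation <- function(per_path) {
  stopifnot(is.data.frame(per_path), nrow(per_path) >= 3L,
            all(c("length_km", "mean_score") %in% names(per_path)))
  if (stats::sd(per_path$length_km) == 0 ||
      stats::sd(per_path$mean_score) == 0)
    return(list(r = NA_real_, flag = "zero-variance"))
  list(r = stats::cor(per_path$length_km, per_path$mean_score),
       flag = NULL)
}
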