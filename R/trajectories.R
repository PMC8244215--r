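#' Telemetry fixes and trajectories
#'
#' Fixes are plain data.frames with columns `animal_id`, `t` (hours),
#' `x`, `y` (map units) and optionally a behaviour label. A `trajectory`
#' wraps an ordered run of fixes between a source and a destination.
#'
#' @param fixes data.frame of time-ordered fixes of one animal.
#' @param id trajectory id.
#' @return a `trajectory`: list with `fixes`, `id`, `source`, `dest`,
#'   `inbetween` (fixes without the endpoints), `length_km` (summed
#'   straight-line steps) and `duration_days`.
#' @export
trajectory <- function(fixes, id = 1L) {
  stopifnot(is.data.frame(fixes), nrow(fixes) >= 2L)
  if (is.unsorted(fixes$t, strictly = TRUE))
    stop("fix timestamps must be strictly increasing")
  steps <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2)
  structure(
    list(fixes = fixes, id = id,
         source = fixes[1L, , drop = FALSE],
         dest = fixes[nrow(fixes), , drop = FALSE],
         inbetween = fixes[-c(1L, nrow(fixes)), , drop = FALSE],
         length_km = sum(steps) / 1000,
         duration_days = (fixes$t[nrow(fixes)] - fixes$t[1L]) / 24),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory %s: %d fixes, %.2f km, %.2f days\n",
              x$id, nrow(x$fixes), x$length_km, x$duration_days))
  invisible(x)
}

#' Read/write telemetry fixes as CSV
#'
#' Columns `animal_id,t,x,y` plus any extra columns present (e.g.
#' `behavior`, `behavior_truth`).
#'
#' @param fixes data.frame of fixes.
#' @param path file path.
#' @export
write_fixes_csv <- function(fixes, path) {
  utils::write.csv(fixes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes_csv
#' @export
read_fixes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' a-LoCoH home range
#'
#' Adaptive local convex hulls: for each fix (root point) the nearest
#' neighbours are added in order of increasing distance while their
#' cumulative distance to the root stays within `a_param`; the local hull
#' is the convex hull of the root and the included neighbours. Hulls are
#' sorted by area and accumulated, smallest first, until they jointly
#' contain at least `isopleth` of the fixes; the home range is the union
#' of the retained hulls. Degenerate (collinear or < 3 point) hulls fall
#' back to a thin buffered segment and are flagged.
#'
#' @param fixes data.frame of one animal's fixes.
#' @param a_param distance budget in map units, or `"auto"` (maximum
#'   pairwise fix distance).
#' @param isopleth fraction of fixes the union must contain (default 1).
#' @return a `home_range`: list with `hulls` (vertex matrices),
#'   `a_param`, `isopleth`, `degenerate` (flag), `coverage` (achieved
#'   fraction).
#' @export
alocoh_home_range <- function(fixes, a_param = "auto", isopleth = 1) {
  stopifnot(is.data.frame(fixes))
  n <- nrow(fixes)
  if (n < 10L) stop("need at least 10 fixes to build a home range")
  if (isopleth <= 0 || isopleth > 1) stop("'isopleth' must be in (0, 1]")
  pts <- cbind(fixes$x, fixes$y)
  dmat <- as.matrix(stats::dist(pts))
  if (identical(a_param, "auto")) a_param <- max(dmat)
  stopifnot(is.numeric(a_param), a_param >= 0)

  degenerate <- FALSE
  hulls <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(dmat[i, ])
    ord <- ord[ord != i]
    keep <- ord[cumsum(dmat[i, ord]) <= a_param]
    hp <- pts[unique(c(i, keep)), , drop = FALSE]
    if (nrow(unique(hp)) >= 3L) {
      h <- grDevices::chull(hp)
      hull <- hp[h, , drop = FALSE]
      if (polygon_area(hull) == 0) hull <- buffered_segment(hp)
    } else {
      hull <- buffered_segment(hp)
    }
    if (polygon_area(hull) == 0) degenerate <- TRUE
    hulls[[i]] <- hull
    areas[i] <- polygon_area(hull)
  }

  ord <- order(areas)
  inside <- rep(FALSE, n)
  chosen <- integer(0)
  cover <- 0
  for (i in ord) {
    chosen <- c(chosen, i)
    inside <- inside | point_in_polygon(pts[, 1], pts[, 2], hulls[[i]])
    cover <- mean(inside)
    if (cover >= isopleth) break
  }
  structure(list(hulls = hulls[chosen], a_param = a_param,
                 isopleth = isopleth, degenerate = degenerate,
                 coverage = cover),
            class = "home_range")
}

# thin rectangle around a (possibly zero-length) point run; keeps the
# hull machinery total on collinear inputs
buffered_segment <- function(pts, eps = 1e-6) {
  a <- pts[which.min(pts[, 1] + pts[, 2]), ]
  b <- pts[which.max(pts[, 1] + pts[, 2]), ]
  d <- b - a
  len <- sqrt(sum(d^2))
  u <- if (len == 0) c(1, 0) else d / len
  v <- c(-u[2], u[1]) * eps
  rbind(a + v, b + v, b - v, a - v)
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range: %d hulls (a = %g, isopleth %g, coverage %.2f)%s\n",
              length(x$hulls), x$a_param, x$isopleth, x$coverage,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Classify fixes as territorial or exploratory
#'
#' A fix inside the home-range union (boundary included) is territorial;
#' anything else is exploratory.
#'
#' @param fixes data.frame of fixes.
#' @param home_range a `home_range` for the same animal.
#' @return character vector of labels.
#' @export
classify_fixes <- function(fixes, home_range) {
  stopifnot(inherits(home_range, "home_range"))
  inside <- rep(FALSE, nrow(fixes))
  for (h in home_range$hulls)
    inside <- inside | point_in_polygon(fixes$x, fixes$y, h)
  ifelse(inside, "territorial", "exploratory")
}

#' Split exploratory fixes into source-destination trajectories
#'
#' Fixes of each animal are cut (i) after a fix falling inside a
#' population nucleus, (ii) at a change of behavioural label, and (iii)
#' where the general heading nearly reverses: the angle between the mean
#' displacement vectors of the `window` steps before and after a fix
#' reaches `turn_threshold` degrees. Segments shorter than 3 fixes are
#' discarded; concatenating the retained segments reproduces the input
#' fixes minus the discarded ones.
#'
#' @param fixes time-ordered data.frame of fixes (may mix animals).
#' @param nuclei a `nuclei_set` (or `NULL` to skip nucleus cuts).
#' @param labels behaviour labels aligned with `fixes` (or `NULL`).
#' @param turn_threshold heading-reversal cut angle in degrees.
#' @param window steps on each side of the candidate cut.
#' @return list of `trajectory` objects.
#' @export
split_trajectories <- function(fixes, nuclei = NULL, labels = NULL,
                               turn_threshold = 150, window = 3L) {
  if (nrow(fixes) == 0L) return(list())
  out <- list()
  for (animal in unique(fixes$animal_id)) {
    sel <- fixes$animal_id == animal
    fx <- fixes[sel, , drop = FALSE]
    lb <- if (is.null(labels)) NULL else labels[sel]
    n <- nrow(fx)
    cut_after <- rep(FALSE, n)  # TRUE at i: segment ends at fix i
    if (!is.null(nuclei) && length(nuclei$polygons) > 0) {
      innuc <- nucleus_containing(nuclei, fx$x, fx$y) > 0L
      # cut when entering a nucleus (fix inside ends the segment)
      cut_after <- cut_after | (innuc & !c(FALSE, innuc[-n]))
    }
    if (!is.null(lb) && n > 1L)
      cut_after[seq_len(n - 1L)] <- cut_after[seq_len(n - 1L)] |
        lb[-n] != lb[-1L]
    if (n > 2L && window >= 1L) {
      dx <- diff(fx$x); dy <- diff(fx$y)
      for (i in seq_len(n - 1L)[-1L]) {   # interior fixes
        pre <- max(1L, i - window):(i - 1L)
        post <- i:min(n - 1L, i + window - 1L)
        v1 <- c(sum(dx[pre]), sum(dy[pre]))
        v2 <- c(sum(dx[post]), sum(dy[post]))
        n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
        if (n1 == 0 || n2 == 0) next
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
        if (ang >= turn_threshold) cut_after[i] <- TRUE
      }
    }
    cut_after[n] <- TRUE
    starts <- c(1L, which(cut_after)[-sum(cut_after)] + 1L)
    ends <- which(cut_after)
    for (s in seq_along(starts)) {
      seg <- fx[starts[s]:ends[s], , drop = FALSE]
      if (nrow(seg) < 3L) next
      out[[length(out) + 1L]] <-
        trajectory(seg, id = sprintf("%s_%02d", animal, s))
    }
  }
  out
}

#' Percentile of consecutive-step displacements
#'
#' Empirical quantile (linear interpolation) of the straight-line
#' distances between consecutive fixes at the nominal fix interval;
#' pairs separated by data gaps (interval > `interval_tol` times the
#' nominal interval) are excluded. The 0.99 quantile is the availability
#' radius used by the habitat and validation modules.
#'
#' @param fixes data.frame of one or more animals' time-ordered fixes.
#' @param q quantile in (0, 1).
#' @param interval_tol multiple of the nominal (median) interval beyond
#'   which a pair counts as a gap.
#' @return displacement radius in map units.
#' @export
displacement_percentile <- function(fixes, q = 0.99, interval_tol = 1.5) {
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  steps <- consecutive_steps(fixes, interval_tol)
  if (length(steps) == 0L) stop("no consecutive fix pairs at the nominal interval")
  as.numeric(stats::quantile(steps, q, type = 7))
}

consecutive_steps <- function(fixes, interval_tol = 1.5) {
  steps <- numeric(0)
  for (animal in unique(fixes$animal_id)) {
    fx <- fixes[fixes$animal_id == animal, , drop = FALSE]
    if (nrow(fx) < 2L) next
    dt <- diff(fx$t)
    nominal <- stats::median(dt)
    ok <- dt <= interval_tol * nominal
    d <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
    steps <- c(steps, d[ok])
  }
  steps
}

#' Generalized Pareto distance weights
#'
#' `fit_gpd` fits a generalized Pareto distribution with location 0 to
#' positive step lengths by maximum likelihood (L-BFGS-B on `(log sigma,
#' xi)`), falling back to method-of-moments estimates with a flag when
#' the optimiser fails. `gpd_density` evaluates the fitted density, used
#' as the distance weight for available habitat.
#'
#' @param step_lengths positive displacements (map units), >= 30 values.
#' @return `fit_gpd`: a `gpd_params` list with `xi` (shape), `sigma`
#'   (scale), `fallback` flag and `loglik`.
#' @export
fit_gpd <- function(step_lengths) {
  x <- step_lengths[is.finite(step_lengths) & step_lengths > 0]
  if (length(x) < 30L) stop("need at least 30 positive step lengths")
  mom <- gpd_moments(x)
  if (stats::sd(x) == 0) {
    return(structure(list(xi = 0, sigma = mean(x), fallback = TRUE,
                          loglik = NA_real_), class = "gpd_params"))
  }
  nll <- function(par) {
    sigma <- exp(par[1]); xi <- par[2]
    if (xi >= 0) {
      z <- 1 + xi * x / sigma
    } else {
      if (max(x) >= -sigma / xi) return(1e10)
      z <- 1 + xi * x / sigma
    }
    if (any(z <= 0)) return(1e10)
    if (abs(xi) < 1e-8) sum(log(sigma) + x / sigma)
    else sum(log(sigma) + (1 / xi + 1) * log(z))
  }
  start <- c(log(max(mom$sigma, 1e-8)), max(min(mom$xi, 0.8), -0.4))
  fit <- try(stats::optim(start, nll, method = "L-BFGS-B",
                          lower = c(-20, -0.95), upper = c(50, 5)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value) ||
      fit$value >= 1e9) {
    return(structure(list(xi = mom$xi, sigma = mom$sigma, fallback = TRUE,
                          loglik = NA_real_), class = "gpd_params"))
  }
  structure(list(xi = fit$par[2], sigma = exp(fit$par[1]),
                 fallback = FALSE, loglik = -fit$value),
            class = "gpd_params")
}

gpd_moments <- function(x) {
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(list(xi = 0, sigma = m))
  xi <- (1 - m^2 / v) / 2
  list(xi = xi, sigma = m * (1 - xi))
}

#' @rdname fit_gpd
#' @param d distances (>= 0).
#' @param gpd a `gpd_params`.
#' @export
gpd_density <- function(d, gpd) {
  stopifnot(inherits(gpd, "gpd_params"))
  sigma <- gpd$sigma; xi <- gpd$xi
  if (abs(xi) < 1e-8) return(exp(-d / sigma) / sigma)
  z <- 1 + xi * d / sigma
  out <- numeric(length(d))
  ok <- z > 0
  out[ok] <- (1 / sigma) * z[ok]^(-(1 / xi + 1))
  out
}

#' @export
print.gpd_params <- function(x, ...) {
  cat(sprintf("gpd_params: xi = %.4f, sigma = %.4g%s\n", x$xi, x$sigma,
              if (x$fallback) " [moment fallback]" else ""))
  invisible(x)
}

#' Per-animal train/validation partition by movement extent
#'
#' Ranks animals by the length of their longest trajectory and reserves
#' the top `n_val` animals for validation — the animals with the longest
#' inter-nuclei movements — keeping each animal wholly on one side.
#'
#' @param trajs list of `trajectory` objects.
#' @param n_val number of validation animals.
#' @return list with character vectors `train` and `validation`.
#' @export
partition_by_movement <- function(trajs, n_val) {
  stopifnot(length(trajs) > 0L, n_val >= 0)
  animals <- vapply(trajs, function(tr) tr$fixes$animal_id[1], character(1))
  lens <- vapply(trajs, function(tr) tr$length_km, numeric(1))
  best <- tapply(lens, animals, max)
  ord <- names(sort(best, decreasing = TRUE))
  n_val <- min(n_val, length(ord))
  list(validation = ord[seq_len(n_val)],
       train = setdiff(ord, ord[seq_len(n_val)]))
}
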