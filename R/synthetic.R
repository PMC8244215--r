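#' Synthetic landscapes, nuclei and telemetry
#'
#' The study data this pipeline was designed for (multi-year GPS
#' telemetry of a territorial carnivore) are not openly available, so the
#' package ships a generative stand-in with the statistical structure the
#' analysis assumes: spatially autocorrelated categorical land cover with
#' known class selection strengths, population nuclei placed in
#' high-conductance terrain, territorial fixes from a mean-reverting
#' wander, and exploratory trajectories sampled *exactly* from the RSP
#' path distribution at a known theta, so that parameter-recovery tests
#' have a ground truth.
#'
#' @name synthetic
NULL

#' Generate an autocorrelated categorical landscape
#'
#' Draws one Gaussian white-noise field per class, smooths each with a
#' Gaussian kernel of sd `autocorr_range` cells, and assigns each cell to
#' the class whose smoothed field is largest. The result is returned as
#' one-hot per-class proportion layers (a `landcover_stack`), mirroring a
#' classified land-cover map at native resolution.
#'
#' @param n_rows,n_cols grid dimensions (positive).
#' @param n_classes number of cover classes (>= 2).
#' @param autocorr_range smoothing sd in cells (>= 1); typical patch
#'   diameter grows with it.
#' @param seed integer seed; fixed seed gives identical output.
#' @param res,xll,yll grid geometry (map units).
#' @return a `landcover_stack`: list with `layers` (named list of
#'   `raster2d`, values in \{0,1\}), `classes`, `res`.
#' @export
generate_landscape <- function(n_rows, n_cols, n_classes, autocorr_range,
                               seed, res = 125, xll = 0, yll = 0) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be positive")
  if (n_classes < 2) stop("need at least 2 classes")
  if (autocorr_range < 1) stop("'autocorr_range' must be >= 1")
  set.seed(as.integer(seed))
  fields <- lapply(seq_len(n_classes), function(k) {
    noise <- raster2d(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                      res = res, xll = xll, yll = yll)
    gaussian_blur(noise, autocorr_range)$values
  })
  winner <- matrix(1L, n_rows, n_cols)
  best <- fields[[1]]
  for (k in seq_len(n_classes)[-1]) {
    better <- fields[[k]] > best
    winner[better] <- k
    best[better] <- fields[[k]][better]
  }
  classes <- paste0("class_", LETTERS[seq_len(n_classes)])
  layers <- lapply(seq_len(n_classes), function(k)
    raster2d((winner == k) * 1, res = res, xll = xll, yll = yll))
  names(layers) <- classes
  structure(list(layers = layers, classes = classes, res = res),
            class = "landcover_stack")
}

#' @export
print.landcover_stack <- function(x, ...) {
  d <- dim(x$layers[[1]]$values)
  cat(sprintf("landcover_stack: %d classes (%s), %d x %d cells, res %g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              d[1], d[2], x$res))
  invisible(x)
}

#' Ground-truth conductance from known selection coefficients
#'
#' Per-cell conductance `= plogis(sum_k beta_k * proportion_k)`, with the
#' reference class contributing zero — the same link used by
#' [predict_conductance()], so surfaces built here are exactly
#' recoverable by a point-selection-function fit with the true
#' coefficients.
#'
#' @param stack a `landcover_stack`.
#' @param beta_true named numeric vector, one coefficient per
#'   non-reference class.
#' @param reference_class class name carrying coefficient 0.
#' @return a `raster2d` of conductance values in (0, 1).
#' @export
conductance_from_truth <- function(stack, beta_true, reference_class) {
  stopifnot(inherits(stack, "landcover_stack"))
  if (!reference_class %in% stack$classes)
    stop("unknown reference class: ", reference_class)
  other <- setdiff(stack$classes, reference_class)
  if (!setequal(names(beta_true), other))
    stop("'beta_true' must name exactly the non-reference classes")
  lp <- 0 * stack$layers[[1]]$values
  for (cl in other) lp <- lp + beta_true[[cl]] * stack$layers[[cl]]$values
  g <- stack$layers[[1]]
  raster2d(stats::plogis(lp), res = g$res, xll = g$xll, yll = g$yll)
}

#' Place population nuclei on a conductance surface
#'
#' Samples nucleus centres among cells with probability proportional to
#' conductance, rejecting candidates closer than `min_separation` to an
#' accepted centre or within `radius` of the raster edge, and returns
#' disk polygons around the accepted centres.
#'
#' @param conductance a `raster2d`.
#' @param n_nuclei number of nuclei (>= 0).
#' @param radius nucleus disk radius (map units).
#' @param min_separation minimum centre-to-centre distance (map units).
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget.
#' @return a `nuclei_set`.
#' @export
place_nuclei <- function(conductance, n_nuclei, radius, min_separation,
                         seed, max_tries = 10000L) {
  stopifnot(is_raster2d(conductance), n_nuclei >= 0)
  if (n_nuclei == 0L) return(nuclei_set(list()))
  set.seed(as.integer(seed))
  v <- conductance$values
  d <- dim(v)
  cand <- which(!is.na(v) & v > 0)
  xy <- cell_xy(conductance, cand)
  inset <- xy[, 1] >= conductance$xll + radius &
    xy[, 1] <= conductance$xll + d[2] * conductance$res - radius &
    xy[, 2] >= conductance$yll + radius &
    xy[, 2] <= conductance$yll + d[1] * conductance$res - radius
  cand <- cand[inset]; xy <- xy[inset, , drop = FALSE]
  if (length(cand) == 0L) stop("no interior cells available for nuclei")
  w <- v[cand]
  centres <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centres) < n_nuclei) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(paste("could not place", n_nuclei, "nuclei with separation",
                 min_separation, "- reduce n_nuclei, min_separation or",
                 "radius, or enlarge the landscape"))
    k <- sample.int(length(cand), 1L, prob = w)
    p <- xy[k, ]
    if (nrow(centres) == 0L ||
        all(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2) >=
            min_separation)) {
      centres <- rbind(centres, p)
    }
  }
  polys <- lapply(seq_len(n_nuclei), function(i)
    disk_polygon(centres[i, 1], centres[i, 2], radius))
  nuclei_set(polys)
}

#' Sample an exploratory trajectory from the RSP path distribution
#'
#' Draws a walk from the killed Markov chain conditioned on absorption at
#' `dest`: from node i the next node j is chosen with probability
#' proportional to `w_ij * z_j`, where `w_ij = p_ij exp(-theta kappa_ij)`
#' and `z` is the backward absorption-weight vector. This is the exact
#' optimal-policy representation of the RSP path distribution, so the
#' empirical visit statistics of many sampled walks converge to the
#' analytic expectations of [rsp_passage()] at the same theta. Every
#' `stride`-th visited cell (plus start and end) is emitted as a GPS fix
#' with isotropic Gaussian positional noise (truncated to the raster
#' extent) and timestamps spaced `fix_interval` hours apart.
#'
#' @param ts a `transition_system`.
#' @param source,dest distinct node indices.
#' @param theta_true non-negative randomness level of the walk.
#' @param stride cells between emitted fixes (>= 1).
#' @param gps_noise_sd positional noise sd (map units).
#' @param seed integer seed.
#' @param animal_id id stored on the fixes.
#' @param fix_interval hours between consecutive fixes (default 4, a
#'   typical GPS collar duty cycle).
#' @param t0 timestamp of the first fix (h).
#' @param max_steps hard cap on walk length.
#' @return a data.frame of fixes (`animal_id`, `t`, `x`, `y`,
#'   `behavior_truth = "exploratory"`) with the full node sequence in
#'   `attr(, "nodes")`.
#' @export
simulate_exploratory_trajectory <- function(ts, source, dest, theta_true,
                                            stride = 1L, gps_noise_sd = 0,
                                            seed = 1L, animal_id = "sim",
                                            fix_interval = 4, t0 = 0,
                                            max_steps = 5e6) {
  stopifnot(inherits(ts, "transition_system"), theta_true >= 0, stride >= 1)
  source <- as.integer(source); dest <- as.integer(dest)
  if (source == dest) stop("source and dest must differ")
  set.seed(as.integer(seed))
  n <- length(ts$node_cell)
  W <- rsp_W(ts, theta_true, dest)
  z <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - W, e_vec(n, dest)))
  if (!is.finite(z[source]) || z[source] <= 0)
    stop("destination unreachable from source in this graph")

  # per-node sampling tables: neighbours and cumulative probs of w_ij z_j
  Wt <- methods::as(Matrix::t(W), "CsparseMatrix")  # column i = out-edges of i
  nbr <- vector("list", n); cum <- vector("list", n)
  ptr <- Wt@p
  for (i in seq_len(n)) {
    idx <- if (ptr[i + 1L] > ptr[i]) (ptr[i] + 1L):ptr[i + 1L] else integer(0)
    js <- Wt@i[idx] + 1L
    wz <- Wt@x[idx] * z[js]
    tot <- sum(wz)
    if (i != dest && (length(js) == 0L || tot <= 0))
      next
    nbr[[i]] <- js
    cum[[i]] <- cumsum(wz) / tot
  }

  path <- integer(1024L); path[1L] <- source
  len <- 1L
  node <- source
  while (node != dest) {
    if (len >= max_steps)
      stop("walk exceeded max_steps without absorbing; raise max_steps")
    node <- nbr[[node]][findInterval(stats::runif(1), cum[[node]]) + 1L]
    len <- len + 1L
    if (len > length(path)) path <- c(path, integer(length(path)))
    path[len] <- node
  }
  path <- path[seq_len(len)]

  emit <- unique(c(seq(1L, len, by = stride), len))
  xy <- cell_xy(ts_raster(ts), ts$node_cell[path[emit]])
  if (gps_noise_sd > 0) {
    g <- ts$geometry
    xy[, 1] <- pmin(pmax(xy[, 1] + stats::rnorm(nrow(xy), 0, gps_noise_sd),
                         g$xll), g$xll + g$dim[2] * g$res)
    xy[, 2] <- pmin(pmax(xy[, 2] + stats::rnorm(nrow(xy), 0, gps_noise_sd),
                         g$yll), g$yll + g$dim[1] * g$res)
  }
  out <- data.frame(animal_id = animal_id,
                    t = t0 + (seq_along(emit) - 1) * fix_interval,
                    x = xy[, 1], y = xy[, 2],
                    behavior_truth = "exploratory",
                    stringsAsFactors = FALSE)
  attr(out, "nodes") <- path
  out
}

#' Simulate territorial fixes around a home-range centre
#'
#' Discrete-time Ornstein-Uhlenbeck wander: each coordinate reverts to the
#' centre with autocorrelation `phi` per fix interval and innovation sd
#' chosen so the stationary sd of the position is `home_sd`. Fixes are
#' labelled `"territorial"`.
#'
#' @param center length-2 numeric (x, y).
#' @param home_sd stationary positional sd (map units, >= 0).
#' @param n_fixes number of fixes (>= 10).
#' @param seed integer seed.
#' @param phi per-step autocorrelation in (0, 1).
#' @param gps_noise_sd extra positional noise sd.
#' @param animal_id,fix_interval,t0 as in
#'   [simulate_exploratory_trajectory()].
#' @return a data.frame of fixes with `behavior_truth = "territorial"`.
#' @export
simulate_territorial_fixes <- function(center, home_sd, n_fixes, seed,
                                       phi = 0.85, gps_noise_sd = 0,
                                       animal_id = "sim", fix_interval = 4,
                                       t0 = 0) {
  stopifnot(length(center) == 2, home_sd >= 0, phi > 0, phi < 1)
  if (n_fixes < 10) stop("need at least 10 fixes")
  set.seed(as.integer(seed))
  innov_sd <- home_sd * sqrt(1 - phi^2)
  x <- numeric(n_fixes); y <- numeric(n_fixes)
  x[1] <- stats::rnorm(1, 0, home_sd); y[1] <- stats::rnorm(1, 0, home_sd)
  for (i in seq_len(n_fixes)[-1]) {
    x[i] <- phi * x[i - 1] + stats::rnorm(1, 0, innov_sd)
    y[i] <- phi * y[i - 1] + stats::rnorm(1, 0, innov_sd)
  }
  x <- x + center[1]; y <- y + center[2]
  if (gps_noise_sd > 0) {
    x <- x + stats::rnorm(n_fixes, 0, gps_noise_sd)
    y <- y + stats::rnorm(n_fixes, 0, gps_noise_sd)
  }
  data.frame(animal_id = animal_id,
             t = t0 + (seq_len(n_fixes) - 1) * fix_interval,
             x = x, y = y, behavior_truth = "territorial",
             stringsAsFactors = FALSE)
}

#' Simulate matched used/available strata for PSF recovery
#'
#' For each stratum a random centre cell is drawn; candidate cells are
#' those within `radius` of the centre. The used cell is sampled with
#' probability proportional to `gpd_weight * exp(beta . composition)` and
#' `n_available` available cells are sampled proportional to the GPD
#' weight alone, so a used-versus-available logistic contrast is an
#' exponential tilt whose coefficients are exactly `beta_true`.
#'
#' @param stack a `landcover_stack`.
#' @param beta_true named coefficients (non-reference classes).
#' @param reference_class reference class name.
#' @param n_strata number of strata.
#' @param radius availability radius (map units).
#' @param gpd a `gpd_params` object for distance weights.
#' @param n_available available rows sampled per stratum.
#' @param seed integer seed.
#' @return a `used_available_table` (see [used_available_table()]).
#' @export
simulate_psf_strata <- function(stack, beta_true, reference_class,
                                n_strata, radius, gpd, n_available = 10L,
                                seed = 1L) {
  stopifnot(inherits(stack, "landcover_stack"))
  set.seed(as.integer(seed))
  ref <- stack$layers[[1]]
  d <- dim(ref$values)
  comp_mat <- sapply(stack$classes, function(cl)
    as.vector(stack$layers[[cl]]$values))
  other <- setdiff(stack$classes, reference_class)
  beta_vec <- sapply(stack$classes, function(cl)
    if (cl == reference_class) 0 else beta_true[[cl]])
  cells <- which(!is.na(ref$values))
  xy_all <- cell_xy(ref, cells)

  rows <- vector("list", n_strata * 2L)
  for (s in seq_len(n_strata)) {
    centre <- cells[sample.int(length(cells), 1L)]
    cxy <- cell_xy(ref, centre)
    dist <- sqrt((xy_all[, 1] - cxy[1])^2 + (xy_all[, 2] - cxy[2])^2)
    disk <- which(dist <= radius)
    wts <- gpd_density(dist[disk], gpd)
    score <- exp(comp_mat[cells[disk], , drop = FALSE] %*% beta_vec)
    used_k <- disk[sample.int(length(disk), 1L, prob = wts * score)]
    avail_k <- disk[sample.int(length(disk), n_available, replace = TRUE,
                               prob = wts)]
    used_cell <- cells[used_k]
    rows[[2L * s - 1L]] <- data.frame(
      stratum = s, role = "used",
      x = xy_all[used_k, 1], y = xy_all[used_k, 2], weight = 1,
      t(comp_mat[used_cell, ]), check.names = FALSE)
    rows[[2L * s]] <- data.frame(
      stratum = s, role = "available",
      x = xy_all[avail_k, 1], y = xy_all[avail_k, 2],
      weight = 1 / n_available,
      comp_mat[cells[avail_k], , drop = FALSE], check.names = FALSE)
  }
  used_available_table(do.call(rbind, rows), classes = stack$classes)
}
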