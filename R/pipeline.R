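#' Simulation configuration
#'
#' The default values define the synthetic study conditions the package
#' is exercised under: a 100 x 100 landscape of three cover classes at
#' 125 m resolution with patch structure at ~1 km scale, one strongly
#' selected and one strongly avoided class, five population nuclei, GPS
#' fixes every 4 h with 25 m positional noise, and exploratory
#' trajectories drawn from the RSP distribution at an interior
#' randomness level theta = 5e-4.
#'
#' @param n_rows,n_cols landscape dimensions (cells).
#' @param n_classes cover classes.
#' @param autocorr_range landscape smoothing sd (cells).
#' @param res cell size (m).
#' @param beta_true named true selection coefficients (non-reference).
#' @param reference_class reference cover class.
#' @param theta_true randomness level generating the trajectories.
#' @param n_nuclei,nucleus_radius,min_separation nuclei layout (m).
#' @param n_trajectories inter-nuclei trajectories to simulate.
#' @param stride cells between emitted fixes.
#' @param gps_noise_sd GPS error sd (m).
#' @param fix_interval hours between fixes.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_rows = 100L, n_cols = 100L,
                              n_classes = 4L, autocorr_range = 8,
                              res = 125,
                              beta_true = c(class_B = 2.98,
                                            class_C = 1.21,
                                            class_D = -3.93),
                              reference_class = "class_A",
                              theta_true = 5e-4,
                              n_nuclei = 5L, nucleus_radius = 500,
                              min_separation = 4000,
                              n_trajectories = 30L, stride = 10L,
                              gps_noise_sd = 25, fix_interval = 4,
                              seed = 1L) {
  stopifnot(theta_true >= 0, n_classes >= 2, stride >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a complete synthetic study
#'
#' Generates the landscape, the ground-truth conductance, the transition
#' system, the nuclei, and `n_trajectories` exploratory trajectories
#' between distinct nuclei sampled exactly from the RSP distribution at
#' `theta_true`. Stage seeds are derived deterministically from the
#' master seed.
#'
#' @param cfg a `simulation_config`.
#' @return list with `cfg`, `stack`, `conductance`, `ts`, `nuclei`,
#'   `nucleus_nodes`, `trajs` (list of `trajectory`), `fixes` (stacked
#'   data.frame).
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  seed <- as.integer(cfg$seed)
  stack <- generate_landscape(cfg$n_rows, cfg$n_cols, cfg$n_classes,
                              cfg$autocorr_range, seed = seed,
                              res = cfg$res)
  conductance <- conductance_from_truth(stack, cfg$beta_true,
                                        cfg$reference_class)
  ts <- build_transition_system(conductance)
  nuclei <- place_nuclei(conductance, cfg$n_nuclei, cfg$nucleus_radius,
                         cfg$min_separation, seed = seed + 1L)
  nodes <- nuclei_nodes(ts, nuclei)

  # candidate endpoint nodes per nucleus: trajectories start and end
  # where a path meets a nucleus, anywhere inside its polygon
  xy <- cell_xy(ts_raster(ts), ts$node_cell)
  members <- lapply(seq_along(nuclei$polygons), function(k) {
    inside <- which(point_in_polygon(xy[, 1], xy[, 2],
                                     nuclei$polygons[[k]]))
    if (length(inside) == 0L) nodes[k] else inside
  })

  set.seed(seed + 2L)
  ends <- t(replicate(cfg$n_trajectories,
                      sample.int(length(nodes), 2L)))
  end_nodes <- cbind(
    vapply(members[ends[, 1]], function(m) m[sample.int(length(m), 1L)],
           integer(1)),
    vapply(members[ends[, 2]], function(m) m[sample.int(length(m), 1L)],
           integer(1)))
  trajs <- vector("list", cfg$n_trajectories)
  for (i in seq_len(cfg$n_trajectories)) {
    fx <- simulate_exploratory_trajectory(
      ts, end_nodes[i, 1], end_nodes[i, 2], cfg$theta_true,
      stride = cfg$stride, gps_noise_sd = cfg$gps_noise_sd,
      seed = seed + 100L + i, animal_id = sprintf("sim_%02d", i),
      fix_interval = cfg$fix_interval)
    trajs[[i]] <- trajectory(fx, id = sprintf("traj_%02d", i))
  }
  fixes <- do.call(rbind, lapply(trajs, `[[`, "fixes"))
  list(cfg = cfg, stack = stack, conductance = conductance, ts = ts,
       nuclei = nuclei, nucleus_nodes = nodes, trajs = trajs,
       fixes = fixes)
}

#' Run the theta-calibration study
#'
#' For every theta in the grid, sums the per-trajectory RSP passage
#' surfaces into one connectivity surface, then scores it with the four
#' validation methods: mean squared error against the Brownian-bridge
#' occupancy of the in-between fixes, percentage of in-between fixes
#' inside percentile corridors, AIC of the logistic used-versus-available
#' fit, and the mean weighted rank percentile of used points. Returns
#' score tables, the per-method optimal theta, and per-path diagnostics.
#'
#' @param ts a `transition_system` for the conductance surface under
#'   study.
#' @param trajs list of `trajectory` objects (sources/destinations give
#'   the RSP endpoints; in-between fixes drive the validations).
#' @param theta_grid increasing non-negative thetas (default
#'   [default_theta_grid()]).
#' @param percentiles corridor percentiles for the representation
#'   method.
#' @param delta GPS error sd handed to the Brownian-bridge model.
#' @param q displacement quantile defining the availability radius.
#' @param max_available per-fix availability cap.
#' @param seed seed for fold/subsample randomness.
#' @param verbose print stage progress.
#' @return a `calibration_report`: list with `surfaces` (per-theta
#'   `raster2d`), `bb_surface`, `scores` (long data.frame: method,
#'   percentile, theta, value, direction), `optimal` (data.frame per
#'   method), `per_path` (per-trajectory ranking/corridor means per
#'   theta), `path_length` (per-theta Pearson r), `radius`, `gpd`,
#'   `sigma_m`.
#' @export
run_calibration <- function(ts, trajs,
                            theta_grid = default_theta_grid(),
                            percentiles = c(85, 90, 95, 99),
                            delta = 0, q = 0.99,
                            max_available = 5000L, seed = 1L,
                            verbose = FALSE) {
  stopifnot(inherits(ts, "transition_system"), length(trajs) >= 1L)
  if (is.unsorted(theta_grid, strictly = TRUE))
    stop("'theta_grid' must be strictly increasing")
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- ts_raster(ts)               # NA off-graph
  grid$values[ts$node_cell] <- 0

  # endpoints snapped to graph nodes
  ends <- lapply(trajs, function(tr)
    c(ts_node_from_xy(ts, tr$source$x, tr$source$y),
      ts_node_from_xy(ts, tr$dest$x, tr$dest$y)))

  say("computing %d passage surfaces (%d thetas x %d trajectories)",
      length(theta_grid) * length(trajs), length(theta_grid),
      length(trajs))
  surfaces <- vector("list", length(theta_grid))
  names(surfaces) <- format_theta(theta_grid)
  for (k in seq_along(theta_grid)) {
    acc <- NULL
    for (i in seq_along(trajs)) {
      ps <- rsp_passage(ts, ends[[i]][1], ends[[i]][2], theta_grid[k])
      acc <- if (is.null(acc)) ps$surface else
        sum_passages(list(acc, ps$surface))
    }
    surfaces[[k]] <- acc
    say("  theta = %g done", theta_grid[k])
  }

  # Brownian-bridge occupancy of the in-between fixes
  sig <- vapply(trajs, function(tr)
    estimate_bb_sigma(tr, delta = delta)$sigma_m, numeric(1))
  bb <- brownian_bridge_surface(trajs, grid, sigma_m = sig,
                                delta = delta)
  say("Brownian-bridge surface done (median sigma_m = %.1f)",
      stats::median(sig))

  # point-level validation inputs from in-between fixes
  used <- do.call(rbind, lapply(trajs, `[[`, "inbetween"))
  traj_of_fix <- rep(vapply(trajs, `[[`, character(1), "id"),
                     vapply(trajs, function(tr) nrow(tr$inbetween),
                            integer(1)))
  all_fixes <- do.call(rbind, lapply(trajs, `[[`, "fixes"))
  radius <- displacement_percentile(all_fixes, q = q)
  gpd <- fit_gpd(consecutive_steps(all_fixes))
  avail <- available_points(used, grid, radius, gpd,
                            max_cells = max_available, seed = seed)
  say("availability radius = %.0f map units (q = %.2f), %d used fixes",
      radius, q, nrow(used))

  scores <- list()
  per_path <- list()
  add <- function(df) scores[[length(scores) + 1L]] <<- df
  for (k in seq_along(theta_grid)) {
    th <- theta_grid[k]
    s <- surfaces[[k]]
    m <- mse_score(s, bb, theta = th)
    add(data.frame(method = "brownian_bridge", percentile = NA_real_,
                   theta = th, value = m$value, direction = m$direction))
    for (p in percentiles) {
      cs <- corridor_representation_score(s, p, used, theta = th)
      add(data.frame(method = "corridors", percentile = p, theta = th,
                     value = cs$value, direction = cs$direction))
      if (p == 90)
        per_path[[length(per_path) + 1L]] <- data.frame(
          method = "corridors", theta = th, trajectory_id = traj_of_fix,
          score = as.numeric(cs$detail) * 100)
    }
    ls_ <- logistic_validation_score(s, used, avail, theta = th)
    add(data.frame(method = "logistic", percentile = NA_real_,
                   theta = th, value = ls_$value,
                   direction = ls_$direction))
    rs <- ranking_score(s, used, avail, theta = th)
    add(data.frame(method = "ranking", percentile = NA_real_, theta = th,
                   value = rs$value, direction = rs$direction))
    per_path[[length(per_path) + 1L]] <- data.frame(
      method = "ranking", theta = th, trajectory_id = traj_of_fix,
      score = rs$detail)
    say("validated theta = %g", th)
  }
  scores <- do.call(rbind, scores)
  per_path <- stats::aggregate(
    score ~ method + theta + trajectory_id,
    data = do.call(rbind, per_path), FUN = mean, na.rm = TRUE)

  lengths_km <- data.frame(
    trajectory_id = vapply(trajs, `[[`, character(1), "id"),
    length_km = vapply(trajs, `[[`, numeric(1), "length_km"))
  per_path <- merge(per_path, lengths_km, by = "trajectory_id")
  pl <- do.call(rbind, lapply(split(per_path,
                                    per_path[c("method", "theta")]),
                              function(d) {
    if (nrow(d) < 3L) return(NULL)
    r <- path_length_correlation(data.frame(
      trajectory_id = d$trajectory_id, length_km = d$length_km,
      mean_score = d$score))
    data.frame(method = d$method[1], theta = d$theta[1], pearson_r = r$r)
  }))
  rownames(pl) <- NULL

  optimal <- optimal_theta_table(scores)
  structure(list(surfaces = surfaces, bb_surface = bb, scores = scores,
                 optimal = optimal, per_path = per_path,
                 path_length = pl, radius = radius, gpd = gpd,
                 sigma_m = sig, theta_grid = theta_grid),
            class = "calibration_report")
}

format_theta <- function(theta) formatC(theta, format = "g")

# per-method (and per-percentile for corridors) optimal theta
optimal_theta_table <- function(scores) {
  keys <- unique(scores[c("method", "percentile")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- scores$method == keys$method[i] &
      (is.na(keys$percentile[i]) | scores$percentile %in%
         keys$percentile[i])
    d <- scores[sel, ]
    sl <- lapply(seq_len(nrow(d)), function(j)
      validation_score(d$method[j], d$theta[j], d$value[j],
                       d$direction[j]))
    data.frame(method = keys$method[i], percentile = keys$percentile[i],
               best_theta = select_optimal_theta(sl))
  })
  do.call(rbind, out)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("calibration_report\n")
  cat(sprintf("  thetas: %s\n",
              paste(format_theta(x$theta_grid), collapse = ", ")))
  cat(sprintf("  availability radius: %.0f map units\n", x$radius))
  cat("  optimal theta per method:\n")
  print(x$optimal, row.names = FALSE)
  invisible(x)
}

#' Compare corridor networks across approaches
#'
#' Computes the inter-nuclei flux surface and percentile corridor
#' network for each requested approach (RSP at given thetas, circuit
#' theory, LCP), then reports the percentage of area each network shares
#' with the reference network (RSP at `reference_theta`, the optimum of
#' the representation-in-corridors validation in the standard design)
#' and the Pearson correlation of each flux surface with the reference
#' surface.
#'
#' @param ts a `transition_system`.
#' @param nuclei a `nuclei_set`.
#' @param reference_theta theta of the reference RSP network.
#' @param rsp_thetas further RSP thetas to compare (the grid extremes,
#'   other methods' optima, ...). Labels are taken from an optional
#'   `names()` attribute.
#' @param include_circuit,include_lcp include the traditional baselines.
#' @param percentile corridor percentile (default 90).
#' @param kernel_sigma LCP kernel sd in cells.
#' @return a `corridor_comparison`: list with `table` (data.frame:
#'   approach, theta, shared_area_pct, surface_correlation), `networks`,
#'   `fluxes`, `reference`.
#' @export
run_corridor_comparison <- function(ts, nuclei, reference_theta,
                                    rsp_thetas = numeric(0),
                                    include_circuit = TRUE,
                                    include_lcp = TRUE,
                                    percentile = 90, kernel_sigma = 1) {
  stopifnot(inherits(ts, "transition_system"),
            inherits(nuclei, "nuclei_set"))
  approaches <- list(list(label = "rsp_reference", method = "rsp",
                          theta = reference_theta))
  for (i in seq_along(rsp_thetas)) {
    lb <- names(rsp_thetas)[i]
    if (is.null(lb) || !nzchar(lb))
      lb <- paste0("rsp_theta_", format_theta(rsp_thetas[i]))
    approaches[[length(approaches) + 1L]] <-
      list(label = lb, method = "rsp", theta = rsp_thetas[[i]])
  }
  if (include_circuit)
    approaches[[length(approaches) + 1L]] <-
      list(label = "circuit", method = "circuit", theta = NA_real_)
  if (include_lcp)
    approaches[[length(approaches) + 1L]] <-
      list(label = "lcp", method = "lcp", theta = NA_real_)

  fluxes <- list(); networks <- list()
  for (ap in approaches) {
    fl <- internuclei_flux(ts, nuclei, method = ap$method,
                           theta = if (is.na(ap$theta)) 0 else ap$theta,
                           kernel_sigma = kernel_sigma)
    fluxes[[ap$label]] <- fl
    networks[[ap$label]] <- delineate_corridors(fl, percentile, nuclei)
  }
  ref <- networks[["rsp_reference"]]
  tab <- do.call(rbind, lapply(approaches, function(ap) {
    data.frame(
      approach = ap$label,
      method = ap$method,
      theta = ap$theta,
      shared_area_pct = shared_area(ref, networks[[ap$label]]),
      surface_correlation =
        surface_correlation(fluxes[["rsp_reference"]],
                            fluxes[[ap$label]])$r)
  }))
  structure(list(table = tab, networks = networks, fluxes = fluxes,
                 reference = "rsp_reference", percentile = percentile),
            class = "corridor_comparison")
}

#' @export
print.corridor_comparison <- function(x, ...) {
  cat(sprintf("corridor_comparison (percentile %g, reference = %s)\n",
              x$percentile, x$reference))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a reproducibility manifest
#'
#' Serialises a configuration (plus seeds and package version) to YAML
#' so a run can be reproduced exactly.
#'
#' @param cfg a `simulation_config` or plain list.
#' @param path output YAML path.
#' @param extra named list appended to the manifest.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  m <- c(unclass(cfg), extra,
         list(package_version =
                as.character(utils::packageVersion("rspaths"))))
  m <- lapply(m, function(v) if (is.numeric(v) || is.character(v) ||
                                 is.logical(v)) v else
                                   as.character(deparse(v)))
  yaml::write_yaml(m, path)
  invisible(path)
}
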