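#' Inter-nuclei flux surface
#'
#' Sums the per-pair connectivity surface over all unordered pairs of
#' nucleus centroids (snapped to the nearest on-graph cell, preferring a
#' cell inside the polygon) under the requested engine: RSP passage at a
#' given theta, circuit-theory current flow, or LCP kernel density.
#'
#' @param ts a `transition_system`.
#' @param nuclei a `nuclei_set` with >= 2 nuclei.
#' @param method `"rsp"`, `"lcp"` or `"circuit"`.
#' @param theta randomness level (used by `method = "rsp"` only).
#' @param kernel_sigma Gaussian buffering sd in cells for `"lcp"`.
#' @return a `raster2d` flux surface; the number of pairs computed is
#'   recorded in `attr(, "n_pairs")`.
#' @export
internuclei_flux <- function(ts, nuclei, method = c("rsp", "lcp", "circuit"),
                             theta = 0, kernel_sigma = 1) {
  stopifnot(inherits(ts, "transition_system"),
            inherits(nuclei, "nuclei_set"))
  method <- match.arg(method)
  K <- length(nuclei$polygons)
  if (K < 2L) stop("need at least 2 nuclei")
  nodes <- nuclei_nodes(ts, nuclei)
  pairs <- utils::combn(K, 2, simplify = FALSE)
  pairs <- lapply(pairs, function(p) c(nodes[p[1]], nodes[p[2]]))

  out <- if (method == "lcp") {
    lcp_density(ts, pairs, kernel_sigma)
  } else if (method == "circuit") {
    sum_passages(lapply(pairs, function(p) circuit_flow(ts, p[1], p[2])))
  } else {
    sum_passages(lapply(pairs, function(p)
      rsp_passage(ts, p[1], p[2], theta)))
  }
  attr(out, "n_pairs") <- length(pairs)
  out
}

# snap each nucleus centroid to an on-graph node: nearest on-graph cell
# whose centre lies inside the polygon, else nearest overall (flagged)
nuclei_nodes <- function(ts, nuclei) {
  r <- ts_raster(ts)
  xy <- cell_xy(r, ts$node_cell)
  vapply(seq_along(nuclei$polygons), function(k) {
    cen <- nuclei$centroids[k, ]
    inside <- point_in_polygon(xy[, 1], xy[, 2], nuclei$polygons[[k]])
    d2 <- (xy[, 1] - cen[1])^2 + (xy[, 2] - cen[2])^2
    if (any(inside)) {
      cand <- which(inside)
      cand[which.min(d2[inside])]
    } else {
      warning("nucleus ", nuclei$ids[[k]],
              " contains no on-graph cell; snapped to nearest node")
      which.min(d2)
    }
  }, integer(1))
}

#' Delineate a percentile corridor network
#'
#' Cells inside any nucleus polygon are excluded first; the threshold is
#' the given percentile of the remaining (eligible, non-nodata) flux
#' values and the corridor mask keeps cells at or above it, so the mask
#' covers `100 - percentile` percent of eligible cells up to ties. A
#' constant flux surface is flagged degenerate.
#'
#' @param flux a `raster2d` flux surface.
#' @param percentile threshold percentile in (0, 100); 90 delineates the
#'   top 10% of pixels.
#' @param nuclei a `nuclei_set` to exclude (may be empty).
#' @return a `corridor_network`: list with `mask` (logical `raster2d`,
#'   nodata `NA`), `percentile`, `threshold`, `eligible` (cell count),
#'   `flag`.
#' @export
delineate_corridors <- function(flux, percentile, nuclei = nuclei_set(list())) {
  stopifnot(is_raster2d(flux), percentile > 0, percentile < 100,
            inherits(nuclei, "nuclei_set"))
  d <- dim(flux$values)
  innuc <- matrix(FALSE, d[1], d[2])
  if (length(nuclei$polygons) > 0) {
    cells <- which(!is.na(flux$values))
    xy <- cell_xy(flux, cells)
    innuc[cells] <- nucleus_containing(nuclei, xy[, 1], xy[, 2]) > 0L
  }
  eligible <- !is.na(flux$values) & !innuc
  vals <- flux$values[eligible]
  if (length(vals) == 0L) stop("no eligible cells outside nuclei")
  flag <- NULL
  if (stats::sd(vals) == 0) flag <- "degenerate-constant-flux"
  thr <- stats::quantile(vals, percentile / 100, type = 7)
  maskm <- matrix(NA, d[1], d[2])
  maskm[!is.na(flux$values)] <- FALSE
  maskm[eligible] <- flux$values[eligible] >= thr
  mask <- raster2d(maskm * 1, res = flux$res, xll = flux$xll,
                   yll = flux$yll)
  structure(list(mask = mask, percentile = percentile,
                 threshold = unname(thr), eligible = sum(eligible),
                 flag = flag),
            class = "corridor_network")
}

#' @export
print.corridor_network <- function(x, ...) {
  ncorr <- sum(x$mask$values == 1, na.rm = TRUE)
  cat(sprintf(
    "corridor_network: percentile %g, %d corridor cells of %d eligible (%.1f%%)%s\n",
    x$percentile, ncorr, x$eligible, 100 * ncorr / x$eligible,
    if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Percentage of shared corridor area
#'
#' `100 * |a intersect b| / |a|`, the share of network `a` covered by
#' network `b`. With equal-sized masks (same percentile on the same
#' grid) the measure is symmetric; report both directions when sizes
#' differ.
#'
#' @param a,b `corridor_network` objects on the same grid (`a` is the
#'   reference).
#' @return percentage in [0, 100] (`NA` with a warning when `a` is
#'   empty).
#' @export
shared_area <- function(a, b) {
  stopifnot(inherits(a, "corridor_network"),
            inherits(b, "corridor_network"))
  stop_if_geometry_differs(a$mask, b$mask)
  ma <- a$mask$values == 1
  mb <- b$mask$values == 1
  na_ <- sum(ma, na.rm = TRUE)
  if (na_ == 0L) {
    warning("empty reference corridor mask; shared area undefined")
    return(NA_real_)
  }
  100 * sum(ma & mb, na.rm = TRUE) / na_
}
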