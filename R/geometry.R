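# planar polygon helpers (no CRS; coordinates in map units)

#' Point-in-polygon test
#'
#' Even-odd ray casting with boundary points counted as inside (closed
#' polygons), stable to floating-point jitter via a small tolerance on
#' the boundary check.
#'
#' @param x,y point coordinates (vectors).
#' @param poly two-column matrix of polygon vertices (not necessarily
#'   closed).
#' @param tol boundary tolerance in map units.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly, tol = 1e-9) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(x))
  onedge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- px[j[k]]; y1 <- py[j[k]]; x2 <- px[k]; y2 <- py[k]
    # boundary: distance from point to segment within tol
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2))
    d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
    onedge <- onedge | d2 <= tol^2
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
  }
  inside | onedge
}

# regular n-gon approximating a disk
disk_polygon <- function(cx, cy, radius, n_vertices = 32L) {
  a <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x = cx + radius * cos(a), y = cy + radius * sin(a))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Population-nuclei polygon set
#'
#' @param polygons list of two-column vertex matrices.
#' @param ids character or integer ids (defaults to sequence).
#' @return a `nuclei_set`: list with `polygons`, `ids`, `centroids`
#'   (two-column matrix of polygon vertex means).
#' @export
nuclei_set <- function(polygons, ids = NULL) {
  stopifnot(is.list(polygons))
  if (is.null(ids)) ids <- seq_along(polygons)
  stopifnot(length(ids) == length(polygons))
  cent <- t(vapply(polygons, colMeans, numeric(2)))
  if (length(polygons) == 0L) cent <- matrix(numeric(0), 0, 2)
  colnames(cent) <- c("x", "y")
  structure(list(polygons = polygons, ids = ids, centroids = cent),
            class = "nuclei_set")
}

#' @export
print.nuclei_set <- function(x, ...) {
  cat(sprintf("nuclei_set: %d polygons\n", length(x$polygons)))
  invisible(x)
}

#' Which nucleus contains each point (0 = none)
#'
#' @param nuclei a `nuclei_set`.
#' @param x,y point coordinates.
#' @return integer vector of nucleus positions (0 when outside all).
#' @export
nucleus_containing <- function(nuclei, x, y) {
  out <- integer(length(x))
  for (k in seq_along(nuclei$polygons)) {
    hit <- out == 0L & point_in_polygon(x, y, nuclei$polygons[[k]])
    out[hit] <- k
  }
  out
}

#' Read/write nuclei as GeoJSON
#'
#' Plain GeoJSON FeatureCollection of Polygons with an `id` property;
#' coordinates are planar map units (no CRS member is written).
#'
#' @param nuclei a `nuclei_set`.
#' @param path file path.
#' @export
write_nuclei_geojson <- function(nuclei, path) {
  feats <- lapply(seq_along(nuclei$polygons), function(k) {
    poly <- nuclei$polygons[[k]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = nuclei$ids[[k]]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(ring))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nuclei_geojson
#' @export
read_nuclei_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  polys <- list(); ids <- list()
  for (f in gj$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    polys[[length(polys) + 1L]] <- m
    ids[[length(ids) + 1L]] <- f$properties$id
  }
  nuclei_set(polys, unlist(ids))
}
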