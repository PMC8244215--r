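#' Planar square-cell raster
#'
#' Lightweight container for the gridded surfaces the pipeline moves around
#' (conductance, passage, occupancy, corridor masks). Values are held in a
#' numeric matrix whose first row is the *top* row of the map; `NA` marks
#' nodata. All coordinates are planar map units (metres unless stated
#' otherwise); there is no CRS handling.
#'
#' @param values numeric matrix (row 1 = northernmost row); `NA` = nodata.
#' @param res cell size in map units (cells are square).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @return an object of class `raster2d`.
#' @export
raster2d <- function(values, res = 1, xll = 0, yll = 0) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(dim(values) < 1L)) stop("raster must have positive dimensions")
  if (!is.numeric(res) || length(res) != 1L || res <= 0)
    stop("'res' must be a single positive number")
  structure(
    list(values = values, res = as.numeric(res),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "raster2d"
  )
}

#' @export
dim.raster2d <- function(x) dim(x$values)

#' @export
print.raster2d <- function(x, ...) {
  d <- dim(x$values)
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf(
    "raster2d: %d x %d cells, res %g, extent x [%g, %g] y [%g, %g]\n",
    d[1], d[2], x$res, x$xll, x$xll + d[2] * x$res, x$yll,
    x$yll + d[1] * x$res))
  cat(sprintf("  values in [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @rdname raster2d
#' @param x a `raster2d`.
#' @export
is_raster2d <- function(x) inherits(x, "raster2d")

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$res, a$xll, a$yll), c(b$res, b$xll, b$yll)))
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b)) stop("rasters do not share grid geometry")
}

#' Cell index <-> coordinate conversion
#'
#' Cells are numbered in R's native column-major order,
#' `cell = (col - 1) * nrow + row`, with row 1 at the top of the map, so
#' `r$values[cell]` always addresses the right cell. `cell_xy` returns
#' cell-centre coordinates; `xy_cell` maps points to the cell containing
#' them (points outside the extent return `NA`).
#'
#' @param r a `raster2d`.
#' @param cell integer vector of cell indices.
#' @return `cell_xy`: two-column matrix of x, y; `xy_cell`: integer vector.
#' @export
cell_xy <- function(r, cell) {
  d <- dim(r$values)
  row <- (cell - 1L) %% d[1] + 1L
  col <- (cell - 1L) %/% d[1] + 1L
  cbind(x = r$xll + (col - 0.5) * r$res,
        y = r$yll + (d[1] - row + 0.5) * r$res)
}

#' @rdname cell_xy
#' @param x,y point coordinates in map units.
#' @export
xy_cell <- function(r, x, y) {
  d <- dim(r$values)
  col <- floor((x - r$xll) / r$res) + 1
  row <- d[1] - floor((y - r$yll) / r$res)
  # points on the top/right edge belong to the outermost cell
  col[x == r$xll + d[2] * r$res] <- d[2]
  row[y == r$yll + d[1] * r$res] <- 1
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  out <- (col - 1) * d[1] + row
  out[bad] <- NA_integer_
  as.integer(out)
}

#' Block-aggregate a raster
#'
#' Mean over `factor` x `factor` blocks, ignoring nodata cells within a
#' block (a block that is all nodata stays nodata). Trailing rows/columns
#' that do not fill a block are averaged over the cells present. The cell
#' size is multiplied by `factor`; with full blocks and no nodata the
#' global mean is preserved exactly.
#'
#' @param r a `raster2d`.
#' @param factor integer aggregation factor (>= 1).
#' @return a coarser `raster2d`.
#' @export
aggregate_raster <- function(r, factor) {
  stopifnot(is_raster2d(r))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be >= 1")
  if (factor == 1L) return(r)
  v <- r$values
  d <- dim(v)
  nr <- ceiling(d[1] / factor)
  nc <- ceiling(d[2] / factor)
  bi <- (rep(seq_len(d[1]), times = d[2]) - 1L) %/% factor + 1L
  bj <- (rep(seq_len(d[2]), each = d[1]) - 1L) %/% factor + 1L
  grp <- bi + (bj - 1L) * nr
  sums <- tapply(as.vector(v), grp, function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0L) NA_real_ else mean(z)
  })
  out <- matrix(NA_real_, nr, nc)
  out[as.integer(names(sums))] <- as.numeric(sums)
  # y origin moves so the *top-left* corner stays fixed
  raster2d(out, res = r$res * factor, xll = r$xll,
           yll = r$yll + d[1] * r$res - nr * factor * r$res)
}

#' Pearson correlation between two surfaces
#'
#' Computed over cells that are non-nodata in both rasters.
#'
#' @param a,b `raster2d` objects on the same grid.
#' @return list with `r` (Pearson correlation, `NA` if degenerate),
#'   `n` (cells used) and `flag` ("zero-variance" when undefined).
#' @export
surface_correlation <- function(a, b) {
  stopifnot(is_raster2d(a), is_raster2d(b))
  stop_if_geometry_differs(a, b)
  ok <- !is.na(a$values) & !is.na(b$values)
  x <- a$values[ok]; y <- b$values[ok]
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(x), flag = "zero-variance"))
  list(r = stats::cor(x, y), n = length(x), flag = NULL)
}

#' Read/write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster exchange. Only square cells are
#' supported; nodata is written as -9999.
#'
#' @param r a `raster2d`.
#' @param path file path.
#' @return `read_raster_asc` returns a `raster2d`; `write_raster_asc`
#'   returns `path` invisibly.
#' @export
write_raster_asc <- function(r, path) {
  stopifnot(is_raster2d(r))
  d <- dim(r$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$res),
    "NODATA_value -9999")
  v <- r$values
  v[is.na(v)] <- -9999
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE,
                                                  digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), hdr, ignore.case = TRUE, value = TRUE)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster2d(m, res = val("cellsize"), xll = val("xllcorner"),
           yll = val("yllcorner"))
}

#' Gaussian blur of a raster
#'
#' Separable truncated-Gaussian convolution (kernel cut at 4 sd); taps
#' falling outside the grid are folded back by per-source
#' renormalisation, so total mass is preserved exactly. `sigma = 0`
#' returns the input.
#'
#' @param r a `raster2d` (nodata treated as 0 during convolution and
#'   restored afterwards).
#' @param sigma kernel standard deviation in cells.
#' @return a blurred `raster2d`.
#' @export
gaussian_blur <- function(r, sigma) {
  stopifnot(is_raster2d(r), sigma >= 0)
  if (sigma == 0) return(r)
  v <- r$values
  nas <- is.na(v)
  v[nas] <- 0
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  v <- conv_axis(v, k)          # down columns
  v <- t(conv_axis(t(v), k))    # across rows
  v[nas] <- NA_real_
  raster2d(v, res = r$res, xll = r$xll, yll = r$yll)
}

# 1-D convolution of each column of m with kernel k; each source cell's
# kernel is renormalised over its in-range taps so mass is conserved
conv_axis <- function(m, k) {
  n <- nrow(m)
  half <- (length(k) - 1L) %/% 2L
  wk <- numeric(n)
  for (o in seq(-half, half)) {
    src <- seq_len(n) + o
    keep <- src >= 1L & src <= n
    wk[src[keep]] <- wk[src[keep]] + k[o + half + 1L]
  }
  msc <- m / wk
  out <- matrix(0, n, ncol(m))
  for (o in seq(-half, half)) {
    src <- seq_len(n) + o
    keep <- src >= 1L & src <= n
    out[keep, ] <- out[keep, ] + k[o + half + 1L] *
      msc[src[keep], , drop = FALSE]
  }
  out
}
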