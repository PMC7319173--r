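# Minimal in-memory raster on the package's equal-area grid, with a plain-text
# serialisation.  Cell [i, j] sits at (x0 + (j-1)*dx, y0 + (i-1)*dy) km in the
# projection defined by `center`; row index grows northward.

#' Construct an equal-area grid raster
#'
#' A lightweight raster container used for bathymetry, land masks and daily
#' sea-ice concentration fields: a numeric matrix of cell values on a regular
#' grid in the study projection ([laea_project()]), plus an optional logical
#' land mask of the same shape.  Values on land cells are stored as `NA`.
#'
#' @param values Numeric matrix, `ny x nx`; element `[i, j]` is the cell centred
#'   at `(x0 + (j-1)*dx, y0 + (i-1)*dy)` kilometres.
#' @param x0,y0 Coordinates (km) of the centre of cell `[1, 1]`.
#' @param dx,dy Cell size in kilometres (25 for the sea-ice grid emulated here).
#' @param center Projection centre `c(lon, lat)`.
#' @param land Optional logical matrix flagging land cells.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, x0, y0, dx, dy, center, land = NULL) {
  stopifnot(is.matrix(values), dx > 0, dy > 0, length(center) == 2)
  if (is.null(land)) {
    land <- matrix(FALSE, nrow(values), ncol(values))
  }
  stopifnot(is.logical(land), all(dim(land) == dim(values)))
  values[land] <- NA_real_
  structure(
    list(values = values, x0 = x0, y0 = y0, dx = dx, dy = dy,
         center = as.numeric(center), land = land),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf(
    "grid_raster: %d x %d cells of %g x %g km, origin (%g, %g) km, center (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$dx, x$dy, x$x0, x$y0,
    x$center[1], x$center[2]))
  cat(sprintf("  land cells: %d; value range: %s\n", sum(x$land),
              paste(signif(range(x$values, na.rm = TRUE), 4), collapse = " .. ")))
  invisible(x)
}

#' Nearest-cell index for planar coordinates
#'
#' @param r A [grid_raster()].
#' @param x,y Planar coordinates (km).
#' @return Integer matrix with columns `i`, `j`; `NA` rows for points outside
#'   the grid.
#' @keywords internal
raster_index <- function(r, x, y) {
  i <- as.integer(round((y - r$y0) / r$dy)) + 1L
  j <- as.integer(round((x - r$x0) / r$dx)) + 1L
  bad <- i < 1L | i > nrow(r$values) | j < 1L | j > ncol(r$values) |
    !is.finite(i) | !is.finite(j)
  i[bad] <- NA_integer_
  j[bad] <- NA_integer_
  cbind(i = i, j = j)
}

#' Cell-centre coordinates
#' @keywords internal
raster_xy <- function(r, i, j) {
  cbind(x = r$x0 + (j - 1) * r$dx, y = r$y0 + (i - 1) * r$dy)
}

#' Geographic coordinates of all cell centres
#' @param r A [grid_raster()].
#' @return `data.frame` with `i`, `j`, `x`, `y`, `lon`, `lat`, one row per cell.
#' @export
raster_cells <- function(r) {
  ij <- expand.grid(i = seq_len(nrow(r$values)), j = seq_len(ncol(r$values)))
  xy <- raster_xy(r, ij$i, ij$j)
  ll <- laea_inverse(xy[, "x"], xy[, "y"], r$center)
  cbind(ij, x = xy[, "x"], y = xy[, "y"], ll)
}

#' Look up raster values at geographic positions
#'
#' Nearest-cell lookup.  Land cells and points outside the grid return `NA`;
#' use [raster_is_land()] to distinguish the two.
#'
#' @param r A [grid_raster()].
#' @param lon,lat Coordinates in decimal degrees.
#' @return Numeric vector of cell values.
#' @export
raster_lookup <- function(r, lon, lat) {
  xy <- laea_project(lon, lat, r$center)
  ij <- raster_index(r, xy$x, xy$y)
  out <- rep(NA_real_, nrow(ij))
  ok <- !is.na(ij[, "i"])
  out[ok] <- r$values[cbind(ij[ok, "i"], ij[ok, "j"])]
  out
}

#' Is a position on a land cell?
#'
#' @inheritParams raster_lookup
#' @return Logical vector; `NA` for points outside the grid.
#' @export
raster_is_land <- function(r, lon, lat) {
  xy <- laea_project(lon, lat, r$center)
  ij <- raster_index(r, xy$x, xy$y)
  out <- rep(NA, nrow(ij))
  ok <- !is.na(ij[, "i"])
  out[ok] <- r$land[cbind(ij[ok, "i"], ij[ok, "j"])]
  out
}

#' Write / read a grid raster as plain text
#'
#' Simple self-describing text format: a header of `key value` lines, a
#' `[values]` block of `ny` whitespace-separated rows (southernmost row first,
#' `NA` for land), and a `[land]` block of 0/1 flags.
#'
#' @param r A [grid_raster()].
#' @param path File path.
#' @return `write_grid_raster` returns `path` invisibly; `read_grid_raster`
#'   returns a [grid_raster()].
#' @export
write_grid_raster <- function(r, path) {
  stopifnot(inherits(r, "grid_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# sealdive grid_raster v1",
    paste("ny", nrow(r$values)), paste("nx", ncol(r$values)),
    paste("x0", format(r$x0, digits = 15)), paste("y0", format(r$y0, digits = 15)),
    paste("dx", format(r$dx, digits = 15)), paste("dy", format(r$dy, digits = 15)),
    paste("center_lon", format(r$center[1], digits = 15)),
    paste("center_lat", format(r$center[2], digits = 15)),
    "[values]"
  ), con)
  utils::write.table(r$values, con, row.names = FALSE, col.names = FALSE)
  writeLines("[land]", con)
  utils::write.table(r$land * 1L, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_raster
#' @export
read_grid_raster <- function(path) {
  lines <- readLines(path)
  hdr_end <- match("[values]", lines)
  if (is.na(hdr_end)) stop("not a grid_raster file (missing [values] block): ", path)
  hdr <- lines[2:(hdr_end - 1)]
  kv <- do.call(rbind, strsplit(hdr, " ", fixed = TRUE))
  h <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  ny <- as.integer(h["ny"]); nx <- as.integer(h["nx"])
  land_at <- match("[land]", lines)
  vals <- matrix(scan(text = lines[(hdr_end + 1):(land_at - 1)],
                      what = numeric(), quiet = TRUE, na.strings = "NA"),
                 nrow = ny, ncol = nx, byrow = TRUE)
  land <- matrix(scan(text = lines[(land_at + 1):length(lines)],
                      what = integer(), quiet = TRUE),
                 nrow = ny, ncol = nx, byrow = TRUE) == 1L
  grid_raster(vals, h["x0"], h["y0"], h["dx"], h["dy"],
              c(h["center_lon"], h["center_lat"]), land)
}

#' Daily raster stack
#'
#' A dated collection of [grid_raster()] fields (one per day), used for daily
#' sea-ice concentration.
#'
#' @param rasters Named list of [grid_raster()]s; names are `YYYY-MM-DD` dates.
#' @return Object of class `raster_stack`.
#' @export
raster_stack <- function(rasters) {
  stopifnot(length(rasters) > 0, !is.null(names(rasters)))
  dates <- as.Date(names(rasters))
  if (any(is.na(dates))) stop("raster_stack names must be YYYY-MM-DD dates")
  structure(list(dates = dates, rasters = rasters), class = "raster_stack")
}

#' Extract the raster for a given date from a stack
#' @param stack A [raster_stack()].
#' @param date A `Date` (or string coercible to one).
#' @return A [grid_raster()], or error if the date is absent.
#' @export
stack_on <- function(stack, date) {
  stopifnot(inherits(stack, "raster_stack"))
  key <- format(as.Date(date), "%Y-%m-%d")
  r <- stack$rasters[[key]]
  if (is.null(r)) stop("no raster for date ", key)
  r
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d daily fields, %s .. %s\n",
              length(x$rasters), min(x$dates), max(x$dates)))
  invisible(x)
}

# 8-neighbour connected-component labelling of a logical matrix.
# Returns an integer matrix of component labels (0 = background).
#' @keywords internal
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nbr_i <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_j <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cell - 1L) %% ny) + 1L
      j <- ((cell - 1L) %/% ny) + 1L
      ii <- i + nbr_i; jj <- j + nbr_j
      ok <- ii >= 1L & ii <= ny & jj >= 1L & jj <= nx
      nb <- (jj[ok] - 1L) * ny + ii[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}
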