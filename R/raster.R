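#' Gridded raster layer on a planar 250 m grid
#'
#' Lightweight raster container used for bathymetry, terrain complexity and
#' distance layers.  Values are stored as a matrix with row 1 at the northern
#' edge (north-up); the grid is georeferenced by its lower-left corner and a
#' square cell size, matching the ESRI ASCII grid convention.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll planar coordinates (m) of the lower-left corner.
#' @param cell cell size in metres (square cells).
#' @return An object of class `searaster`.
#' @export
searaster <- function(values, xll, yll, cell = 250) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), cell > 0, is.finite(xll), is.finite(yll))
  structure(
    list(values = values, xll = xll, yll = yll, cell = cell,
         nrow = nrow(values), ncol = ncol(values)),
    class = "searaster"
  )
}

#' @export
print.searaster <- function(x, ...) {
  cat(sprintf("<searaster> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cell, x$xll, x$yll))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %.3g, mean %.3g, max %.3g\n",
                min(v), mean(v), max(v)))
  invisible(x)
}

#' @export
dim.searaster <- function(x) c(x$nrow, x$ncol)

# y coordinate of the top (northern) edge
raster_ytop <- function(r) r$yll + r$nrow * r$cell

#' Cell-centre coordinates of a raster
#'
#' @param r a [searaster].
#' @return list with vectors `x` (length ncol) and `y` (length nrow, north
#'   to south), plus matrices `X`, `Y` aligned with `r$values`.
#' @export
cell_centers <- function(r) {
  x <- r$xll + (seq_len(r$ncol) - 0.5) * r$cell
  y <- raster_ytop(r) - (seq_len(r$nrow) - 0.5) * r$cell
  list(x = x, y = y,
       X = matrix(x, r$nrow, r$ncol, byrow = TRUE),
       Y = matrix(y, r$nrow, r$ncol))
}

#' Map planar coordinates to raster cell indices
#'
#' Cells are half-open: a point on a shared edge belongs to the cell to its
#' east/south, so no point is assigned twice.
#'
#' @param r a [searaster] (or anything with xll, yll, cell, nrow, ncol).
#' @param x,y planar coordinates (m).
#' @return data.frame with columns `row`, `col` (1-based; NA outside grid).
#' @export
cell_index <- function(r, x, y) {
  col <- floor((x - r$xll) / r$cell) + 1L
  row <- floor((raster_ytop(r) - y) / r$cell) + 1L
  bad <- col < 1L | col > r$ncol | row < 1L | row > r$nrow
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Look up raster values at planar coordinates
#'
#' @inheritParams cell_index
#' @return numeric vector (NA outside the grid).
#' @export
raster_lookup <- function(r, x, y) {
  ij <- cell_index(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(ij$row)
  out[ok] <- r$values[cbind(ij$row[ok], ij$col[ok])]
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text `.asc` raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from north to south.  NODATA cells become NA on read and are written back
#' as the NODATA value.
#'
#' @param path file path.
#' @return [searaster] (for the reader).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  body <- paste(lines[(i + 1L):length(lines)], collapse = " ")
  vals <- scan(text = body, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  searaster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' @param r a [searaster] to write.
#' @param nodata value used for NA cells.
#' @param digits significant digits for values.
#' @rdname read_esri_ascii
#' @export
write_esri_ascii <- function(r, path, nodata = -9999, digits = 6) {
  stopifnot(inherits(r, "searaster"))
  v <- r$values
  v[!is.finite(v)] <- nodata
  hdr <- c(
    paste("ncols", r$ncol), paste("nrows", r$nrow),
    paste("xllcorner", format(r$xll, scientific = FALSE)),
    paste("yllcorner", format(r$yll, scientific = FALSE)),
    paste("cellsize", format(r$cell, scientific = FALSE)),
    paste("NODATA_value", nodata)
  )
  rows <- apply(v, 1, function(z) paste(signif(z, digits), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
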