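#' Euclidean distance raster to a geometry set
#'
#' Exact planar distance from every cell centre to the nearest point on any
#' of the supplied geometries (point-to-point and point-to-segment).
#'
#' @param grid a [searaster] supplying the grid (values ignored).
#' @param lines list of 2-column polyline vertex matrices.
#' @param points n x 2 matrix of points.
#' @return [searaster] of distances in metres.
#' @export
distance_raster <- function(grid, lines = list(), points = NULL) {
  if (length(lines) == 0 && NROW(points) == 0)
    stop("distance_raster needs at least one geometry")
  cc <- cell_centers(grid)
  d <- geom_min_distance(as.vector(cc$X), as.vector(cc$Y), lines, points)
  searaster(matrix(d, grid$nrow, grid$ncol), grid$xll, grid$yll, grid$cell)
}

# 3x3 Horn finite-difference slope magnitude (rise over run) with mirrored
# edge padding.
horn_slope <- function(m, cell) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) stop("raster must be at least 3 x 3")
  # mirror pad by one cell
  p <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, nc, drop = FALSE])
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  z1 <- p[i - 1, j - 1]; z2 <- p[i - 1, j]; z3 <- p[i - 1, j + 1]
  z4 <- p[i, j - 1];                         z6 <- p[i, j + 1]
  z7 <- p[i + 1, j - 1]; z8 <- p[i + 1, j]; z9 <- p[i + 1, j + 1]
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * cell)
  dzdy <- ((z7 + 2 * z8 + z9) - (z1 + 2 * z2 + z3)) / (8 * cell)
  sqrt(dzdx^2 + dzdy^2)
}

#' Benthic terrain complexity
#'
#' Local variability of the sea floor: the rate of change of slope (the
#' second derivative of depth), computed by applying the Horn 3x3 slope
#' operator to the bathymetry and then applying the same operator to the
#' resulting slope surface.  Edge cells use mirrored padding.  Invariant to
#' a constant depth offset and to the sign convention of the depth datum;
#' zero for constant and (in the interior) planar bathymetry.
#'
#' @param depth a [searaster] of depth (m).
#' @return [searaster] of complexity (1/m).
#' @export
terrain_complexity <- function(depth) {
  stopifnot(inherits(depth, "searaster"))
  slope <- horn_slope(depth$values, depth$cell)
  searaster(horn_slope(slope, depth$cell), depth$xll, depth$yll, depth$cell)
}

#' Build the seven-layer covariate stack
#'
#' Layers on one 250 m grid: `depth`, `complexity`, and Euclidean distances
#' to the colony (`d_colony`), coast (`d_coast`), pipelines and cable routes
#' combined (`d_pipes_cables`), wells (`d_wells`) and shipwrecks
#' (`d_shipwrecks`).
#'
#' @param bathymetry [searaster] of depth (m, positive down).
#' @param colony c(x, y) planar colony location.
#' @param coastline 2-column vertex matrix of the coast polyline.
#' @param structures a [structure_set] with at least one geometry of each of
#'   pipelines/cables, wells and shipwrecks.
#' @return object of class `covariate_stack`: list of named [searaster]s
#'   sharing the grid.
#' @export
covariate_stack <- function(bathymetry, colony, coastline, structures) {
  stopifnot(inherits(bathymetry, "searaster"))
  g <- bathymetry
  pc <- structure_geoms(structures, "pipes_cables")
  layers <- list(
    depth = bathymetry,
    complexity = terrain_complexity(bathymetry),
    d_colony = distance_raster(g, points = matrix(colony, ncol = 2)),
    d_coast = distance_raster(g, lines = list(as.matrix(coastline))),
    d_pipes_cables = distance_raster(g, lines = pc$lines),
    d_wells = distance_raster(g, points = structures$wells),
    d_shipwrecks = distance_raster(g, points = structures$shipwrecks)
  )
  structure(layers, class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  g <- x[[1]]
  cat(sprintf("<covariate_stack> %d layers on %d x %d grid @ %g m\n",
              length(x), g$nrow, g$ncol, g$cell))
  cat(" ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Extract covariates for foraging events, one row per unique cell
#'
#' Events already deduplicated per cell by [intensive_areas()] pass through
#' one-to-one; any residual duplicates are collapsed.  Events outside the
#' grid are dropped (count in attribute `n_dropped`).
#'
#' @param stack a [covariate_stack].
#' @param events data.frame with either `row`/`col` or `x`/`y`.
#' @return data.frame: `row`, `col` plus one column per layer.
#' @export
extract_covariates <- function(stack, events) {
  g <- stack[[1]]
  if (all(c("row", "col") %in% names(events))) {
    ij <- events[, c("row", "col")]
  } else {
    ij <- cell_index(g, events$x, events$y)
  }
  ok <- !is.na(ij$row) & !is.na(ij$col) &
    ij$row >= 1 & ij$row <= g$nrow & ij$col >= 1 & ij$col <= g$ncol
  n_dropped <- sum(!ok)
  ij <- ij[ok, , drop = FALSE]
  ij <- unique(ij)
  out <- ij
  for (nm in names(stack))
    out[[nm]] <- stack[[nm]]$values[cbind(ij$row, ij$col)]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Variance inflation factors for a covariate table
#'
#' VIF_j = 1 / (1 - R^2_j) where R^2_j comes from an ordinary least-squares
#' regression of covariate j on all the others.  Values above the threshold
#' (default 3) are flagged as collinear; a perfectly collinear covariate is
#' reported as Inf.
#'
#' @param obs data.frame of numeric covariates (>= 2 columns, more rows
#'   than columns).
#' @param threshold flag level (default 3).
#' @return data.frame `variable`, `vif`, `flagged`.
#' @export
vif_screen <- function(obs, threshold = 3) {
  obs <- as.data.frame(obs)
  obs <- obs[, vapply(obs, is.numeric, logical(1)), drop = FALSE]
  p <- ncol(obs)
  stopifnot(p >= 2, nrow(obs) > p)
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm(obs[[j]] ~ ., data = obs[, -j, drop = FALSE])
    # a perfect fit (exact collinearity) is expected here and handled below
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = names(obs), vif = vif, flagged = vif > threshold)
}
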