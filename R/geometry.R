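#' Planar projection for geographic coordinates
#'
#' All analysis distances (250 m grid, 250 m buffer, speeds) are metric, so
#' longitude/latitude input is projected to local planar metres with an
#' equirectangular projection centred on the colony.  Adequate for a study
#' region spanning a few degrees of latitude.
#'
#' @param lon,lat geographic coordinates (degrees).
#' @param origin c(lon0, lat0) of the projection centre (the colony).
#' @return data.frame with planar `x`, `y` in metres.
#' @export
lonlat_to_planar <- function(lon, lat, origin) {
  stopifnot(length(origin) == 2, all(is.finite(origin)))
  R <- 6371000
  lat0 <- origin[2] * pi / 180
  data.frame(
    x = (lon - origin[1]) * pi / 180 * R * cos(lat0),
    y = (lat - origin[2]) * pi / 180 * R
  )
}

#' @param x,y planar metres relative to `origin`.
#' @rdname lonlat_to_planar
#' @export
planar_to_lonlat <- function(x, y, origin) {
  R <- 6371000
  lat0 <- origin[2] * pi / 180
  data.frame(
    lon = origin[1] + x / (R * cos(lat0)) * 180 / pi,
    lat = origin[2] + y / R * 180 / pi
  )
}

# Minimum distance from each point (px, py) to a polyline given as a
# 2-column vertex matrix.  Vectorised over points; exact point-to-segment
# projection with clamping.
dist_to_polyline <- function(px, py, verts) {
  verts <- as.matrix(verts)
  if (nrow(verts) == 1)
    return(sqrt((px - verts[1, 1])^2 + (py - verts[1, 2])^2))
  d2 <- rep(Inf, length(px))
  for (k in seq_len(nrow(verts) - 1)) {
    ax <- verts[k, 1]; ay <- verts[k, 2]
    bx <- verts[k + 1, 1]; by <- verts[k + 1, 2]
    dx <- bx - ax; dy <- by - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
    d2 <- pmin(d2, (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
  }
  sqrt(d2)
}

# Minimum distance from points to a geometry collection: `lines` is a list
# of vertex matrices, `points` an n x 2 matrix (either may be empty).
geom_min_distance <- function(px, py, lines = list(), points = NULL) {
  d <- rep(Inf, length(px))
  for (ln in lines) d <- pmin(d, dist_to_polyline(px, py, ln))
  if (!is.null(points) && NROW(points) > 0) {
    points <- matrix(as.numeric(as.matrix(points)), ncol = 2)
    for (k in seq_len(nrow(points)))
      d <- pmin(d, sqrt((px - points[k, 1])^2 + (py - points[k, 2])^2))
  }
  d
}

#' Anthropogenic structure sets
#'
#' Container for the four structure types considered: pipelines and cable
#' routes (polylines), wells and shipwrecks (points).
#'
#' @param pipelines,cables lists of 2-column vertex matrices (planar m).
#' @param wells,shipwrecks 2-column matrices of point coordinates.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(pipelines = list(), cables = list(),
                          wells = NULL, shipwrecks = NULL) {
  as_pts <- function(p) {
    if (is.null(p) || NROW(p) == 0) return(matrix(numeric(0), ncol = 2))
    matrix(as.numeric(as.matrix(p)), ncol = 2)
  }
  as_lines <- function(l) lapply(l, function(v) matrix(as.numeric(as.matrix(v)), ncol = 2))
  structure(
    list(pipelines = as_lines(pipelines), cables = as_lines(cables),
         wells = as_pts(wells), shipwrecks = as_pts(shipwrecks)),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d pipelines, %d cables, %d wells, %d shipwrecks\n",
              length(x$pipelines), length(x$cables),
              nrow(x$wells), nrow(x$shipwrecks)))
  invisible(x)
}

# Geometries of a structure set by type label; "pipes_cables" merges the two
# polyline classes the way they are modelled as one variable.
structure_geoms <- function(structures, type) {
  switch(type,
    pipeline    = list(lines = structures$pipelines, points = NULL),
    cable       = list(lines = structures$cables, points = NULL),
    pipes_cables = list(lines = c(structures$pipelines, structures$cables),
                        points = NULL),
    well        = ,
    wells       = list(lines = list(), points = structures$wells),
    shipwreck   = ,
    shipwrecks  = list(lines = list(), points = structures$shipwrecks),
    any         = list(lines = c(structures$pipelines, structures$cables),
                       points = rbind(structures$wells, structures$shipwrecks)),
    stop("unknown structure type: ", type)
  )
}

# Does a structure set contain any geometry of the given type?
has_structure_type <- function(structures, type) {
  g <- structure_geoms(structures, type)
  length(g$lines) > 0 || NROW(g$points) > 0
}

#' Distance from points to structures of a given type
#'
#' @param structures a [structure_set].
#' @param x,y planar coordinates (m).
#' @param type one of "pipeline", "cable", "pipes_cables", "wells",
#'   "shipwrecks", "any".
#' @return numeric vector of minimum Euclidean distances (m).
#' @export
structure_distance <- function(structures, x, y, type = "any") {
  g <- structure_geoms(structures, type)
  if (length(g$lines) == 0 && NROW(g$points) == 0)
    stop("structure set has no geometry of type '", type, "'")
  geom_min_distance(x, y, g$lines, g$points)
}

#' Read / write structures as GeoJSON
#'
#' A FeatureCollection of Point and LineString features; each feature carries
#' a property `stype` in {pipeline, cable, well, shipwreck}.  Coordinates are
#' written in geographic lon/lat when an `origin` is supplied, otherwise in
#' planar metres.
#'
#' @param path file path.
#' @param origin optional c(lon0, lat0); if given, coordinates are converted.
#' @return a [structure_set] (for the reader).
#' @export
read_structures_geojson <- function(path, origin = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  pl <- list(); cb <- list(); we <- NULL; sw <- NULL
  to_planar <- function(m) {
    if (is.null(origin)) return(m)
    p <- lonlat_to_planar(m[, 1], m[, 2], origin)
    cbind(p$x, p$y)
  }
  for (ft in gj$features) {
    st <- ft$properties$stype
    geom <- ft$geometry
    if (is.null(st) || is.null(geom)) next
    if (geom$type == "Point") {
      xy <- to_planar(matrix(unlist(geom$coordinates), ncol = 2, byrow = TRUE))
      if (st == "well") we <- rbind(we, xy)
      else if (st == "shipwreck") sw <- rbind(sw, xy)
    } else if (geom$type == "LineString") {
      m <- do.call(rbind, lapply(geom$coordinates, function(c2) unlist(c2)[1:2]))
      m <- to_planar(m)
      if (st == "pipeline") pl[[length(pl) + 1]] <- m
      else if (st == "cable") cb[[length(cb) + 1]] <- m
    }
  }
  structure_set(pipelines = pl, cables = cb, wells = we, shipwrecks = sw)
}

#' @param structures a [structure_set] to write.
#' @rdname read_structures_geojson
#' @export
write_structures_geojson <- function(structures, path, origin = NULL) {
  to_out <- function(m) {
    if (!is.null(origin)) {
      ll <- planar_to_lonlat(m[, 1], m[, 2], origin)
      m <- cbind(ll$lon, ll$lat)
    }
    m
  }
  feats <- list()
  add_line <- function(verts, st) {
    m <- to_out(verts)
    coords <- lapply(seq_len(nrow(m)), function(k) c(m[k, 1], m[k, 2]))
    feats[[length(feats) + 1]] <<- list(
      type = "Feature", properties = list(stype = st),
      geometry = list(type = "LineString", coordinates = coords))
  }
  add_point <- function(xy, st) {
    m <- to_out(matrix(xy, ncol = 2))
    feats[[length(feats) + 1]] <<- list(
      type = "Feature", properties = list(stype = st),
      geometry = list(type = "Point", coordinates = c(m[1, 1], m[1, 2])))
  }
  for (v in structures$pipelines) add_line(v, "pipeline")
  for (v in structures$cables) add_line(v, "cable")
  for (k in seq_len(nrow(structures$wells))) add_point(structures$wells[k, ], "well")
  for (k in seq_len(nrow(structures$shipwrecks))) add_point(structures$shipwrecks[k, ], "shipwreck")
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
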