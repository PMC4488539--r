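#' Attach per-interval underwater time to a regularised track
#'
#' First-passage diving substitutes time spent underwater for elapsed time,
#' so each inter-fix interval of the regularised track needs the number of
#' seconds of diving it contains.  A dive contributes its full duration to
#' the interval containing its start time.
#'
#' @param traj regularised track (`time`, `x`, `y`).
#' @param dives dive table (needs `start`, `duration`; optionally
#'   `dive_class`).
#' @param include one of "all" (default: benthic + pelagic dives both count
#'   as time underwater) or "benthic".
#' @return `traj` with an added `uw` column: underwater seconds in the
#'   interval starting at each fix (0 for the last fix).
#' @export
attach_underwater <- function(traj, dives, include = c("all", "benthic")) {
  include <- match.arg(include)
  d <- dives
  if (include == "benthic" && "dive_class" %in% names(d))
    d <- d[!is.na(d$dive_class) & d$dive_class == "benthic", , drop = FALSE]
  n <- nrow(traj)
  uw <- numeric(n)
  if (nrow(d) > 0) {
    idx <- findInterval(d$start, traj$time)
    idx[idx < 1L] <- 1L
    idx[idx >= n] <- n - 1L  # dives at/after the last fix fold into the final interval
    agg <- tapply(d$duration, idx, sum)
    uw[as.integer(names(agg))] <- as.numeric(agg)
  }
  traj$uw <- uw
  traj
}

# Underwater seconds accumulated during the single passage (first entry to
# first exit of the circle of radius r centred on fix p) for one radius.
# Partial boundary intervals are pro-rated linearly in distance.
fpd_one <- function(t, dcen, uw, p, r) {
  n <- length(t)
  inside <- dcen <= r
  if (!inside[p]) return(0)
  a <- p
  while (a > 1 && inside[a - 1]) a <- a - 1
  b <- p
  while (b < n && inside[b + 1]) b <- b + 1
  total <- if (b > a) sum(uw[a:(b - 1)]) else 0
  if (a > 1) {
    gap <- dcen[a - 1] - dcen[a]
    frac <- if (gap > 0) (r - dcen[a]) / gap else 1
    total <- total + uw[a - 1] * min(1, max(0, frac))
  }
  if (b < n) {
    gap <- dcen[b + 1] - dcen[b]
    frac <- if (gap > 0) (r - dcen[b]) / gap else 1
    total <- total + uw[b] * min(1, max(0, frac))
  }
  total
}

#' First-passage diving profile at one track point
#'
#' For each candidate radius, the time spent underwater while the animal
#' remains inside the circle centred on the focal fix, during the single
#' passage containing that fix (first entry to first exit, as in classic
#' first-passage time analysis).
#'
#' @param traj regularised track with `uw` from [attach_underwater()].
#' @param point index of the focal fix.
#' @param radii vector of radii in metres (all > 0).
#' @return data.frame `radius`, `time_underwater` (s), non-decreasing in
#'   radius.
#' @export
fpd_profile <- function(traj, point, radii) {
  if (any(radii <= 0)) stop("radii must be positive")
  if (is.null(traj$uw)) stop("track has no underwater time; run attach_underwater()")
  dcen <- sqrt((traj$x - traj$x[point])^2 + (traj$y - traj$y[point])^2)
  tu <- vapply(radii, function(r) fpd_one(traj$time, dcen, traj$uw, point, r),
               numeric(1))
  data.frame(radius = radii, time_underwater = tu)
}

#' First-passage diving values for every track point
#'
#' @inheritParams fpd_profile
#' @return matrix (points x radii) of underwater seconds.
#' @export
fpd_matrix <- function(traj, radii) {
  if (any(radii <= 0)) stop("radii must be positive")
  if (is.null(traj$uw)) stop("track has no underwater time; run attach_underwater()")
  n <- nrow(traj)
  out <- matrix(0, n, length(radii),
                dimnames = list(NULL, paste0("r", radii)))
  for (p in seq_len(n)) {
    dcen <- sqrt((traj$x - traj$x[p])^2 + (traj$y - traj$y[p])^2)
    for (j in seq_along(radii))
      out[p, j] <- fpd_one(traj$time, dcen, traj$uw, p, radii[j])
  }
  out
}

#' Default log-spaced radii grid
#'
#' 15 log-spaced radii from the grid cell size (250 m) to a typical trip
#' extent (20 km).
#'
#' @param from,to,n range and count.
#' @export
default_radii <- function(from = 250, to = 20000, n = 15) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Select the operational scale of intensive foraging
#'
#' The operational scale is the radius maximising the variance of
#' log(first-passage diving time) across track points; zero values are
#' excluded before taking logs.
#'
#' @param fpd matrix from [fpd_matrix()] (points x radii).
#' @param radii the radii corresponding to the columns.
#' @return the selected radius; attributes `variances` (per radius) and
#'   `degenerate` (TRUE when no radius shows variance and the smallest is
#'   returned with a warning).
#' @export
select_scale <- function(fpd, radii) {
  stopifnot(ncol(fpd) == length(radii), length(radii) >= 2, nrow(fpd) >= 2)
  v <- apply(fpd, 2, function(col) {
    pos <- col[col > 0]
    if (length(pos) < 2) return(NA_real_)
    stats::var(log(pos))
  })
  if (all(is.na(v)) || all(v[!is.na(v)] == 0)) {
    warning("no variance in first-passage values at any radius; returning smallest")
    out <- min(radii)
    attr(out, "variances") <- v
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- radii[which.max(v)]
  attr(out, "variances") <- v
  attr(out, "degenerate") <- FALSE
  out
}

#' Extract intensive foraging areas as deduplicated grid-cell events
#'
#' Track points whose first-passage diving value at the operational scale
#' exceeds the per-trip quantile threshold are flagged; benthic dives
#' located at flagged points are mapped to 250 m grid cells, and multiple
#' dives in one cell are combined into a single foraging event to avoid
#' pseudo-replication.
#'
#' @param traj regularised track with `uw`.
#' @param located_dives dive table with `x`, `y` (from [merge_dives()]);
#'   only rows with `dive_class == "benthic"` are used when the column is
#'   present.
#' @param scale operational radius (m) from [select_scale()].
#' @param grid a [searaster] (or grid-bearing object) defining the cells.
#' @param quantile threshold quantile of the per-point values (default
#'   0.75).
#' @return data.frame of events: `row`, `col`, `x`, `y` (cell centre),
#'   `n_dives`, `fpd_s` (max value among contributing points); zero rows if
#'   no point exceeds the threshold.
#' @export
intensive_areas <- function(traj, located_dives, scale, grid,
                            quantile = 0.75) {
  stopifnot(scale > 0)
  fpd <- fpd_matrix(traj, scale)[, 1]
  thr <- stats::quantile(fpd, quantile, names = FALSE)
  flagged <- fpd > thr
  d <- located_dives
  if ("dive_class" %in% names(d))
    d <- d[!is.na(d$dive_class) & d$dive_class == "benthic", , drop = FALSE]
  if (nrow(d) == 0 || !any(flagged)) return(empty_event_table())
  n <- nrow(traj)
  idx <- findInterval(d$start, traj$time)
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  d <- d[flagged[idx], , drop = FALSE]
  pt_fpd <- fpd[idx[flagged[idx]]]
  if (nrow(d) == 0) return(empty_event_table())
  ij <- cell_index(grid, d$x, d$y)
  ok <- !is.na(ij$row)
  d <- d[ok, , drop = FALSE]; ij <- ij[ok, , drop = FALSE]
  pt_fpd <- pt_fpd[ok]
  if (nrow(d) == 0) return(empty_event_table())
  key <- paste(ij$row, ij$col)
  split_idx <- split(seq_len(nrow(d)), key)
  ytop <- raster_ytop(grid)
  out <- do.call(rbind, lapply(split_idx, function(ii) {
    r <- ij$row[ii[1]]; cc <- ij$col[ii[1]]
    data.frame(
      row = r, col = cc,
      x = grid$xll + (cc - 0.5) * grid$cell,
      y = ytop - (r - 0.5) * grid$cell,
      n_dives = length(ii),
      fpd_s = max(pt_fpd[ii]))
  }))
  rownames(out) <- NULL
  out[order(out$row, out$col), , drop = FALSE]
}

empty_event_table <- function() {
  data.frame(row = integer(0), col = integer(0), x = numeric(0),
             y = numeric(0), n_dives = integer(0), fpd_s = numeric(0))
}

#' Write foraging events as CSV and GeoJSON points
#'
#' @param events event table from [intensive_areas()].
#' @param path output CSV path; a sibling `.geojson` is written alongside.
#' @param origin optional c(lon0, lat0) to emit geographic coordinates.
#' @export
write_events <- function(events, path, origin = NULL) {
  ev <- cbind(id = seq_len(nrow(events)), events)
  utils::write.csv(ev, path, row.names = FALSE)
  feats <- lapply(seq_len(nrow(events)), function(k) {
    xy <- c(events$x[k], events$y[k])
    if (!is.null(origin)) {
      ll <- planar_to_lonlat(xy[1], xy[2], origin)
      xy <- c(ll$lon, ll$lat)
    }
    list(type = "Feature",
         properties = list(n_dives = events$n_dives[k],
                           fpd_s = events$fpd_s[k]),
         geometry = list(type = "Point", coordinates = xy))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       sub("\\.csv$", ".geojson", path),
                       auto_unbox = TRUE, digits = 10)
  invisible(path)
}
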