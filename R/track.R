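#' Read a GPS track CSV
#'
#' Expects columns `time` (ISO-8601 UTC or numeric seconds), `lon`, `lat`.
#' Coordinates are projected to planar metres about `origin` (the colony)
#' when supplied; otherwise columns `x`, `y` in metres are expected.
#'
#' @param path file path.
#' @param origin c(lon0, lat0) projection centre, or NULL for planar input.
#' @return data.frame with `time` (s), `x`, `y` (m).
#' @export
read_gps_csv <- function(path, origin = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tm <- parse_time(d$time)
  if (all(c("lon", "lat") %in% names(d))) {
    if (is.null(origin)) stop("lon/lat track needs a projection origin")
    p <- lonlat_to_planar(d$lon, d$lat, origin)
    out <- data.frame(time = tm, x = p$x, y = p$y)
  } else if (all(c("x", "y") %in% names(d))) {
    out <- data.frame(time = tm, x = as.numeric(d$x), y = as.numeric(d$y))
  } else stop("track CSV needs lon/lat or x/y columns: ", path)
  out[order(out$time), , drop = FALSE]
}

#' Speed-filter a GPS track
#'
#' Removes implausible fixes with an iterative neighbour-speed test: while
#' any consecutive pair of retained fixes implies a speed above `vmax`, the
#' interior fix with the largest implied speed to a neighbour is dropped and
#' speeds are recomputed.  The first and last fixes are always kept.  The
#' result contains no over-speed pair and re-running the filter changes
#' nothing.
#'
#' @param fixes data.frame (`time`, `x`, `y`), planar metres, >= 2 rows.
#' @param vmax maximum plausible sustained speed in m/s (default 3, a
#'   typical otariid ceiling).
#' @return filtered data.frame; attribute `n_removed` gives the count, and
#'   attribute `degenerate` is TRUE if all interior fixes were removed.
#' @export
speed_filter <- function(fixes, vmax = 3) {
  stopifnot(nrow(fixes) >= 2, vmax > 0)
  fixes <- fixes[order(fixes$time), , drop = FALSE]
  keep <- rep(TRUE, nrow(fixes))
  n0 <- nrow(fixes)
  repeat {
    idx <- which(keep)
    if (length(idx) <= 2) break
    t <- fixes$time[idx]; x <- fixes$x[idx]; y <- fixes$y[idx]
    v <- sqrt(diff(x)^2 + diff(y)^2) / pmax(diff(t), .Machine$double.eps)
    if (all(v <= vmax)) break
    # speed attributed to each interior fix: max of inbound/outbound, with
    # ties broken towards the fix that is over-speed on both sides (the
    # spike itself rather than its neighbours)
    vin <- v[-length(v)]; vout <- v[-1]
    worst <- which.max(pmax(vin, vout) + 1e-9 * pmin(vin, vout)) + 1L
    keep[idx[worst]] <- FALSE
  }
  out <- fixes[keep, , drop = FALSE]
  attr(out, "n_removed") <- n0 - nrow(out)
  attr(out, "degenerate") <- nrow(out) == 2 && n0 > 2
  if (isTRUE(attr(out, "degenerate")))
    warning("speed filter removed all interior fixes")
  out
}

#' Regularise a track to a fixed time interval
#'
#' Positions are linearly interpolated in time at `t0, t0 + interval, ...`
#' starting at the first fix; no extrapolation beyond the last fix.
#'
#' @param traj filtered data.frame (`time`, `x`, `y`).
#' @param interval spacing in seconds (default 600, i.e. 10 min).
#' @return data.frame (`time`, `x`, `y`) with attribute
#'   `regular_interval = interval`.
#' @export
interpolate_track <- function(traj, interval = 600) {
  stopifnot(interval > 0)
  if (nrow(traj) < 2) stop("cannot interpolate a track with fewer than 2 fixes")
  tt <- seq(traj$time[1], traj$time[nrow(traj)], by = interval)
  out <- data.frame(
    time = tt,
    x = stats::approx(traj$time, traj$x, xout = tt)$y,
    y = stats::approx(traj$time, traj$y, xout = tt)$y
  )
  attr(out, "regular_interval") <- interval
  out
}

#' Attach dive locations by interpolating the track at dive start times
#'
#' Each dive is located on the segment between the bracketing track fixes by
#' time-linear interpolation.  Dives outside the track's time span by more
#' than `tolerance` are dropped (count reported as attribute `n_dropped`);
#' dives within tolerance are clamped to the nearest endpoint.
#'
#' @param traj regularised track (`time`, `x`, `y`).
#' @param dives dive table (needs `start`).
#' @param tolerance seconds a dive may fall outside the track span
#'   (default 600).
#' @return dives with added `x`, `y` columns.
#' @export
merge_dives <- function(traj, dives, tolerance = 600) {
  t0 <- traj$time[1]; t1 <- traj$time[nrow(traj)]
  inside <- dives$start >= t0 - tolerance & dives$start <= t1 + tolerance
  n_dropped <- sum(!inside)
  d <- dives[inside, , drop = FALSE]
  ts <- pmin(pmax(d$start, t0), t1)
  d$x <- stats::approx(traj$time, traj$x, xout = ts)$y
  d$y <- stats::approx(traj$time, traj$y, xout = ts)$y
  attr(d, "n_dropped") <- n_dropped
  d
}
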