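#' Read a depth trace CSV
#'
#' Expects columns `time` (ISO-8601 UTC or numeric seconds) and `depth_m`.
#'
#' @param path file path.
#' @return data.frame with numeric `time` (s since epoch) and `depth` (m,
#'   positive down).
#' @export
read_depth_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "depth_m") %in% names(d)))
    stop("depth CSV must have columns time, depth_m: ", path)
  data.frame(time = parse_time(d$time), depth = as.numeric(d$depth_m))
}

parse_time <- function(t) {
  if (is.numeric(t)) return(as.numeric(t))
  as.numeric(as.POSIXct(t, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                       "%Y-%m-%dT%H:%M:%OS",
                                       "%Y-%m-%d %H:%M:%OS")))
}

#' Zero-offset correction of a depth trace
#'
#' Pressure sensors drift, so the apparent depth of the sea surface wanders
#' away from zero over a deployment.  The surface baseline is estimated as a
#' rolling low quantile of depth (the animal surfaces regularly, so the low
#' quantile tracks the surface reading), evaluated on a coarse grid of
#' windows and linearly interpolated between them, then subtracted.
#' Corrected depths are clipped at 0.
#'
#' @param series data.frame with `time` (s) and `depth` (m).
#' @param window window width in seconds over which the surface quantile is
#'   taken; must span several surfacings (default 1800 s).
#' @param probs quantile treated as the surface reading (default 0.05).
#' @return corrected series, same shape, with attribute `baseline`.
#' @export
zero_offset_correct <- function(series, window = 1800, probs = 0.05) {
  stopifnot(window > 0)
  if (nrow(series) == 0) stop("empty depth series")
  t <- series$time; z <- series$depth
  span <- diff(range(t))
  if (span <= window) {
    base <- rep(stats::quantile(z, probs, names = FALSE), length(z))
  } else {
    knots <- seq(t[1], t[length(t)], by = window / 2)
    if (knots[length(knots)] < t[length(t)]) knots <- c(knots, t[length(t)])
    qs <- vapply(knots, function(k) {
      sel <- t >= k - window / 2 & t <= k + window / 2
      stats::quantile(z[sel], probs, names = FALSE)
    }, numeric(1))
    base <- stats::approx(knots, qs, xout = t, rule = 2)$y
  }
  out <- data.frame(time = t, depth = pmax(0, z - base))
  attr(out, "baseline") <- base
  out
}

#' Detect dives in a corrected depth trace
#'
#' A dive is a maximal submergence interval (depth above the surface
#' threshold) whose maximum depth reaches `min_depth`.  Each dive is
#' summarised with duration, maximum depth, bottom-time proportion and the
#' benthic/pelagic score (bottom-time proportion x maximum depth).
#'
#' @param series corrected depth series (`time`, `depth`).
#' @param min_depth minimum dive depth in metres (default 5).
#' @param surface_threshold depth above which the animal counts as submerged
#'   (default 0.5 m); needed to delimit dives.
#' @param bottom_fraction fraction of maximum depth defining the bottom
#'   phase (default 0.8); see [bottom_proportion()].
#' @return data.frame of dives: `start`, `end`, `duration`, `max_depth`,
#'   `bottom_time_prop`, `score`, `dive_class` (NA until classified),
#'   ordered by start time.
#' @export
detect_dives <- function(series, min_depth = 5, surface_threshold = 0.5,
                         bottom_fraction = 0.8) {
  t <- series$time; z <- series$depth
  sub <- z > surface_threshold
  if (!any(sub)) return(empty_dive_table())
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- list()
  for (k in which(keep)) {
    i0 <- starts[k]; i1 <- ends[k]
    zz <- z[i0:i1]
    mx <- max(zz)
    if (mx < min_depth) next
    tt <- t[i0:i1]
    dur <- if (i1 > i0) tt[length(tt)] - tt[1] else 0
    if (dur <= 0) next
    bp <- bottom_proportion(data.frame(time = tt, depth = zz),
                            bottom_fraction = bottom_fraction)
    out[[length(out) + 1]] <- data.frame(
      start = tt[1], end = tt[length(tt)], duration = dur, max_depth = mx,
      bottom_time_prop = bp, score = bp * mx,
      dive_class = NA_character_)
  }
  if (!length(out)) return(empty_dive_table())
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

empty_dive_table <- function() {
  data.frame(start = numeric(0), end = numeric(0), duration = numeric(0),
             max_depth = numeric(0), bottom_time_prop = numeric(0),
             score = numeric(0), dive_class = character(0))
}

#' Proportion of a dive spent in its bottom phase
#'
#' The bottom phase is the time at depth >= `bottom_fraction` of the dive's
#' maximum depth (the usual time-depth-recorder convention).  Time is
#' accrued per sample using midpoint interval weights, so irregular sampling
#' is handled.
#'
#' @param slice data.frame (`time`, `depth`) covering exactly one dive.
#' @param bottom_fraction fraction of maximum depth defining "bottom"
#'   (default 0.8).
#' @return fraction in \[0, 1\].
#' @export
bottom_proportion <- function(slice, bottom_fraction = 0.8) {
  t <- slice$time; z <- slice$depth
  if (length(t) < 2 || t[length(t)] <= t[1]) stop("zero-duration dive")
  # per-sample weights: half the gap to each neighbour
  dt <- diff(t)
  w <- c(dt[1] / 2, (dt[-length(dt)] + dt[-1]) / 2, dt[length(dt)] / 2)
  thr <- bottom_fraction * max(z)
  sum(w[z >= thr]) / sum(w)
}

#' Classify dives as benthic or pelagic from the score distribution
#'
#' Each dive's score (bottom-time proportion x maximum depth, in metres) is
#' low for pelagic, V-shaped dives and high for flat-bottomed benthic dives,
#' so the score distribution of a benthic forager is bimodal.  A Gaussian
#' kernel density estimate (Silverman's rule-of-thumb bandwidth) is fitted
#' to the scores on a 512-point grid spanning \[0, max score\]; the two
#' highest local maxima are located and the nadir is the density minimum
#' between them (ties broken towards the lower score).  Scores below the
#' nadir are pelagic, at or above it benthic.
#'
#' @param dives dive table from [detect_dives()] (>= 2 dives).
#' @param fallback_threshold optional score threshold used when the density
#'   is unimodal; if NULL (default) a unimodal density leaves all dives
#'   unclassified and sets `unimodal = TRUE`.
#' @return list with `dives` (dive table with `dive_class` filled),
#'   `nadir` (score threshold, NA if unimodal and no fallback), and
#'   `unimodal` (logical).
#' @export
classify_dives <- function(dives, fallback_threshold = NULL) {
  if (nrow(dives) < 2) stop("need at least 2 dives to classify")
  s <- dives$score
  unimodal <- FALSE
  nadir <- NA_real_
  if (diff(range(s)) < sqrt(.Machine$double.eps)) {
    unimodal <- TRUE
  } else {
    den <- stats::density(s, bw = "nrd0", n = 512, from = 0, to = max(s))
    y <- den$y
    n <- length(y)
    is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
    # grid boundary points can be modes too (e.g. mass piled at 0)
    is_max[1] <- y[1] > y[2]
    is_max[n] <- y[n] > y[n - 1]
    peaks <- which(is_max)
    if (length(peaks) < 2) {
      unimodal <- TRUE
    } else {
      top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
      lo <- min(top2); hi <- max(top2)
      between <- lo:hi
      nadir_i <- between[which.min(y[between])]  # which.min takes the first: lowest score
      nadir <- den$x[nadir_i]
    }
  }
  if (unimodal) {
    if (!is.null(fallback_threshold)) nadir <- fallback_threshold
    else {
      dives$dive_class <- "unclassified"
      return(list(dives = dives, nadir = NA_real_, unimodal = TRUE))
    }
  }
  dives$dive_class <- ifelse(s < nadir, "pelagic", "benthic")
  list(dives = dives, nadir = nadir, unimodal = unimodal)
}

#' Write a dive table to CSV
#'
#' @param dives dive table.
#' @param path file path.
#' @export
write_dive_csv <- function(dives, path) {
  utils::write.csv(dives, path, row.names = FALSE)
  invisible(path)
}
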