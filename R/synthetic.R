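#' Generate a synthetic seascape
#'
#' A planar Bass-Strait-like world on a 250 m grid: near-uniform bathymetry
#' (a configurable mean depth of 60 m plus a smooth low-relief field built
#' from random Gaussian bumps), a straight coastline along the northern
#' edge, a colony on that coast, and sparse anthropogenic structures —
#' pipelines and cables as roughly shore-normal polylines, wells and
#' shipwrecks as scattered points.  Fully reproducible from the seed.
#'
#' @param n_rows,n_cols grid dimensions (default 400 x 400 = 100 km sides).
#' @param cell cell size in metres (default 250).
#' @param mean_depth mean sea-floor depth in metres (default 60).
#' @param relief_amplitude typical bump amplitude in metres (default 5);
#'   0 gives constant depth.
#' @param n_pipelines,n_cables,n_wells,n_shipwrecks structure counts.
#' @param seed integer seed.
#' @return object of class `seascape`: list with `bathymetry`
#'   ([searaster]), `colony` (x, y), `coastline` (vertex matrix),
#'   `structures` ([structure_set]), and the grid parameters.
#' @export
generate_seascape <- function(n_rows = 400, n_cols = 400, cell = 250,
                              mean_depth = 60, relief_amplitude = 5,
                              n_pipelines = 3, n_cables = 2,
                              n_wells = 6, n_shipwrecks = 5, seed = 1) {
  if (n_rows <= 0 || n_cols <= 0 || cell <= 0)
    stop("grid dimensions and cell size must be positive")
  withr::with_seed(seed, {
    width <- n_cols * cell; height <- n_rows * cell
    bathy <- searaster(matrix(mean_depth, n_rows, n_cols), 0, 0, cell)
    if (relief_amplitude > 0) {
      cc <- cell_centers(bathy)
      field <- matrix(0, n_rows, n_cols)
      for (k in 1:12) {
        cx <- stats::runif(1, 0, width); cy <- stats::runif(1, 0, height)
        sd <- stats::runif(1, 0.05, 0.2) * width
        amp <- stats::runif(1, -relief_amplitude, relief_amplitude)
        field <- field + amp * exp(-((cc$X - cx)^2 + (cc$Y - cy)^2) / (2 * sd^2))
      }
      bathy$values <- pmax(mean_depth + field, 5)
    }
    ytop <- height
    coastline <- rbind(c(0, ytop), c(width, ytop))
    # the colony is an offshore island, not a point on the mainland coast
    colony <- c(width / 2, ytop - 0.12 * height)
    shore_line <- function() {
      # shore-normal polyline with lateral wiggle, from the coast southwards
      x0 <- stats::runif(1, 0.1 * width, 0.9 * width)
      len <- stats::runif(1, 0.5, 0.85) * height
      ys <- seq(ytop, ytop - len, by = -5000)
      xs <- x0 + cumsum(c(0, stats::rnorm(length(ys) - 1, 0, 1500)))
      cbind(pmin(pmax(xs, 0), width), ys)
    }
    pipelines <- replicate(n_pipelines, shore_line(), simplify = FALSE)
    cables <- replicate(n_cables, shore_line(), simplify = FALSE)
    rand_pts <- function(n) cbind(stats::runif(n, 0.05 * width, 0.95 * width),
                                  stats::runif(n, 0.1 * height, 0.9 * height))
    structures <- structure_set(
      pipelines = pipelines, cables = cables,
      wells = rand_pts(n_wells), shipwrecks = rand_pts(n_shipwrecks))
    structure(list(
      bathymetry = bathy, colony = colony, coastline = coastline,
      structures = structures, cell = cell,
      n_rows = n_rows, n_cols = n_cols, mean_depth = mean_depth,
      seed = seed
    ), class = "seascape")
  })
}

#' @export
print.seascape <- function(x, ...) {
  cat(sprintf("<seascape> %d x %d cells @ %g m, mean depth %g m\n",
              x$n_rows, x$n_cols, x$cell, mean(x$bathymetry$values)))
  print(x$structures)
  invisible(x)
}

#' Specification of one synthetic foraging trip
#'
#' Ground-truth knobs for the trip generator.  Defaults reflect the study
#' system: trips of 3-7 days from the colony, a dive rate giving roughly
#' 850 dives over a 6-day trip, and continuous benthic diving with a
#' pelagic admixture while transiting.
#'
#' @param duration_d trip length in days; NULL (default) draws uniformly
#'   from `duration_range`.
#' @param duration_range allowed range in days (default c(3, 7)).
#' @param fix_interval GPS fix spacing in seconds (default 300).
#' @param dive_rate dives per hour (default 6).
#' @param attraction_strength non-negative; 0 is neutral, larger values bias
#'   foraging patch centres towards structures with probability
#'   a / (1 + a).
#' @param attraction_targets structure types that attract patches.
#' @param pelagic_mix probability a non-bout dive is pelagic (default 0.35).
#' @param n_patches number of foraging patches; NULL draws 2-4.
#' @param patch_radius typical patch radius in metres (default 2000).
#' @param forage_frac fraction of the trip spent in intensive foraging
#'   bouts (default 0.2); the rest is transit and broad searching.
#' @param search_radius scale of the wide searching movement around each
#'   focal region (default 8000 m).
#' @param depth_interval depth sampling interval in seconds (default 10).
#' @param surface_drift c(start, end) sensor surface offset in metres
#'   applied linearly over the record (default c(0, 0)).
#' @param seed integer seed.
#' @return list of class `trip_spec`.
#' @export
trip_spec <- function(duration_d = NULL, duration_range = c(3, 7),
                      fix_interval = 300, dive_rate = 6,
                      attraction_strength = 0,
                      attraction_targets = c("pipeline", "cable", "well", "shipwreck"),
                      pelagic_mix = 0.35, n_patches = NULL,
                      patch_radius = 2000, forage_frac = 0.2,
                      search_radius = 8000, depth_interval = 10,
                      surface_drift = c(0, 0), seed = 1) {
  stopifnot(fix_interval > 0, dive_rate > 0, attraction_strength >= 0)
  if (!is.null(duration_d) &&
      (duration_d < duration_range[1] || duration_d > duration_range[2]))
    stop("duration_d outside duration_range")
  structure(as.list(environment()), class = "trip_spec")
}

# sample a point on or near a structure of one of the target types
sample_structure_point <- function(structures, targets, jitter = 500) {
  pool <- list()
  for (ty in targets) {
    if (ty %in% c("pipeline", "cable")) {
      lines <- if (ty == "pipeline") structures$pipelines else structures$cables
      for (ln in lines) pool[[length(pool) + 1]] <- list(kind = "line", g = ln)
    } else {
      pts <- if (ty == "well") structures$wells else structures$shipwrecks
      for (k in seq_len(nrow(pts)))
        pool[[length(pool) + 1]] <- list(kind = "point", g = pts[k, ])
    }
  }
  if (!length(pool)) stop("no structures of the requested attraction targets")
  pick <- pool[[sample.int(length(pool), 1)]]
  if (pick$kind == "point") {
    xy <- pick$g
  } else {
    v <- pick$g
    k <- sample.int(nrow(v) - 1, 1)
    t <- stats::runif(1)
    xy <- v[k, ] + t * (v[k + 1, ] - v[k, ])
  }
  xy + stats::rnorm(2, 0, jitter)
}

#' Generate one synthetic foraging trip with ground truth
#'
#' Simulates a central-place trip as a state-switching correlated random
#' walk: fast, directed transit legs between the colony and foraging patch
#' centres, broad searching movement around each focal region, and slow,
#' tortuous movement within patches (the intensive-foraging bouts).  With
#' `attraction_strength > 0`, patch centres are biased towards the named
#' structure types.  A depth trace is generated along the track: square-ish
#' benthic dives to the local sea-floor depth during patch bouts, and a
#' benthic/pelagic mixture while transiting, so the dive-score distribution
#' is genuinely bimodal.  The trip starts and ends at the colony.
#'
#' @param seascape a [generate_seascape()] result.
#' @param spec a [trip_spec()].
#' @param depth generate the depth trace (default TRUE; skip for
#'   track-only simulations).
#' @return list with `track` (time, x, y), `states` (per-fix behavioural
#'   state and patch id), `depth` (time, depth; NULL if `depth = FALSE`),
#'   `truth` (one row per dive: start, duration, max_depth, type, in_bout,
#'   patch, structure_driven), `patches` (centres and provenance), `spec`.
#' @export
generate_trip <- function(seascape, spec = trip_spec(), depth = TRUE) {
  stopifnot(inherits(seascape, "seascape"), inherits(spec, "trip_spec"))
  if (spec$attraction_strength > 0) {
    ok <- any(vapply(spec$attraction_targets, function(ty)
      has_structure_type(seascape$structures,
                         switch(ty, pipeline = "pipeline", cable = "cable",
                                well = "wells", shipwreck = "shipwrecks")),
      logical(1)))
    if (!ok) stop("attraction targets absent from the seascape")
  }
  withr::with_seed(spec$seed, {
    dur_d <- if (is.null(spec$duration_d))
      stats::runif(1, spec$duration_range[1], spec$duration_range[2])
    else spec$duration_d
    T_total <- dur_d * 86400
    dt <- spec$fix_interval
    colony <- seascape$colony
    width <- seascape$n_cols * seascape$cell
    height <- seascape$n_rows * seascape$cell
    v_transit <- 1.2; v_forage <- 0.35

    n_patches <- if (is.null(spec$n_patches)) sample(2:4, 1) else spec$n_patches
    reach <- min(0.35 * v_transit * T_total, 45000)
    p_struct <- spec$attraction_strength / (1 + spec$attraction_strength)
    patches <- list()
    for (k in seq_len(n_patches)) {
      from_struct <- stats::runif(1) < p_struct
      for (try in 1:50) {
        xy <- if (from_struct)
          sample_structure_point(seascape$structures, spec$attraction_targets)
        else {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- sqrt(stats::runif(1)) * reach
          colony + rad * c(cos(ang), sin(ang))
        }
        inside <- xy[1] > 0 && xy[1] < width && xy[2] > 0 && xy[2] < height &&
          sqrt(sum((xy - colony)^2)) < 1.3 * reach
        if (inside) break
      }
      xy[1] <- min(max(xy[1], 2 * seascape$cell), width - 2 * seascape$cell)
      xy[2] <- min(max(xy[2], 2 * seascape$cell), height - 2 * seascape$cell)
      patches[[k]] <- list(center = xy, structure_driven = from_struct)
    }

    # time budget: transit legs at v_transit; `forage_frac` of the trip in
    # intensive bouts at patch centres; the rest in broad searching around
    # the focal regions
    waypts <- c(list(colony), lapply(patches, `[[`, "center"), list(colony))
    leg_d <- vapply(seq_len(length(waypts) - 1), function(i)
      sqrt(sum((waypts[[i + 1]] - waypts[[i]])^2)), numeric(1))
    t_transit <- sum(leg_d) / v_transit
    dwell_total <- spec$forage_frac * T_total
    search_total <- max(T_total - 1.25 * t_transit - dwell_total,
                        0.1 * T_total)
    dwell <- rep(dwell_total / n_patches, n_patches)
    search_t <- rep(search_total / n_patches, n_patches)
    v_search <- 0.7

    # simulate fixes
    pos <- colony
    heading <- stats::runif(1, 0, 2 * pi)
    times <- 0; xs <- pos[1]; ys <- pos[2]
    state <- "transit"; states <- "transit"; patch_ids <- 0L
    target_i <- 1L  # next patch (n_patches + 1 = colony return)
    dwell_left <- 0
    t <- 0
    max_steps <- ceiling(1.6 * T_total / dt)
    for (step in seq_len(max_steps)) {
      target <- if (target_i <= n_patches) patches[[target_i]]$center else colony
      if (state == "transit") {
        bearing <- atan2(target[2] - pos[2], target[1] - pos[1])
        heading <- bearing + stats::rnorm(1, 0, 0.25)
        v <- max(0.2, stats::rnorm(1, v_transit, 0.15))
      } else if (state == "forage") {
        heading <- heading + stats::rnorm(1, 0, 1.4)
        ctr <- patches[[target_i]]$center
        if (sqrt(sum((pos - ctr)^2)) > spec$patch_radius) {
          # drift back towards the patch centre
          heading <- atan2(ctr[2] - pos[2], ctr[1] - pos[1]) + stats::rnorm(1, 0, 0.6)
        }
        v <- max(0.05, stats::rnorm(1, v_forage, 0.1))
      } else {  # search: wide wandering around the focal region
        heading <- heading + stats::rnorm(1, 0, 0.8)
        ctr <- patches[[target_i]]$center
        if (sqrt(sum((pos - ctr)^2)) > spec$search_radius)
          heading <- atan2(ctr[2] - pos[2], ctr[1] - pos[1]) + stats::rnorm(1, 0, 0.6)
        v <- max(0.1, stats::rnorm(1, v_search, 0.15))
      }
      pos <- pos + v * dt * c(cos(heading), sin(heading))
      pos[1] <- min(max(pos[1], seascape$cell), width - seascape$cell)
      pos[2] <- min(max(pos[2], seascape$cell), height - seascape$cell)
      t <- t + dt
      times <- c(times, t); xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
      if (state == "transit") {
        if (target_i > n_patches) {
          if (sqrt(sum((pos - colony)^2)) < 2 * seascape$cell) break
        } else if (sqrt(sum((pos - target)^2)) < 1000) {
          state <- "forage"; dwell_left <- dwell[target_i]
        }
      } else if (state == "forage") {
        dwell_left <- dwell_left - dt
        if (dwell_left <= 0) { state <- "search"; dwell_left <- search_t[target_i] }
      } else {
        dwell_left <- dwell_left - dt
        if (dwell_left <= 0) { target_i <- target_i + 1L; state <- "transit" }
      }
      states <- c(states, state)
      patch_ids <- c(patch_ids, if (state == "forage") target_i else 0L)
      if (t > 1.5 * T_total) break
    }
    states <- c(states[seq_len(length(times) - 1)], "transit")
    patch_ids <- c(patch_ids[seq_len(length(times) - 1)], 0L)
    xs[length(xs)] <- colony[1]; ys[length(ys)] <- colony[2]
    track <- data.frame(time = times, x = xs, y = ys)
    st <- data.frame(time = times, state = states, patch = patch_ids)

    # dive schedule and depth trace
    truth <- NULL; depth_series <- NULL
    mean_gap <- 3600 / spec$dive_rate
    dive_starts <- numeric(0)
    tcur <- stats::runif(1, 0, mean_gap)
    while (tcur < times[length(times)] - 400) {
      dive_starts <- c(dive_starts, tcur)
      tcur <- tcur + mean_gap * stats::runif(1, 0.7, 1.3)
    }
    rows <- list()
    segs <- list()  # per dive: times/depths of the profile
    for (ds in dive_starts) {
      i <- findInterval(ds, times)
      px <- stats::approx(times, xs, xout = ds)$y
      py <- stats::approx(times, ys, xout = ds)$y
      local_depth <- raster_lookup(seascape$bathymetry, px, py)
      if (!is.finite(local_depth)) local_depth <- seascape$mean_depth
      in_bout <- states[i] == "forage"
      pel <- !in_bout && stats::runif(1) < spec$pelagic_mix
      if (pel) {
        mx <- stats::runif(1, 0.2, 0.45) * local_depth
        rate <- 1.5
        t_leg <- mx / rate
        prof_t <- c(0, t_leg, 2 * t_leg)
        prof_z <- c(0, mx, 0)
        type <- "pelagic"
      } else {
        mx <- local_depth * stats::runif(1, 0.95, 1.0)
        rate <- 1.5
        t_leg <- mx / rate
        bottom <- stats::runif(1, 60, 180)
        prof_t <- c(0, t_leg, t_leg + bottom, 2 * t_leg + bottom)
        prof_z <- c(0, mx, mx, 0)
        type <- "benthic"
      }
      rows[[length(rows) + 1]] <- data.frame(
        start = ds, duration = prof_t[length(prof_t)], max_depth = mx,
        type = type, in_bout = in_bout,
        patch = if (in_bout) patch_ids[i] else 0L,
        structure_driven = in_bout && patch_ids[i] > 0 &&
          patches[[patch_ids[i]]]$structure_driven)
      segs[[length(segs) + 1]] <- list(t = ds + prof_t, z = prof_z)
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(start = numeric(0), duration = numeric(0),
                 max_depth = numeric(0), type = character(0),
                 in_bout = logical(0), patch = integer(0),
                 structure_driven = logical(0))
    if (depth) {
      tt <- seq(0, times[length(times)], by = spec$depth_interval)
      zz <- numeric(length(tt))
      for (sg in segs) {
        sel <- tt >= sg$t[1] & tt <= sg$t[length(sg$t)]
        if (any(sel))
          zz[sel] <- pmax(zz[sel], stats::approx(sg$t, sg$z, xout = tt[sel])$y)
      }
      drift <- spec$surface_drift[1] +
        (spec$surface_drift[2] - spec$surface_drift[1]) * tt / tt[length(tt)]
      depth_series <- data.frame(time = tt, depth = zz + drift)
    }
    list(track = track, states = st, depth = depth_series, truth = truth,
         patches = patches, duration_s = times[length(times)], spec = spec)
  })
}

#' Buffered-area fraction of structures in a seascape
#'
#' Fraction of grid cell centres lying within `radius` of any structure,
#' optionally restricted to a disc around a centre point.  This is the
#' analytic null for buffer occupancy by a track that samples the region
#' uniformly.
#'
#' @param seascape a seascape.
#' @param radius buffer radius (m, default 250).
#' @param center,max_dist optional disc restriction (planar point and
#'   radius in metres).
#' @return fraction in \[0, 1\].
#' @export
buffered_area_fraction <- function(seascape, radius = 250,
                                   center = NULL, max_dist = NULL) {
  cc <- cell_centers(seascape$bathymetry)
  px <- as.vector(cc$X); py <- as.vector(cc$Y)
  if (!is.null(center) && !is.null(max_dist)) {
    sel <- (px - center[1])^2 + (py - center[2])^2 <= max_dist^2
    px <- px[sel]; py <- py[sel]
  }
  d <- structure_distance(seascape$structures, px, py, "any")
  mean(d <= radius)
}
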