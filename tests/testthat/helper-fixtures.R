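# Shared fixture builders for the test suite.  All synthetic, all seeded.

# 1 Hz depth trace containing the given dive profiles (list of list(t0,
# profile times, depths)) on a flat surface baseline.
make_depth_trace <- function(total_s, dives, hz = 1) {
  tt <- seq(0, total_s, by = 1 / hz)
  zz <- numeric(length(tt))
  for (d in dives) {
    sel <- tt >= d$t[1] & tt <= d$t[length(d$t)]
    zz[sel] <- pmax(zz[sel], stats::approx(d$t, d$z, xout = tt[sel])$y)
  }
  data.frame(time = tt, depth = zz)
}

# square dive: instant-ish descent/ascent with a flat bottom
square_dive <- function(t0, depth, bottom_s, rate = 2) {
  leg <- depth / rate
  list(t = t0 + c(0, leg, leg + bottom_s, 2 * leg + bottom_s),
       z = c(0, depth, depth, 0))
}

# V-shaped dive: linear down then linear up
v_dive <- function(t0, depth, total_s) {
  list(t = t0 + c(0, total_s / 2, total_s), z = c(0, depth, 0))
}

# independent brute-force dive scan: walk the samples, find runs above the
# surface threshold, keep those reaching min_depth
oracle_dive_scan <- function(series, min_depth = 5, surface = 0.5) {
  t <- series$time; z <- series$depth
  out <- NULL
  i <- 1; n <- length(t)
  while (i <= n) {
    if (z[i] > surface) {
      j <- i
      while (j < n && z[j + 1] > surface) j <- j + 1
      if (max(z[i:j]) >= min_depth)
        out <- rbind(out, data.frame(start = t[i], end = t[j],
                                     max_depth = max(z[i:j])))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out)) data.frame(start = numeric(0), end = numeric(0),
                               max_depth = numeric(0)) else out
}

# small seascape for fast pipeline-level tests
small_seascape <- function(seed = 1, n = 140)
  generate_seascape(n_rows = n, n_cols = n, seed = seed)

# straight-line regularised track with uniform underwater fraction
transit_track <- function(n = 400, v = 1.2, dt = 600, uw_frac = 0.4) {
  traj <- data.frame(time = (0:(n - 1)) * dt, x = (0:(n - 1)) * dt * v, y = 0)
  traj$uw <- c(rep(uw_frac * dt, n - 1), 0)
  traj
}

# controlled two-patch trajectory: transit legs + bouts confined to discs
# of known radius R (rejection-sampled random walk), uniform diving
two_patch_track <- function(R = 2000, v = 1.2, dt = 600, bout_n = 60,
                            uw_frac = 0.4, seed = 5) {
  withr::with_seed(seed, {
    mk_bout <- function(cx, cy, n) {
      xs <- numeric(n); ys <- numeric(n); x <- cx; y <- cy
      for (i in seq_len(n)) {
        repeat {
          nx <- x + stats::rnorm(1, 0, 300); ny <- y + stats::rnorm(1, 0, 300)
          if ((nx - cx)^2 + (ny - cy)^2 <= R^2) break
        }
        x <- nx; y <- ny; xs[i] <- x; ys[i] <- y
      }
      cbind(xs, ys)
    }
    seg <- function(x0, y0, x1, y1) {
      d <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
      n <- max(2, round(d / (v * dt)))
      cbind(seq(x0, x1, length.out = n), seq(y0, y1, length.out = n))
    }
    pts <- rbind(seg(0, 0, 20000, 0), mk_bout(20000, 0, bout_n),
                 seg(20000, 0, 40000, 15000), mk_bout(40000, 15000, bout_n),
                 seg(40000, 15000, 0, 0))
    traj <- data.frame(time = (seq_len(nrow(pts)) - 1) * dt,
                       x = pts[, 1], y = pts[, 2])
    traj$uw <- c(rep(uw_frac * dt, nrow(traj) - 1), 0)
    traj
  })
}

# run the per-seal analysis chain on one generated trip and return the
# contribution table plus intermediates (used by recovery-style tests)
seal_chain <- function(sea, spec, background, stack = NULL,
                       background_n = 4000, max_iter = 1000) {
  trip <- generate_trip(sea, spec)
  dep <- zero_offset_correct(trip$depth)
  dv <- detect_dives(dep)
  cl <- classify_dives(dv)
  dv <- cl$dives
  if (cl$unimodal) dv$dive_class <- "benthic"
  reg <- attach_underwater(interpolate_track(speed_filter(trip$track)), dv)
  loc <- merge_dives(reg, dv)
  radii <- default_radii()
  sc <- suppressWarnings(as.numeric(select_scale(fpd_matrix(reg, radii), radii)))
  ev <- intensive_areas(reg, loc, sc, sea$bathymetry)
  if (is.null(stack))
    stack <- covariate_stack(sea$bathymetry, sea$colony, sea$coastline,
                             sea$structures)
  obs <- extract_covariates(stack, ev)
  if (is.null(background))
    background <- sample_background(stack, n = background_n, seed = spec$seed)
  pp <- partition_data(obs, seed = spec$seed)
  m <- fit_maxent(pp$train, background, max_iter = max_iter)
  list(trip = trip, dives = dv, track = reg, events = ev, obs = obs,
       model = m, contrib = variable_contribution(m),
       auc = evaluate_auc(m, pp$test, background), scale = sc)
}
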