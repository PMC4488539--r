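test_that("FPD equals total underwater time for a stationary diver", {
  traj <- data.frame(time = (0:99) * 600, x = 0, y = 0)
  traj$uw <- c(rep(100, 99), 0)
  for (r in c(250, 1000, 20000)) {
    pr <- fpd_profile(traj, 50, r)
    expect_equal(pr$time_underwater, sum(traj$uw))
  }
})

test_that("FPD on a uniform transit matches the 2rf/v closed form", {
  v <- 1.2; f <- 0.4
  traj <- transit_track(n = 400, v = v, uw_frac = f)
  radii <- c(1000, 3000, 8000, 15000)
  pr <- fpd_profile(traj, 200, radii)
  expect_equal(pr$time_underwater, 2 * radii * f / v, tolerance = 0.05)
})

test_that("FPD profiles are non-decreasing in radius and bounded by trip total", {
  sea <- small_seascape(seed = 4)
  trip <- generate_trip(sea, trip_spec(duration_d = 3, seed = 5))
  dv <- detect_dives(zero_offset_correct(trip$depth))
  reg <- attach_underwater(interpolate_track(speed_filter(trip$track)), dv)
  radii <- default_radii()
  total <- sum(reg$uw)
  for (p in round(seq(2, nrow(reg) - 1, length.out = 12))) {
    pr <- fpd_profile(reg, p, radii)
    expect_true(all(diff(pr$time_underwater) >= -1e-9))
    expect_true(all(pr$time_underwater <= total + 1e-6))
  }
  # at a radius spanning the whole trip, FPD = total for every point
  span <- 10 * max(abs(c(reg$x, reg$y))) + 1e5
  fr <- fpd_matrix(reg, span)
  expect_true(all(abs(fr[, 1] - total) < 1e-6))
  expect_error(fpd_profile(reg, 3, c(-5, 100)), "positive")
})

test_that("scale selection recovers a known patch radius and is rigid-motion invariant", {
  R <- 2000
  traj <- two_patch_track(R = R, seed = 5)
  radii <- default_radii()
  sc <- select_scale(fpd_matrix(traj, radii), radii)
  expect_gte(as.numeric(sc), R / 2)
  expect_lte(as.numeric(sc), R * 2)
  # variance curve should be unimodal around its peak (single dominant patch scale)
  v <- attr(sc, "variances")
  pk <- which.max(v)
  expect_true(all(diff(v[pk:length(v)]) <= 1e-9))

  # rotation + translation + time shift leave the selection unchanged
  th <- 0.7
  rot <- traj
  rot$x <- cos(th) * traj$x - sin(th) * traj$y + 5e4
  rot$y <- sin(th) * traj$x + cos(th) * traj$y - 2e4
  rot$time <- rot$time + 86400
  expect_equal(as.numeric(select_scale(fpd_matrix(rot, radii), radii)),
               as.numeric(sc))
})

test_that("uniform behaviour triggers the degenerate scale warning", {
  traj <- data.frame(time = (0:49) * 600, x = 0, y = 0)
  traj$uw <- c(rep(100, 49), 0)
  radii <- c(500, 1000, 2000)
  expect_warning(sc <- select_scale(fpd_matrix(traj, radii), radii),
                 "no variance")
  expect_equal(as.numeric(sc), 500)
})

test_that("intensive areas deduplicate to grid cells and obey count bounds", {
  grid <- searaster(matrix(60, 100, 100), 0, 0, 250)
  # one tight patch smaller than a cell in the middle of a transit
  traj <- withr::with_seed(2, {
    a <- data.frame(time = (0:29) * 600, x = seq(0, 20000, length.out = 30),
                    y = 1000)
    b <- data.frame(time = (30:69) * 600, x = 20050 + runif(40, 0, 80),
                    y = 1050 + runif(40, 0, 80))
    cc <- data.frame(time = (70:99) * 600,
                     x = seq(20100, 24000, length.out = 30), y = 1000)
    rbind(a, b, cc)
  })
  traj$uw <- c(rep(200, nrow(traj) - 1), 0)
  dives <- data.frame(start = traj$time[31:69], duration = 180,
                      x = traj$x[31:69], y = traj$y[31:69],
                      dive_class = "benthic")
  ev <- intensive_areas(traj, dives, scale = 1000, grid)
  expect_equal(nrow(ev), 1)
  expect_true(ev$n_dives <= nrow(dives))

  # bound: events <= occupied cells and <= flagged benthic dives
  sea <- small_seascape(seed = 3)
  trip <- generate_trip(sea, trip_spec(duration_d = 4, n_patches = 2, seed = 21))
  dv <- classify_dives(detect_dives(zero_offset_correct(trip$depth)))$dives
  reg <- attach_underwater(interpolate_track(speed_filter(trip$track)), dv)
  loc <- merge_dives(reg, dv)
  radii <- default_radii()
  sc <- as.numeric(select_scale(fpd_matrix(reg, radii), radii))
  ev2 <- intensive_areas(reg, loc, sc, sea$bathymetry)
  benthic <- sum(loc$dive_class == "benthic")
  occupied <- nrow(unique(cell_index(sea$bathymetry, loc$x, loc$y)))
  expect_lte(nrow(ev2), benthic)
  expect_lte(nrow(ev2), occupied)
  expect_equal(nrow(ev2), nrow(unique(ev2[, c("row", "col")])))
})

test_that("flagged cells recover truth-labelled bout dives on a synthetic trip", {
  sea <- small_seascape(seed = 3, n = 160)
  trip <- generate_trip(sea, trip_spec(duration_d = 5, n_patches = 2, seed = 21))
  dv <- classify_dives(detect_dives(zero_offset_correct(trip$depth)))$dives
  reg <- attach_underwater(interpolate_track(speed_filter(trip$track)), dv)
  loc <- merge_dives(reg, dv)
  radii <- default_radii()
  sc <- as.numeric(select_scale(fpd_matrix(reg, radii), radii))
  ev <- intensive_areas(reg, loc, sc, sea$bathymetry)
  truth <- trip$truth[trip$truth$in_bout, ]
  tx <- approx(trip$track$time, trip$track$x, xout = truth$start)$y
  ty <- approx(trip$track$time, trip$track$y, xout = truth$start)$y
  ij <- cell_index(sea$bathymetry, tx, ty)
  hit <- paste(ij$row, ij$col) %in% paste(ev$row, ev$col)
  expect_gte(mean(hit), 0.9)
})
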