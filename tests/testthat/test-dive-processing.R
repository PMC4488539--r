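test_that("zero-offset correction removes constant and drifting surface offsets", {
  dives <- list(square_dive(600, 40, 120), square_dive(2400, 35, 100),
                square_dive(4200, 45, 150), square_dive(6000, 38, 90))
  base <- make_depth_trace(7200, dives)

  # constant +2 m offset
  off <- base; off$depth <- off$depth + 2
  corr <- zero_offset_correct(off, window = 1800)
  surface <- base$depth == 0
  expect_lt(max(corr$depth[surface]), 0.25)
  # dive depths preserved to within the offset estimate
  expect_equal(max(corr$depth), max(base$depth), tolerance = 0.02)

  # already zeroed: unchanged within tolerance
  corr0 <- zero_offset_correct(base, window = 1800)
  expect_lt(max(abs(corr0$depth - base$depth)), 1e-6)

  # linear drift 0 -> 3 m over a day-long record
  long <- make_depth_trace(86400, lapply(seq(600, 85000, by = 1200),
                                         function(t0) square_dive(t0, 40, 120)))
  drift <- long
  drift$depth <- drift$depth + 3 * drift$time / max(drift$time)
  corrd <- zero_offset_correct(drift, window = 1800)
  expect_lt(max(corrd$depth[long$depth == 0]), 0.5)

  expect_error(zero_offset_correct(data.frame(time = numeric(0),
                                              depth = numeric(0))),
               "empty")
})

test_that("dive detection finds threshold-crossing submergences", {
  tr <- data.frame(time = 0:5, depth = c(0, 0, 6, 10, 6, 0))
  d <- detect_dives(tr)
  expect_equal(nrow(d), 1)
  expect_equal(d$max_depth, 10)

  shallow <- data.frame(time = 0:5, depth = c(0, 2, 4.9, 4.9, 2, 0))
  expect_equal(nrow(detect_dives(shallow)), 0)
})

test_that("dive detection matches an exhaustive interval scan on random traces", {
  for (seed in 1:8) {
    trace <- withr::with_seed(seed, {
      n_dives <- sample(5:20, 1)
      t0s <- sort(runif(n_dives, 0, 20000))
      t0s <- t0s[c(TRUE, diff(t0s) > 500)]  # keep dives separated
      dives <- lapply(t0s, function(t0) {
        if (runif(1) < 0.5) square_dive(t0, runif(1, 2, 60), runif(1, 30, 200))
        else v_dive(t0, runif(1, 2, 60), runif(1, 60, 300))
      })
      make_depth_trace(21000, dives)
    })
    got <- detect_dives(trace)
    want <- oracle_dive_scan(trace)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$max_depth, want$max_depth)
  }
})

test_that("bottom proportion matches analytic and counting oracles", {
  # square wave: all time at the bottom
  sq <- square_dive(0, 40, 300, rate = 1e6)
  slice <- data.frame(time = seq(0, 300, by = 1))
  slice$depth <- approx(sq$t, sq$z, xout = slice$time, rule = 2)$y
  expect_equal(bottom_proportion(slice), 1.0, tolerance = 0.005)

  # V dive: fraction of a triangle above 80% of max is 0.2
  vv <- v_dive(0, 50, 1000)
  sl <- data.frame(time = seq(0, 1000, by = 0.5))
  sl$depth <- approx(vv$t, vv$z, xout = sl$time)$y
  expect_equal(bottom_proportion(sl), 0.2, tolerance = 0.005)

  # skewed random profile: equals a direct per-sample count
  sl2 <- withr::with_seed(3, {
    t <- seq(0, 600, by = 1)
    data.frame(time = t, depth = 30 + 10 * sin(t / 50) + rnorm(length(t)))
  })
  thr <- 0.8 * max(sl2$depth)
  expect_equal(bottom_proportion(sl2),
               mean(sl2$depth >= thr), tolerance = 0.01)

  expect_error(bottom_proportion(data.frame(time = 1, depth = 5)),
               "zero-duration")
})

test_that("KDE-nadir classifier separates a bimodal score mixture", {
  make_dives <- function(scores) {
    data.frame(start = seq_along(scores), end = seq_along(scores) + 100,
               duration = 100, max_depth = pmax(scores, 1),
               bottom_time_prop = 0.5, score = scores,
               dive_class = NA_character_)
  }
  # well-separated two-Gaussian mixture, known components
  scores <- withr::with_seed(11, c(rnorm(500, 5, 1.2), rnorm(500, 30, 4)))
  truth <- rep(c("pelagic", "benthic"), each = 500)
  cl <- classify_dives(make_dives(scores))
  expect_false(cl$unimodal)
  expect_lt(mean(cl$dives$dive_class != truth), 0.02)

  # equal clusters at 10 and 20: nadir near the midpoint 15
  sym <- withr::with_seed(4, c(rnorm(400, 10, 1), rnorm(400, 20, 1)))
  cls <- classify_dives(make_dives(sym))
  expect_equal(cls$nadir, 15, tolerance = 1.5)

  # identical scores: unimodal signal, all unclassified
  cu <- classify_dives(make_dives(rep(12, 50)))
  expect_true(cu$unimodal)
  expect_true(all(cu$dives$dive_class == "unclassified"))
  # fallback threshold classifies anyway
  cf <- classify_dives(make_dives(rep(12, 50)), fallback_threshold = 10)
  expect_true(all(cf$dives$dive_class == "benthic"))

  # order invariance
  perm <- withr::with_seed(9, sample(length(scores)))
  clp <- classify_dives(make_dives(scores[perm]))
  expect_equal(clp$dives$dive_class, cl$dives$dive_class[perm])

  # scale consistency: doubling depths doubles scores, same partition
  d1 <- make_dives(scores)
  d2 <- d1; d2$score <- d1$score * 2; d2$max_depth <- d1$max_depth * 2
  c2 <- classify_dives(d2)
  expect_equal(c2$nadir, 2 * cl$nadir, tolerance = 0.05 * cl$nadir)
  expect_equal(c2$dives$dive_class, cl$dives$dive_class)
})

test_that("dive score is bottom proportion times maximum depth", {
  trace <- make_depth_trace(4000, list(square_dive(500, 40, 200),
                                       v_dive(2000, 30, 400)))
  d <- detect_dives(trace)
  expect_equal(d$score, d$bottom_time_prop * d$max_depth)
  expect_true(all(d$score >= 0 & d$score <= d$max_depth))
})
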