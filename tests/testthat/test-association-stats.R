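test_that("buffer occupancy handles the trivial extremes", {
  st <- structure_set(wells = rbind(c(0, 0)),
                      pipelines = list(cbind(c(-1e5, -1e5), c(0, 1e4))),
                      shipwrecks = rbind(c(-2e5, 0)))
  # track always far from everything
  far <- data.frame(time = (0:50) * 600, x = 5e4 + (0:50) * 100, y = 5e4)
  occ <- buffer_occupancy(far, st)
  expect_equal(occ$prop_any, 0)
  expect_equal(occ$n_types_visited, 0)

  # stationary at the well for the whole trip
  home <- data.frame(time = (0:50) * 600, x = 10, y = -10)
  occh <- buffer_occupancy(home, st)
  expect_equal(occh$prop_any, 1)
  expect_equal(occh$prop_wells, 1)
  expect_equal(occh$prop_pipes_cables, 0)
})

test_that("a straight crossing of a buffered pipeline accrues the chord time", {
  v <- 1.5; dt <- 600
  # pipeline along x = 0; cross it perpendicular at speed v
  st <- structure_set(pipelines = list(cbind(c(0, 0), c(-1e5, 1e5))))
  xs <- seq(-30000, 30000, by = v * dt)
  tr <- data.frame(time = seq_along(xs) * dt, x = xs, y = 0)
  occ <- buffer_occupancy(tr, st, radius = 250)
  chord <- 2 * 250 / v
  expect_lt(abs(occ$pipes_cables_s - chord), dt + 1e-9)
})

test_that("occupancy is monotone in buffer radius", {
  sea <- small_seascape(seed = 5)
  trip <- generate_trip(sea, trip_spec(duration_d = 3, seed = 9), depth = FALSE)
  reg <- interpolate_track(speed_filter(trip$track))
  props <- vapply(c(250, 1000, 4000, 12000), function(r)
    buffer_occupancy(reg, sea$structures, radius = r)$prop_any, numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("cohort structure-use summary matches hand tabulation and is order invariant", {
  row_occ <- function(id, pc, we) data.frame(
    individual_id = id, pipes_cables_s = pc, wells_s = we, shipwrecks_s = 0,
    any_structure_s = pc + we, trip_duration_s = 86400,
    prop_pipes_cables = pc / 86400, prop_wells = we / 86400,
    prop_shipwrecks = 0, prop_any = (pc + we) / 86400,
    n_types_visited = (pc > 0) + (we > 0))
  occ <- rbind(row_occ("a", 3600, 0), row_occ("b", 1800, 0),
               row_occ("c", 3600, 600), row_occ("d", 0, 0))
  s <- summarize_structure_use(occ)
  expect_equal(s$pct_visiting, 75)
  expect_equal(unname(s$pct_of_visitors["pipes_cables"]), 100)
  expect_equal(unname(s$pct_of_visitors["wells"]), 100 / 3, tolerance = 1e-9)
  expect_equal(s$n_multi_type, 1)
  # order invariance
  s2 <- summarize_structure_use(occ[c(3, 1, 4, 2), ])
  expect_equal(s2$pct_visiting, s$pct_visiting)
  expect_equal(s2$pct_of_visitors, s$pct_of_visitors)
  # all-zero occupancy
  s0 <- summarize_structure_use(row_occ("z", 0, 0))
  expect_equal(s0$pct_visiting, 0)
})

test_that("Kruskal-Wallis handles ties, identical data, and tiny-group enumeration", {
  # identical values: H = 0, p = 1
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$H, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$p, 1)

  # exact permutation oracle on three groups of three small integers
  x <- c(1, 3, 2, 7, 5, 9, 4, 8, 6)
  grp <- list(x[1:3], x[4:6], x[7:9])
  got <- kruskal_wallis(grp)

  # independent H: rank formula computed from scratch
  r <- rank(x)
  Hdir <- 12 / (9 * 10) * sum(tapply(r, rep(1:3, each = 3), sum)^2 / 3) - 3 * 10
  expect_equal(got$H, Hdir, tolerance = 1e-10)
  expect_equal(got$df, 2)

  # exact permutation p: enumerate all 1680 assignments into groups of 3
  idx <- 1:9
  Hs <- c()
  for (g1 in utils::combn(idx, 3, simplify = FALSE)) {
    rest <- setdiff(idx, g1)
    for (g2 in utils::combn(rest, 3, simplify = FALSE)) {
      g3 <- setdiff(rest, g2)
      rr <- rank(x)
      H <- 12 / (9 * 10) * (sum(rr[g1])^2 / 3 + sum(rr[g2])^2 / 3 +
                              sum(rr[g3])^2 / 3) - 3 * 10
      Hs <- c(Hs, H)
    }
  }
  p_exact <- mean(Hs >= Hdir - 1e-12)
  # chi-square approximation agrees with the exact tail to within 0.1
  expect_lt(abs(got$p - p_exact), 0.1)
})

test_that("arcsine transform follows its closed forms", {
  expect_equal(arcsin_transform(0), 0)
  expect_equal(arcsin_transform(1), pi / 2)
  expect_equal(arcsin_transform(0.25), pi / 6)
  expect_equal(arcsin_transform(0.25, sqrt = FALSE), asin(0.25))
  expect_error(arcsin_transform(1.2), "0, 1")
})

test_that("AICc model set ranks, weights, averages, and recovers the true model", {
  d <- withr::with_seed(1, {
    d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
    d$y <- 2 * d$x1 + rnorm(30)
    d
  })
  # single candidate: weight 1, delta 0
  one <- aicc_model_set(d, "y", list(m = "x1"))
  expect_equal(one$table$weight, 1)
  expect_equal(one$table$delta_AICc, 0)

  ms <- aicc_model_set(d, "y", list(a = "x1", b = "x2", c = c("x1", "x2"),
                                    null = character(0)))
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_equal(min(ms$table$delta_AICc), 0)
  # AICc oracle for one fitted model
  fit <- lm(y ~ x1, data = d)
  k <- 3
  expect_equal(ms$table$AICc[ms$table$model == "a"],
               AIC(fit) + 2 * k * (k + 1) / (30 - k - 1), tolerance = 1e-10)
  # averaged coefficient lies between 0 and the full-model estimate
  expect_gt(ms$averaged["x1"], 0)

  # recovery rate across seeded replicates: the generating model {x1}
  # should usually rank first (the spurious predictor enters by chance
  # in roughly one replicate in ten)
  wins <- 0
  for (r in 1:50) {
    dr <- withr::with_seed(r, {
      dd <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
      dd$y <- 2 * dd$x1 + rnorm(30)
      dd
    })
    mr <- aicc_model_set(dr, "y", list(a = "x1", b = "x2", c = c("x1", "x2")))
    wins <- wins + (mr$table$model[1] == "a")
  }
  expect_gte(wins, 40)
})

test_that("missing predictor rows are dropped to a common likelihood sample", {
  d <- data.frame(x1 = c(1:8, NA, 10), x2 = rnorm(10), y = rnorm(10))
  ms <- aicc_model_set(d, "y", list(a = "x1", b = "x2"))
  expect_equal(ms$n, 9)
})
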