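test_that("distance rasters are exact for points and match brute force for polylines", {
  grid <- searaster(matrix(0, 20, 20), 0, 0, 250)
  cc <- cell_centers(grid)
  # point at a cell centre: 0 there; 4 cells along the row: 1000 m
  p <- c(cc$x[5], cc$y[10])
  d <- distance_raster(grid, points = matrix(p, ncol = 2))
  expect_equal(d$values[10, 5], 0)
  expect_equal(d$values[10, 9], 1000)

  # random polylines vs densified brute force
  for (seed in 1:3) {
    lines <- withr::with_seed(seed, lapply(1:3, function(i) {
      n <- sample(2:5, 1)
      cbind(runif(n, 0, 5000), runif(n, 0, 5000))
    }))
    dr <- distance_raster(grid, lines = lines)
    dense <- do.call(rbind, lapply(lines, function(v) {
      out <- NULL
      for (k in seq_len(nrow(v) - 1)) {
        L <- sqrt(sum((v[k + 1, ] - v[k, ])^2))
        tt <- seq(0, 1, length.out = max(2, ceiling(L)))
        out <- rbind(out, cbind(v[k, 1] + tt * (v[k + 1, 1] - v[k, 1]),
                                v[k, 2] + tt * (v[k + 1, 2] - v[k, 2])))
      }
      out
    }))
    brute <- matrix(NA_real_, 20, 20)
    for (i in 1:20) for (j in 1:20)
      brute[i, j] <- sqrt(min((cc$x[j] - dense[, 1])^2 + (cc$y[i] - dense[, 2])^2))
    expect_lt(max(abs(dr$values - brute)), 1)
  }
  expect_error(distance_raster(grid), "at least one geometry")
})

test_that("distance rasters are 1-Lipschitz across neighbouring cells", {
  grid <- searaster(matrix(0, 30, 30), 0, 0, 250)
  d <- withr::with_seed(8, distance_raster(
    grid, lines = list(cbind(runif(4, 0, 7500), runif(4, 0, 7500))),
    points = cbind(runif(3, 0, 7500), runif(3, 0, 7500))))
  v <- d$values
  expect_lte(max(abs(diff(v))), 250 + 1e-9)       # down columns
  expect_lte(max(abs(t(diff(t(v))))), 250 + 1e-9) # across rows
})

test_that("terrain complexity is zero for flat and planar depth, analytic for quadratic", {
  flat <- searaster(matrix(60, 10, 10), 0, 0, 250)
  expect_true(all(terrain_complexity(flat)$values == 0))

  # planar ramp: zero second derivative in the interior
  cc <- cell_centers(searaster(matrix(0, 12, 12), 0, 0, 250))
  ramp <- searaster(0.01 * cc$X + 0.005 * cc$Y, 0, 0, 250)
  cr <- terrain_complexity(ramp)$values
  expect_lt(max(abs(cr[3:10, 3:10])), 1e-12)

  # quadratic z = a x^2 (x > 0 everywhere): slope = 2ax, complexity = 2a
  a <- 1e-6
  quad <- searaster(a * cc$X^2, 0, 0, 250)
  cq <- terrain_complexity(quad)$values
  expect_equal(max(abs(cq[3:10, 3:10] - 2 * a)), 0, tolerance = 1e-8)

  # invariant to datum offset and sign flip
  r <- searaster(withr::with_seed(1, matrix(rnorm(144, 60, 5), 12, 12)), 0, 0, 250)
  c1 <- terrain_complexity(r)$values
  r2 <- r; r2$values <- r$values + 100
  r3 <- r; r3$values <- -r$values
  expect_equal(terrain_complexity(r2)$values, c1)
  expect_equal(terrain_complexity(r3)$values, c1)

  expect_error(terrain_complexity(searaster(matrix(0, 2, 2), 0, 0, 250)),
               "3 x 3")
})

test_that("covariate extraction deduplicates cells and matches direct lookups", {
  sea <- small_seascape(seed = 6, n = 60)
  st <- covariate_stack(sea$bathymetry, sea$colony, sea$coastline,
                        sea$structures)
  # 10 events in the same cell collapse to one row
  ev1 <- data.frame(row = rep(7, 10), col = rep(9, 10))
  expect_equal(nrow(extract_covariates(st, ev1)), 1)
  # k distinct cells give k rows
  evk <- data.frame(row = c(3, 5, 9), col = c(4, 4, 20))
  obs <- extract_covariates(st, evk)
  expect_equal(nrow(obs), 3)
  # values equal direct indexing
  for (nm in names(st))
    expect_equal(obs[[nm]], st[[nm]]$values[cbind(evk$row, evk$col)])
  # out-of-grid events dropped with count
  evo <- data.frame(row = c(3, 1000), col = c(4, 4))
  obso <- extract_covariates(st, evo)
  expect_equal(nrow(obso), 1)
  expect_equal(attr(obso, "n_dropped"), 1)
})

test_that("VIF screen matches brute-force 1/(1-R2) and flags collinearity", {
  X <- withr::with_seed(5, as.data.frame(matrix(rnorm(200 * 4), 200, 4)))
  names(X) <- paste0("v", 1:4)
  got <- vif_screen(X)
  # independent oracle: explicit least squares via the normal equations
  for (j in 1:4) {
    A <- cbind(1, as.matrix(X[, -j]))
    y <- X[[j]]
    beta <- solve(crossprod(A), crossprod(A, y))
    r2 <- 1 - sum((y - A %*% beta)^2) / sum((y - mean(y))^2)
    expect_equal(got$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
  expect_false(any(got$flagged))

  # duplicated column: infinite VIF, flagged
  X2 <- X; X2$v5 <- X$v1
  got2 <- vif_screen(X2)
  expect_true(all(got2$flagged[c(1, 5)]))
  expect_true(all(is.infinite(got2$vif[c(1, 5)])))
})

test_that("ESRI ASCII and structures GeoJSON round-trip", {
  r <- searaster(withr::with_seed(2, matrix(round(rnorm(30, 60, 5), 3), 5, 6)),
                 -1000, 2000, 250)
  r$values[2, 3] <- NA
  f <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(r, f)
  r2 <- read_esri_ascii(f)
  expect_equal(r2$values, r$values, tolerance = 1e-4)
  expect_equal(c(r2$xll, r2$yll, r2$cell), c(r$xll, r$yll, r$cell))

  st <- structure_set(
    pipelines = list(cbind(c(0, 5000), c(0, 8000))),
    cables = list(cbind(c(1000, 2000, 3000), c(0, 500, 0))),
    wells = rbind(c(2500, 2500)), shipwrecks = rbind(c(100, 9000)))
  g <- withr::local_tempfile(fileext = ".geojson")
  origin <- c(146.3, -39.15)
  write_structures_geojson(st, g, origin = origin)
  st2 <- read_structures_geojson(g, origin = origin)
  px <- c(0, 1234, 4000); py <- c(0, 567, 7000)
  for (ty in c("pipes_cables", "wells", "shipwrecks"))
    expect_equal(structure_distance(st2, px, py, ty),
                 structure_distance(st, px, py, ty), tolerance = 0.5)
})
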