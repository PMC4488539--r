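#' Default pipeline configuration
#'
#' The fixed analysis constants: 5 m minimum dive depth, 10-min track
#' regularisation, 3 m/s speed filter, 250 m structure buffer, 70/30
#' presence split, 10000 background points, regularisation multiplier 1,
#' convergence threshold 1e-5, 1000 maximum iterations, 15 log-spaced
#' first-passage radii from 250 m to 20 km, and the 0.75 intensive-use
#' quantile.
#'
#' @param ... overrides of any default element.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_depth = 5, surface_threshold = 0.5, bottom_fraction = 0.8,
    zoc_window = 1800,
    vmax = 3, interval = 600,
    radii_from = 250, radii_to = 20000, radii_n = 15,
    fpd_quantile = 0.75,
    buffer = 250,
    train_frac = 0.7, background_n = 10000,
    r = 1, tol = 1e-5, max_iter = 1000,
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML, flat keys matching [default_config()] plus the input paths
#' (`data_dir`, `colony_lon`, `colony_lat`).  Unknown keys are an error;
#' missing keys take defaults.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c(names(default_config()),
               "data_dir", "colony_lon", "colony_lat")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- default_config()
  cfg[names(raw)] <- raw
  cfg
}

iso_time <- function(t, epoch = "2010-06-01 00:00:00") {
  format(as.POSIXct(epoch, tz = "UTC") + t, "%Y-%m-%dT%H:%M:%SZ")
}

#' Write a synthetic cohort dataset to disk
#'
#' Generates a seascape and one trip per seal and writes the full input
#' layout the pipeline reads: per-seal GPS CSV (`time,lon,lat`), depth CSV
#' (`time,depth_m`), structures GeoJSON, coastline CSV, bathymetry ESRI
#' ASCII grid, per-seal truth-label CSV, a morphometrics table and a ready
#' `config.yml`.  All coordinates are written in geographic lon/lat about
#' the colony; the bathymetry grid is written in colony-centred planar
#' metres.
#'
#' @param out_dir output directory.
#' @param n_seals number of individuals (default 6).
#' @param seed master seed; per-seal trip seeds derive from it.
#' @param seascape_args list of overrides for [generate_seascape()].
#' @param trip_args list of overrides for [trip_spec()] (applied to every
#'   seal).
#' @param colony_lonlat geographic colony location (default near the study
#'   colony).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, the config list (with `data_dir` set).
#' @export
simulate_cohort <- function(out_dir, n_seals = 6, seed = 1,
                            seascape_args = list(), trip_args = list(),
                            colony_lonlat = c(146.3, -39.15),
                            overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty; set overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sea <- do.call(generate_seascape,
                 c(seascape_args[setdiff(names(seascape_args), "seed")],
                   list(seed = seed)))
  cx <- sea$colony[1]; cy <- sea$colony[2]
  # colony-centred planar frame on disk
  b <- sea$bathymetry
  write_esri_ascii(searaster(b$values, b$xll - cx, b$yll - cy, b$cell),
                   file.path(out_dir, "bathymetry.asc"))
  shift_line <- function(v) cbind(v[, 1] - cx, v[, 2] - cy)
  shift_pts <- function(p) if (NROW(p)) cbind(p[, 1] - cx, p[, 2] - cy) else p
  st0 <- structure_set(
    pipelines = lapply(sea$structures$pipelines, shift_line),
    cables = lapply(sea$structures$cables, shift_line),
    wells = shift_pts(sea$structures$wells),
    shipwrecks = shift_pts(sea$structures$shipwrecks))
  write_structures_geojson(st0, file.path(out_dir, "structures.geojson"),
                           origin = colony_lonlat)
  coast <- shift_line(sea$coastline)
  ll <- planar_to_lonlat(coast[, 1], coast[, 2], colony_lonlat)
  utils::write.csv(data.frame(lon = ll$lon, lat = ll$lat),
                   file.path(out_dir, "coastline.csv"), row.names = FALSE)
  morpho <- withr::with_seed(seed + 7L, data.frame(
    seal = seq_len(n_seals),
    mass_kg = round(stats::rnorm(n_seals, 77, 12), 1),
    standard_length_cm = round(stats::rnorm(n_seals, 152, 8), 1),
    girth_cm = round(stats::rnorm(n_seals, 103, 8), 1),
    flipper_cm = round(stats::rnorm(n_seals, 42.7, 2.5), 1),
    axis_cm = round(stats::rnorm(n_seals, 64.4, 4), 1),
    age_y = ifelse(stats::runif(n_seals) < 0.3, NA,
                   sample(4:13, n_seals, replace = TRUE))))
  utils::write.csv(morpho, file.path(out_dir, "morphometrics.csv"),
                   row.names = FALSE)
  for (i in seq_len(n_seals)) {
    spec <- do.call(trip_spec,
                    c(trip_args[setdiff(names(trip_args), "seed")],
                      list(seed = seed * 1000L + i)))
    trip <- generate_trip(sea, spec, depth = TRUE)
    tll <- planar_to_lonlat(trip$track$x - cx, trip$track$y - cy, colony_lonlat)
    utils::write.csv(
      data.frame(time = iso_time(trip$track$time), lon = tll$lon, lat = tll$lat),
      file.path(out_dir, sprintf("track_%02d.csv", i)), row.names = FALSE)
    utils::write.csv(
      data.frame(time = iso_time(trip$depth$time),
                 depth_m = round(trip$depth$depth, 3)),
      file.path(out_dir, sprintf("depth_%02d.csv", i)), row.names = FALSE)
    utils::write.csv(trip$truth,
                     file.path(out_dir, sprintf("truth_%02d.csv", i)),
                     row.names = FALSE)
  }
  cfg <- default_config(seed = seed)
  cfg$data_dir <- out_dir
  cfg$colony_lon <- colony_lonlat[1]
  cfg$colony_lat <- colony_lonlat[2]
  yaml::write_yaml(cfg, file.path(out_dir, "config.yml"))
  invisible(cfg)
}

# stage log line to stderr
log_stage <- function(fmt, ...) message(sprintf(paste0("[sealforage] ", fmt), ...))

#' Run the full analysis pipeline over an on-disk dataset
#'
#' Executes, per individual: zero-offset correction, dive detection and
#' benthic/pelagic classification; speed filtering and 10-min track
#' regularisation; first-passage diving analysis (scale selection and
#' intensive-area extraction); covariate extraction on the 250 m stack;
#' the presence-background habitat model with 70/30 evaluation and
#' percent contributions; and 250 m buffer occupancy.  Individuals with
#' fewer than 5 presence cells are reported with empty model fields and
#' skipped, not fatal.  Writes per-seal and cohort outputs plus a manifest
#' to `out_dir` when given.
#'
#' @param config list from [default_config()]/[read_config()], or a path
#'   to a YAML config; must contain `data_dir`, `colony_lon`, `colony_lat`.
#' @param out_dir optional output directory for CSV/JSON results.
#' @return list with `seal_table`, `occupancy`, `cohort`
#'   (structure-use summary), `kruskal` (structure-type contribution
#'   comparison), `models` (per-seal `maxent_model`s), `events` (per-seal
#'   event tables), `vif`, and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  for (key in c("data_dir", "colony_lon", "colony_lat"))
    if (is.null(config[[key]])) stop("config lacks required key: ", key)
  dd <- config$data_dir
  origin <- c(config$colony_lon, config$colony_lat)
  bathy <- read_esri_ascii(file.path(dd, "bathymetry.asc"))
  structures <- read_structures_geojson(file.path(dd, "structures.geojson"),
                                        origin = origin)
  coast_ll <- utils::read.csv(file.path(dd, "coastline.csv"))
  coast <- lonlat_to_planar(coast_ll$lon, coast_ll$lat, origin)
  colony <- c(0, 0)  # colony-centred frame
  log_stage("covariate stack: %d x %d grid", bathy$nrow, bathy$ncol)
  stack <- covariate_stack(bathy, colony, cbind(coast$x, coast$y), structures)
  background <- sample_background(stack, n = config$background_n,
                                  seed = config$seed,
                                  replace = config$background_n > bathy$nrow * bathy$ncol)
  radii <- default_radii(config$radii_from, config$radii_to, config$radii_n)
  morpho_path <- file.path(dd, "morphometrics.csv")
  morpho <- if (file.exists(morpho_path)) utils::read.csv(morpho_path) else NULL

  track_files <- sort(dir(dd, pattern = "^track_[0-9]+\\.csv$", full.names = TRUE))
  if (!length(track_files)) stop("no track files in ", dd)
  ids <- as.integer(sub("^track_0*([0-9]+)\\.csv$", "\\1", basename(track_files)))

  seal_rows <- list(); occ_rows <- list()
  models <- list(); events_all <- list(); obs_all <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    trk <- read_gps_csv(track_files[k], origin = origin)
    dep <- read_depth_csv(file.path(dd, sprintf("depth_%02d.csv", id)))
    dep <- zero_offset_correct(dep, window = config$zoc_window)
    dives <- detect_dives(dep, min_depth = config$min_depth,
                          surface_threshold = config$surface_threshold,
                          bottom_fraction = config$bottom_fraction)
    cls <- if (nrow(dives) >= 2) classify_dives(dives) else
      list(dives = dives, nadir = NA, unimodal = TRUE)
    dives <- cls$dives
    if (cls$unimodal && nrow(dives) > 0) {
      log_stage("seal %d: unimodal score distribution; treating all dives as benthic", id)
      dives$dive_class <- "benthic"
    }
    filt <- speed_filter(trk, vmax = config$vmax)
    reg <- interpolate_track(filt, interval = config$interval)
    reg <- attach_underwater(reg, dives, include = "all")
    located <- merge_dives(reg, dives)
    fpd <- fpd_matrix(reg, radii)
    scale <- suppressWarnings(select_scale(fpd, radii))
    ev <- intensive_areas(reg, located, as.numeric(scale), bathy,
                          quantile = config$fpd_quantile)
    log_stage("seal %d: %d fixes -> %d regular, %d dives (%d benthic), scale %.0f m, %d foraging cells",
              id, nrow(trk), nrow(reg), nrow(dives),
              sum(dives$dive_class == "benthic", na.rm = TRUE),
              as.numeric(scale), nrow(ev))
    events_all[[as.character(id)]] <- ev
    obs <- extract_covariates(stack, ev)
    obs_all[[as.character(id)]] <- obs
    contrib <- stats::setNames(rep(NA_real_, 7),
                               c("depth", "complexity", "d_colony", "d_coast",
                                 "d_pipes_cables", "d_wells", "d_shipwrecks"))
    auc <- NA_real_
    fit <- tryCatch({
      parts <- partition_data(obs, train_frac = config$train_frac,
                              seed = config$seed + id)
      m <- fit_maxent(parts$train, background, r = config$r,
                      tol = config$tol, max_iter = config$max_iter)
      auc <- evaluate_auc(m, parts$test, background)
      ct <- variable_contribution(m)
      contrib[ct$variable] <- ct$contribution
      m
    }, sealforage_insufficient_presences = function(e) {
      log_stage("seal %d: %s", id, conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) models[[as.character(id)]] <- fit
    occ <- buffer_occupancy(reg, structures, radius = config$buffer,
                            individual_id = as.character(id))
    occ_rows[[k]] <- occ
    row <- data.frame(seal = id, n_dives = nrow(dives),
                      n_benthic = sum(dives$dive_class == "benthic", na.rm = TRUE),
                      scale_m = as.numeric(scale),
                      foraging_cells = nrow(obs),
                      t(contrib), auc = auc,
                      prop_any_structure = occ$prop_any)
    seal_rows[[k]] <- row
  }
  seal_table <- do.call(rbind, seal_rows)
  occupancy <- do.call(rbind, occ_rows)
  if (!is.null(morpho))
    seal_table <- merge(morpho, seal_table, by = "seal", all.y = TRUE)
  cohort <- summarize_structure_use(occupancy)
  modelled <- seal_table[!is.na(seal_table$d_pipes_cables), , drop = FALSE]
  kru <- if (nrow(modelled) >= 2)
    kruskal_wallis(list(pipes_cables = modelled$d_pipes_cables,
                        wells = modelled$d_wells,
                        shipwrecks = modelled$d_shipwrecks))
  else NULL
  vif <- if (sum(vapply(obs_all, nrow, integer(1))) > 10)
    vif_screen(do.call(rbind, obs_all)[, names(stack)])
  else NULL
  out <- list(seal_table = seal_table, occupancy = occupancy,
              cohort = cohort, kruskal = kru, models = models,
              events = events_all, vif = vif, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(seal_table, file.path(out_dir, "seal_table.csv"),
                     row.names = FALSE)
    utils::write.csv(occupancy, file.path(out_dir, "occupancy.csv"),
                     row.names = FALSE)
    for (id in names(events_all))
      write_events(events_all[[id]],
                   file.path(out_dir, sprintf("events_%s.csv", id)),
                   origin = origin)
    for (id in names(models))
      write_model_json(models[[id]],
                       file.path(out_dir, sprintf("model_%s.json", id)))
    manifest <- list(
      data_dir = dd, parameters = config,
      n_seals = nrow(seal_table),
      package_version = as.character(utils::packageVersion("sealforage")),
      r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
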