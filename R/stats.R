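#' Time spent within a buffer of sea-floor structures
#'
#' Occupancy is accrued over the regularised track: the midpoint of each
#' 10-min interval is tested against the buffered geometry of each structure
#' type, and the interval's seconds count towards every type whose buffer
#' contains the midpoint, and towards the union ("any structure").  The
#' buffer (default 250 m) absorbs locational error in the structure
#' geometries.
#'
#' @param traj regularised track (`time`, `x`, `y`) with attribute
#'   `regular_interval` (or near-constant spacing).
#' @param structures a [structure_set]; an empty set gives zero occupancy.
#' @param radius buffer radius in metres (default 250).
#' @param individual_id optional label.
#' @return one-row data.frame: seconds and proportions per type
#'   (`pipes_cables`, `wells`, `shipwrecks`), for any structure, trip
#'   duration, and `n_types_visited`.
#' @export
buffer_occupancy <- function(traj, structures, radius = 250,
                             individual_id = NA_character_) {
  stopifnot(radius > 0, nrow(traj) >= 2)
  dt <- diff(traj$time)
  mx <- (traj$x[-1] + traj$x[-nrow(traj)]) / 2
  my <- (traj$y[-1] + traj$y[-nrow(traj)]) / 2
  trip_s <- sum(dt)
  types <- c("pipes_cables", "wells", "shipwrecks")
  secs <- stats::setNames(numeric(3), types)
  inside_any <- rep(FALSE, length(mx))
  for (ty in types) {
    if (!has_structure_type(structures, ty)) next
    d <- structure_distance(structures, mx, my, ty)
    inside <- d <= radius
    secs[ty] <- sum(dt[inside])
    inside_any <- inside_any | inside
  }
  any_s <- sum(dt[inside_any])
  data.frame(
    individual_id = individual_id,
    pipes_cables_s = secs["pipes_cables"], wells_s = secs["wells"],
    shipwrecks_s = secs["shipwrecks"], any_structure_s = any_s,
    trip_duration_s = trip_s,
    prop_pipes_cables = secs["pipes_cables"] / trip_s,
    prop_wells = secs["wells"] / trip_s,
    prop_shipwrecks = secs["shipwrecks"] / trip_s,
    prop_any = any_s / trip_s,
    n_types_visited = sum(secs > 0),
    row.names = NULL
  )
}

#' Cohort summary of structure use
#'
#' Tabulates, over a set of per-individual occupancy rows, how many
#' individuals visited any structure (any-structure time > 0), the
#' percentage of those visitors using each type, the distribution of
#' visit-time proportions, and how many visited more than one type.
#'
#' @param occupancy data.frame of rows from [buffer_occupancy()].
#' @return list with `n`, `n_visiting`, `pct_visiting`, `pct_of_visitors`
#'   (named vector per type), `n_multi_type`, `pct_multi_type`, and
#'   `prop_any_quantiles`.
#' @export
summarize_structure_use <- function(occupancy) {
  stopifnot(nrow(occupancy) >= 1)
  visiting <- occupancy$any_structure_s > 0
  nv <- sum(visiting)
  of_vis <- function(col) if (nv == 0) NA_real_ else
    100 * sum(occupancy[[col]][visiting] > 0) / nv
  list(
    n = nrow(occupancy),
    n_visiting = nv,
    pct_visiting = 100 * nv / nrow(occupancy),
    pct_of_visitors = c(
      pipes_cables = of_vis("pipes_cables_s"),
      wells = of_vis("wells_s"),
      shipwrecks = of_vis("shipwrecks_s")),
    n_multi_type = sum(occupancy$n_types_visited > 1),
    pct_multi_type = 100 * sum(occupancy$n_types_visited > 1) / nrow(occupancy),
    prop_any_quantiles = stats::quantile(occupancy$prop_any,
                                         c(0, 0.25, 0.5, 0.75, 1))
  )
}

#' Kruskal-Wallis rank-sum comparison
#'
#' Tie-corrected H with df = k - 1 and a chi-square p-value.  When every
#' value in the pooled sample is identical the statistic is defined as 0
#' with p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return list `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  pooled <- unlist(groups)
  if (length(pooled) < 3) stop("need at least 3 values in total")
  if (diff(range(pooled)) == 0)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Arcsine transform of a proportion
#'
#' The variance-stabilising arcsin(sqrt(p)) by default; `sqrt = FALSE`
#' gives plain arcsin(p).
#'
#' @param p proportions in \[0, 1\].
#' @param sqrt apply the square root first (default TRUE).
#' @return radians in \[0, pi/2\].
#' @export
arcsin_transform <- function(p, sqrt = TRUE) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
  if (sqrt) asin(base::sqrt(p)) else asin(p)
}

#' AICc comparison and averaging of a linear model set
#'
#' Fits an ordinary least-squares model per candidate predictor set (always
#' with intercept), computes AICc = AIC + 2k(k+1)/(n-k-1) with k the number
#' of estimated parameters including the residual variance, ranks by
#' delta-AICc, computes Akaike weights and R-squared, and returns
#' full-model-averaged coefficients (absent terms count as zero, weights
#' summed over all models).  Rows with missing values in the response or
#' any candidate predictor are dropped first so all models share one
#' likelihood sample.  A singular design is skipped with a note.
#'
#' @param data data.frame.
#' @param response response column name.
#' @param candidates list of character vectors of predictor names; use
#'   `character(0)` for the intercept-only model.  Names label the rows.
#' @return list with `table` (model, df, AICc, delta_AICc, weight, r2),
#'   `averaged` (named coefficient vector), `n` (rows used), and `skipped`.
#' @export
aicc_model_set <- function(data, response, candidates) {
  stopifnot(length(candidates) >= 1)
  vars <- unique(c(response, unlist(candidates)))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  n <- nrow(d)
  labels <- names(candidates)
  if (is.null(labels))
    labels <- vapply(candidates, function(p)
      if (length(p) == 0) "Intercept" else paste(p, collapse = " + "),
      character(1))
  rows <- list(); fits <- list(); skipped <- character(0)
  for (i in seq_along(candidates)) {
    preds <- candidates[[i]]
    k <- length(preds) + 2  # coefficients + intercept + sigma
    if (n <= k + 1) { skipped <- c(skipped, labels[i]); next }
    fml <- stats::reformulate(if (length(preds)) preds else "1",
                              response = response)
    fit <- stats::lm(fml, data = d)
    if (any(is.na(stats::coef(fit)))) { skipped <- c(skipped, labels[i]); next }
    aicc <- stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
    rows[[length(rows) + 1]] <- data.frame(
      model = labels[i], df = k, AICc = aicc,
      r2 = summary(fit)$r.squared)
    fits[[length(fits) + 1]] <- fit
  }
  if (!length(rows)) stop("no candidate model could be fitted")
  tab <- do.call(rbind, rows)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta_AICc / 2)
  tab$weight <- tab$weight / sum(tab$weight)
  ord <- order(tab$delta_AICc)
  tab <- tab[ord, c("model", "df", "AICc", "delta_AICc", "weight", "r2")]
  fits <- fits[ord]
  rownames(tab) <- NULL
  # full model-averaged coefficients
  all_terms <- unique(unlist(lapply(fits, function(f) names(stats::coef(f)))))
  avg <- stats::setNames(numeric(length(all_terms)), all_terms)
  for (i in seq_along(fits)) {
    cf <- stats::coef(fits[[i]])
    avg[names(cf)] <- avg[names(cf)] + tab$weight[i] * cf
  }
  list(table = tab, averaged = avg, n = n, skipped = skipped)
}

#' Per-individual morphometrics and habitat-model summary table
#'
#' The bundled study table for 36 adult female Australian fur seals from
#' the Kanowna Island colony (Bass Strait): body mass, standard length,
#' girth, fore-flipper length, axis length and age (NA where unknown); the
#' percent contribution of the seven habitat covariates to each
#' individual's fitted habitat model; the number of 250 m grid cells with
#' intensive foraging; model AUC; and whether distance to an anthropogenic
#' structure was the greatest contributing factor (`structure_top`).  Two
#' individuals had too few dive locations for a model (NA model columns).
#' Derived flipper/standard-length and axis/standard-length ratios are
#' appended.
#'
#' @return data.frame, one row per seal.
#' @export
seal_morphometrics <- function() {
  path <- system.file("extdata", "kanowna_seals.csv", package = "sealforage")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$fl_sl <- d$flipper_cm / d$standard_length_cm
  d$axis_sl <- d$axis_cm / d$standard_length_cm
  d
}
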