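#' Split presence cells into training and evaluation sets
#'
#' Random disjoint 70/30 split (sizes ceiling(0.7 n) / remainder).  With
#' fewer than `min_n` presence cells no reliable model can be built and the
#' individual is refused with a classed error
#' (`sealforage_insufficient_presences`), to be reported and skipped by the
#' caller.
#'
#' @param cells data.frame of presence cells (one row per unique cell).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed (split is reproducible).
#' @param min_n minimum usable presence count (default 5).
#' @return list with `train` and `test` data.frames.
#' @export
partition_data <- function(cells, train_frac = 0.7, seed = 1, min_n = 5) {
  n <- nrow(cells)
  if (n < min_n)
    stop(structure(
      class = c("sealforage_insufficient_presences", "error", "condition"),
      list(message = sprintf("insufficient presence cells (%d < %d) to build a model", n, min_n),
           call = sys.call(-1))))
  idx <- withr::with_seed(seed, sample.int(n, ceiling(train_frac * n)))
  list(train = cells[idx, , drop = FALSE],
       test = cells[-idx, , drop = FALSE])
}

#' Sample background cells from a covariate stack
#'
#' Uniform random grid cells with their covariate values; the background
#' characterises available habitat for the presence-background model.
#'
#' @param stack a [covariate_stack].
#' @param n number of background points (default 10000).
#' @param seed integer seed.
#' @param replace sample with replacement (required if `n` exceeds the cell
#'   count).
#' @return data.frame `row`, `col` plus one column per layer.
#' @export
sample_background <- function(stack, n = 10000, seed = 1, replace = FALSE) {
  g <- stack[[1]]
  ncell <- g$nrow * g$ncol
  if (!replace && n > ncell)
    stop("background size ", n, " exceeds ", ncell,
         " grid cells; set replace = TRUE")
  idx <- withr::with_seed(seed, sample.int(ncell, n, replace = replace))
  row <- ((idx - 1L) %% g$nrow) + 1L
  col <- ((idx - 1L) %/% g$nrow) + 1L
  out <- data.frame(row = row, col = col)
  for (nm in names(stack))
    out[[nm]] <- stack[[nm]]$values[cbind(row, col)]
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Build the scaled feature matrix for a set of rows given per-variable
# background ranges.  Linear features are min-max scaled to [0,1] (clamped
# for out-of-range presences); quadratic features are their squares.
maxent_features <- function(data, variables, scaling, use_quadratic) {
  cols <- list()
  meta <- list()
  for (v in variables) {
    s <- (data[[v]] - scaling$min[v]) / scaling$range[v]
    s <- pmin(1, pmax(0, s))
    cols[[paste0(v, ".lin")]] <- s
    meta[[length(meta) + 1]] <- data.frame(feature = paste0(v, ".lin"),
                                           variable = v, form = "linear")
    if (use_quadratic) {
      cols[[paste0(v, ".quad")]] <- s^2
      meta[[length(meta) + 1]] <- data.frame(feature = paste0(v, ".quad"),
                                             variable = v, form = "quadratic")
    }
  }
  list(F = do.call(cbind, cols), meta = do.call(rbind, meta))
}

#' Fit a presence-background maximum-entropy habitat model
#'
#' Estimates the Gibbs distribution q(x) = exp(w . f(x)) / Z over the
#' background that maximises the L1-regularised training gain
#' \deqn{G(w) = \bar{f}_{pres} \cdot w - \log\frac{1}{m}\sum_{bg} e^{w \cdot f}
#'   - \sum_f \lambda_f |w_f|,}
#' the penalised log-likelihood improvement over the uniform distribution.
#' Features are linear and quadratic terms of each covariate, min-max
#' scaled to \[0,1\] by the background range.  The per-feature penalty is
#' \eqn{\lambda_f = r \beta \, s_f / \sqrt{m}} with class constant
#' \eqn{\beta = 0.05}, \eqn{s_f} the presence standard deviation of the
#' feature and m the presence count.
#'
#' Optimisation is cyclic coordinate ascent: each feature weight takes a
#' soft-thresholded Newton step with backtracking, so the penalised gain
#' never decreases and each accepted step moves exactly one feature —
#' which gives a clean per-variable attribution of gain increments, the
#' basis of the percent-contribution table.
#'
#' @param presences training presence rows (covariate columns).
#' @param background background rows from [sample_background()].
#' @param variables covariate column names (default: the seven stack
#'   layers present in both inputs).
#' @param features "lq" (linear + quadratic, default) or "l".
#' @param r regularisation multiplier (default 1).
#' @param tol convergence threshold on the gain improvement per cycle
#'   (default 1e-5).
#' @param max_iter maximum optimisation cycles (default 1000).
#' @return object of class `maxent_model`.
#' @export
fit_maxent <- function(presences, background,
                       variables = NULL, features = c("lq", "l"),
                       r = 1, tol = 1e-5, max_iter = 1000) {
  features <- match.arg(features)
  if (nrow(presences) == 0) stop("no presence rows")
  if (is.null(variables)) {
    default_vars <- c("depth", "complexity", "d_colony", "d_coast",
                      "d_pipes_cables", "d_wells", "d_shipwrecks")
    variables <- intersect(default_vars,
                           intersect(names(presences), names(background)))
    if (length(variables) == 0)
      variables <- setdiff(intersect(names(presences), names(background)),
                           c("row", "col"))
  }
  bg_min <- vapply(variables, function(v) min(background[[v]]), numeric(1))
  bg_max <- vapply(variables, function(v) max(background[[v]]), numeric(1))
  rng <- pmax(bg_max - bg_min, .Machine$double.eps)
  scaling <- list(min = bg_min, range = rng)
  use_quad <- features == "lq"
  fp <- maxent_features(presences, variables, scaling, use_quad)
  fb <- maxent_features(background, variables, scaling, use_quad)
  Fp <- fp$F; Fb <- fb$F
  meta <- fp$meta
  nf <- ncol(Fp)
  m_pres <- nrow(Fp); m_bg <- nrow(Fb)

  fbar <- colMeans(Fp)
  s_pres <- pmax(apply(Fp, 2, stats::sd), 1e-3)
  lambda <- r * 0.05 * s_pres / sqrt(m_pres)

  w <- numeric(nf)
  eta <- rep(0, m_bg)
  lse <- log(m_bg)
  gain <- function(w, lse) sum(fbar * w) - (lse - log(m_bg)) - sum(lambda * abs(w))
  g_cur <- 0
  gain_by_feature <- numeric(nf)
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    cycle_gain <- 0
    for (f in seq_len(nf)) {
      q <- exp(eta - lse)
      Eq <- sum(q * Fb[, f])
      Vq <- sum(q * Fb[, f]^2) - Eq^2
      grad <- fbar[f] - Eq
      h <- max(Vq, 1e-10)
      z <- w[f] + grad / h
      w_new <- sign(z) * max(abs(z) - lambda[f] / h, 0)
      delta <- w_new - w[f]
      if (abs(delta) < 1e-12) next
      # backtracking: halve the step until the penalised gain improves
      improved <- FALSE
      for (bt in 1:30) {
        eta_try <- eta + delta * Fb[, f]
        lse_try <- logsumexp(eta_try)
        w_try <- w
        w_try[f] <- w[f] + delta
        g_try <- gain(w_try, lse_try)
        if (g_try >= g_cur - 1e-12) { improved <- TRUE; break }
        delta <- delta / 2
      }
      if (!improved) next
      inc <- g_try - g_cur
      w[f] <- w[f] + delta
      eta <- eta_try
      lse <- lse_try
      g_cur <- g_try
      if (inc > 0) gain_by_feature[f] <- gain_by_feature[f] + inc
      cycle_gain <- cycle_gain + max(inc, 0)
    }
    trace <- c(trace, g_cur)
    if (cycle_gain < tol) { converged <- TRUE; break }
  }
  names(w) <- colnames(Fp)
  names(gain_by_feature) <- colnames(Fp)
  structure(list(
    variables = variables, features = meta, weights = w,
    scaling = scaling, lambda = lambda, use_quadratic = use_quad,
    log_z = lse, m_bg = m_bg,
    background = background[, variables, drop = FALSE],
    gain = g_cur, gain_trace = trace, gain_by_feature = gain_by_feature,
    iterations = iter, converged = converged,
    settings = list(r = r, tol = tol, max_iter = max_iter)
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d variables, %d features; gain %.4f after %d cycles (%s)\n",
              length(x$variables), length(x$weights), x$gain, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict from a fitted maximum-entropy model
#'
#' @param object a `maxent_model`.
#' @param newdata data.frame with the model's covariate columns.
#' @param type "link" (the linear predictor w . f(x)) or "raw" (the Gibbs
#'   probability exp(w . f(x)) / Z normalised over the training background,
#'   so raw predictions over that background sum to 1).
#' @param ... unused.
#' @export
predict.maxent_model <- function(object, newdata, type = c("link", "raw"), ...) {
  type <- match.arg(type)
  ff <- maxent_features(newdata, object$variables, object$scaling,
                        object$use_quadratic)
  eta <- as.vector(ff$F %*% object$weights)
  if (type == "link") eta else exp(eta - object$log_z)
}

#' Evaluate a model by presence-vs-background AUC
#'
#' Rank-based area under the ROC curve of model scores for the held-out
#' test presences against the background, with midranks for ties (so a
#' constant score gives 0.5).  Equivalent to the Mann-Whitney U statistic
#' divided by n1 n2.
#'
#' @param model a `maxent_model`.
#' @param test held-out presence rows.
#' @param background background rows.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(model, test, background) {
  if (nrow(test) == 0) stop("empty test set")
  sp <- predict(model, test)
  sb <- predict(model, background)
  rank_auc(sp, sb)
}

# midrank AUC of positive scores vs negative scores
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Percent contribution of each variable
#'
#' Training-gain attribution: every accepted optimiser step moves one
#' feature and changes the penalised gain; positive increments are summed
#' per variable (linear and quadratic features pooled) and normalised to
#' percentages.  A model with zero total gain returns uniform contributions
#' with a warning.
#'
#' @param model a `maxent_model`.
#' @return data.frame `variable`, `contribution` (percent, sums to 100).
#' @export
variable_contribution <- function(model) {
  by_var <- tapply(model$gain_by_feature, model$features$variable, sum)
  by_var <- by_var[model$variables]
  names(by_var) <- model$variables
  by_var[is.na(by_var)] <- 0
  tot <- sum(by_var)
  if (tot <= 0) {
    warning("model has zero total gain; contributions set uniform")
    contrib <- rep(100 / length(by_var), length(by_var))
  } else {
    contrib <- 100 * as.numeric(by_var) / tot
  }
  data.frame(variable = model$variables, contribution = contrib)
}

#' Permutation importance of each variable
#'
#' Cross-check on the gain-based contribution: each variable's values are
#' permuted across the pooled presence + background rows, the AUC of
#' training presences vs background is recomputed, and the drop from the
#' unpermuted AUC is normalised to percentages.
#'
#' @param model a `maxent_model`.
#' @param presences training presence rows.
#' @param background background rows.
#' @param seed integer seed for the permutations.
#' @return data.frame `variable`, `importance` (percent).
#' @export
permutation_importance <- function(model, presences, background, seed = 1) {
  base_auc <- rank_auc(predict(model, presences), predict(model, background))
  np <- nrow(presences)
  drops <- withr::with_seed(seed, vapply(model$variables, function(v) {
    pooled <- c(presences[[v]], background[[v]])
    perm <- sample(pooled)
    p2 <- presences; b2 <- background
    p2[[v]] <- perm[seq_len(np)]
    b2[[v]] <- perm[-seq_len(np)]
    max(0, base_auc - rank_auc(predict(model, p2), predict(model, b2)))
  }, numeric(1)))
  tot <- sum(drops)
  imp <- if (tot > 0) 100 * drops / tot else rep(100 / length(drops), length(drops))
  data.frame(variable = model$variables, importance = as.numeric(imp))
}

#' Dump a fitted model to JSON
#'
#' @param model a `maxent_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    variables = model$variables,
    features = model$features,
    weights = as.list(model$weights),
    scaling = list(min = as.list(model$scaling$min),
                   range = as.list(model$scaling$range)),
    log_z = model$log_z,
    gain = model$gain,
    iterations = model$iterations,
    converged = model$converged,
    settings = model$settings
  ), path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}
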